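# ctvent

Robust CT-ventilation imaging from a paired exhale/inhale CT scan and a
deformable-registration displacement field, for researchers in functional
lung imaging and radiotherapy planning.

Regional lung ventilation is estimated as the Jacobian determinant field
det J(x) of the exhale-to-inhale transformation φ. Rather than
differentiating the registration field voxel-wise (which is highly
sensitive to the registration algorithm), the package measures volume
change over subregions Ω_k grown until a statistical uncertainty tolerance
τ is met, using either of two estimators:

* **IJF** (transformation-based): hit-or-miss Monte Carlo —
  ∫_Ω det J ≈ H, the number of target-lung voxels whose inverse-mapped
  position lands in Ω; accepted when 1.96·√(H(1−H/M))/H ≤ τ.
* **MCVC** (intensity-based): mass conservation —
  ∫_Ω det J ≈ (R̄_Ω / T̄_φ(Ω)) · |Ω| from HU-derived densities; accepted
  when both sample means meet the tolerance.

The voxel field is parameterized by Shepard moving least squares over
dart-thrown knots, v = Cq, and the knot values solve the constrained
least-squares problem

    min_q ‖Âq − b‖² + λ Σ_k (q_k − h/N)²   s.t.  1ᵀCq = h,  q ≥ ε,

whose equality constraint enforces consistency with the whole-lung volume
change h and whose bounds guarantee a strictly positive Jacobian field.
A synthetic phantom generator with analytically known Jacobians, an
evaluation harness (affine resampling, 3×3 median filtering, masked
Spearman correlation, τ sweeps, exact Wilcoxon signed-rank tests) and
NIfTI-1/MetaImage I/O complete the toolchain. See the methods vignette
(`vignettes/ctvent-methods.Rmd`) for the models, parameter defaults and
known discretization limits.

## Worked example

```r
library(ctvent)

# synthetic inhale/exhale case with a known sinusoidal Jacobian field
spec <- phantom_spec(deformation = list(type = "sinusoid",
                                        amplitude_mm = 2, wavelength_mm = 40))
case <- generate_phantom(spec)

# transformation-based reconstruction at tolerance 0.07
res <- compute_ventilation(case, method = "ijf", tau = 0.07, seed = 1)
res
#> <ventilation_result> IJF: 152 knots, residual 3026, constraint gap 5e-15
#>   field range [0.2424, 3.441], 97 bound-active knots

# agreement with the analytic Jacobian field
v_true <- case$true_jacobian$data[case$mask_R$data]
cor(res$v, v_true, method = "spearman")
#> [1] 0.8121494

# summary statistics of the published 15-patient correlation table
st <- correlation_table_stats()
st$summary
#>   method  n   min  q25 median  q75  max
#> 1    ijf 15  0.12 0.44   0.82 0.86 0.90
#> 2   mcvc 15 -0.06 0.08   0.48 0.62 0.84
st$wilcoxon$p_value
#> [1] 0.003356934
```

The reconstruction recovers the imposed expansion/compression pattern
(rank correlation ≈ 0.81 against the analytic field on the deliberately
coarse default phantom grid; ≥ 0.94 across the τ ∈ [0.03, 0.15] window on
the resolution-matched phantom the acceptance suite uses — see the
vignette on why subregion size is a voxel count). The table statistics
reproduce the published per-method medians and ranges, and the exact
paired signed-rank test confirms the transformation-based method's higher
correlations.

A thin CLI wrapping these functions is installed at
`inst/cli/ctvent` (`phantom`, `run`, `sweep`, `correlate`, `table-stats`
verbs; YAML configuration files, NIfTI-1/MetaImage volumes).

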