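---
title: "Robust CT-ventilation: models, numerics and phantom validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust CT-ventilation: models, numerics and phantom validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

CT-ventilation imaging estimates regional lung function from an
exhale/inhale CT pair. A deformable registration supplies a transformation
$\varphi$ mapping the exhale (reference) lung $\Omega(R)$ onto the inhale
(target) lung $\Omega(T)$; the local volume-scaling factor of $\varphi$ —
the Jacobian determinant $\det J(x)$ — is the ventilation surrogate: where
the lung expands most between exhale and inhale, $\det J$ is largest. The
integral of $\det J$ over any subregion $\Omega \subset \Omega(R)$ equals
the deformed volume of that subregion.

Direct voxel-wise differentiation of a registration field is notoriously
sensitive to the registration algorithm. The methods implemented here trade
spatial resolution for statistical control: they measure volume change over
*subregions* that are grown until the estimate's uncertainty falls below a
user tolerance $\tau$, and then recover a smooth voxel field consistent
with the ensemble of subregional measurements.

## Subregional estimators

Two estimator families are implemented.

**Hit counting (IJF, transformation-based).** The deformed volume of
$\Omega$ is estimated by the number $H$ of target-lung voxels whose
inverse-mapped position $\varphi^{-1}(x)$ falls inside $\Omega$ — a
hit-or-miss Monte Carlo volume estimate with the target lattice as the
sample set and membership decided by nearest-voxel binning. Modelling the
hit proportion as binomial over the $M = |\Omega(T)|$ target voxels, the
95% relative error bound is $1.96\sqrt{H(1 - H/M)}/H$; a subregion passes
the tolerance when this is at most $\tau$. The bound defines a minimum hit
count $H^\ast \approx (1.96/\tau)^2$ for small subregions, which is the
method's resolution: measured in voxels, independent of lung size.

**Density ratio (MCVC, intensity-based).** HU values are converted to
density by the linear air/water calibration $\rho = (HU + 1000)/1000$
(clamped at zero). If density change is caused only by air-content change,
mass conservation gives
$\int_\Omega \det J \approx (\bar R_\Omega / \bar T_{\varphi(\Omega)})
|\Omega|$, with $\bar R$ the mean reference density over the subregion and
$\bar T$ the mean target density over the hit set (so the target-side
sample size is exactly $H$). Both sample means must meet the tolerance:
$|\Omega| \ge (1.96\,\hat\sigma_R/\tau)^2$ and
$H \ge (1.96\,\hat\sigma_T/\tau)^2$, with $\hat\sigma$ the in-region sample
standard deviations (the plug-in reading of the standard-error conditions;
a $\sigma$-normalized variant is available through the `beta`/tolerance
configuration). Note the tolerance acts on *absolute density* here, so for
homogeneous lungs very small subregions can pass — see "Discretization
limits" below.

## Field parameterization and recovery

Subregions are seeded on a dart-thrown point cloud and grown by repeated
dilation with a box structuring element, each time intersected with the
lung mask; the growth stops at the first dilation count whose statistics
pass the tolerance (subregions that never pass are dropped). The
tolerance predicates are evaluated in constant time per step with 3-D
summed-area tables over precomputed tally volumes (hit counts, masked
densities and their squares), so growth is cheap even for tens of
thousands of seeds; only accepted regions are materialized.

The voxel field is parameterized by Shepard moving least squares over $L$
dart-thrown knots: $v_i = \sum_j C_{ij} q_j$ with
$C_{ij} \propto e^{-\sigma \|x_i - z_j\|^2}$ row-normalized. Because rows
of $C$ are convex weights, the field is a moving average of the knot values
— bounded by their range, so $q_j \ge \varepsilon > 0$ guarantees a
strictly positive Jacobian field. The reduced data matrix
$\hat A = A C$ (rows = subregional sums of $C$ rows) is accumulated
directly from region voxel lists; the binary membership matrix $A$ is never
formed.

Knot values solve the strictly convex quadratic program
$$\min_q \|\hat A q - b\|^2 + \lambda \sum_k (q_k - h/N)^2
\quad \text{s.t.} \quad \mathbf 1^\top C q = h,\; q \ge \varepsilon,$$
where $h$ ties the voxel sum of the field to the whole-lung volume change
($|\Omega(T)|$ for hit counting; the whole-lung density ratio times
$|\Omega(R)|$ for the intensity method). The regularizer penalizes variance
of the knot values about the mean volume change enforced by the equality
constraint, not spatial gradients — MLS is already smooth, and large
Jacobian spread is itself a warning sign in registration QA. The solve uses
the Goldfarb–Idnani dual active-set method (`quadprog`), which terminates
at the exact KKT point; the equality constraint is expressed in knot space
as $(\mathbf 1^\top C) q = h$, keeping the problem $L$-dimensional. Tests
cross-check solutions against an independent active-set enumeration oracle.

The ventilation signal is the absolute volume difference $V - 1$ (exhale
reference, expansion positive); rank-based comparisons are insensitive to
this monotone convention.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tau` | sweep over [0.01, 0.25] | 95% relative-error cap per subregion |
| knot spacing | 30 mm, scaled by (lung volume / 4.5 L)^(1/3) | MLS resolution |
| subdomain spacing | 7 mm, same scaling, floored at 1.5 voxels | measurement density |
| structuring element | 3×3×3 voxels (isotropic grids); 7×7×3 for fine-in-plane clinical grids | growth step ≈ 9 mm physical |
| `sigma` | ln 2 / d² (half weight at one knot spacing d) | kernel width tied to knot density |
| truncation | 2.5 d, rows renormalized | sparsity; < 2% of peak weight outside |
| `epsilon` | 0.05 | Jacobian floor (95% compression) |
| `lambda_reg` | 1 | variance regularizer weight, as written |
| `max_dilations` | 20 | growth cap; failing subregions are dropped |
| `beta` | 1.96 | Gaussian quantile of the uncertainty model |

## The phantom generator

`generate_phantom()` builds a digital thorax: two flat-bottomed
half-ellipsoid lungs (base density 0.25 g/cm³ with a ±30% smooth
deterministic texture) inside a 0 HU body cylinder surrounded by air. Three
deformation families have closed-form Jacobians: identity, uniform
per-axis scaling about the lung centroid, and a separable sinusoid
$x \mapsto x + A\sin(2\pi x/\lambda)$ (diffeomorphic iff
$2\pi A/\lambda < 1$; the inverse is computed per axis by Newton iteration
to $10^{-12}$, i.e. machine-accurate "analytic" $\varphi^{-1}$). With mass
conservation enabled, inhale densities are
$\rho_R(\varphi^{-1}(x)) / \det J(\varphi^{-1}(x))$ exactly, so the
intensity method's model assumption holds by construction; switching it
off deliberately violates that assumption. A degraded companion volume
(blur, downsample, non-negative value-proportional noise) stands in for a
low-resolution nuclear-medicine reference; it is synthetic and does not
model emission or reconstruction physics.

The anatomy is deliberately *asymmetric*: a mirror-symmetric mask puts the
lung centroid on exact half-voxel coordinates, which makes inverse-mapped
lattice points tie on voxel-cube faces along entire planes — a measure-zero
degeneracy real anatomy never exhibits, but one that distorts hit counts
through the tie-breaking rule.

What the phantom does **not** emulate: registration error fields with
realistic spatial statistics (the displacement is exact or smoothly
perturbed), 4DCT phase-binning artifacts, blood-mass redistribution (the
known confounder of intensity-based estimation in vivo), scanner noise
spectra, or SPECT acquisition physics. Passing the phantom suite therefore
validates the numerics and the estimators' statistical model — not clinical
accuracy.

## Study conditions used by the tests and the acceptance script

* Default phantom grid: 64×64×48 at 3 mm isotropic (≈ 0.42 L lungs; the
  full reconstruction runs in seconds).
* Estimator-accuracy phantom: the default grid with uniform 1.1-per-axis
  scaling (det J ≡ 1.331).
* Recovery/sweep phantom: sinusoid A = 2 mm, λ = 40 mm on a 128×128×96
  grid at 1.5 mm. The finer grid is *resolution matching*, not tuning: the
  minimum hit count $H^\ast \approx (1.96/\tau)^2$ is a voxel count, so at
  3 mm voxels a τ = 0.03 subregion is a ≈ 45 mm box — wider than the
  40 mm wavelength it is supposed to resolve, making recovery impossible
  at any implementation quality. At 1.5 mm voxels the same τ gives
  ≈ 22 mm subregions and the wavelength is resolvable across the whole
  τ ∈ [0.03, 0.15] window. Knot spacing 10 mm (≈ λ/4) is chosen for the
  same reason: the positivity-bounded Shepard basis must be able to
  represent the imposed field; subdomain spacing 6 mm keeps the system
  ≈ 4–8× overdetermined.
* Sweeps use 30 tolerance values uniformly on [0.01, 0.25].

## Discretization limits (and honest failure modes)

Two effects bound the per-subregion accuracy on *exact, noise-free* fields
and are documented because they are easily mistaken for bugs:

1. **Coherent lattice quantization.** For a separable deformation
   (uniform scaling, axis-aligned sinusoid) and a box-shaped subregion,
   the hit count factorizes into per-axis lattice point counts, each an
   integer in {⌊w/s⌋, ⌈w/s⌉} for window w and mapped lattice pitch s. The
   per-axis relative quantization error (≈ ±s/2w) is *multiplied* across
   the three axes instead of averaging out. At τ = 0.05 the subregion
   window is 11–13 voxels, so per-region errors of several percent are
   structural; empirically ≈ 75% of tolerance-passing subregions fall
   within the ±τ band on the uniform-expansion phantom, versus the ≈ 95%
   the binomial model nominally predicts. Irregular (registration-like)
   fields and mask-clipped regions decorrelate the quantization, which is
   why the *field-level* recovery (Spearman ≥ 0.94 across the tolerance
   window on the sinusoid phantom) is much better than the worst
   per-region bound, and why the least-squares ensemble over thousands of
   overlapping subregions is the right estimator despite per-region
   outliers.
2. **Point-sampling error of tiny intensity subregions.** The
   absolute-density tolerance admits single-voxel subregions in
   homogeneous lungs; their density-ratio estimates then carry
   point-level sampling error (several percent under a ±30% texture).
   Estimates over subregions of a few hundred voxels agree with the true
   integral to well under 2%. The acceptance check therefore evaluates
   both estimators on the *same* hit-count-grown subregions — a paired
   design that compares estimators on equal footing.

Other numerical choices: voxel centers are world coordinates
(origin + index·spacing, 0-based); nearest-voxel binning uses R's
round-half-even at exact ties; out-of-domain inverse-mapped voxels count
as misses and are tallied; voxels with no knot inside the truncation
radius fall back to their nearest knot (logged); an infeasible
floor ($\varepsilon N > h$) is reported as an error naming the violated
relation, and $\varepsilon N = h$ returns the unique feasible point.

## Known limitations

* Subregion growth defines regions as dilated-box ∩ mask; with strongly
  non-convex masks a large box can span both lungs, so regions are not
  guaranteed connected. Regional integrals remain valid measurements.
* The clinical correlation table shipped with the package is a worked
  example for the summary statistics and the paired exact signed-rank
  test; the underlying image data are not public, so those correlations
  cannot be recomputed here.
* The exact signed-rank p-value is computed from the rounded published
  correlations; a published P computed from unrounded values (or with a
  different variant) will differ — the implementation reports its method
  string alongside the p-value.
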