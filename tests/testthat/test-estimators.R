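test_that("HU to density follows the linear air/water calibration", {
  vol <- image_volume(array(c(-1000, 0, -700, -1024, 500, -300), c(1, 2, 3)))
  rho <- hu_to_density(vol)
  expect_equal(as.numeric(rho$data), c(0, 1, 0.3, 0, 1.5, 0.7))
})

test_that("identity mapping makes every region voxel its own hit", {
  case <- identity_phantom()
  hm <- build_hit_map(case$inverse_displacement, case$mask_T, case$mask_R)
  expect_equal(hm$M, sum(case$mask_T$data))
  expect_equal(hm$n_outside, 0L)
  idx <- which(case$mask_R$data)[200:400]
  hits <- count_hits(idx, hm)
  expect_equal(hits$H, length(idx))
  expect_setequal(hits$hit_indices, idx)
  # region fully outside the deformed lung catches nothing
  outside <- which(!case$mask_R$data)[1:50]
  expect_equal(count_hits(outside, hm)$H, 0L)
})

test_that("hit counts match a brute-force enumeration on the analytic field", {
  case <- scaling_phantom()
  prep <- scaling_prep_ijf()
  hm <- prep$hit_map
  # oracle: test every target lung voxel against the region's voxel cubes
  geom <- ctvent:::grid_geometry(case$mask_T)
  Xt <- ctvent:::world_coordinate_matrix(geom, hm$target_lin)
  Y <- ctvent:::phantom_phi_inverse(case$spec, Xt,
                                    ctvent:::deformation_center(case$spec))
  half_sp <- case$mask_R$spacing / 2
  set.seed(31)
  for (rep in 1:4) {
    ctr <- prep$seed_ijk[sample(nrow(prep$seed_ijk), 1), ]
    idx <- ctvent:::box_mask_indices(case$mask_R$data, ctr, c(1L, 1L, 1L), 5)
    centers <- ctvent:::world_coordinate_matrix(geom, idx)
    H_oracle <- 0L
    lo <- apply(centers, 2, min) - half_sp
    hi <- apply(centers, 2, max) + half_sp
    cand <- which(Y[, 1] >= lo[1] & Y[, 1] < hi[1] & Y[, 2] >= lo[2] &
                    Y[, 2] < hi[2] & Y[, 3] >= lo[3] & Y[, 3] < hi[3])
    for (t in cand) {
      inside <- abs(centers[, 1] - Y[t, 1]) <= half_sp[1] &
        abs(centers[, 2] - Y[t, 2]) <= half_sp[2] &
        abs(centers[, 3] - Y[t, 3]) <= half_sp[3]
      if (any(inside)) H_oracle <- H_oracle + 1L
    }
    expect_equal(count_hits(idx, hm)$H, H_oracle)
  }
})

test_that("hit-count uncertainty criterion reproduces worked values", {
  expect_equal(ijf_uncertainty(2000, 1e6), 1.96 * sqrt(2000 * 0.998) / 2000,
               tolerance = 1e-12)
  expect_lt(ijf_uncertainty(2000, 1e6), 0.05)   # tolerance met at tau = 0.05
  est <- ijf_estimate(integer(0), structure(
    list(counts = array(0, c(2, 2, 2)), M = 100, reference_dims = c(2, 2, 2),
         mapped_lin = integer(0), target_lin = integer(0)),
    class = "hit_map"), tau = 0.5)
  expect_false(est$tolerance_met)   # H = 0 never passes
  expect_equal(ijf_uncertainty(100, 1e6), 0.196, tolerance = 1e-3)
})

test_that("large interior regions estimate the uniform expansion within tolerance", {
  prep <- scaling_prep_ijf()
  case <- scaling_phantom()
  tau <- 0.05
  set.seed(13)
  n_ok <- 0; n_tot <- 0
  for (i in sample(nrow(prep$seed_ijk), 40)) {
    idx <- ctvent:::box_mask_indices(case$mask_R$data, prep$seed_ijk[i, ],
                                     prep$half, 6)
    est <- ijf_estimate(idx, prep$hit_map, tau)
    if (!est$tolerance_met) next
    n_tot <- n_tot + 1
    ratio <- est$value / est$size
    if (abs(ratio - 1.331) <= tau * 1.331) n_ok <- n_ok + 1
  }
  expect_gt(n_tot, 20)
  # most sizeable regions land inside the tolerance band; exact lattice
  # quantization keeps this below the Gaussian-model nominal rate
  expect_gt(n_ok / n_tot, 0.6)
})

test_that("intensity estimates reduce to region size under identity", {
  case <- identity_phantom()
  hm <- build_hit_map(case$inverse_displacement, case$mask_T, case$mask_R)
  rho_R <- hu_to_density(case$reference_image)
  rho_T <- hu_to_density(case$target_image)
  idx <- which(case$mask_R$data)[500:900]
  est <- mcvc_estimate(idx, rho_R, rho_T, hm, tau = 0.05)
  expect_equal(est$value, length(idx), tolerance = 1e-12)
  expect_true(est$tolerance_met)
})

test_that("intensity estimates recover the mass-conserving expansion within 2 percent", {
  case <- scaling_phantom()
  hm <- build_hit_map(case$inverse_displacement, case$mask_T, case$mask_R)
  rho_R <- hu_to_density(case$reference_image)
  rho_T <- hu_to_density(case$target_image)
  prep <- scaling_prep_ijf()
  set.seed(17)
  for (i in sample(nrow(prep$seed_ijk), 10)) {
    idx <- ctvent:::box_mask_indices(case$mask_R$data, prep$seed_ijk[i, ],
                                     c(1L, 1L, 1L), 5)
    est <- mcvc_estimate(idx, rho_R, rho_T, hm, tau = 0.05)
    expect_equal(est$value, 1.331 * length(idx), tolerance = 0.02)
  }
})

test_that("constant densities have zero standard error and always pass", {
  d <- c(10, 10, 10)
  ident <- array(0, c(d, 3))
  mask <- image_volume(array(TRUE, d), c(1, 1, 1))
  hm <- build_hit_map(displacement_field(ident, c(1, 1, 1)), mask, mask)
  rho <- image_volume(array(0.4, d), c(1, 1, 1))
  est <- mcvc_estimate(which(mask$data)[1:2], rho, rho, hm, tau = 1e-6)
  expect_true(est$tolerance_met)
  expect_equal(est$value, 2)
})

test_that("estimates are invariant to voxel visit order", {
  prep <- scaling_prep_ijf()
  case <- scaling_phantom()
  idx <- ctvent:::box_mask_indices(case$mask_R$data, prep$seed_ijk[10, ],
                                   c(1L, 1L, 1L), 4)
  set.seed(2)
  perm <- sample(idx)
  a <- ijf_estimate(idx, prep$hit_map, 0.05)
  b <- ijf_estimate(perm, prep$hit_map, 0.05)
  expect_equal(a$value, b$value)
  expect_equal(a$tolerance_met, b$tolerance_met)
})
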