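test_that("identity deformation gives unit Jacobian and identical images", {
  case <- identity_phantom()
  expect_true(all(case$true_jacobian$data[case$mask_R$data] == 1))
  expect_identical(case$reference_image$data, case$target_image$data)
  expect_identical(case$mask_R$data, case$mask_T$data)
  expect_true(all(case$inverse_displacement$data == 0))
})

test_that("uniform scaling gives the product of axis scales everywhere", {
  case <- scaling_phantom()
  expect_equal(unique(as.numeric(case$true_jacobian$data)), 1.331,
               tolerance = 1e-12)
  spec2 <- phantom_spec(deformation = list(type = "uniform_scale",
                                           scale = c(2, 1, 1)))
  expect_equal(analytic_jacobian(spec2, c(10, 20, 30)), 2)
  expect_equal(analytic_jacobian(phantom_spec(), c(0, 0, 0)), 1)
})

test_that("analytic sinusoid Jacobian matches Richardson-refined finite differences", {
  spec <- sinusoid_phantom()$spec
  set.seed(11)
  X <- cbind(runif(20, 20, 160), runif(20, 20, 160), runif(20, 20, 120))
  fd_det <- function(X, step) {
    J <- matrix(1, nrow(X), 1)
    out <- numeric(nrow(X))
    for (r in seq_len(nrow(X))) {
      Jm <- matrix(0, 3, 3)
      for (dcol in 1:3) {
        e <- c(0, 0, 0); e[dcol] <- step
        fp <- ctvent:::phantom_phi(spec, matrix(X[r, ] + e, 1))
        fm <- ctvent:::phantom_phi(spec, matrix(X[r, ] - e, 1))
        Jm[, dcol] <- (fp - fm) / (2 * step)
      }
      out[r] <- det(Jm)
    }
    out
  }
  h <- spec$spacing_mm[1] / 100
  richardson <- (4 * fd_det(X, h / 2) - fd_det(X, h)) / 3
  expect_equal(analytic_jacobian(spec, X), richardson, tolerance = 1e-6)
})

test_that("analytic Jacobian agrees with lattice finite differences of the inverse map", {
  # differentiate the stored inverse displacement on the voxel lattice and
  # invert: det J_phi(phi^-1(x)) * det J_{phi^-1}(x) = 1
  case <- sinusoid_phantom()
  u <- case$inverse_displacement
  d <- dim(u$data)[1:3]
  inner <- as.matrix(expand.grid(i = 5:(d[1] - 4), j = 5:(d[2] - 4),
                                 k = 5:(d[3] - 4)))
  sp <- u$spacing
  set.seed(21)
  for (r in sample(nrow(inner), 25)) {
    ijk <- inner[r, ]
    Jm <- diag(3)
    for (dcol in 1:3) {
      e <- c(0L, 0L, 0L); e[dcol] <- 1L
      for (comp in 1:3) {
        up <- u$data[ijk[1] + e[1], ijk[2] + e[2], ijk[3] + e[3], comp]
        um <- u$data[ijk[1] - e[1], ijk[2] - e[2], ijk[3] - e[3], comp]
        Jm[comp, dcol] <- (comp == dcol) + (up - um) / (2 * sp[dcol])
      }
    }
    x <- u$origin + (ijk - 1) * sp
    y <- ctvent:::phantom_phi_inverse(case$spec, matrix(x, 1))
    # the lattice-step difference quotient attenuates each axis derivative
    # by sinc(2*pi*step/lambda) ~ 0.96; compounded over three axes near the
    # compression extremes this allows discrepancies up to ~6%
    expect_equal(1 / det(Jm), analytic_jacobian(case$spec, y),
                 tolerance = 8e-2)
  }
})

test_that("mass conservation holds point-wise before noise", {
  # density_T(x) * detJ(phi^-1(x)) == density_R(phi^-1(x)) inside the lung
  case <- scaling_phantom()
  sel <- which(case$mask_T$data)[1:500]
  geom <- ctvent:::grid_geometry(case$target_image)
  X <- ctvent:::world_coordinate_matrix(geom, sel)
  Y <- ctvent:::phantom_phi_inverse(case$spec, X,
                                    ctvent:::deformation_center(case$spec))
  rho_T <- (case$target_image$data[sel] + 1000) / 1000
  rho_R_at_Y <- ctvent:::phantom_density(case$spec, Y)
  expect_equal(rho_T * analytic_jacobian(case$spec, Y), rho_R_at_Y,
               tolerance = 1e-10)
})

test_that("global volume bookkeeping closes within 2 percent", {
  for (case in list(scaling_phantom(), sinusoid_phantom())) {
    expect_lt(case$volume_bookkeeping[["relative_gap"]], 0.02)
  }
})

test_that("same seed gives byte-identical phantoms", {
  spec <- phantom_spec(hu_noise_sd = 25, seed = 77)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$reference_image$data, b$reference_image$data)
  expect_identical(a$target_image$data, b$target_image$data)
  expect_identical(a$spect_like_reference$data, b$spect_like_reference$data)
})

test_that("non-diffeomorphic or aliased sinusoid specs are rejected", {
  expect_error(phantom_spec(deformation = list(type = "sinusoid",
                                               amplitude_mm = 10,
                                               wavelength_mm = 40)),
               "diffeomorphic")
  expect_error(phantom_spec(deformation = list(type = "sinusoid",
                                               amplitude_mm = 0.1,
                                               wavelength_mm = 10)),
               "alias")
  expect_error(phantom_spec(deformation = list(type = "vortex")), "unknown")
  expect_error(phantom_spec(grid_dims = c(8, 64, 64)), "16")
})

test_that("degrading to a reference is identity when nothing is degraded", {
  vol <- image_volume(array(runif(16 * 16 * 8), c(16, 16, 8)), c(2, 2, 2))
  out <- degrade_to_reference(vol, c(2, 2, 2), blur_fwhm_mm = 0, noise_cv = 0)
  expect_equal(out$data, vol$data, tolerance = 1e-12)
})

test_that("degrading preserves constants before noise", {
  vol <- image_volume(array(1.331, c(24, 24, 12)), c(2, 2, 2))
  out <- degrade_to_reference(vol, c(5, 5, 5), blur_fwhm_mm = 8, noise_cv = 0)
  expect_equal(unique(round(as.numeric(out$data), 10)), 1.331)
  expect_error(degrade_to_reference(vol, c(-1, 5, 5)), "positive")
  expect_error(degrade_to_reference(vol, c(1, 1, 1)), "finer")
})

test_that("phantom specs round-trip through the text configuration format", {
  spec <- phantom_spec(deformation = list(type = "sinusoid",
                                          amplitude_mm = c(2, 1, 2),
                                          wavelength_mm = c(40, 50, 60)),
                       hu_noise_sd = 10, seed = 3L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(spec, f)
  expect_equal(read_phantom_spec(f), spec)
})

test_that("displacement perturbation has the requested scale and smoothness", {
  case <- identity_phantom()
  pd <- perturb_displacement(case$inverse_displacement, sd_voxels = 0.5,
                             correlation_mm = 15, seed = 4)
  for (comp in 1:3) {
    s <- sd(pd$data[, , , comp])
    expect_equal(s, 0.5 * 3, tolerance = 0.05)  # 0.5 voxels of 3 mm
    # smoothness: neighbouring voxels are strongly correlated
    a <- pd$data[1:63, , , comp]; b <- pd$data[2:64, , , comp]
    expect_gt(cor(as.numeric(a), as.numeric(b)), 0.9)
  }
})
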