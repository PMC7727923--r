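#' Specification of a synthetic inhale/exhale phantom
#'
#' Defines a digital thorax phantom: a pair of flat-bottomed half-ellipsoid
#' "lungs" inside a soft-tissue cylinder (0 HU) surrounded by air (-1000 HU),
#' deformed by an analytically known diffeomorphism so that the Jacobian
#' determinant of the exhale-to-inhale map is available in closed form at
#' every point. The exhale frame is the reference: ventilation is computed on
#' it, and expansion deformations give Jacobians above one.
#'
#' Deformation families:
#' * `list(type = "identity")`
#' * `list(type = "uniform_scale", scale = c(sx, sy, sz))` — scaling about the
#'   reference lung-mask centroid.
#' * `list(type = "sinusoid", amplitude_mm = A, wavelength_mm = lambda)` —
#'   separable per-axis map `x -> x + A_d sin(2 pi x_d / lambda_d)`;
#'   requires `2 pi A / lambda < 1` on every axis so the map stays
#'   diffeomorphic, and wavelengths of at least 4 voxels to avoid aliasing.
#'
#' @param grid_dims integer triple, at least 16 per axis. Default 64 x 64 x 48.
#' @param spacing_mm positive triple (mm). Default 3 mm isotropic.
#' @param deformation a list describing the deformation (see Details).
#' @param base_density mean lung tissue density in g/cm^3, in (0, 1].
#' @param density_texture_amplitude relative amplitude (in \[0, 1)) of the
#'   smooth deterministic density texture superimposed on the lungs; a value
#'   of 0 gives homogeneous lungs.
#' @param hu_noise_sd standard deviation of additive Gaussian HU noise applied
#'   to both images (0 = noise free).
#' @param mass_conserving logical; if `TRUE` the inhale densities are
#'   constructed so that `density_T(phi(x)) * detJ(x) = density_R(x)` exactly
#'   before noise, the assumption under which intensity-based estimation is
#'   exact. If `FALSE` the inhale image keeps the exhale densities (a
#'   deliberate violation).
#' @param seed integer seed controlling all phantom randomness.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(64, 64, 48),
                         spacing_mm = c(3, 3, 3),
                         deformation = list(type = "identity"),
                         base_density = 0.25,
                         density_texture_amplitude = 0.3,
                         hu_noise_sd = 0,
                         mass_conserving = TRUE,
                         seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 16L))
    stop("'grid_dims' must be an integer triple with at least 16 voxels per axis")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be a positive triple")
  if (!is.list(deformation) || is.null(deformation$type))
    stop("'deformation' must be a list with a 'type' element")
  if (!deformation$type %in% c("identity", "uniform_scale", "sinusoid"))
    stop(sprintf("unknown deformation family '%s'", deformation$type))
  if (deformation$type == "uniform_scale") {
    s <- rep_len(as.numeric(deformation$scale), 3L)
    if (any(s <= 0)) stop("scale factors must be positive")
    deformation$scale <- s
  }
  if (deformation$type == "sinusoid") {
    A <- rep_len(as.numeric(deformation$amplitude_mm), 3L)
    lam <- rep_len(as.numeric(deformation$wavelength_mm), 3L)
    if (any(lam <= 0) || any(A < 0)) stop("invalid sinusoid parameters")
    if (any(2 * pi * A / lam >= 1))
      stop("sinusoid is not diffeomorphic: need 2*pi*A/lambda < 1 on every axis")
    if (any(lam < 4 * spacing_mm))
      stop("sinusoid wavelength below 4 voxels would alias")
    deformation$amplitude_mm <- A
    deformation$wavelength_mm <- lam
  }
  if (!is.numeric(base_density) || base_density <= 0 || base_density > 1)
    stop("'base_density' must lie in (0, 1]")
  if (density_texture_amplitude < 0 || density_texture_amplitude >= 1)
    stop("'density_texture_amplitude' must lie in [0, 1)")
  if (hu_noise_sd < 0) stop("'hu_noise_sd' must be non-negative")
  structure(list(grid_dims = grid_dims, spacing_mm = spacing_mm,
                 deformation = deformation, base_density = base_density,
                 density_texture_amplitude = density_texture_amplitude,
                 hu_noise_sd = hu_noise_sd,
                 mass_conserving = isTRUE(mass_conserving),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_geometry <- function(spec) {
  list(dims = spec$grid_dims, spacing = spec$spacing_mm, origin = c(0, 0, 0))
}

phantom_extent <- function(spec) (spec$grid_dims - 1) * spec$spacing_mm

# analytic anatomy indicators, defined in world coordinates so masks and
# images remain consistent under point-wise evaluation at mapped positions
phantom_anatomy <- function(spec) {
  ext <- phantom_extent(spec)
  # deliberately asymmetric (as real anatomy is): a perfectly symmetric
  # phantom puts the mask centroid on exact half-voxel coordinates, which
  # makes inverse-mapped points tie on voxel boundaries along whole planes
  lungs <- list(
    list(center = c(0.2832, 0.4965, 0.5241) * ext,
         semi = c(0.1447, 0.2031, 0.3618) * ext),
    list(center = c(0.7181, 0.5043, 0.5172) * ext,
         semi = c(0.1421, 0.1962, 0.3549) * ext))
  body_center <- c(0.5, 0.5, 0.5) * ext
  body_radius <- 0.45 * min(ext[1], ext[2])
  lung_ind <- function(X) {
    inside <- rep(FALSE, nrow(X))
    for (lg in lungs) {
      q <- ((X[, 1] - lg$center[1]) / lg$semi[1])^2 +
        ((X[, 2] - lg$center[2]) / lg$semi[2])^2 +
        ((X[, 3] - lg$center[3]) / lg$semi[3])^2
      # flat "diaphragm" cut below the ellipsoid center
      inside <- inside | (q <= 1 & X[, 3] >= lg$center[3] - 0.75 * lg$semi[3])
    }
    inside
  }
  body_ind <- function(X) {
    (X[, 1] - body_center[1])^2 + (X[, 2] - body_center[2])^2 <= body_radius^2
  }
  list(lung = lung_ind, body = body_ind)
}

# smooth deterministic density texture in [-1, 1]; fixed incommensurate
# wavelengths give non-constant, rank-rich structure without randomness
phantom_texture <- function(X) {
  sin(2 * pi * X[, 1] / 61 + 0.9) *
    sin(2 * pi * X[, 2] / 47 + 2.0) *
    sin(2 * pi * X[, 3] / 71 + 4.2)
}

phantom_density <- function(spec, X) {
  spec$base_density * (1 + spec$density_texture_amplitude * phantom_texture(X))
}

density_to_hu <- function(rho) 1000 * rho - 1000

deformation_center <- function(spec) {
  geom <- phantom_geometry(spec)
  anat <- phantom_anatomy(spec)
  X <- world_coordinate_matrix(geom)
  m <- anat$lung(X)
  colMeans(X[m, , drop = FALSE])
}

# forward map phi (reference -> target), applied row-wise
phantom_phi <- function(spec, Y, center = NULL) {
  def <- spec$deformation
  switch(def$type,
         identity = Y,
         uniform_scale = {
           if (is.null(center)) center <- deformation_center(spec)
           sweep(sweep(Y, 2, center) %*% diag(def$scale), 2, center, "+")
         },
         sinusoid = {
           Z <- Y
           for (d in 1:3)
             Z[, d] <- Y[, d] + def$amplitude_mm[d] *
               sin(2 * pi * Y[, d] / def$wavelength_mm[d])
           Z
         })
}

# inverse map phi^-1 (target -> reference). The sinusoid is inverted per axis
# by Newton iteration on the monotone scalar map, solved only on the unique
# coordinate values of each axis (the map is separable), to 1e-12.
phantom_phi_inverse <- function(spec, X, center = NULL) {
  def <- spec$deformation
  switch(def$type,
         identity = X,
         uniform_scale = {
           if (is.null(center)) center <- deformation_center(spec)
           sweep(sweep(X, 2, center) %*% diag(1 / def$scale), 2, center, "+")
         },
         sinusoid = {
           Y <- X
           for (d in 1:3) {
             A <- def$amplitude_mm[d]; lam <- def$wavelength_mm[d]
             ux <- unique(X[, d])
             y <- ux  # initial guess
             for (it in 1:100) {
               g <- y + A * sin(2 * pi * y / lam) - ux
               gp <- 1 + A * (2 * pi / lam) * cos(2 * pi * y / lam)
               step <- g / gp
               y <- y - step
               if (max(abs(step)) < 1e-13) break
             }
             Y[, d] <- y[match(X[, d], ux)]
           }
           Y
         })
}

#' Closed-form Jacobian determinant of a phantom deformation
#'
#' Evaluates det J of the forward (exhale-to-inhale) map at reference-frame
#' world coordinates.
#'
#' @param spec a [phantom_spec()].
#' @param x a numeric triple or an n x 3 matrix of world coordinates.
#' @return numeric vector of positive Jacobian determinants.
#' @export
analytic_jacobian <- function(spec, x) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  X <- if (is.matrix(x)) x else matrix(x, ncol = 3)
  def <- spec$deformation
  switch(def$type,
         identity = rep(1, nrow(X)),
         uniform_scale = rep(prod(def$scale), nrow(X)),
         sinusoid = {
           j <- rep(1, nrow(X))
           for (d in 1:3)
             j <- j * (1 + def$amplitude_mm[d] * (2 * pi / def$wavelength_mm[d]) *
                         cos(2 * pi * X[, d] / def$wavelength_mm[d]))
           j
         })
}

#' Generate a synthetic inhale/exhale phantom case
#'
#' Builds mutually consistent exhale (reference) and inhale (target) HU
#' volumes, binary lung masks in both frames, the inverse displacement field
#' sampled on the target grid, the analytic Jacobian volume on the reference
#' grid, and a degraded low-resolution noisy reference ventilation (a
#' synthetic stand-in for a nuclear-medicine comparator). Deterministic and
#' bit-reproducible for a given spec.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_case`: a list with elements
#'   `reference_image`, `target_image`, `mask_R`, `mask_T`,
#'   `inverse_displacement`, `true_jacobian`, `spect_like_reference`,
#'   `spec`, and bookkeeping diagnostics.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("'spec' must be a phantom_spec")
  geom <- phantom_geometry(spec)
  anat <- phantom_anatomy(spec)
  X <- world_coordinate_matrix(geom)
  center <- if (spec$deformation$type == "uniform_scale")
    deformation_center(spec) else NULL

  lung_R <- anat$lung(X)
  body_R <- anat$body(X)
  hu_R <- rep(-1000, nrow(X))
  hu_R[body_R] <- 0
  hu_R[lung_R] <- density_to_hu(phantom_density(spec, X[lung_R, , drop = FALSE]))

  # target image: pull back through phi^-1 and rescale density by det J
  Y <- phantom_phi_inverse(spec, X, center)
  lung_T <- anat$lung(Y)
  body_T <- anat$body(Y)
  hu_T <- rep(-1000, nrow(X))
  hu_T[body_T] <- 0
  if (any(lung_T)) {
    rho <- phantom_density(spec, Y[lung_T, , drop = FALSE])
    if (spec$mass_conserving)
      rho <- rho / analytic_jacobian(spec, Y[lung_T, , drop = FALSE])
    hu_T[lung_T] <- density_to_hu(rho)
  }

  if (spec$hu_noise_sd > 0) {
    hu_R <- hu_R + with_seed(substream_seed(spec$seed, 11L),
                             stats::rnorm(length(hu_R), 0, spec$hu_noise_sd))
    hu_T <- hu_T + with_seed(substream_seed(spec$seed, 12L),
                             stats::rnorm(length(hu_T), 0, spec$hu_noise_sd))
  }

  d <- geom$dims
  jac <- analytic_jacobian(spec, X)
  u <- Y - X
  case <- structure(list(
    reference_image = image_volume(array(hu_R, d), geom$spacing, geom$origin),
    target_image = image_volume(array(hu_T, d), geom$spacing, geom$origin),
    mask_R = image_volume(array(lung_R, d), geom$spacing, geom$origin),
    mask_T = image_volume(array(lung_T, d), geom$spacing, geom$origin),
    inverse_displacement = displacement_field(array(u, c(d, 3L)),
                                              geom$spacing, geom$origin),
    true_jacobian = image_volume(array(jac, d), geom$spacing, geom$origin),
    spec = spec), class = "phantom_case")

  # degraded comparator: analytic Jacobian blurred to ~nuclear-medicine
  # resolution, downsampled and given rank-preserving non-negative noise
  jac_for_ref <- case$true_jacobian
  jac_for_ref$data[!case$mask_R$data] <- 1
  case$spect_like_reference <- degrade_to_reference(
    jac_for_ref, coarse_spacing_mm = pmax(spec$spacing_mm, 6),
    blur_fwhm_mm = 10, noise_seed = substream_seed(spec$seed, 13L),
    noise_cv = 0.1)

  # global volume bookkeeping: sum of det J over the reference mask should
  # match the target lung voxel count (both in reference-voxel units)
  vol_T <- sum(lung_T)
  vol_J <- sum(jac[lung_R])
  case$volume_bookkeeping <- c(target_voxels = vol_T, jacobian_integral = vol_J,
                               relative_gap = abs(vol_T - vol_J) / max(vol_J, 1))
  case
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case> %s deformation, grid %s, |lung_R| = %d voxels\n",
              x$spec$deformation$type,
              paste(x$spec$grid_dims, collapse = "x"),
              sum(x$mask_R$data)))
  cat(sprintf("  volume bookkeeping gap: %.3f%%\n",
              100 * x$volume_bookkeeping[["relative_gap"]]))
  invisible(x)
}

# separable Gaussian blur with edge renormalization (kernel mass is divided
# out so constants stay constant near boundaries)
separable_gaussian_blur <- function(a, sd_vox) {
  blur_axis <- function(a, axis, sd) {
    if (sd <= 0) return(a)
    r <- max(1L, ceiling(3 * sd))
    k <- stats::dnorm(seq(-r, r), sd = sd)
    k <- k / sum(k)
    d <- dim(a)
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    b <- aperm(a, perm)
    db <- dim(b)
    m <- matrix(b, nrow = db[1])
    n <- db[1]
    out <- matrix(0, n, ncol(m))
    wt <- numeric(n)
    for (o in seq(-r, r)) {
      w <- k[o + r + 1]
      src <- seq_len(n) + o
      keep <- src >= 1 & src <= n
      out[keep, ] <- out[keep, ] + w * m[src[keep], ]
      wt[keep] <- wt[keep] + w
    }
    out <- out / wt
    aperm(array(out, db), order(perm))
  }
  for (ax in 1:3) a <- blur_axis(a, ax, sd_vox[ax])
  a
}

#' Degrade a volume to a low-resolution noisy reference
#'
#' Emulates the role of a low-resolution functional comparator image:
#' Gaussian blur, downsampling onto a coarser grid, and non-negative
#' multiplicative-style noise (Gaussian with standard deviation proportional
#' to the local value, truncated at zero) that preserves rank structure in
#' expectation.
#'
#' @param vol an [image_volume()].
#' @param coarse_spacing_mm target spacing triple; must not be finer than the
#'   input spacing on any axis.
#' @param blur_fwhm_mm full width at half maximum of the Gaussian blur (0 for
#'   none).
#' @param noise_seed integer seed for the noise stream.
#' @param noise_cv coefficient of variation of the noise (0 for none).
#' @return an `image_volume` on the coarse grid.
#' @export
degrade_to_reference <- function(vol, coarse_spacing_mm, blur_fwhm_mm = 0,
                                 noise_seed = 1L, noise_cv = 0) {
  coarse_spacing_mm <- rep_len(as.numeric(coarse_spacing_mm), 3L)
  if (any(coarse_spacing_mm <= 0)) stop("coarse spacing must be positive")
  if (any(coarse_spacing_mm < vol$spacing - 1e-9))
    stop("coarse spacing must not be finer than the input spacing")
  a <- vol$data
  if (blur_fwhm_mm > 0) {
    sd_vox <- (blur_fwhm_mm / 2.35482) / vol$spacing
    a <- separable_gaussian_blur(a, sd_vox)
  }
  blurred <- image_volume(a, vol$spacing, vol$origin)
  ext <- (dim(vol$data) - 1) * vol$spacing
  dims_c <- pmax(2L, as.integer(floor(ext / coarse_spacing_mm)) + 1L)
  geom_c <- list(dims = dims_c, spacing = coarse_spacing_mm, origin = vol$origin)
  Xc <- world_coordinate_matrix(geom_c)
  vals <- trilinear_sample(blurred, Xc)
  if (noise_cv > 0) {
    vals <- with_seed(noise_seed, {
      noisy <- vals + stats::rnorm(length(vals), 0, noise_cv * pmax(vals, 0))
      pmax(noisy, 0)
    })
  }
  image_volume(array(vals, dims_c), coarse_spacing_mm, vol$origin)
}

#' Perturb a displacement field with smooth random noise
#'
#' Adds a spatially smooth random vector field, emulating the variability
#' between deformable-registration solutions. Noise is drawn white on a
#' coarse grid (one node per `correlation_mm`), trilinearly upsampled, and
#' scaled so each component has the requested standard deviation in voxel
#' units.
#'
#' @param disp a [displacement_field()].
#' @param sd_voxels per-component noise standard deviation in voxel units.
#' @param correlation_mm correlation length of the noise in mm.
#' @param seed integer seed.
#' @return a perturbed `displacement_field` on the same grid.
#' @export
perturb_displacement <- function(disp, sd_voxels = 0.5, correlation_mm = 15,
                                 seed = 1L) {
  d <- dim(disp$data)[1:3]
  ext <- (d - 1) * disp$spacing
  dims_c <- pmax(2L, as.integer(ceiling(ext / correlation_mm)) + 1L)
  sp_c <- ext / (dims_c - 1)
  Xf <- world_coordinate_matrix(list(dims = d, spacing = disp$spacing,
                                     origin = disp$origin))
  out <- disp
  noise <- with_seed(seed, stats::rnorm(prod(dims_c) * 3L))
  noise <- array(noise, c(dims_c, 3L))
  for (comp in 1:3) {
    cv <- image_volume(noise[, , , comp], sp_c, disp$origin)
    smooth <- trilinear_sample(cv, Xf)
    s <- stats::sd(smooth)
    if (s > 0)
      smooth <- smooth * (sd_voxels * disp$spacing[comp] / s)
    out$data[, , , comp] <- out$data[, , , comp] + array(smooth, d)
  }
  out
}

#' Round-trip a phantom spec through a plain-text configuration file
#'
#' @param spec a [phantom_spec()].
#' @param path YAML file path.
#' @return `read_phantom_spec` returns a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- yaml::read_yaml(path)
  phantom_spec(grid_dims = x$grid_dims, spacing_mm = x$spacing_mm,
               deformation = x$deformation, base_density = x$base_density,
               density_texture_amplitude = x$density_texture_amplitude,
               hu_noise_sd = x$hu_noise_sd,
               mass_conserving = x$mass_conserving, seed = x$seed)
}
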