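#' Convert Hounsfield units to physical density
#'
#' Linear air/water calibration: `rho = (HU + 1000) / 1000` g/cm^3, clamped
#' below at zero. Air (-1000 HU) maps to 0, water (0 HU) to 1.
#'
#' @param hu an [image_volume()] of HU values.
#' @return an `image_volume` of densities in g/cm^3.
#' @export
hu_to_density <- function(hu) {
  out <- hu
  out$data <- pmax((hu$data + 1000) / 1000, 0)
  out
}

#' Map target voxels through the inverse transformation
#'
#' Precomputes, for every target-lung voxel, the reference voxel its inverse
#' mapped position lands in (nearest voxel center), together with per
#' reference-voxel hit tallies. This is the membership oracle underlying the
#' hit-or-miss volume estimator: a target voxel `x` is a "hit" for a
#' reference subregion when `phi^-1(x)` falls inside it. Voxels mapping
#' outside the reference image domain are counted as misses and tallied in
#' `n_outside`.
#'
#' @param displacement a [displacement_field()] on the target grid encoding
#'   `phi^-1(x) = x + u(x)` in world mm.
#' @param mask_T target lung mask ([image_volume()], same grid as
#'   `displacement`).
#' @param reference_geometry the reference grid: an `image_volume` (e.g. the
#'   reference mask) whose geometry defines the landing grid.
#' @return an object of class `hit_map`: list with `target_lin` (target
#'   voxel indices in the mask), `mapped_lin` (reference voxel index each one
#'   lands in, `NA` if outside), `counts` (reference-grid array of hit
#'   tallies), `M` (number of target lung voxels) and `n_outside`.
#' @export
build_hit_map <- function(displacement, mask_T, reference_geometry) {
  stopifnot_same_grid(displacement, mask_T, "displacement field and target mask")
  target_lin <- which(mask_T$data != 0)
  if (length(target_lin) == 0L) stop("target mask is empty")
  geom_T <- grid_geometry(mask_T)
  X <- world_coordinate_matrix(geom_T, target_lin)
  d <- dim(displacement$data)[1:3]
  nvox <- prod(d)
  U <- cbind(displacement$data[target_lin],
             displacement$data[target_lin + nvox],
             displacement$data[target_lin + 2 * nvox])
  Y <- X + U
  geom_R <- grid_geometry(reference_geometry)
  mapped <- world_to_nearest_linear(geom_R, Y)
  counts <- array(0, geom_R$dims)
  tab <- tabulate(mapped[!is.na(mapped)], nbins = prod(geom_R$dims))
  counts[] <- tab
  structure(list(target_lin = target_lin, mapped_lin = mapped,
                 counts = counts, M = length(target_lin),
                 n_outside = sum(is.na(mapped)),
                 reference_dims = geom_R$dims),
            class = "hit_map")
}

#' Count hits of a reference subregion
#'
#' @param region a `subregion` or an integer vector of reference voxel
#'   indices.
#' @param hit_map a [build_hit_map()] result.
#' @return list with `H` (hit count) and `hit_indices` (target voxel linear
#'   indices whose mapped position lands in the region).
#' @export
count_hits <- function(region, hit_map) {
  idx <- region_indices(region)
  H <- sum(hit_map$counts[idx])
  inreg <- logical(prod(hit_map$reference_dims))
  inreg[idx] <- TRUE
  sel <- !is.na(hit_map$mapped_lin) & inreg[pmax(hit_map$mapped_lin, 1L)]
  list(H = as.integer(H), hit_indices = hit_map$target_lin[sel])
}

region_indices <- function(region) {
  if (inherits(region, "subregion")) region$voxel_indices
  else as.integer(region)
}

#' Relative-uncertainty criterion for the hit-count estimator
#'
#' The hit proportion is a binomial sample mean; with `beta = 1.96` (the
#' 95% Gaussian quantile) the relative error of the estimated volume is, with
#' 95% probability, at most `beta * sqrt(H (1 - H/M)) / H`. A subregion
#' passes the tolerance when this bound drops to `tau` or below, which
#' implicitly defines the minimum admissible hit count.
#'
#' @param H hit count(s).
#' @param M total number of target lung voxels.
#' @param beta Gaussian quantile (default 1.96).
#' @return the criterion value(s); `Inf` where `H = 0`.
#' @export
ijf_uncertainty <- function(H, M, beta = 1.96) {
  ifelse(H > 0, beta * sqrt(pmax(H * (1 - H / M), 0)) / H, Inf)
}

#' Subregional volume-change estimate from hit counting (IJF)
#'
#' Estimates the deformed volume of a reference subregion as the number of
#' target voxels whose inverse-mapped positions land inside it (volumes in
#' reference-voxel units). The estimate is accepted when the 95% relative
#' uncertainty bound is at most `tau`.
#'
#' @param region a `subregion` or integer index vector.
#' @param hit_map a [build_hit_map()] result.
#' @param tau uncertainty tolerance in (0, 1).
#' @param beta Gaussian quantile for the uncertainty model (default 1.96).
#' @return an object of class `subregion_estimate` with fields `region`,
#'   `method = "ijf"`, `H`, `value` (the estimate, `NA` when `H = 0`),
#'   `tolerance_met`, `criterion`, `tau`, `size`.
#' @export
ijf_estimate <- function(region, hit_map, tau, beta = 1.96) {
  idx <- region_indices(region)
  H <- as.integer(sum(hit_map$counts[idx]))
  crit <- ijf_uncertainty(H, hit_map$M, beta)
  structure(list(region = region, method = "ijf", H = H,
                 value = if (H > 0) as.numeric(H) else NA_real_,
                 tolerance_met = H > 0 && crit <= tau,
                 criterion = crit, tau = tau, size = length(idx)),
            class = "subregion_estimate")
}

#' Subregional volume-change estimate from density ratios (MCVC)
#'
#' Under air-mass conservation, the deformed volume of a subregion equals the
#' ratio of its mean reference density to the mean target density over the
#' deformed subregion, times the subregion volume. The mean target density is
#' taken over the hit set (target voxels mapping into the region), so the
#' target-side sample size is exactly the hit count. Both sample means must
#' meet the tolerance: `|region| >= (beta * sd_R / tau)^2` and
#' `H >= (beta * sd_T / tau)^2`, with the sample standard deviations taken
#' in-region (zero when fewer than two samples).
#'
#' @param region a `subregion` or integer index vector.
#' @param density_R,density_T reference/target density volumes (see
#'   [hu_to_density()]).
#' @param hit_map a [build_hit_map()] result.
#' @param tau uncertainty tolerance (density units, g/cm^3).
#' @param beta Gaussian quantile (default 1.96).
#' @param min_target_density floor on the mean target density below which the
#'   ratio is considered numerically invalid (default 1e-3 g/cm^3).
#' @return a `subregion_estimate` with method `"mcvc"`.
#' @export
mcvc_estimate <- function(region, density_R, density_T, hit_map, tau,
                          beta = 1.96, min_target_density = 1e-3) {
  idx <- region_indices(region)
  n <- length(idx)
  hits <- count_hits(idx, hit_map)
  H <- hits$H
  rR <- density_R$data[idx]
  mR <- mean(rR)
  sdR <- if (n >= 2) stats::sd(rR) else 0
  if (H >= 1) {
    rT <- density_T$data[hits$hit_indices]
    mT <- mean(rT)
    sdT <- if (H >= 2) stats::sd(rT) else 0
  } else {
    mT <- NA_real_; sdT <- Inf
  }
  valid <- H >= 1 && is.finite(mT) && mT > min_target_density
  value <- if (valid) mR / mT * n else NA_real_
  met <- valid && n >= (beta * sdR / tau)^2 && H >= (beta * sdT / tau)^2
  structure(list(region = region, method = "mcvc", H = H, value = value,
                 tolerance_met = met, criterion = c(sd_R = sdR, sd_T = sdT),
                 tau = tau, size = n),
            class = "subregion_estimate")
}

#' @export
print.subregion_estimate <- function(x, ...) {
  cat(sprintf("<subregion_estimate> %s: |region| = %d, H = %d, value = %.4g, %s\n",
              toupper(x$method), x$size, x$H, x$value,
              if (x$tolerance_met) "tolerance met" else "tolerance NOT met"))
  invisible(x)
}
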