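#' Resample a volume through a world-space affine transform
#'
#' Applies a 4 x 4 affine (mapping input world coordinates to target world
#' coordinates) and resamples the transformed image onto a target grid by
#' trilinear interpolation. Each target voxel center is pulled back through
#' the inverse affine and sampled in the input volume; positions falling
#' outside the input field of view are marked missing (`NA`).
#'
#' @param image an [image_volume()].
#' @param affine invertible 4 x 4 matrix (homogeneous world transform). Use
#'   `diag(4)` when the volumes already share a world frame.
#' @param target_grid grid geometry: an `image_volume` to copy geometry
#'   from, or a list with `dims`, `spacing`, `origin`.
#' @return an `image_volume` on the target grid.
#' @export
resample_with_affine <- function(image, affine, target_grid) {
  if (!is.matrix(affine) || any(dim(affine) != c(4, 4)))
    stop("'affine' must be a 4 x 4 matrix")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12)
    stop("'affine' is singular")
  geom <- if (inherits(target_grid, "image_volume")) grid_geometry(target_grid)
  else target_grid
  Xt <- world_coordinate_matrix(geom)
  inv <- solve(affine)
  Xs <- cbind(Xt, 1) %*% t(inv)
  vals <- trilinear_sample(image, Xs[, 1:3, drop = FALSE])
  image_volume(array(vals, geom$dims), geom$spacing, geom$origin)
}

#' Slice-wise 3 x 3 median filter
#'
#' Applies a 3 x 3 median filter independently to every axial (third-axis)
#' slice, the standard pre-smoothing of low-resolution nuclear-medicine
#' ventilation before voxel-wise comparison. Edge pixels use the reduced
#' window that fits inside the slice.
#'
#' @param image an [image_volume()].
#' @return the filtered `image_volume`.
#' @export
median_filter_slicewise <- function(image) {
  d <- dim(image$data)
  out <- image
  nx <- d[1]; ny <- d[2]
  for (k in seq_len(d[3])) {
    sl <- image$data[, , k]
    # gather the 9 shifted copies with NA padding, then row-wise median
    nb <- matrix(NA_real_, nx * ny, 9L)
    col <- 0L
    for (dj in -1:1) for (di in -1:1) {
      col <- col + 1L
      src_i <- seq_len(nx) + di
      src_j <- seq_len(ny) + dj
      oki <- src_i >= 1 & src_i <= nx
      okj <- src_j >= 1 & src_j <= ny
      sh <- matrix(NA_real_, nx, ny)
      sh[oki, okj] <- sl[src_i[oki], src_j[okj]]
      nb[, col] <- sh
    }
    med <- apply(nb, 1, stats::median, na.rm = TRUE)
    out$data[, , k] <- matrix(med, nx, ny)
  }
  out
}

#' Masked voxel-wise Spearman correlation
#'
#' Spearman rank correlation (midranks for ties) between two volumes over a
#' binary mask. Voxels with a missing value in either volume are excluded
#' pairwise. If either input is constant over the usable voxels the
#' correlation is undefined and `NA` is returned (never coerced to 0).
#'
#' @param a,b [image_volume()]s on a common grid.
#' @param mask binary `image_volume` on the same grid.
#' @return the correlation, with attribute `n_voxels`; `NA` when undefined.
#' @export
spearman_masked <- function(a, b, mask) {
  stopifnot_same_grid(a, b, "correlation inputs")
  stopifnot_same_grid(a, mask, "input and mask")
  sel <- mask$data != 0
  x <- a$data[sel]; y <- b$data[sel]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("fewer than 3 usable voxels under the mask")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(NA_real_, n_voxels = n))
  structure(stats::cor(x, y, method = "spearman"), n_voxels = n)
}

#' Five-number summary with midpoint interpolation
#'
#' Order statistics (minimum, lower quartile, median, upper quartile,
#' maximum) using midpoint interpolation at even counts
#' (`stats::quantile` type 2).
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector `min, q25, median, q75, max`.
#' @export
summarize_correlations <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("'values' must be a non-empty vector of finite numbers")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 2, names = FALSE)
  c(min = min(values), q25 = q[1], median = q[2], q75 = q[3], max = max(values))
}

#' Exact Wilcoxon signed-rank test for paired data
#'
#' Two-sided signed-rank test on paired differences, with midranks for tied
#' absolute differences and zero differences dropped. For `n <= 25` the
#' p-value is computed from the exact permutation distribution of the
#' negative-rank sum (dynamic programming over doubled ranks, so midranks
#' are handled exactly); above that a normal approximation with tie
#' correction is used. The method actually used is reported.
#'
#' @param x numeric vector (differences, or first members of pairs).
#' @param y optional second members; differences are `x - y`.
#' @return list with `w_minus`, `w_plus`, `n` (non-zero differences),
#'   `p_value`, `method`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L) stop("need at least 5 non-zero differences")
  r <- rank(abs(d))
  w_minus <- sum(r[d < 0])
  w_plus <- sum(r[d > 0])
  if (n <= 25L) {
    t2 <- as.integer(round(2 * r))
    total <- sum(t2)
    f <- numeric(total + 1L)  # f[s + 1] = #subsets whose doubled-rank sum is s
    f[1] <- 1
    for (t in t2) {
      shifted <- c(numeric(t), f[seq_len(total + 1L - t)])
      f <- f + shifted
    }
    w2 <- as.integer(round(2 * w_minus))
    denom <- 2^n
    p_le <- sum(f[seq_len(w2 + 1L)]) / denom
    p_ge <- sum(f[(w2 + 1L):(total + 1L)]) / denom
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (sign-flip distribution, midranks)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_minus - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(w_minus = w_minus, w_plus = w_plus, n = n, p_value = p, method = method)
}

#' Correlate a ventilation image against a reference ventilation
#'
#' Implements the comparison protocol: the ventilation image is mapped into
#' the reference frame with a world-space affine and resampled onto the
#' reference grid; the reference is median filtered slice-wise (3 x 3); the
#' lung mask is resampled to the reference grid with a 50% partial-volume
#' threshold; the masked voxel-wise Spearman correlation is returned.
#'
#' @param vent ventilation [image_volume()] (signal or Jacobian field; the
#'   correlation is rank-based, so either monotone convention works).
#' @param reference reference ventilation `image_volume` (e.g. the degraded
#'   comparator of a phantom, or a clinical ventilation scan).
#' @param mask lung mask on the ventilation grid.
#' @param affine 4 x 4 world transform from the ventilation frame to the
#'   reference frame (identity by default).
#' @param filter_reference apply the 3 x 3 slice-wise median to the
#'   reference (default TRUE).
#' @return Spearman correlation with attribute `n_voxels`.
#' @export
correlate_ventilation <- function(vent, reference, mask, affine = diag(4),
                                  filter_reference = TRUE) {
  ref <- if (filter_reference) median_filter_slicewise(reference) else reference
  same <- same_grid(vent, reference) && identical(affine, diag(4))
  if (same) {
    return(spearman_masked(vent, ref, mask))
  }
  vent_r <- resample_with_affine(vent, affine, reference)
  mask_num <- image_volume(array(as.numeric(mask$data != 0), dim(mask$data)),
                           mask$spacing, mask$origin)
  mask_r <- resample_with_affine(mask_num, affine, reference)
  mask_bin <- mask_r
  mask_bin$data <- !is.na(mask_r$data) & mask_r$data >= 0.5
  spearman_masked(vent_r, ref, mask_bin)
}

#' Sweep the uncertainty tolerance
#'
#' Runs the full reconstruction (subregion growth, subregional estimation,
#' system assembly, constrained solve, signal conversion) for every value of
#' the uncertainty tolerance and, when a reference ventilation is supplied,
#' correlates each result against it. The default grid is 30 values
#' uniformly spaced on \[0.01, 0.25\]. Per-tolerance failures (e.g. no
#' admissible subregions at very small tolerances) are recorded and the
#' sweep continues.
#'
#' @param prep a [prepare_ventilation()] result.
#' @param tau_values tolerance grid (default `seq(0.01, 0.25, length.out = 30)`).
#' @param reference optional reference ventilation [image_volume()] to
#'   correlate against.
#' @param affine world transform to the reference frame (identity default).
#' @param cfg a [solve_config()].
#' @param case_id label recorded in the output.
#' @param filter_reference apply the 3 x 3 slice-wise median to the
#'   reference before correlating (default TRUE; disable for noise-free
#'   analytic references). Applied once, outside the tolerance loop.
#' @param keep_results keep each `ventilation_result` (default FALSE to save
#'   memory).
#' @return a data.frame with one row per tolerance value: `case_id`,
#'   `method`, `tau`, `rho`, `n_voxels`, `K`, `L`, `residual_norm`,
#'   `constraint_gap`, `error` (message for failed tolerances). When
#'   `keep_results` is TRUE the results are attached as an attribute.
#' @export
sweep_tau <- function(prep, tau_values = seq(0.01, 0.25, length.out = 30),
                      reference = NULL, affine = diag(4),
                      cfg = solve_config(), case_id = "case",
                      filter_reference = TRUE, keep_results = FALSE) {
  if (any(tau_values <= 0 | tau_values >= 1))
    stop("tolerance values must lie in (0, 1)")
  if (!is.null(reference) && filter_reference)
    reference <- median_filter_slicewise(reference)
  rows <- vector("list", length(tau_values))
  results <- if (keep_results) vector("list", length(tau_values)) else NULL
  for (i in seq_along(tau_values)) {
    tau <- tau_values[i]
    rec <- list(case_id = case_id, method = prep$method, tau = tau,
                rho = NA_real_, n_voxels = NA_integer_, K = NA_integer_,
                L = ncol(prep$model$C), residual_norm = NA_real_,
                constraint_gap = NA_real_, error = NA_character_)
    out <- tryCatch({
      res <- ventilate_at_tau(prep, tau, cfg)
      rec$K <- res$K
      rec$residual_norm <- res$result$residual_norm
      rec$constraint_gap <- res$result$constraint_gap
      if (!is.null(reference)) {
        sig <- ventilation_signal(res$result)
        rho <- correlate_ventilation(sig, reference, prep$case$mask_R, affine,
                                     filter_reference = FALSE)
        rec$rho <- as.numeric(rho)
        rec$n_voxels <- attr(rho, "n_voxels")
      }
      if (keep_results) results[[i]] <- res$result
      rec
    }, error = function(e) { rec$error <- conditionMessage(e); rec })
    rows[[i]] <- out
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  if (keep_results) attr(df, "results") <- results
  df
}

#' Percentile curves over a sweep
#'
#' Summarizes per-case sweep records into per-tolerance percentile curves
#' (min, 25th, median, 75th, max) of the correlation, and reports the
#' tolerance with the highest median correlation.
#'
#' @param records a data.frame of sweep records (rbind of [sweep_tau()]
#'   outputs across cases).
#' @return list with `curves` (data.frame, one row per tolerance) and
#'   `optimal_tau`.
#' @export
summarize_sweep <- function(records) {
  ok <- is.finite(records$rho)
  if (!any(ok)) stop("no finite correlations in the sweep records")
  sp <- split(records$rho[ok], records$tau[ok])
  curves <- do.call(rbind, lapply(names(sp), function(t) {
    s <- summarize_correlations(sp[[t]])
    data.frame(tau = as.numeric(t), min = s["min"], q25 = s["q25"],
               median = s["median"], q75 = s["q75"], max = s["max"],
               n_cases = length(sp[[t]]))
  }))
  curves <- curves[order(curves$tau), ]
  rownames(curves) <- NULL
  list(curves = curves,
       optimal_tau = curves$tau[which.max(curves$median)])
}
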