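#' Build the Shepard moving-least-squares weight matrix
#'
#' Parameterizes a voxel field on the reference lung by `L` knot values:
#' `v_i = sum_j C_ij q_j` where `C_ij` is the Gaussian kernel
#' `w(r) = exp(-sigma r^2)` evaluated at the voxel-to-knot distance and
#' normalized so every row sums to one (a partition of unity, hence a
#' bound-preserving moving-average operator). For sparsity the kernel is
#' truncated at `truncation_factor` times the nominal knot spacing and
#' renormalized; a voxel with no knot inside the truncation radius falls
#' back to full weight on its nearest knot.
#'
#' The default kernel scale ties smoothness to knot density: the weight at
#' one nominal knot spacing `d` equals one half, i.e. `sigma = ln(2) / d^2`.
#'
#' @param mask reference lung mask ([image_volume()]).
#' @param knots a [dart_throw()] point set (knot locations in world mm).
#' @param sigma Gaussian kernel scale in mm^-2 (default `log(2) / d^2`).
#' @param truncation_factor truncation radius in units of the nominal knot
#'   spacing (default 2.5; weight below 2% of peak outside).
#' @return an object of class `mls_model`: list with `knots`, `sigma`,
#'   `C` (sparse N x L row-stochastic matrix), `voxel_order` (linear indices
#'   of the mask voxels, fixing the row enumeration), `geometry`,
#'   `n_fallback` (voxels assigned to their nearest knot).
#' @export
build_weight_matrix <- function(mask, knots, sigma = NULL,
                                truncation_factor = 2.5) {
  Z <- knots$points
  L <- nrow(Z)
  if (L < 1L) stop("at least one knot is required")
  d_nom <- knots$nominal_spacing_mm
  if (is.null(sigma)) sigma <- log(2) / d_nom^2
  if (sigma <= 0) stop("'sigma' must be positive")
  voxel_order <- which(mask$data != 0)
  N <- length(voxel_order)
  if (N == 0L) stop("mask is empty")
  geom <- grid_geometry(mask)
  # map full-grid linear index -> row number in C
  rowmap <- integer(prod(geom$dims))
  rowmap[voxel_order] <- seq_len(N)
  radius <- truncation_factor * d_nom

  ii <- vector("list", L); xx <- vector("list", L)
  d <- geom$dims
  for (j in seq_len(L)) {
    z <- Z[j, ]
    lo <- pmax(ceiling((z - radius - geom$origin) / geom$spacing) + 1L, 1L)
    hi <- pmin(floor((z + radius - geom$origin) / geom$spacing) + 1L, d)
    if (any(lo > hi)) next
    sub <- mask$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    w <- which(sub != 0)
    if (length(w) == 0L) next
    sd_ <- dim(sub)
    w0 <- w - 1L
    i1 <- lo[1] + w0 %% sd_[1]
    j1 <- lo[2] + (w0 %/% sd_[1]) %% sd_[2]
    k1 <- lo[3] + w0 %/% (sd_[1] * sd_[2])
    lin <- i1 + d[1] * (j1 - 1L) + d[1] * d[2] * (k1 - 1L)
    px <- geom$origin[1] + (i1 - 1) * geom$spacing[1]
    py <- geom$origin[2] + (j1 - 1) * geom$spacing[2]
    pz <- geom$origin[3] + (k1 - 1) * geom$spacing[3]
    r2 <- (px - z[1])^2 + (py - z[2])^2 + (pz - z[3])^2
    keep <- r2 <= radius^2
    if (!any(keep)) next
    ii[[j]] <- rowmap[lin[keep]]
    xx[[j]] <- exp(-sigma * r2[keep])
  }
  jj <- rep.int(seq_len(L), vapply(ii, length, integer(1)))
  C <- Matrix::sparseMatrix(i = unlist(ii), j = jj, x = unlist(xx),
                            dims = c(N, L))
  rs <- Matrix::rowSums(C)
  empty <- which(rs == 0)
  if (length(empty)) {
    # fall back to the single nearest knot
    Xe <- world_coordinate_matrix(geom, voxel_order[empty])
    nearest <- vapply(seq_along(empty), function(r) {
      which.min((Z[, 1] - Xe[r, 1])^2 + (Z[, 2] - Xe[r, 2])^2 +
                  (Z[, 3] - Xe[r, 3])^2)
    }, integer(1))
    C <- C + Matrix::sparseMatrix(i = empty, j = nearest,
                                  x = rep(1, length(empty)), dims = c(N, L))
    rs[empty] <- 1
  }
  C <- Matrix::Diagonal(x = 1 / rs) %*% C
  structure(list(knots = knots, sigma = sigma, C = methods::as(C, "CsparseMatrix"),
                 voxel_order = voxel_order, geometry = geom,
                 n_fallback = length(empty)),
            class = "mls_model")
}

#' @export
print.mls_model <- function(x, ...) {
  cat(sprintf("<mls_model> %d voxels x %d knots, sigma = %.4g mm^-2, nnz(C) = %d\n",
              nrow(x$C), ncol(x$C), x$sigma, length(x$C@x)))
  invisible(x)
}

#' Evaluate the MLS field at every mask voxel
#'
#' Computes `v = C q`, a convex combination of the knot values, so the result
#' is bounded by the range of `q`.
#'
#' @param model an [build_weight_matrix()] result.
#' @param q numeric vector of knot values (length `L`).
#' @return numeric vector of field values, one per mask voxel in
#'   `model$voxel_order` order.
#' @export
evaluate_field <- function(model, q) {
  if (length(q) != ncol(model$C)) stop("length(q) must equal the knot count")
  if (any(!is.finite(q))) stop("knot values must be finite")
  as.numeric(model$C %*% q)
}

# place a voxel-order vector back into a full-grid volume (NA outside mask)
field_to_volume <- function(model, v, fill = NA_real_) {
  a <- array(fill, model$geometry$dims)
  a[model$voxel_order] <- v
  image_volume(a, model$geometry$spacing, model$geometry$origin)
}

#' Assemble the subregional least-squares system
#'
#' Builds the reduced data matrix whose row `k` is the sum of the MLS weight
#' rows over the voxels of subregion `k`, so that the regional integral of
#' the parameterized field is a linear function of the knot values. The
#' accumulation works directly from region voxel lists; the binary
#' region-membership matrix is never materialized.
#'
#' @param estimates list of tolerance-passing `subregion_estimate`s.
#' @param model an `mls_model`.
#' @param h global volume-consistency constant (see
#'   [global_constraint_constant()]).
#' @return an object of class `linear_system`: list with `A_hat` (K x L
#'   dense matrix), `b`, `region_sizes`, `N`, `h`, `regions` (the voxel index
#'   lists).
#' @export
assemble_system <- function(estimates, model, h) {
  keep <- vapply(estimates, function(e)
    isTRUE(e$tolerance_met) && is.finite(e$value), logical(1))
  estimates <- estimates[keep]
  K <- length(estimates)
  L <- ncol(model$C)
  if (K < L)
    stop(sprintf(paste("only %d admissible subregions for %d knots;",
                       "decrease the subdomain spacing or use fewer knots"),
                 K, L))
  rowmap <- integer(prod(model$geometry$dims))
  rowmap[model$voxel_order] <- seq_len(nrow(model$C))
  A_hat <- matrix(0, K, L)
  b <- numeric(K)
  sizes <- integer(K)
  regions <- vector("list", K)
  # dense accumulation when the weight matrix is small enough, else sparse
  use_dense <- as.numeric(nrow(model$C)) * L <= 5e7
  Cd <- if (use_dense) as.matrix(model$C) else NULL
  Ct <- if (!use_dense) Matrix::t(model$C) else NULL
  for (k in seq_len(K)) {
    idx <- region_indices(estimates[[k]]$region)
    rows <- rowmap[idx]
    if (any(rows == 0L)) stop("subregion extends outside the reference mask")
    A_hat[k, ] <- if (use_dense) colSums(Cd[rows, , drop = FALSE])
    else as.numeric(Matrix::rowSums(Ct[, rows, drop = FALSE]))
    b[k] <- estimates[[k]]$value
    sizes[k] <- length(idx)
    regions[[k]] <- idx
  }
  structure(list(A_hat = A_hat, b = b, region_sizes = sizes,
                 N = nrow(model$C), h = h, regions = regions,
                 method = estimates[[1]]$method),
            class = "linear_system")
}

#' @export
print.linear_system <- function(x, ...) {
  cat(sprintf("<linear_system> K = %d subregions x L = %d knots, N = %d voxels, h = %.4g\n",
              nrow(x$A_hat), ncol(x$A_hat), x$N, x$h))
  invisible(x)
}
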