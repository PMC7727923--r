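#' Configuration for the constrained ventilation solve
#'
#' @param epsilon strict lower bound on the knot values (Jacobian floor);
#'   default 0.05, i.e. at most 95% local compression.
#' @param lambda_reg weight of the variance regularizer (default 1, the
#'   plain unweighted sum).
#' @param equality_tolerance admissible relative gap on the global volume
#'   equality constraint (default 1e-6).
#' @param solver_max_iter iteration cap passed to the QP solver (kept for
#'   diagnostics; the dual active-set solver terminates finitely).
#' @return an object of class `solve_config`.
#' @export
solve_config <- function(epsilon = 0.05, lambda_reg = 1,
                         equality_tolerance = 1e-6, solver_max_iter = 200L) {
  if (epsilon <= 0) stop("'epsilon' must be positive")
  if (lambda_reg < 0) stop("'lambda_reg' must be non-negative")
  structure(list(epsilon = epsilon, lambda_reg = lambda_reg,
                 equality_tolerance = equality_tolerance,
                 solver_max_iter = as.integer(solver_max_iter)),
            class = "solve_config")
}

#' Global volume-consistency constant
#'
#' The equality constraint ties the voxel sum of the recovered Jacobian
#' field to the whole-lung volume change: for the transformation-based
#' method this is the target lung volume (in reference-voxel units); for the
#' intensity-based method it is the ratio of whole-lung mean densities times
#' the reference lung volume.
#'
#' @param method `"ijf"` or `"mcvc"`.
#' @param mask_R,mask_T reference/target lung masks ([image_volume()]).
#' @param density_R,density_T density volumes; required for `"mcvc"` only.
#' @return the constant `h` in voxel-volume units.
#' @export
global_constraint_constant <- function(method, mask_R, mask_T,
                                       density_R = NULL, density_T = NULL) {
  method <- match.arg(tolower(method), c("ijf", "mcvc"))
  nR <- sum(mask_R$data != 0)
  nT <- sum(mask_T$data != 0)
  if (nR == 0L || nT == 0L) stop("masks must be non-empty")
  if (method == "ijf") return(as.numeric(nT))
  if (is.null(density_R) || is.null(density_T))
    stop("densities are required for the intensity-based constant")
  mR <- mean(density_R$data[mask_R$data != 0])
  mT <- mean(density_T$data[mask_T$data != 0])
  if (mT <= 0) stop("mean target density is zero; cannot form the density ratio")
  mR / mT * nR
}

#' Solve the constrained, variance-regularized least-squares problem
#'
#' Recovers knot values `q` minimizing
#' `||A_hat q - b||^2 + lambda * sum_k (q_k - h/N)^2`
#' subject to the global volume equality `sum_i v_i = h` (written in knot
#' space as `(1' C) q = h`) and the positivity bounds `q >= epsilon`. The
#' regularizer penalizes variance of the knot values about the mean voxel
#' volume change enforced by the equality constraint. Because the MLS field
#' is a convex combination of the knot values, `q >= epsilon > 0` guarantees
#' a strictly positive recovered field.
#'
#' The quadratic program is strictly convex (for `lambda > 0`) and is solved
#' by the Goldfarb-Idnani dual active-set method, which terminates at the
#' exact KKT point up to round-off.
#'
#' @param system a [assemble_system()] result.
#' @param model the `mls_model` used to build the system.
#' @param cfg a [solve_config()].
#' @return an object of class `ventilation_result`: list with `q`, `v`
#'   (voxel field in `voxel_order` enumeration), `V` (field as an
#'   `image_volume`, `NA` outside the mask), `h`, `residual_norm`,
#'   `constraint_gap`, `n_active_bounds`, `method`.
#' @export
solve_ventilation <- function(system, model, cfg = solve_config()) {
  A <- system$A_hat; b <- system$b; h <- system$h; N <- system$N
  L <- ncol(A)
  eps <- cfg$epsilon; lam <- cfg$lambda_reg
  a <- as.numeric(Matrix::colSums(model$C))
  if (eps * N > h * (1 + 1e-12))
    stop(sprintf(paste("infeasible configuration: epsilon * N = %.6g exceeds",
                       "the global volume constant h = %.6g"), eps * N, h))
  if (abs(eps * N - h) <= 1e-12 * max(h, 1)) {
    # the feasible set degenerates to the single point q = epsilon
    q <- rep(eps, L)
  } else {
    D <- 2 * (crossprod(A) + diag(lam, L))
    dv <- 2 * (as.numeric(crossprod(A, b)) + lam * h / N)
    sc <- 1 / mean(diag(D))  # uniform rescale for numerical conditioning
    sol <- tryCatch(
      quadprog::solve.QP(Dmat = D * sc, dvec = dv * sc,
                         Amat = cbind(a, diag(L)),
                         bvec = c(h, rep(eps, L)), meq = 1L),
      error = function(e)
        stop(sprintf("QP solve failed: %s (K = %d, L = %d, h = %.4g)",
                     conditionMessage(e), nrow(A), L, h)))
    q <- sol$solution
    q <- pmax(q, eps)  # clip round-off excursions below the bound
  }
  v <- evaluate_field(model, q)
  gap <- abs(sum(v) - h) / abs(h)
  res <- sqrt(sum((as.numeric(A %*% q) - b)^2))
  if (gap > cfg$equality_tolerance)
    warning(sprintf("global volume constraint gap %.3g exceeds tolerance %.3g",
                    gap, cfg$equality_tolerance))
  structure(list(q = q, v = v, V = field_to_volume(model, v), h = h,
                 residual_norm = res, constraint_gap = gap,
                 n_active_bounds = sum(q <= eps * (1 + 1e-9)),
                 epsilon = eps, lambda_reg = lam,
                 method = system$method),
            class = "ventilation_result")
}

#' @export
print.ventilation_result <- function(x, ...) {
  cat(sprintf("<ventilation_result> %s: %d knots, residual %.4g, constraint gap %.2g\n",
              toupper(if (is.null(x$method)) "?" else x$method),
              length(x$q), x$residual_norm, x$constraint_gap))
  cat(sprintf("  field range [%.4g, %.4g], %d bound-active knots\n",
              min(x$v), max(x$v), x$n_active_bounds))
  invisible(x)
}

#' Convert a Jacobian field to a ventilation signal
#'
#' The recovered field estimates the local volume-scaling factor det J. The
#' ventilation signal is the absolute volume difference: `V - 1` when the
#' reference frame is the exhale phase (expansion positive, the default),
#' `1 - V` when the reference is the inhale phase.
#'
#' @param V an [image_volume()] of Jacobian estimates (or a
#'   `ventilation_result`, whose field volume is used).
#' @param direction `"reference_is_exhale"` or `"reference_is_inhale"`.
#' @return an `image_volume` of signal values.
#' @export
ventilation_signal <- function(V, direction = c("reference_is_exhale",
                                                "reference_is_inhale")) {
  direction <- match.arg(direction)
  if (inherits(V, "ventilation_result")) V <- V$V
  out <- V
  out$data <- if (direction == "reference_is_exhale") V$data - 1 else 1 - V$data
  out
}
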