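#' Bundle the inputs of a ventilation reconstruction
#'
#' Validates grid consistency between the exhale (reference) image, inhale
#' (target) image, the two lung masks and the inverse displacement field.
#' A [generate_phantom()] case can be used directly anywhere a `vent_case`
#' is accepted, since it carries the same fields.
#'
#' @param reference_image,target_image HU [image_volume()]s. The target
#'   image may be `NULL` for the transformation-based method, which only
#'   uses the masks and the displacement field.
#' @param mask_R,mask_T binary lung masks on the reference/target grids.
#' @param inverse_displacement a [displacement_field()] on the target grid.
#' @return an object of class `vent_case`.
#' @export
vent_case <- function(reference_image, target_image, mask_R, mask_T,
                      inverse_displacement) {
  stopifnot_same_grid(reference_image, mask_R, "reference image and mask")
  if (!is.null(target_image))
    stopifnot_same_grid(target_image, mask_T, "target image and mask")
  stopifnot_same_grid(mask_T, inverse_displacement,
                      "target mask and displacement field")
  structure(list(reference_image = reference_image,
                 target_image = target_image,
                 mask_R = mask_R, mask_T = mask_T,
                 inverse_displacement = inverse_displacement),
            class = "vent_case")
}

#' Sampling spacings scaled to the lung size
#'
#' The clinical defaults — 30 mm knot spacing and 7 mm subdomain-center
#' spacing — assume adult human lungs (about 4.5 L). For smaller domains
#' (e.g. phantoms) both spacings shrink with the cube root of the lung
#' volume so the knots-per-lung and subdomains-per-lung ratios are
#' preserved; the subdomain spacing is floored at 1.5 voxels.
#'
#' @param mask lung mask ([image_volume()]).
#' @return list with `knot_spacing_mm` and `subdomain_spacing_mm`.
#' @export
scaled_spacings <- function(mask) {
  vol_mm3 <- sum(mask$data != 0) * prod(mask$spacing)
  scale <- (vol_mm3 / 4.5e6)^(1 / 3)
  scale <- min(max(scale, 0.2), 1)
  list(knot_spacing_mm = 30 * scale,
       subdomain_spacing_mm = max(7 * scale, 1.5 * max(mask$spacing)))
}

#' Prepare a ventilation reconstruction
#'
#' Performs every tolerance-independent step once: dart-throws the MLS knots
#' and the subdomain seed points, builds the weight matrix, precomputes the
#' hit map (and, for the intensity-based method, the density volumes and
#' per-voxel density tallies), the summed-area tables used by subregion
#' growth, and the global volume constant. The result can then be solved at
#' any tolerance with [ventilate_at_tau()] or swept with [sweep_tau()].
#'
#' @param case a [vent_case()] or [generate_phantom()] result.
#' @param method `"ijf"` (transformation-based hit counting) or `"mcvc"`
#'   (intensity-based density ratios).
#' @param knot_spacing_mm,subdomain_spacing_mm sampling spacings; default
#'   [scaled_spacings()].
#' @param element box structuring element for subregion growth (odd integer
#'   triple); default from voxel anisotropy (see [grow_subregion()]).
#' @param max_dilations growth cap per subregion (default 20); subregions
#'   that never meet the tolerance are dropped.
#' @param beta Gaussian quantile of the uncertainty model (default 1.96).
#' @param seed integer seed for both dart-throwing streams.
#' @return an object of class `vent_prep`.
#' @export
prepare_ventilation <- function(case, method = c("ijf", "mcvc"),
                                knot_spacing_mm = NULL,
                                subdomain_spacing_mm = NULL,
                                element = NULL, max_dilations = 20L,
                                beta = 1.96, seed = 1L) {
  method <- match.arg(method)
  if (method == "mcvc" && is.null(case$target_image))
    stop("the intensity-based method requires a target image")
  sp <- scaled_spacings(case$mask_R)
  if (is.null(knot_spacing_mm)) knot_spacing_mm <- sp$knot_spacing_mm
  if (is.null(subdomain_spacing_mm))
    subdomain_spacing_mm <- sp$subdomain_spacing_mm
  if (is.null(element))
    element <- 2L * default_element(case$mask_R$spacing) + 1L

  knots <- dart_throw(case$mask_R, knot_spacing_mm,
                      seed = substream_seed(seed, 1L))
  model <- build_weight_matrix(case$mask_R, knots)
  seeds <- dart_throw(case$mask_R, subdomain_spacing_mm,
                      seed = substream_seed(seed, 2L))
  hit_map <- build_hit_map(case$inverse_displacement, case$mask_T, case$mask_R)

  d <- grid_geometry(case$mask_R)$dims
  maskd <- case$mask_R$data != 0
  tallies <- list(I_mask = integral_volume(array(as.numeric(maskd), d)),
                  I_hits = integral_volume(hit_map$counts))
  density_R <- density_T <- NULL
  if (method == "mcvc") {
    density_R <- hu_to_density(case$reference_image)
    density_T <- hu_to_density(case$target_image)
    rhoR <- density_R$data * maskd
    tallies$I_rhoR <- integral_volume(rhoR)
    tallies$I_rhoR2 <- integral_volume(rhoR^2)
    # per reference-voxel sums of the target densities landing there
    tvals <- density_T$data[hit_map$target_lin]
    ok <- !is.na(hit_map$mapped_lin)
    tsum <- array(0, d); tsum2 <- array(0, d)
    if (any(ok)) {
      agg <- rowsum(cbind(tvals[ok], tvals[ok]^2), hit_map$mapped_lin[ok])
      at <- as.integer(rownames(agg))
      tsum[at] <- agg[, 1]
      tsum2[at] <- agg[, 2]
    }
    tallies$I_tsum <- integral_volume(tsum)
    tallies$I_tsum2 <- integral_volume(tsum2)
    tallies$tsum <- tsum
    tallies$tsum2 <- tsum2
  }
  h <- global_constraint_constant(method, case$mask_R, case$mask_T,
                                  density_R, density_T)
  lin0 <- seeds$voxel_lin - 1L
  seed_ijk <- cbind(lin0 %% d[1], (lin0 %/% d[1]) %% d[2],
                    lin0 %/% (d[1] * d[2])) + 1L
  structure(list(case = case, method = method, model = model, knots = knots,
                 seeds = seeds, seed_ijk = seed_ijk, hit_map = hit_map,
                 tallies = tallies, density_R = density_R,
                 density_T = density_T, h = h,
                 element = element,
                 half = element_half_widths(element),
                 max_dilations = as.integer(max_dilations), beta = beta,
                 dims = d, seed = as.integer(seed)),
            class = "vent_prep")
}

#' @export
print.vent_prep <- function(x, ...) {
  cat(sprintf("<vent_prep> %s: %d knots, %d subdomain seeds, M = %d, h = %.4g\n",
              toupper(x$method), nrow(x$knots$points), nrow(x$seed_ijk),
              x$hit_map$M, x$h))
  invisible(x)
}

# growth predicate over summed-area tables, vectorized across seeds
growth_pass_fn <- function(prep, tau) {
  beta <- prep$beta
  if (prep$method == "ijf") {
    M <- prep$hit_map$M
    function(lo, hi) {
      H <- box_sums(prep$tallies$I_hits, lo, hi)
      H >= 1 & ijf_uncertainty(H, M, beta) <= tau
    }
  } else {
    function(lo, hi) {
      n <- box_sums(prep$tallies$I_mask, lo, hi)
      H <- box_sums(prep$tallies$I_hits, lo, hi)
      sR <- box_sums(prep$tallies$I_rhoR, lo, hi)
      sR2 <- box_sums(prep$tallies$I_rhoR2, lo, hi)
      sT <- box_sums(prep$tallies$I_tsum, lo, hi)
      sT2 <- box_sums(prep$tallies$I_tsum2, lo, hi)
      varR <- ifelse(n >= 2, pmax(sR2 - sR^2 / pmax(n, 1), 0) / pmax(n - 1, 1), 0)
      varT <- ifelse(H >= 2, pmax(sT2 - sT^2 / pmax(H, 1), 0) / pmax(H - 1, 1), 0)
      mT <- ifelse(H >= 1, sT / pmax(H, 1), 0)
      n >= 1 & H >= 1 & mT > 1e-3 &
        n >= (beta / tau)^2 * varR & H >= (beta / tau)^2 * varT
    }
  }
}

# fast tally-based intensity estimate; numerically equal to mcvc_estimate()
# up to summation order
mcvc_estimate_fast <- function(idx, prep, tau) {
  n <- length(idx)
  H <- sum(prep$hit_map$counts[idx])
  rR <- prep$density_R$data[idx]
  mR <- mean(rR)
  sdR <- if (n >= 2) stats::sd(rR) else 0
  sT <- sum(prep$tallies$tsum[idx])
  sT2 <- sum(prep$tallies$tsum2[idx])
  mT <- if (H >= 1) sT / H else NA_real_
  sdT <- if (H >= 2) sqrt(max(sT2 - H * mT^2, 0) / (H - 1)) else 0
  valid <- H >= 1 && is.finite(mT) && mT > 1e-3
  met <- valid && n >= (prep$beta * sdR / tau)^2 && H >= (prep$beta * sdT / tau)^2
  structure(list(region = idx, method = "mcvc", H = as.integer(H),
                 value = if (valid) mR / mT * n else NA_real_,
                 tolerance_met = met, criterion = c(sd_R = sdR, sd_T = sdT),
                 tau = tau, size = n),
            class = "subregion_estimate")
}

#' Reconstruct the ventilation image at one tolerance
#'
#' Grows every subdomain seed until its uncertainty criterion passes (or the
#' dilation cap is reached, in which case the subregion is dropped), forms
#' the subregional estimates, assembles the reduced least-squares system and
#' solves it.
#'
#' @param prep a [prepare_ventilation()] result.
#' @param tau uncertainty tolerance in (0, 1).
#' @param cfg a [solve_config()].
#' @return list with `result` (a `ventilation_result`), `K` (admissible
#'   subregions), `n_dropped`, `dilation_counts`.
#' @export
ventilate_at_tau <- function(prep, tau, cfg = solve_config()) {
  if (tau <= 0 || tau >= 1) stop("'tau' must lie in (0, 1)")
  kvec <- grow_dilation_counts(prep$seed_ijk, prep$dims, prep$half,
                               prep$max_dilations, growth_pass_fn(prep, tau))
  sel <- which(!is.na(kvec))
  if (length(sel) == 0L)
    stop(sprintf("no subregion meets tolerance %.4g within %d dilations",
                 tau, prep$max_dilations))
  maskd <- prep$case$mask_R$data
  estimates <- vector("list", length(sel))
  for (s in seq_along(sel)) {
    i <- sel[s]
    idx <- box_mask_indices(maskd, prep$seed_ijk[i, ], prep$half, kvec[i])
    estimates[[s]] <- if (prep$method == "ijf")
      ijf_estimate(idx, prep$hit_map, tau, prep$beta)
    else mcvc_estimate_fast(idx, prep, tau)
  }
  system <- assemble_system(estimates, prep$model, prep$h)
  result <- solve_ventilation(system, prep$model, cfg)
  result$tau <- tau
  list(result = result, K = nrow(system$A_hat),
       n_dropped = nrow(prep$seed_ijk) - nrow(system$A_hat),
       dilation_counts = kvec)
}

#' One-shot ventilation reconstruction
#'
#' Convenience wrapper: [prepare_ventilation()] followed by
#' [ventilate_at_tau()].
#'
#' @inheritParams prepare_ventilation
#' @param tau uncertainty tolerance.
#' @param cfg a [solve_config()].
#' @param ... passed to [prepare_ventilation()].
#' @return a `ventilation_result` (with the preparation attached as
#'   attribute `"prep"`).
#' @export
compute_ventilation <- function(case, method = c("ijf", "mcvc"), tau = 0.07,
                                cfg = solve_config(), seed = 1L, ...) {
  prep <- prepare_ventilation(case, method, seed = seed, ...)
  out <- ventilate_at_tau(prep, tau, cfg)
  res <- out$result
  attr(res, "prep") <- prep
  attr(res, "K") <- out$K
  res
}

#' Published per-case correlations (worked example data)
#'
#' Voxel-wise Spearman correlations between CT-ventilation and SPECT
#' ventilation reported for 15 lung-cancer patients, one row per method at
#' its optimal uncertainty tolerance (0.07 for the transformation-based
#' method, 0.03 for the intensity-based one). Shipped as a plain-text table
#' for the worked summary-statistics example; the underlying images are not
#' public.
#'
#' @return data.frame with columns `case`, `method`, `tau`, `rho`.
#' @export
clinical_correlations <- function() {
  path <- system.file("extdata", "clinical_correlations.csv",
                      package = "ctvent", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summary statistics and paired test for a correlations table
#'
#' Reproduces the published-table worked example: five-number summaries per
#' method and the exact Wilcoxon signed-rank comparison of the paired
#' per-case correlations.
#'
#' @param df data.frame with columns `case`, `method`, `rho` (default: the
#'   shipped [clinical_correlations()] table).
#' @return list with `summary` (one row per method) and `wilcoxon` (the
#'   paired test between the first and second method, when exactly two are
#'   present).
#' @export
correlation_table_stats <- function(df = clinical_correlations()) {
  methods <- unique(df$method)
  summ <- do.call(rbind, lapply(methods, function(m) {
    s <- summarize_correlations(df$rho[df$method == m])
    cbind(data.frame(method = m, n = sum(df$method == m)),
          as.data.frame(as.list(s)))
  }))
  wil <- NULL
  if (length(methods) == 2L) {
    a <- df[df$method == methods[1], ]
    b <- df[df$method == methods[2], ]
    a <- a[order(a$case), ]; b <- b[order(b$case), ]
    if (nrow(a) == nrow(b) && all(a$case == b$case))
      wil <- wilcoxon_signed_rank(a$rho, b$rho)
  }
  list(summary = summ, wilcoxon = wil)
}

#' Run a ventilation case from a configuration file
#'
#' File-level entry point: reads a YAML configuration naming the input
#' volumes, reconstructs the ventilation image (single tolerance or a
#' sweep), and writes the ventilation and signal volumes, a subregion
#' diagnostics table, and a machine-readable run report into the output
#' directory. Deterministic given the configured seed.
#'
#' Configuration keys: `reference_image`, `target_image`, `mask_R`,
#' `mask_T`, `displacement` (file paths); `method` (`ijf`/`mcvc`); `tau`
#' (number, or list `min`,`max`,`count` for a sweep); optional
#' `reference_ventilation` and `affine` (path to a 4 x 4 matrix as
#' whitespace-separated text) for correlation; optional `knot_spacing_mm`,
#' `subdomain_spacing_mm`, `epsilon`, `lambda_reg`, `seed`.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created if missing).
#' @return the `ventilation_result` (single tolerance) or the sweep record
#'   data.frame, invisibly.
#' @export
run_case <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  req <- c("reference_image", "mask_R", "mask_T", "displacement", "method",
           "tau")
  missing_keys <- setdiff(req, names(cfg))
  if (length(missing_keys))
    stop(sprintf("configuration is missing: %s",
                 paste(missing_keys, collapse = ", ")))
  method <- match.arg(tolower(cfg$method), c("ijf", "mcvc"))
  if (method == "mcvc" && is.null(cfg$target_image))
    stop("the intensity-based method requires a target image")
  for (key in intersect(c("reference_image", "target_image", "mask_R",
                          "mask_T", "displacement"), names(cfg)))
    if (!file.exists(cfg[[key]]))
      stop(sprintf("input file for '%s' not found: %s", key, cfg[[key]]))
  to_mask <- function(v) { v$data <- v$data != 0; v }
  case <- vent_case(read_volume(cfg$reference_image),
                    if (is.null(cfg$target_image)) NULL
                    else read_volume(cfg$target_image),
                    to_mask(read_volume(cfg$mask_R)),
                    to_mask(read_volume(cfg$mask_T)),
                    read_volume(cfg$displacement))
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  scfg <- solve_config(
    epsilon = if (is.null(cfg$epsilon)) 0.05 else cfg$epsilon,
    lambda_reg = if (is.null(cfg$lambda_reg)) 1 else cfg$lambda_reg)
  prep <- prepare_ventilation(case, method,
                              knot_spacing_mm = cfg$knot_spacing_mm,
                              subdomain_spacing_mm = cfg$subdomain_spacing_mm,
                              seed = seed)
  reference <- if (!is.null(cfg$reference_ventilation))
    read_volume(cfg$reference_ventilation) else NULL
  affine <- if (!is.null(cfg$affine))
    as.matrix(utils::read.table(cfg$affine)) else diag(4)
  dimnames(affine) <- NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.list(cfg$tau)) {
    taus <- seq(cfg$tau$min, cfg$tau$max, length.out = cfg$tau$count)
    records <- sweep_tau(prep, taus, reference = reference, affine = affine,
                         cfg = scfg)
    utils::write.csv(records, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(method = method, seed = seed,
                          n_tau = length(taus),
                          n_failed = sum(!is.na(records$error))),
                     file.path(out_dir, "report.yaml"))
    return(invisible(records))
  }

  out <- ventilate_at_tau(prep, cfg$tau, scfg)
  res <- out$result
  sig <- ventilation_signal(res)
  write_volume(res$V, file.path(out_dir, "ventilation.nii.gz"))
  write_volume(sig, file.path(out_dir, "signal.nii.gz"))
  diag_df <- data.frame(seed_lin = prep$seeds$voxel_lin,
                        dilations = out$dilation_counts)
  utils::write.csv(diag_df, file.path(out_dir, "subregions.csv"),
                   row.names = FALSE)
  report <- list(method = method, tau = cfg$tau, seed = seed,
                 K = out$K, L = ncol(prep$model$C),
                 n_dropped = out$n_dropped, M = prep$hit_map$M,
                 h = prep$h, residual_norm = res$residual_norm,
                 constraint_gap = res$constraint_gap)
  if (!is.null(reference)) {
    rho <- correlate_ventilation(sig, reference, case$mask_R, affine)
    report$spearman <- as.numeric(rho)
    report$n_voxels <- attr(rho, "n_voxels")
  }
  yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  invisible(res)
}
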