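# Shared fixtures, built once per test run and cached.

.case_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.case_cache[[key]])) .case_cache[[key]] <- builder()
  .case_cache[[key]]
}

scaling_phantom <- function() cached("scaling", function() {
  generate_phantom(phantom_spec(
    deformation = list(type = "uniform_scale", scale = c(1.1, 1.1, 1.1))))
})

identity_phantom <- function() cached("identity", function() {
  generate_phantom(phantom_spec(deformation = list(type = "identity")))
})

sinusoid_phantom <- function() cached("sinusoid", function() {
  generate_phantom(phantom_spec(
    deformation = list(type = "sinusoid", amplitude_mm = 2,
                       wavelength_mm = 40)))
})

# resolution-matched sinusoid case: same world extent, finer voxels, so the
# tolerance-driven subregion size stays below the imposed wavelength
sinusoid_phantom_fine <- function() cached("sinusoid_fine", function() {
  generate_phantom(phantom_spec(
    grid_dims = c(128, 128, 96), spacing_mm = c(1.5, 1.5, 1.5),
    deformation = list(type = "sinusoid", amplitude_mm = 2,
                       wavelength_mm = 40)))
})

scaling_prep_ijf <- function() cached("scaling_prep_ijf", function() {
  prepare_ventilation(scaling_phantom(), "ijf", seed = 42)
})

# small synthetic mask: a solid ellipsoid in a modest grid
small_mask <- function(dims = c(24, 24, 16), spacing = c(2, 2, 2)) {
  geom <- list(dims = dims, spacing = spacing, origin = c(0, 0, 0))
  X <- ctvent:::world_coordinate_matrix(geom)
  ext <- (dims - 1) * spacing
  c0 <- ext / 2
  inside <- ((X[, 1] - c0[1]) / (0.4 * ext[1]))^2 +
    ((X[, 2] - c0[2]) / (0.4 * ext[2]))^2 +
    ((X[, 3] - c0[3]) / (0.4 * ext[3]))^2 <= 1
  image_volume(array(inside, dims), spacing, c(0, 0, 0))
}

# published per-case correlation rows used in worked examples
published_rows <- function() {
  df <- clinical_correlations()
  list(ijf = df$rho[df$method == "ijf"][order(df$case[df$method == "ijf"])],
       mcvc = df$rho[df$method == "mcvc"][order(df$case[df$method == "mcvc"])])
}

# exact signed-rank p-value by full sign-flip enumeration (oracle)
wilcoxon_enumeration_oracle <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d < 0])
  sums <- 0
  for (ri in r) sums <- c(sums, sums + ri)  # all 2^n subset sums
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# global QP optimum by enumerating active sets of the lower bounds (oracle)
qp_enumeration_oracle <- function(A, b, a, h, eps, lambda, N) {
  L <- ncol(A)
  G <- crossprod(A) + diag(lambda, L)
  cc <- as.numeric(crossprod(A, b)) + lambda * h / N
  obj <- function(q) sum((A %*% q - b)^2) + lambda * sum((q - h / N)^2)
  best <- NULL; best_obj <- Inf
  for (mask in 0:(2^L - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(L - 1))) > 0)
    F_ <- setdiff(seq_len(L), S)
    q <- rep(eps, L)
    if (length(F_) > 0) {
      rhs_h <- h - eps * sum(a[S])
      cF <- cc[F_] - if (length(S)) G[F_, S, drop = FALSE] %*% rep(eps, length(S)) else 0
      K <- rbind(cbind(2 * G[F_, F_, drop = FALSE], a[F_]),
                 c(a[F_], 0))
      sol <- tryCatch(solve(K, c(2 * as.numeric(cF), rhs_h)),
                      error = function(e) NULL)
      if (is.null(sol)) next
      q[F_] <- sol[seq_along(F_)]
    } else if (abs(sum(a * q) - h) > 1e-8) next
    if (any(q < eps - 1e-9)) next
    if (abs(sum(a * q) - h) > 1e-6 * max(abs(h), 1)) next
    o <- obj(q)
    if (o < best_obj) { best_obj <- o; best <- q }
  }
  list(q = best, objective = best_obj)
}
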