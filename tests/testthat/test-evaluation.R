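test_that("identity affine on identical grids returns the input", {
  vol <- image_volume(array(runif(8 * 8 * 6), c(8, 8, 6)), c(2, 2, 3))
  out <- resample_with_affine(vol, diag(4), vol)
  expect_equal(out$data, vol$data, tolerance = 1e-12)
  expect_error(resample_with_affine(vol, matrix(0, 4, 4), vol), "singular")
})

test_that("translating a constant image by one voxel keeps it constant", {
  vol <- image_volume(array(5, c(8, 8, 6)), c(2, 2, 3))
  aff <- diag(4); aff[1, 4] <- 2
  out <- resample_with_affine(vol, aff, vol)
  inside <- !is.na(out$data)
  expect_true(all(out$data[inside] == 5))
})

test_that("downsampling a ramp hits the coarse voxel centers exactly", {
  d <- c(16, 16, 8)
  geom <- list(dims = d, spacing = c(1, 1, 2), origin = c(0, 0, 0))
  X <- ctvent:::world_coordinate_matrix(geom)
  ramp <- 2 * X[, 1] + 0.5 * X[, 2] - X[, 3]
  vol <- image_volume(array(ramp, d), geom$spacing, geom$origin)
  coarse <- list(dims = c(8, 8, 4), spacing = c(2, 2, 4), origin = c(0, 0, 0))
  out <- resample_with_affine(vol, diag(4), coarse)
  Xc <- ctvent:::world_coordinate_matrix(coarse)
  expect_equal(as.numeric(out$data), 2 * Xc[, 1] + 0.5 * Xc[, 2] - Xc[, 3],
               tolerance = 1e-6)
})

test_that("slice-wise median filtering matches the sliding-window oracle", {
  set.seed(14)
  d <- c(8, 8, 2)
  vol <- image_volume(array(rnorm(prod(d)), d))
  out <- median_filter_slicewise(vol)
  for (k in 1:d[3]) for (i in 1:d[1]) for (j in 1:d[2]) {
    nb <- vol$data[max(1, i - 1):min(d[1], i + 1),
                   max(1, j - 1):min(d[2], j + 1), k]
    expect_equal(out$data[i, j, k], median(nb))
  }
})

test_that("median filtering removes impulses and keeps constants", {
  a <- array(2, c(8, 8, 1)); a[4, 4, 1] <- 100
  out <- median_filter_slicewise(image_volume(a))
  expect_true(all(out$data == 2))
})

test_that("masked Spearman correlation behaves at the definitional extremes", {
  d <- c(6, 6, 3)
  set.seed(4)
  vals <- rnorm(prod(d))
  a <- image_volume(array(vals, d))
  b <- image_volume(array(-vals, d))
  mask <- image_volume(array(TRUE, d))
  expect_equal(as.numeric(spearman_masked(a, a, mask)), 1)
  expect_equal(as.numeric(spearman_masked(a, b, mask)), -1)
  const <- image_volume(array(1, d))
  expect_true(is.na(spearman_masked(a, const, mask)))
  tiny <- image_volume(array(c(TRUE, rep(FALSE, prod(d) - 1)), d))
  expect_error(spearman_masked(a, b, tiny), "3 usable")
})

test_that("Spearman is invariant under strictly increasing transforms", {
  d <- c(6, 6, 3)
  set.seed(9)
  a <- image_volume(array(rnorm(prod(d)), d))
  b <- image_volume(array(rnorm(prod(d)), d))
  mask <- image_volume(array(TRUE, d))
  base <- spearman_masked(a, b, mask)
  a2 <- a; a2$data <- exp(a$data)
  b2 <- b; b2$data <- 3 * b$data - 7
  expect_equal(as.numeric(spearman_masked(a2, b2, mask)),
               as.numeric(base), tolerance = 1e-12)
})

test_that("the published paired rows correlate as rank-then-Pearson says", {
  rows <- published_rows()
  oracle <- cor(rank(rows$ijf), rank(rows$mcvc))
  expect_equal(cor(rows$ijf, rows$mcvc, method = "spearman"), oracle,
               tolerance = 1e-12)
})

test_that("five-number summaries reproduce the published row statistics", {
  rows <- published_rows()
  s_ijf <- summarize_correlations(rows$ijf)
  expect_equal(unname(s_ijf[c("min", "median", "max")]), c(0.12, 0.82, 0.90))
  s_mcvc <- summarize_correlations(rows$mcvc)
  expect_equal(unname(s_mcvc[c("min", "median", "max")]), c(-0.06, 0.48, 0.84))
  expect_equal(unname(summarize_correlations(7)), rep(7, 5))
  expect_error(summarize_correlations(numeric(0)), "non-empty")
})

test_that("signed-rank extremes have closed-form p-values", {
  w <- wilcoxon_signed_rank(seq(0.1, 1.5, by = 0.1))  # 15 positive diffs
  expect_equal(w$w_minus, 0)
  expect_equal(w$p_value, 2 / 2^15, tolerance = 1e-12)
  # symmetric configuration: p = 1
  d <- c(1, -1, 2, -2, 3, -3, 4, -4)
  expect_equal(wilcoxon_signed_rank(d)$p_value, 1, tolerance = 1e-12)
})

test_that("exact signed-rank p matches full sign-flip enumeration", {
  rows <- published_rows()
  d <- rows$ijf - rows$mcvc
  w <- wilcoxon_signed_rank(rows$ijf, rows$mcvc)
  # the single negative difference carries the rank of |-0.40|
  expect_equal(w$w_minus, rank(abs(d))[d < 0][[1]])
  expect_equal(w$p_value, wilcoxon_enumeration_oracle(d), tolerance = 1e-12)
  expect_match(w$method, "exact")
  # random tied instances
  set.seed(6)
  for (rep in 1:5) {
    d <- round(rnorm(11), 1)
    d <- d[d != 0]
    if (length(d) < 5) next
    expect_equal(wilcoxon_signed_rank(d)$p_value,
                 wilcoxon_enumeration_oracle(d), tolerance = 1e-12)
  }
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(8)
  d <- rnorm(40, mean = 0.3)
  w <- wilcoxon_signed_rank(d)
  expect_match(w$method, "normal")
  ref <- suppressWarnings(wilcox.test(d, exact = FALSE, correct = FALSE))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("sweep summaries order percentiles and locate the best tolerance", {
  rec <- data.frame(case_id = rep(c("a", "b", "c"), each = 3),
                    tau = rep(c(0.05, 0.1, 0.15), 3),
                    rho = c(0.5, 0.9, 0.7, 0.4, 0.8, 0.6, 0.45, 0.85, 0.65))
  s <- summarize_sweep(rec)
  expect_equal(nrow(s$curves), 3)
  expect_equal(s$optimal_tau, 0.1)
  expect_true(all(s$curves$min <= s$curves$q25 &
                    s$curves$q25 <= s$curves$median &
                    s$curves$median <= s$curves$q75 &
                    s$curves$q75 <= s$curves$max))
})
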