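test_that("fluctuations are exactly centered on complete matrices", {
  x <- random_ctm(10, 6, seed = 71)
  fl <- fluctuations(x)
  expect_equal(unname(rowSums(fl$gene_fluct)), rep(0, 10), tolerance = 1e-12)
  expect_equal(sum(fl$mean_fluct), 0, tolerance = 1e-12)
  # the sample-mean fluctuation is the average of the gene fluctuations
  expect_equal(colMeans(fl$gene_fluct), fl$mean_fluct, tolerance = 1e-12)
  expect_equal(unname(fluctuations(ctm(c(10, 14), 1, 2))$gene_fluct[1, ]),
               c(-2, 2))
  const <- ctm(matrix(20, 4, 5))
  expect_true(all(fluctuations(const)$gene_fluct == 0))
})

test_that("sd-vs-mean trend recovers engineered and generated coefficients", {
  # genes with identical sd at all mean levels -> slope 0
  base <- c(-1, 0, 1) / sd(c(-1, 0, 1))
  v <- outer(c(16, 22, 28, 34), rep(1, 3)) + matrix(rep(0.5 * base, each = 4), 4)
  tr0 <- sd_vs_mean_trend(ctm(v))
  expect_equal(tr0$slope, 0, tolerance = 1e-12)
  expect_equal(tr0$intercept, 0.5, tolerance = 1e-12)
  # two points: exact interpolating line (guard relaxed)
  v2 <- rbind(20 + 0.2 * base, 30 + 0.8 * base)
  tr2 <- sd_vs_mean_trend(ctm(v2), min_genes = 2)
  expect_equal(tr2$slope, (0.8 - 0.2) / 10, tolerance = 1e-12)
  # generated: noise sd linear in mean CT with known coefficients; the
  # empirical per-gene sd also carries the offset term
  # sqrt(s_g^2 tau^2 (1 - 1/n) + sigma_g^2), so compare against the slope of
  # that analytic expectation rather than d itself
  sim <- simulate_ct(n_genes = 500, n_samples = 20, seed = 72)
  tr <- sd_vs_mean_trend(sim$matrix)
  tth <- sim$truth
  expected_sd <- sqrt(tth$sensitivities^2 * var(tth$sample_offsets) +
                      tth$noise_sd^2)
  analytic <- lm.fit(cbind(1, tth$gene_means), expected_sd)$coefficients[2]
  expect_equal(tr$slope, unname(analytic), tolerance = 0.2)
  expect_gt(tr$slope, 0)   # the bias signature: variance grows with CT
})

test_that("homogeneous generation shows no sd-vs-mean trend", {
  sim <- simulate_ct(n_genes = 500, n_samples = 20,
                     sensitivities = 1, noise_sd = 0.4, seed = 73)
  tr <- sd_vs_mean_trend(sim$matrix)
  expect_equal(tr$slope, 0, tolerance = 0.01)
})

test_that("correlation with the mean hits the exact and null cases", {
  x <- random_ctm(10, 8, seed = 74)
  fl <- fluctuations(x)
  v <- x$values
  v <- rbind(v, mirror = 30 + fl$mean_fluct, anti = 30 - fl$mean_fluct)
  xc <- ct_matrix(v)
  co <- correlation_with_mean(xc)
  expect_equal(unname(co["mirror"]), 1, tolerance = 1e-9)
  expect_equal(unname(co["anti"]), -1, tolerance = 1e-9)
  expect_true(all(co >= -1 & co <= 1, na.rm = TRUE))
  # zero-variance gene: undefined, not 0
  v2 <- rbind(v, flat = rep(25, 8))
  expect_true(is.na(correlation_with_mean(ct_matrix(v2))["flat"]))
  # independent gene among many: near-zero correlation at fixed seed
  sim <- simulate_ct(n_genes = 200, n_samples = 36, sensitivities = 1,
                     noise_sd = 0.3, seed = 75)
  vi <- sim$matrix$values
  set.seed(76)
  vi <- rbind(vi, indep = runif(36, 20, 21))
  ci <- correlation_with_mean(ct_matrix(vi))
  expect_lt(abs(ci["indep"]), 3 / sqrt(36))
})

test_that("sensitivity slopes: exact multiples, averaging identity, recovery", {
  # genes built as exact multiples of a shared offset: fluct_g = c_g * delta,
  # with mean(c) = 1 so the sample-mean fluctuation is exactly delta
  delta <- c(-0.6, -0.2, 0.1, 0.3, 0.4)
  cs <- c(zero = 0, half = 0.5, one = 1, two = 2, rest = 1.5)
  v <- 25 + outer(cs, delta)
  rownames(v) <- names(cs); colnames(v) <- paste0("s", 1:5)
  sl <- sensitivity_slopes(ct_matrix(v))
  expect_equal(unname(sl[names(cs)]), unname(cs), tolerance = 1e-9)
  # slopes average to exactly 1 on complete matrices
  xr <- random_ctm(8, 10, seed = 77)
  expect_equal(mean(sensitivity_slopes(xr)), 1, tolerance = 1e-12)
  expect_error(sensitivity_slopes(ctm(matrix(20, 3, 4))), "degenerate")
  # parameter recovery: generating slopes {0.5, 1, 2} in proportions with
  # mean 1, light noise, 40 samples
  sim <- simulate_ct(n_genes = 400, n_samples = 40,
                     sensitivities = rep(c(0.5, 1, 2), c(200, 100, 100)),
                     noise_sd = 0.05, offset_sd = 0.5, seed = 78)
  got <- sensitivity_slopes(sim$matrix)
  truth <- sim$truth$sensitivities
  for (s_true in c(0.5, 1, 2)) {
    grp <- names(truth)[truth == s_true]
    expect_lt(max(abs(got[grp] - s_true)), 0.1)
  }
})

test_that("difference ratio equals the slope for exact multiples and guards near-zero means", {
  delta <- c(-0.5, -0.1, 0.2, 0.4)
  cs <- c(half = 0.5, thrice = 3, a = 0.25, b = 0.25)   # mean(c) = 1
  v <- 25 + outer(cs, delta)
  rownames(v) <- names(cs); colnames(v) <- paste0("s", 1:4)
  xr <- ct_matrix(v)
  dr <- difference_ratio(xr, guard = 0.01)
  expect_equal(unname(dr["half"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(dr["thrice"]), 3, tolerance = 1e-9)
  # noise-free synthetic data: ratio and slope coincide exactly
  sim <- simulate_ct(n_genes = 30, n_samples = 10, noise_sd = 0, seed = 80)
  expect_equal(difference_ratio(sim$matrix, guard = 0.01),
               sensitivity_slopes(sim$matrix), tolerance = 1e-9)
  expect_error(difference_ratio(xr, guard = 1e6), "guard")
})

test_that("sensitivity rises with mean CT on bias-model data", {
  sim <- simulate_ct(n_genes = 300, n_samples = 20, seed = 81)
  sl <- sensitivity_slopes(sim$matrix)
  rho <- cor(rowMeans(sim$matrix$values), sl, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("bias_report aggregates consistently and handles degenerate input", {
  sim <- simulate_ct(n_genes = 50, n_samples = 8, seed = 82)
  rep1 <- bias_report(sim$matrix)
  rep2 <- bias_report(sim$matrix)
  expect_identical(rep1, rep2)
  expect_equal(rep1$gene_id, names(gene_sd(sim$matrix)))
  expect_equal(rep1$sd, unname(gene_sd(sim$matrix)))
  const <- ctm(matrix(20, 4, 5))
  repc <- bias_report(const)
  expect_equal(attr(repc, "trend_slope"), 0)
  expect_true(all(is.na(repc$sensitivity_slope) | repc$sensitivity_slope == 0))
})
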