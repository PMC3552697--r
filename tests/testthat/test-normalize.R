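test_that("delta_ct subtracts per-sample CT0 and is invertible", {
  x <- random_ctm(6, 4, seed = 51)
  ct0 <- mean_ct0(x)
  d <- delta_ct(x, ct0)
  expect_equal(d$values["g1", "s2"], x$values["g1", "s2"] - ct0$values["s2"],
               ignore_attr = TRUE)
  back <- sweep(d$values, 2, ct0$values[colnames(d$values)], "+")
  expect_equal(back, x$values)
  # CT0 equal to one gene's own row zeroes that gene
  own <- topk_ct0(x, 1)
  d1 <- delta_ct(x, own)
  expect_equal(unname(d1$values[own$params$genes, ]), rep(0, 4))
  bad <- ct0; names(bad$values) <- paste0("z", 1:4)
  expect_error(delta_ct(x, bad), "sample ids")
})

test_that("delta-delta-CT and fold change obey the doubling calculus", {
  fc <- fold_change(c(g1 = 5, g2 = 4, g3 = 8), c(g1 = 5, g2 = 5, g3 = 5))
  expect_equal(fc$fold_change, c(1, 2, 0.125))
  set.seed(52)
  ddct <- rnorm(50, sd = 3)
  names(ddct) <- paste0("g", 1:50)
  zero <- setNames(rep(0, 50), names(ddct))
  out <- fold_change(ddct, zero)
  expect_equal(-log2(out$fold_change), unname(ddct), tolerance = 1e-12)
  expect_true(all(out$fold_change > 0))
  expect_error(fold_change(c(a = 1), c(b = 1)), "gene ids")
})

test_that("quantile normalization equalizes per-sample distributions and preserves ranks", {
  for (seed in c(53, 54)) {
    x <- random_ctm(20, 5, seed = seed)
    q <- quantile_normalize(x)
    sorted <- apply(q$values, 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
    for (s in colnames(q$values))
      expect_equal(rank(q$values[, s]), rank(x$values[, s]))
  }
  # 3x2 worked case: samples (1,2,3) and (4,5,6) -> both (2.5, 3.5, 4.5)
  x2 <- ctm(cbind(c(1, 2, 3), c(4, 5, 6)))
  q2 <- quantile_normalize(x2)
  expect_equal(unname(q2$values), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
  expect_equal(quantile_normalize(ctm(cbind(c(20, 25, 30))))$values,
               ctm(cbind(c(20, 25, 30)))$values)  # single sample unchanged
  x$values[1, 1] <- NA
  expect_error(quantile_normalize(x), "filter_genes")
})

test_that("quantile normalization agrees with the limma reference on untied data", {
  skip_if_not_installed("limma")
  x <- random_ctm(30, 4, seed = 55)
  q <- quantile_normalize(x)
  ref <- limma::normalizeQuantiles(x$values, ties = TRUE)
  expect_equal(q$values, ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("median normalization equalizes medians and preserves within-sample differences", {
  v <- cbind(s1 = c(18, 20, 22), s2 = c(20, 22, 24), s3 = c(26, 30, 34))
  rownames(v) <- paste0("g", 1:3)
  m <- median_normalize(ct_matrix(v))
  # medians 20, 22, 30 -> overall 22 -> shifts +2, 0, -8
  expect_equal(unname(apply(m$values, 2, median)), rep(22, 3))
  expect_equal(m$values[, "s1"], v[, "s1"] + 2)
  expect_equal(m$values[, "s3"], v[, "s3"] - 8)
  expect_equal(diff(m$values[, "s3"]), diff(v[, "s3"]))
  same <- ctm(cbind(c(1, 2, 3), c(0.5, 2, 9)))
  expect_equal(median_normalize(same)$values, same$values)
})

test_that("cyclic loess removes intensity-dependent disagreement between samples", {
  x <- random_ctm(60, 2, seed = 56)
  ident <- x; ident$values[, 2] <- ident$values[, 1]
  colnames(ident$values) <- colnames(ident$undetected) <- c("s1", "s2")
  out <- cyclic_loess_normalize(ident)
  expect_equal(out$values, ident$values, tolerance = 1e-9)

  # constant multiplicative offset between two samples: mean |M| must shrink
  xm <- x; xm$values[, 2] <- xm$values[, 1] * 1.06
  pre_M <- mean(abs(log(xm$values[, 1]) - log(xm$values[, 2])))
  res <- cyclic_loess_normalize(xm, max_cycles = 5, tol = 1e-4)
  post_M <- mean(abs(log(res$values[, 1]) - log(res$values[, 2])))
  expect_lt(post_M, pre_M)
})

test_that("cyclic loess converges and is near-invariant to sample order", {
  # data with shared structure (loading offsets), where the pairwise trends
  # are real and the cycle reaches its residual plateau quickly
  x <- simulate_ct(n_genes = 50, n_samples = 3, seed = 57)$matrix
  a <- cyclic_loess_normalize(x, max_cycles = 10, tol = 1e-3)
  expect_true(a$params$converged)
  for (perm in list(c(3, 1, 2), c(2, 3, 1))) {
    xp <- x
    xp$values <- x$values[, perm]
    xp$undetected <- x$undetected[, perm]
    b <- cyclic_loess_normalize(xp, max_cycles = 10, tol = 1e-3)
    expect_lt(max(abs(b$values[, colnames(x$values)] - a$values)), 0.1)
  }
})

test_that("cyclic loess reports non-convergence without failing", {
  x <- simulate_ct(n_genes = 40, n_samples = 3, seed = 59)$matrix
  expect_warning(res <- cyclic_loess_normalize(x, max_cycles = 1, tol = 1e-9),
                 "did not converge")
  expect_false(res$params$converged)
  expect_match(res$notes, "did not converge")
})

test_that("normalize_ct dispatches every method with its parameters", {
  sim <- simulate_ct(n_genes = 30, n_samples = 6, seed = 58)
  x <- sim$matrix
  w <- normalize_ct(x, "weighted", wmp = 13)
  expect_equal(w$scale, "delta_ct")
  expect_equal(w$values, delta_ct(x, weighted_mean_ct0(x, wmp = 13))$values)
  expect_equal(normalize_ct(x, "topk", k = 5)$values,
               delta_ct(x, topk_ct0(x, 5))$values)
  expect_equal(normalize_ct(x, "quantile")$scale, "adjusted_ct")
  expect_equal(normalize_ct(x, "geomean")$values,
               delta_ct(x, mean_ct0(x, "geometric"))$values)
})
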