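#' Gene and sample-mean fluctuations
#'
#' A gene's fluctuation in a sample is its CT deviation from that gene's own
#' across-sample mean; a sample's mean fluctuation is the deviation of the
#' sample mean from the overall mean. On complete matrices both are exactly
#' centered, and the sample-mean fluctuation equals the per-sample average of
#' the gene fluctuations — which is why these are the natural coordinates for
#' asking how strongly each gene tracks sample-wide loading differences.
#'
#' @param x a [ct_matrix()] with `>= 2` samples.
#' @return list with `gene_fluct` (genes x samples matrix) and `mean_fluct`
#'   (per-sample vector). Missing cells stay missing.
#' @export
fluctuations <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  v <- x$values
  if (ncol(v) < 2) stop("need >= 2 samples")
  gene_fluct <- v - rowMeans(v, na.rm = TRUE)
  mean_fluct <- colMeans(v, na.rm = TRUE) - mean(v, na.rm = TRUE)
  list(gene_fluct = gene_fluct, mean_fluct = mean_fluct)
}

#' Linear trend of per-gene sd on per-gene mean CT
#'
#' The first signature of the expression-level-dependent bias in CT data:
#' genes measured at higher CT (lower abundance) show larger across-sample
#' standard deviations. Ordinary least squares of sd on mean CT quantifies
#' the trend; a positive slope is the bias.
#'
#' @param x a [ct_matrix()] with `>= 3` genes having a defined sd.
#' @param min_genes minimum number of points required for the fit (default 3;
#'   with exactly 2 the fit is the exact interpolating line).
#' @return list with `slope`, `intercept` (cycles of sd per cycle of mean CT)
#'   and `points`, a data frame of the per-gene (mean_ct, sd) pairs.
#' @export
sd_vs_mean_trend <- function(x, min_genes = 3) {
  stopifnot(inherits(x, "ct_matrix"))
  sds <- gene_sd(x)
  if (length(sds) < min_genes)
    stop("need >= ", min_genes, " genes with a defined sd, have ", length(sds))
  mean_ct <- rowMeans(x$values[names(sds), , drop = FALSE], na.rm = TRUE)
  if (stats::var(mean_ct) == 0) {
    # degenerate design: all genes share a mean CT; the flat line fits when
    # the sds are constant too, otherwise no slope is identifiable
    slope <- if (stats::var(sds) == 0) 0 else NA_real_
    co <- c(mean(sds), slope)
  } else {
    co <- stats::lm.fit(cbind(1, mean_ct), sds)$coefficients
  }
  list(slope = unname(co[2]),
       intercept = unname(co[1]),
       points = data.frame(gene_id = names(sds), mean_ct = unname(mean_ct),
                           sd = unname(sds), stringsAsFactors = FALSE))
}

#' Per-gene correlation with the sample-mean fluctuation
#'
#' Pearson correlation of each gene's fluctuation vector with the sample-mean
#' fluctuation vector. High correlation at high CT shows that low-abundance
#' genes do not merely vary more — their variation tracks the sample-wide
#' loading differences, i.e. it is systematic rather than random noise.
#'
#' For a gene with missing wells the sample-mean fluctuation is recomputed
#' over that gene's observed samples. Genes with zero fluctuation variance
#' get `NA`, not 0.
#'
#' @param x a [ct_matrix()] with `>= 3` samples.
#' @return named numeric vector of per-gene correlations in [-1, 1].
#' @export
correlation_with_mean <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  v <- x$values
  if (ncol(v) < 3) stop("need >= 3 samples")
  fl <- fluctuations(x)
  vapply(rownames(v), function(g) {
    obs <- !is.na(v[g, ])
    if (sum(obs) < 3) return(NA_real_)
    gf <- v[g, obs] - mean(v[g, obs])
    mf <- if (all(obs)) fl$mean_fluct else {
      sub <- colMeans(v[, obs, drop = FALSE], na.rm = TRUE)
      sub - mean(sub)
    }
    if (stats::sd(gf) == 0 || stats::sd(mf) == 0) return(NA_real_)
    stats::cor(gf, mf)
  }, numeric(1))
}

#' Per-gene sensitivity of fluctuations to the sample mean
#'
#' For each gene, the OLS slope of its fluctuations on the sample-mean
#' fluctuations. A slope of 1 means the gene moves one-for-one with the
#' sample mean; slopes above 1 mark genes whose CT over-responds to loading
#' differences — the hallmark of low-abundance genes in RT-PCR data. Both
#' variables are centered, so no intercept is fitted. On complete matrices
#' the slopes average exactly 1 across genes, because the mean fluctuation
#' is itself the average of the gene fluctuations.
#'
#' @param x a [ct_matrix()] with `>= 3` samples and non-degenerate sample
#'   means (some spread in `mean_fluct`).
#' @return named numeric vector of per-gene slopes (dimensionless).
#' @export
sensitivity_slopes <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  v <- x$values
  if (ncol(v) < 3) stop("need >= 3 samples")
  fl <- fluctuations(x)
  if (all(abs(fl$mean_fluct) < .Machine$double.eps^0.5))
    stop("sample-mean fluctuations are all zero: degenerate design, ",
         "no slope is identifiable")
  vapply(rownames(v), function(g) {
    obs <- !is.na(v[g, ])
    if (sum(obs) < 3) return(NA_real_)
    gf <- v[g, obs] - mean(v[g, obs])
    mf <- if (all(obs)) fl$mean_fluct else {
      sub <- colMeans(v[, obs, drop = FALSE], na.rm = TRUE)
      sub - mean(sub)
    }
    den <- sum(mf^2)
    if (den == 0) return(NA_real_)
    sum(gf * mf) / den
  }, numeric(1))
}

#' Mean ratio of gene fluctuation to sample-mean fluctuation
#'
#' For each gene, the average over samples of
#' `gene_fluct / mean_fluct` — an alternative, ratio-based reading of the
#' sensitivity that the slope measures by regression. The ratio blows up in
#' samples whose mean fluctuation is near zero, so samples with
#' `|mean_fluct| < guard` are excluded.
#'
#' @param x a [ct_matrix()].
#' @param guard minimum absolute sample-mean fluctuation (cycles) for a
#'   sample to enter the ratio; default 0.05.
#' @return named numeric vector of per-gene mean difference ratios.
#' @export
difference_ratio <- function(x, guard = 0.05) {
  stopifnot(inherits(x, "ct_matrix"))
  fl <- fluctuations(x)
  ok <- abs(fl$mean_fluct) >= guard
  if (!any(ok))
    stop("no sample has |mean fluctuation| >= ", guard,
         "; use a smaller guard")
  ratios <- sweep(fl$gene_fluct[, ok, drop = FALSE], 2, fl$mean_fluct[ok], "/")
  rowMeans(ratios, na.rm = TRUE)
}

#' Full bias diagnostic report
#'
#' Assembles the expression-level-dependence diagnostics into one per-gene
#' table: mean CT, across-sample sd, correlation with the sample-mean
#' fluctuation, sensitivity slope, and mean difference ratio, plus the
#' sd-vs-mean trend line as attributes. On a degenerate input (all samples
#' identical) the slopes and ratios are reported as `NA`.
#'
#' @param x a [ct_matrix()].
#' @param guard passed to [difference_ratio()].
#' @return a data frame of class `bias_report` with one row per gene and
#'   attributes `trend_slope`, `trend_intercept`.
#' @export
bias_report <- function(x, guard = 0.05) {
  stopifnot(inherits(x, "ct_matrix"))
  ids <- rownames(x$values)
  mean_ct <- rowMeans(x$values, na.rm = TRUE)
  sds <- gene_sd(x)
  sd_full <- stats::setNames(rep(NA_real_, length(ids)), ids)
  sd_full[names(sds)] <- sds
  corr <- correlation_with_mean(x)
  slopes <- tryCatch(sensitivity_slopes(x), error = function(e)
    stats::setNames(rep(NA_real_, length(ids)), ids))
  ratios <- tryCatch(difference_ratio(x, guard = guard), error = function(e)
    stats::setNames(rep(NA_real_, length(ids)), ids))
  trend <- tryCatch(sd_vs_mean_trend(x),
                    error = function(e) list(slope = NA_real_,
                                             intercept = NA_real_))
  rep <- data.frame(gene_id = ids, mean_ct = unname(mean_ct),
                    sd = unname(sd_full), corr_with_mean = unname(corr[ids]),
                    sensitivity_slope = unname(slopes[ids]),
                    mean_difference_ratio = unname(ratios[ids]),
                    stringsAsFactors = FALSE)
  rownames(rep) <- NULL
  attr(rep, "trend_slope") <- trend$slope
  attr(rep, "trend_intercept") <- trend$intercept
  class(rep) <- c("bias_report", "data.frame")
  rep
}

#' @export
print.bias_report <- function(x, n = 10, ...) {
  cat(sprintf("bias_report: %d genes\n", nrow(x)))
  cat(sprintf("  sd-vs-mean-CT trend: slope %.4g, intercept %.4g\n",
              attr(x, "trend_slope"), attr(x, "trend_intercept")))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more genes\n")
  invisible(x)
}

#' @export
plot.bias_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$mean_ct, x$sd, xlab = "mean CT (cycles)",
                 ylab = "sd (cycles)", main = "Variability vs expression", ...)
  graphics::abline(attr(x, "trend_intercept"), attr(x, "trend_slope"),
                   col = 2, lwd = 2)
  graphics::plot(x$mean_ct, x$sensitivity_slope, xlab = "mean CT (cycles)",
                 ylab = "sensitivity slope",
                 main = "Fluctuation response vs expression", ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
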