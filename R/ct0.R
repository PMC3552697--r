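#' Per-gene standard deviation across samples
#'
#' The across-sample standard deviation of a gene's CT values is the
#' stability measure that drives both the top-k and the weighted-mean
#' pseudo-control: the smaller the sd, the more stable the gene. Computed with
#' the sample (n-1) denominator over non-missing entries; genes with fewer
#' than 2 observed values have no defined sd and are omitted (their ids are
#' attached as attribute `"omitted"`).
#'
#' @param x a [ct_matrix()].
#' @return named numeric vector of per-gene sds, in cycles.
#' @export
gene_sd <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  n_obs <- rowSums(!is.na(x$values))
  sds <- apply(x$values, 1, stats::sd, na.rm = TRUE)
  ok <- n_obs >= 2
  out <- sds[ok]
  if (any(!ok)) attr(out, "omitted") <- rownames(x$values)[!ok]
  out
}

new_ct0 <- function(values, method, params = list()) {
  if (any(!is.finite(values))) stop("CT0 values must be finite")
  structure(list(values = values, method = method, params = params),
            class = "ct0")
}

#' @export
print.ct0 <- function(x, ...) {
  cat(sprintf("ct0 pseudo-control (%s): %d samples\n", x$method,
              length(x$values)))
  core <- x$params[setdiff(names(x$params), c("weights", "genes"))]
  if (length(core))
    cat("  params:", paste(names(core), unlist(lapply(core, format)),
                           sep = "=", collapse = ", "), "\n")
  cat(sprintf("  mean %.3f, sd %.3f cycles\n", mean(x$values),
              stats::sd(x$values)))
  print(round(x$values, 3))
  invisible(x)
}

#' Plain mean, median or geometric-mean pseudo-control
#'
#' Uses a per-sample location statistic over all observed genes as the
#' reference CT0 subtracted from every gene's CT. The geometric mean is taken
#' on the CT values themselves (CT is already a log-scale quantity).
#'
#' @param x a [ct_matrix()].
#' @param kind `"arithmetic"`, `"geometric"` or `"median"`.
#' @return a `ct0` object: one CT0 value per sample.
#' @export
mean_ct0 <- function(x, kind = c("arithmetic", "geometric", "median")) {
  stopifnot(inherits(x, "ct_matrix"))
  kind <- match.arg(kind)
  v <- x$values
  empty <- colSums(!is.na(v)) == 0
  if (any(empty))
    stop("sample(s) with no observed CT values: ",
         paste(colnames(v)[empty], collapse = ", "))
  vals <- switch(kind,
    arithmetic = colMeans(v, na.rm = TRUE),
    median = apply(v, 2, stats::median, na.rm = TRUE),
    geometric = exp(colMeans(log(v), na.rm = TRUE)))
  new_ct0(vals, method = paste0(kind, "_mean"), params = list(kind = kind))
}

#' Top-k most-stable-genes pseudo-control
#'
#' Genes are ranked by increasing across-sample standard deviation; the CT
#' values of the k most stable genes are averaged in each sample. The selected
#' gene set is the same for every sample and is reported in `params$genes`.
#' Ties in the sd ranking are broken by gene id, for determinism.
#'
#' @param x a [ct_matrix()].
#' @param k number of stable genes to average, `1 <= k <=` number of genes
#'   with a defined sd.
#' @return a `ct0` object.
#' @export
topk_ct0 <- function(x, k) {
  stopifnot(inherits(x, "ct_matrix"))
  sds <- gene_sd(x)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("`k` must be a positive integer")
  if (k > length(sds))
    stop("k = ", k, " exceeds the ", length(sds),
         " genes with a defined standard deviation")
  ord <- order(sds, names(sds))
  top <- names(sds)[ord][seq_len(k)]
  vals <- colMeans(x$values[top, , drop = FALSE], na.rm = TRUE)
  new_ct0(vals, method = "topk", params = list(k = k, genes = top))
}

#' Weighted-mean pseudo endogenous control
#'
#' Every gene contributes to the per-sample reference CT0, weighted by its
#' empirical stability: gene j receives weight proportional to
#' `(1 / max(sd_j, epsilon))^wmp`, where `sd_j` is its across-sample standard
#' deviation and `wmp` is the weighted mean power. `wmp = 0` gives uniform
#' weights (the plain arithmetic mean); increasing `wmp` shifts dominance
#' toward the most stable genes, and in the large-`wmp` limit the CT0 equals
#' the single most stable gene's CT row. Weights are normalized to sum to 1
#' per sample over the genes observed in that sample, so missing wells do not
#' bias the reference.
#'
#' @param x a [ct_matrix()].
#' @param wmp weighted mean power, `>= 0`. Default 1.
#' @param epsilon floor applied to per-gene sds (cycles) so that
#'   zero-variance genes do not receive infinite weight. Default 0.01.
#' @return a `ct0` object; `params$weights` holds the (unnormalized-per-
#'   sample) gene weights actually used.
#' @examples
#' m <- matrix(c(10, 20, 12, 21), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' x <- ct_matrix(m)
#' weighted_mean_ct0(x, wmp = 1)$values  # weights 1/3, 2/3 -> 16.667, 18.0
#' @export
weighted_mean_ct0 <- function(x, wmp = 1, epsilon = 0.01) {
  stopifnot(inherits(x, "ct_matrix"))
  if (!is.numeric(wmp) || length(wmp) != 1 || wmp < 0)
    stop("`wmp` must be a single nonnegative number")
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("`epsilon` must be a single positive number")
  sds <- gene_sd(x)
  if (length(sds) == 0)
    stop("no gene has a defined standard deviation (need >= 2 observed values)")
  # log-space for numerical stability at large wmp: (1/sd)^wmp can overflow
  lw <- -wmp * log(pmax(sds, epsilon))
  w <- exp(lw - max(lw))
  v <- x$values[names(sds), , drop = FALSE]
  obs <- !is.na(v)
  wm <- w * obs                       # per-sample weights over observed genes
  vals <- colSums(v * wm, na.rm = TRUE) / colSums(wm)
  if (any(!is.finite(vals)))
    stop("sample(s) with no observed weighted genes: ",
         paste(colnames(v)[!is.finite(vals)], collapse = ", "))
  new_ct0(vals, method = "weighted_mean",
          params = list(wmp = wmp, epsilon = epsilon, weights = w / sum(w)))
}

#' Rank-invariant-set pseudo-control
#'
#' Genes whose within-sample expression rank stays within `rank_window` of
#' their rank in a reference sample, in every sample, form the rank-invariant
#' set; its per-sample mean CT is the pseudo-control. Only fully observed
#' genes are candidates (ranks are not comparable across differing gene
#' sets). The default reference is the sample whose mean CT is the median of
#' the per-sample means.
#'
#' @param x a [ct_matrix()].
#' @param reference a sample id, or `"median_sample"` (default).
#' @param rank_window maximum allowed rank displacement; default
#'   `ceiling(0.05 * n_genes)`.
#' @return a `ct0` object; `params$genes` holds the rank-invariant set.
#' @export
rank_invariant_ct0 <- function(x, reference = "median_sample",
                               rank_window = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  v <- x$values
  if (ncol(v) < 2) stop("need >= 2 samples")
  complete <- rowSums(is.na(v)) == 0
  if (!any(complete)) stop("no fully observed genes; apply filter_genes first")
  v <- v[complete, , drop = FALSE]
  if (is.null(rank_window)) rank_window <- ceiling(0.05 * nrow(v))
  if (rank_window < 0) stop("`rank_window` must be nonnegative")
  if (identical(reference, "median_sample")) {
    means <- colMeans(v)
    reference <- colnames(v)[order(means)[floor((ncol(v) + 1) / 2)]]
  }
  if (!reference %in% colnames(v)) stop("unknown reference sample: ", reference)
  rk <- apply(v, 2, rank, ties.method = "average")
  dev <- abs(rk - rk[, reference])
  invariant <- rownames(v)[apply(dev, 1, max) <= rank_window]
  if (length(invariant) == 0)
    stop("no rank-invariant genes at rank_window = ", rank_window,
         "; increase the window")
  vals <- colMeans(v[invariant, , drop = FALSE])
  new_ct0(vals, method = "rank_invariant",
          params = list(reference = reference, rank_window = rank_window,
                        genes = invariant))
}
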