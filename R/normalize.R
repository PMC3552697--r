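new_ct_norm <- function(values, method, params = list(),
                        scale = c("delta_ct", "adjusted_ct"), notes = character()) {
  scale <- match.arg(scale)
  structure(list(values = values, method = method, params = params,
                 scale = scale, notes = notes),
            class = "ct_norm")
}

#' @export
print.ct_norm <- function(x, ...) {
  cat(sprintf("ct_norm: %d genes x %d samples [%s, scale=%s]\n",
              nrow(x$values), ncol(x$values), x$method, x$scale))
  core <- x$params[setdiff(names(x$params), c("weights", "genes", "ct0"))]
  if (length(core))
    cat("  params:", paste(names(core), unlist(lapply(core, format)),
                           sep = "=", collapse = ", "), "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Subtract a pseudo-control to form delta-CT
#'
#' The classical RT-PCR quantification step: for every gene and sample,
#' `dCT = CT - CT0`, where `CT0` is the per-sample reference (an endogenous
#' control or any pseudo-control built by this package). Missing wells stay
#' missing.
#'
#' @param x a [ct_matrix()].
#' @param ct0 a `ct0` object whose sample ids match `x`.
#' @return a `ct_norm` object with `scale = "delta_ct"`; the `ct0` used is
#'   kept in `params$ct0`.
#' @export
delta_ct <- function(x, ct0) {
  stopifnot(inherits(x, "ct_matrix"), inherits(ct0, "ct0"))
  sid <- colnames(x$values)
  if (!setequal(names(ct0$values), sid))
    stop("sample ids of `ct0` do not match the CT matrix")
  shift <- ct0$values[sid]
  vals <- sweep(x$values, 2, shift, "-")
  new_ct_norm(vals, method = paste0("delta_ct/", ct0$method),
              params = c(ct0$params, list(ct0 = ct0)), scale = "delta_ct")
}

#' Delta-delta-CT and fold change between conditions
#'
#' `ddCT = dCT_experimental - dCT_control`; assuming perfect per-cycle
#' doubling, the abundance ratio is `FC = 2^(-ddCT)` (one fewer cycle to
#' threshold means twice the starting material).
#'
#' @param experimental,control named per-gene delta-CT vectors (e.g. one
#'   sample's column of a delta-CT matrix, or per-group gene means).
#' @return a data frame with columns `gene_id`, `delta_delta_ct`,
#'   `fold_change`.
#' @examples
#' fold_change(c(g1 = 2, g2 = 5), c(g1 = 3, g2 = 2))
#' # g1: ddCT -1 -> FC 2 (up);  g2: ddCT 3 -> FC 0.125 (down)
#' @export
fold_change <- function(experimental, control) {
  if (is.null(names(experimental)) || is.null(names(control)))
    stop("both delta-CT vectors must be named by gene id")
  if (!setequal(names(experimental), names(control)))
    stop("gene ids do not match: ",
         paste(head(c(setdiff(names(experimental), names(control)),
                      setdiff(names(control), names(experimental))), 5),
               collapse = ", "))
  control <- control[names(experimental)]
  ddct <- experimental - control
  data.frame(gene_id = names(experimental),
             delta_delta_ct = unname(ddct),
             fold_change = unname(2^(-ddct)),
             stringsAsFactors = FALSE)
}

#' Quantile normalization of a CT matrix
#'
#' Forces every sample to share the same value distribution: within each
#' sample CT values are sorted, each rank is replaced by the mean (or median)
#' of that rank's values across samples, and values are put back in their
#' original order. Tied input values receive the mean of the row statistics
#' their ranks span (midrank convention). Requires a complete matrix; apply
#' [filter_genes()] first.
#'
#' @param x a [ct_matrix()] without missing values.
#' @param center `"mean"` (default) or `"median"` row statistic.
#' @return a `ct_norm` object with `scale = "adjusted_ct"`.
#' @export
quantile_normalize <- function(x, center = c("mean", "median")) {
  stopifnot(inherits(x, "ct_matrix"))
  center <- match.arg(center)
  v <- x$values
  if (anyNA(v))
    stop("quantile normalization requires a complete matrix; ",
         "apply filter_genes() first")
  sorted <- apply(v, 2, sort)
  stat <- if (center == "mean") rowMeans(sorted)
          else apply(sorted, 1, stats::median)
  out <- apply(v, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_along(stat), stat, xout = r)$y
  })
  dimnames(out) <- dimnames(v)
  new_ct_norm(out, method = "quantile", params = list(center = center),
              scale = "adjusted_ct")
}

#' Median-shift normalization
#'
#' Shifts each sample by a constant so that all per-sample medians equal the
#' median of the per-sample medians. Within-sample differences between genes
#' are untouched.
#'
#' @param x a [ct_matrix()]; missing values are ignored in the medians.
#' @return a `ct_norm` object with `scale = "adjusted_ct"`.
#' @export
median_normalize <- function(x) {
  stopifnot(inherits(x, "ct_matrix"))
  v <- x$values
  empty <- colSums(!is.na(v)) == 0
  if (any(empty))
    stop("sample(s) with no observed values: ",
         paste(colnames(v)[empty], collapse = ", "))
  med <- apply(v, 2, stats::median, na.rm = TRUE)
  target <- stats::median(med)
  out <- sweep(v, 2, med - target, "-")
  new_ct_norm(out, method = "median_shift",
              params = list(target_median = target), scale = "adjusted_ct")
}

#' Cyclic loess normalization
#'
#' For every unordered pair of samples, the per-gene difference of log CT
#' values (`M`) is regressed on their average (`A`) with a loess smoother;
#' half the fitted trend is subtracted from the first sample and added to the
#' second, removing intensity-dependent disagreement between the pair. Pairs
#' are cycled until the largest mean absolute fitted trend falls below `tol`
#' or `max_cycles` sweeps have run. Operates on `log(CT)` and back-transforms.
#'
#' @param x a [ct_matrix()] without missing values, `>= 2` samples.
#' @param span loess span in (0, 1]; default 0.7.
#' @param max_cycles maximum number of sweeps over all pairs; default 3.
#' @param tol convergence threshold on the mean |fitted M| of the worst pair;
#'   default 0.01.
#' @return a `ct_norm` object with `scale = "adjusted_ct"`;
#'   `params$converged` records whether `tol` was reached, and a
#'   non-convergence note is kept in `notes` (with a warning).
#' @export
cyclic_loess_normalize <- function(x, span = 0.7, max_cycles = 3, tol = 0.01) {
  stopifnot(inherits(x, "ct_matrix"))
  if (!is.numeric(span) || span <= 0 || span > 1)
    stop("`span` must be in (0, 1]")
  v <- x$values
  if (anyNA(v))
    stop("cyclic loess requires a complete matrix; apply filter_genes() first")
  if (ncol(v) < 2) stop("need >= 2 samples")
  L <- log(v)
  pairs <- utils::combn(ncol(v), 2)
  worst <- Inf; cycles <- 0
  while (cycles < max_cycles && worst >= tol) {
    cycles <- cycles + 1
    worst <- 0
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      M <- L[, i] - L[, j]
      A <- (L[, i] + L[, j]) / 2
      fit <- stats::loess(M ~ A, span = span, degree = 1,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      f <- stats::fitted(fit)
      L[, i] <- L[, i] - f / 2
      L[, j] <- L[, j] + f / 2
      worst <- max(worst, mean(abs(f)))
    }
  }
  converged <- worst < tol
  notes <- character()
  if (!converged) {
    notes <- sprintf("cyclic loess did not converge: mean |F| = %.4g >= tol %.4g after %d cycles",
                     worst, tol, max_cycles)
    warning(notes)
  }
  new_ct_norm(exp(L), method = "cyclic_loess",
              params = list(span = span, max_cycles = max_cycles, tol = tol,
                            cycles_run = cycles, converged = converged),
              scale = "adjusted_ct", notes = notes)
}

#' Normalize a CT matrix by any supported method
#'
#' Single front-end dispatching to every pseudo-control construction and
#' full-matrix baseline in the package. Pseudo-control methods return the
#' delta-CT matrix (`CT - CT0`); `quantile`, `medianshift` and `loess` return
#' an adjusted-CT matrix.
#'
#' @param x a [ct_matrix()].
#' @param method one of `"weighted"`, `"mean"`, `"median"`, `"geomean"`,
#'   `"topk"`, `"rankinv"` (pseudo-control methods), `"quantile"`,
#'   `"medianshift"`, `"loess"` (full-matrix methods).
#' @param ... method parameters: `wmp`, `epsilon` (weighted); `k` (topk);
#'   `reference`, `rank_window` (rankinv); `center` (quantile); `span`,
#'   `max_cycles`, `tol` (loess).
#' @return a `ct_norm` object.
#' @examples
#' sim <- simulate_ct(n_genes = 50, n_samples = 6, seed = 7)
#' nm <- normalize_ct(sim$matrix, method = "weighted", wmp = 13)
#' nm
#' @export
normalize_ct <- function(x, method = c("weighted", "mean", "median", "geomean",
                                       "topk", "rankinv", "quantile",
                                       "medianshift", "loess"), ...) {
  stopifnot(inherits(x, "ct_matrix"))
  method <- match.arg(method)
  switch(method,
    weighted    = delta_ct(x, weighted_mean_ct0(x, ...)),
    mean        = delta_ct(x, mean_ct0(x, kind = "arithmetic")),
    median      = delta_ct(x, mean_ct0(x, kind = "median")),
    geomean     = delta_ct(x, mean_ct0(x, kind = "geometric")),
    topk        = delta_ct(x, topk_ct0(x, ...)),
    rankinv     = delta_ct(x, rank_invariant_ct0(x, ...)),
    quantile    = quantile_normalize(x, ...),
    medianshift = median_normalize(x),
    loess       = cyclic_loess_normalize(x, ...))
}
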