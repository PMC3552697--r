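#' geNorm-style gene stability measure M
#'
#' For each pair of entries (j, k) the pairwise variation `V_jk` is the
#' standard deviation across samples of their CT difference `CT_j - CT_k`;
#' the stability of entry j is the average of `V_jk` over all partners k.
#' Lower M means more stable. CT values are already log-scale in abundance,
#' so CT differences play the role the log expression ratios play in the
#' original microarray setting. A candidate pseudo-control can be scored
#' against the genes by passing it as `candidate`; it is appended as a
#' pseudo-gene named `".ct0"`.
#'
#' Pairs are computed over the samples where both entries are observed; a
#' pair with fewer than 2 overlapping samples is skipped, and an entry left
#' with no valid pairs is omitted with a warning.
#'
#' @param x a [ct_matrix()] with `>= 2` genes and `>= 2` samples.
#' @param candidate optional `ct0` object to score against all genes.
#' @return named numeric vector of M values (all entries, plus `".ct0"` if a
#'   candidate was given).
#' @export
genorm_m <- function(x, candidate = NULL) {
  stopifnot(inherits(x, "ct_matrix"))
  v <- x$values
  if (!is.null(candidate)) {
    stopifnot(inherits(candidate, "ct0"))
    v <- rbind(v, .ct0 = candidate$values[colnames(v)])
  }
  if (nrow(v) < 2 || ncol(v) < 2) stop("need >= 2 genes and >= 2 samples")
  if (!anyNA(v)) {
    # complete case: sd(x_j - x_k) via the covariance matrix, vectorized
    C <- stats::cov(t(v))
    d <- diag(C)
    V <- sqrt(pmax(outer(d, d, "+") - 2 * C, 0))
    m <- (rowSums(V)) / (nrow(v) - 1)   # diagonal is 0
    return(m)
  }
  n <- nrow(v)
  V <- matrix(NA_real_, n, n, dimnames = list(rownames(v), rownames(v)))
  for (j in seq_len(n - 1)) {
    for (k in (j + 1):n) {
      both <- !is.na(v[j, ]) & !is.na(v[k, ])
      if (sum(both) >= 2)
        V[j, k] <- V[k, j] <- stats::sd(v[j, both] - v[k, both])
    }
  }
  m <- rowMeans(V, na.rm = TRUE)
  bad <- rowSums(!is.na(V)) == 0
  if (any(bad)) {
    warning("entries with no valid pairs omitted: ",
            paste(rownames(v)[bad], collapse = ", "))
    m <- m[!bad]
  }
  m
}

#' Rank genes by stability
#'
#' Produces the per-gene stability table (mean CT, across-sample sd,
#' geNorm-style M) sorted ascending by the requested criterion, ties broken
#' by gene id. The most stable genes head the table; the top k rows are the
#' natural candidates for a top-k pseudo-control.
#'
#' @param x a [ct_matrix()].
#' @param criterion `"sd"` (default) or `"genorm"`.
#' @return a data frame of class `stability_report` with columns `gene_id`,
#'   `mean_ct`, `sd`, `genorm_m`.
#' @export
rank_genes <- function(x, criterion = c("sd", "genorm")) {
  stopifnot(inherits(x, "ct_matrix"))
  criterion <- match.arg(criterion)
  sds <- gene_sd(x)
  ids <- names(sds)
  mean_ct <- rowMeans(x$values[ids, , drop = FALSE], na.rm = TRUE)
  sub <- x
  sub$values <- x$values[ids, , drop = FALSE]
  sub$undetected <- x$undetected[ids, , drop = FALSE]
  m <- genorm_m(sub)[ids]
  rep <- data.frame(gene_id = ids, mean_ct = unname(mean_ct),
                    sd = unname(sds), genorm_m = unname(m),
                    stringsAsFactors = FALSE)
  key <- if (criterion == "sd") rep$sd else rep$genorm_m
  rep <- rep[order(key, rep$gene_id), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "criterion") <- criterion
  class(rep) <- c("stability_report", "data.frame")
  rep
}

#' @export
print.stability_report <- function(x, n = 10, ...) {
  cat(sprintf("stability_report: %d genes, sorted by %s (lower = more stable)\n",
              nrow(x), attr(x, "criterion")))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more genes\n")
  invisible(x)
}

#' Evaluate a candidate pseudo-control
#'
#' The three-number summary used to compare CT0 constructions: the mean and
#' across-sample standard deviation of the CT0 values, and the geNorm-style M
#' of the CT0 scored as a pseudo-gene against all genes.
#'
#' @param x a [ct_matrix()].
#' @param ct0 a `ct0` object aligned to the samples of `x`.
#' @return a named list with `mean`, `sd`, `genorm_m`.
#' @export
evaluate_ct0 <- function(x, ct0) {
  stopifnot(inherits(x, "ct_matrix"), inherits(ct0, "ct0"))
  vals <- ct0$values[colnames(x$values)]
  list(mean = mean(vals), sd = stats::sd(vals),
       genorm_m = unname(genorm_m(x, candidate = ct0)[".ct0"]))
}

#' Enumerate weighted-mean powers and pick the most stable
#'
#' The weighting power has no closed-form optimum; it is chosen by evaluating
#' the weighted-mean CT0 over a grid of powers and keeping the one whose CT0
#' is most stable, by across-sample standard deviation or by geNorm M. The
#' default grid is 0 (the plain mean) plus the odd powers 1, 3, ..., 19.
#' Ties go to the smallest power.
#'
#' @param x a [ct_matrix()].
#' @param powers numeric vector of powers to evaluate.
#' @param epsilon sd floor passed to [weighted_mean_ct0()].
#' @return an object of class `wmp_scan`: list with `powers`, `mean_of_ct0`,
#'   `sd_of_ct0`, `genorm_of_ct0`, `best_power_by_sd`, `best_power_by_genorm`.
#' @export
scan_wmp <- function(x, powers = c(0, seq(1, 19, by = 2)), epsilon = 0.01) {
  stopifnot(inherits(x, "ct_matrix"))
  if (length(powers) == 0) stop("`powers` must be non-empty")
  ev <- lapply(powers, function(p)
    evaluate_ct0(x, weighted_mean_ct0(x, wmp = p, epsilon = epsilon)))
  mean_of <- vapply(ev, `[[`, numeric(1), "mean")
  sd_of <- vapply(ev, `[[`, numeric(1), "sd")
  m_of <- vapply(ev, `[[`, numeric(1), "genorm_m")
  pick <- function(score) {
    best <- which(score == min(score))
    powers[best][which.min(powers[best])]
  }
  structure(list(powers = powers, mean_of_ct0 = mean_of, sd_of_ct0 = sd_of,
                 genorm_of_ct0 = m_of, best_power_by_sd = pick(sd_of),
                 best_power_by_genorm = pick(m_of), epsilon = epsilon),
            class = "wmp_scan")
}

#' @export
print.wmp_scan <- function(x, ...) {
  cat("wmp_scan: weighted-mean power selection\n")
  print(data.frame(power = x$powers, mean_ct0 = round(x$mean_of_ct0, 3),
                   stdev = round(x$sd_of_ct0, 4),
                   genorm = round(x$genorm_of_ct0, 4)), row.names = FALSE)
  cat(sprintf("best power by sd: %g   by geNorm M: %g\n",
              x$best_power_by_sd, x$best_power_by_genorm))
  invisible(x)
}

#' @export
plot.wmp_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$powers, x$sd_of_ct0, type = "b", xlab = "weighted mean power",
                 ylab = "sd of CT0 (cycles)", main = "CT0 stability: sd", ...)
  graphics::abline(v = x$best_power_by_sd, lty = 2)
  graphics::plot(x$powers, x$genorm_of_ct0, type = "b",
                 xlab = "weighted mean power", ylab = "geNorm M",
                 main = "CT0 stability: geNorm", ...)
  graphics::abline(v = x$best_power_by_genorm, lty = 2)
  invisible(x)
}

#' @export
as.data.frame.wmp_scan <- function(x, ...) {
  data.frame(power = x$powers, mean_ct0 = x$mean_of_ct0,
             stdev = x$sd_of_ct0, genorm = x$genorm_of_ct0)
}
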