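#' Pair delta-CT values with microarray intensities
#'
#' Inner-joins an RT-PCR delta-CT matrix with a microarray intensity matrix
#' on gene id, per mapped sample. Intensities are transformed to log2 so the
#' two platforms are on comparable (log) scales; delta-CT is expected to
#' correlate *negatively* with log2 intensity, since fewer cycles to
#' threshold means more starting material. When the raw CT matrix is
#' supplied, each gene's mean raw CT is attached (needed for CT-range-binned
#' concordance) and genes whose mean raw CT is at or above the undetected
#' sentinel are excluded.
#'
#' @param delta a `ct_norm` object on the delta-CT scale (or a plain numeric
#'   matrix of delta-CT values with gene rownames and sample colnames).
#' @param array numeric matrix of positive microarray intensities, gene
#'   rownames, array colnames.
#' @param sample_map named character vector mapping delta-CT sample ids to
#'   array column ids; default pairs samples sharing the same id.
#' @param raw optional [ct_matrix()] of the raw CT values behind `delta`,
#'   used to attach per-gene mean raw CT and drop undetected genes.
#' @param undetected_ct sentinel used with `raw`; default `raw$undetected_ct`.
#' @return a list of class `paired_expression_set`: one data frame per mapped
#'   sample with columns `gene_id`, `delta_ct`, `log2_intensity` and (when
#'   `raw` is given) `mean_ct`.
#' @export
pair_platforms <- function(delta, array, sample_map = NULL, raw = NULL,
                           undetected_ct = NULL) {
  d <- if (inherits(delta, "ct_norm")) delta$values else delta
  if (!is.matrix(d) || is.null(rownames(d)) || is.null(colnames(d)))
    stop("`delta` must be a ct_norm or a matrix with gene and sample names")
  if (!is.matrix(array) || is.null(rownames(array)) || is.null(colnames(array)))
    stop("`array` must be a matrix with gene and array names")
  bad <- rownames(array)[apply(array <= 0 | is.na(array), 1, any)]
  if (length(bad))
    stop("nonpositive or missing intensity for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (is.null(sample_map)) {
    shared_s <- intersect(colnames(d), colnames(array))
    if (length(shared_s) == 0)
      stop("no shared sample ids; supply `sample_map`")
    sample_map <- stats::setNames(shared_s, shared_s)
  }
  if (is.null(names(sample_map)))
    stop("`sample_map` must be named: names are delta-CT samples, values array columns")
  genes <- intersect(rownames(d), rownames(array))
  if (length(genes) == 0) stop("no gene ids shared between the two platforms")
  mean_ct <- NULL
  if (!is.null(raw)) {
    stopifnot(inherits(raw, "ct_matrix"))
    if (is.null(undetected_ct)) undetected_ct <- raw$undetected_ct
    mean_ct <- rowMeans(raw$values[intersect(genes, rownames(raw$values)),
                                   , drop = FALSE], na.rm = TRUE)
    genes <- names(mean_ct)[is.finite(mean_ct) & mean_ct < undetected_ct]
    mean_ct <- mean_ct[genes]
  }
  out <- lapply(names(sample_map), function(s) {
    df <- data.frame(gene_id = genes,
                     delta_ct = d[genes, s],
                     log2_intensity = log2(array[genes, sample_map[[s]]]),
                     stringsAsFactors = FALSE)
    if (!is.null(mean_ct)) df$mean_ct <- unname(mean_ct[genes])
    df <- df[stats::complete.cases(df[c("delta_ct", "log2_intensity")]), ]
    rownames(df) <- NULL
    class(df) <- c("paired_expression", "data.frame")
    df
  })
  names(out) <- names(sample_map)
  structure(out, class = "paired_expression_set")
}

#' @export
print.paired_expression_set <- function(x, ...) {
  cat(sprintf("paired_expression_set: %d mapped sample(s)\n", length(x)))
  for (s in names(x))
    cat(sprintf("  %s: %d shared genes\n", s, nrow(x[[s]])))
  invisible(x)
}

#' RT-PCR vs microarray concordance
#'
#' Spearman correlation of delta-CT with log2 microarray intensity, overall
#' and within ranges of mean raw CT. A strongly negative rho indicates the
#' two platforms rank the genes consistently. Binned correlations ask whether
#' concordance depends on abundance: bins are half-open `[lo, hi)` on each
#' gene's mean raw CT, and a bin with fewer than 3 genes is reported with an
#' undefined rho. P-values use a seeded permutation test for fewer than 50
#' genes, the asymptotic t approximation otherwise.
#'
#' @param paired a `paired_expression` data frame from [pair_platforms()]
#'   (one mapped sample).
#' @param ct_bins numeric cut points defining the CT bins; default
#'   `seq(15, 35, by = 5)` giving four 5-cycle bins. `NULL` skips binning.
#' @param n_perm permutations for the small-n p-value; default 10000.
#' @param seed integer seed for the permutation test; default 1.
#' @return an object of class `concordance_report`: list with `overall_rho`,
#'   `overall_p`, `n_shared` and `bins` (data frame `ct_lo`, `ct_hi`,
#'   `n_genes`, `rho`, `p`).
#' @export
concordance <- function(paired, ct_bins = seq(15, 35, by = 5),
                        n_perm = 10000, seed = 1L) {
  if (!is.data.frame(paired) ||
      !all(c("delta_ct", "log2_intensity") %in% names(paired)))
    stop("`paired` must be a paired_expression data frame")
  n <- nrow(paired)
  if (n < 3) stop("need >= 3 paired genes")
  sp <- spearman_test(paired$delta_ct, paired$log2_intensity, n_perm, seed)
  bins <- NULL
  if (!is.null(ct_bins)) {
    if (is.unsorted(ct_bins, strictly = TRUE))
      stop("`ct_bins` must be strictly increasing")
    if (!"mean_ct" %in% names(paired))
      stop("binned concordance needs a `mean_ct` column; ",
           "supply `raw` to pair_platforms()")
    lo <- ct_bins[-length(ct_bins)]; hi <- ct_bins[-1]
    bins <- do.call(rbind, lapply(seq_along(lo), function(b) {
      in_bin <- paired$mean_ct >= lo[b] & paired$mean_ct < hi[b]
      k <- sum(in_bin)
      if (k >= 3) {
        st <- spearman_test(paired$delta_ct[in_bin],
                            paired$log2_intensity[in_bin], n_perm, seed)
        data.frame(ct_lo = lo[b], ct_hi = hi[b], n_genes = k,
                   rho = st$rho, p = st$p)
      } else {
        data.frame(ct_lo = lo[b], ct_hi = hi[b], n_genes = k,
                   rho = NA_real_, p = NA_real_)
      }
    }))
  }
  structure(list(overall_rho = sp$rho, overall_p = sp$p, n_shared = n,
                 bins = bins),
            class = "concordance_report")
}

# Spearman rho with a permutation p-value for small n (asymptotic t for
# n >= 50); permutation randomness is local to this call
spearman_test <- function(x, y, n_perm, seed) {
  rho <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  if (n >= 50) {
    p <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))$p.value
  } else {
    p <- with_local_seed(seed, {
      perm <- replicate(n_perm,
        stats::cor(x, sample(y), method = "spearman"))
      (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (1 + n_perm)
    })
  }
  list(rho = rho, p = p)
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("concordance_report: %d shared genes\n", x$n_shared))
  cat(sprintf("  overall Spearman rho = %.4f (p = %.3g)\n",
              x$overall_rho, x$overall_p))
  if (!is.null(x$bins)) {
    cat("  by mean raw CT range:\n")
    print.data.frame(x$bins, digits = 4, row.names = FALSE)
  }
  invisible(x)
}
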