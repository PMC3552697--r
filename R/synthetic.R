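#' Simulate a CT matrix with expression-level-dependent bias
#'
#' Generates RT-PCR CT data under the mechanism the package's diagnostics are
#' built to detect: each sample carries a loading offset (variation in the
#' amount of starting material) whose imprint on a gene's CT *grows* with
#' that gene's mean CT, and measurement noise likewise grows with mean CT.
#' The generating rule is
#'
#' `CT[g, s] = mu_g + s_g * delta_s + eps[g, s]`,  `eps ~ N(0, sigma_g^2)`
#'
#' with per-gene sensitivity `s_g = a + b * mu_g` and noise sd
#' `sigma_g = c + d * mu_g`. With `b > 0` low-abundance (high-CT) genes
#' over-respond to loading differences, reproducing the monotone
#' sd-vs-mean-CT and slope-vs-mean-CT trends seen in real TLDA-card data.
#' Defaults: gene means uniform on 15–35 cycles; loading offsets
#' `N(0, 0.5^2)` centered to sum 0; sensitivity 0.5 at CT 15 rising to 1.5 at
#' CT 35 (mean 1 over the range); noise sd 0.2 at CT 15 rising to 1.2 at
#' CT 35; 20 samples, as in a typical two-group TLDA study.
#'
#' @param n_genes,n_samples matrix dimensions; both `>= 2`.
#' @param gene_means optional explicit per-gene mean CT vector (overrides the
#'   uniform draw).
#' @param mean_range range of the uniform gene-mean draw; default `c(15, 35)`.
#' @param offset_sd sd of the per-sample loading offsets, cycles; default 0.5.
#' @param sensitivity_coef `c(a, b)` of `s_g = a + b * mu_g`; default
#'   `c(-0.25, 0.05)`.
#' @param noise_coef `c(c, d)` of `sigma_g = c + d * mu_g`; default
#'   `c(-0.55, 0.05)`.
#' @param sensitivities optional explicit per-gene sensitivity vector
#'   (overrides `sensitivity_coef`).
#' @param noise_sd optional explicit per-gene noise sd vector, or a single
#'   value recycled; may be 0 for noise-free fixtures (overrides
#'   `noise_coef`).
#' @param seed integer seed; the result is a pure function of it.
#' @return list of class `ct_sim` with `matrix` (a [ct_matrix()]) and
#'   `truth` (gene_means, sample_offsets, sensitivities, noise_sd, the
#'   coefficient pairs, seed).
#' @examples
#' sim <- simulate_ct(n_genes = 100, n_samples = 10, seed = 42)
#' bias_report(sim$matrix)
#' @export
simulate_ct <- function(n_genes = 200, n_samples = 20, gene_means = NULL,
                        mean_range = c(15, 35), offset_sd = 0.5,
                        sensitivity_coef = c(-0.25, 0.05),
                        noise_coef = c(-0.55, 0.05),
                        sensitivities = NULL, noise_sd = NULL, seed = 1L) {
  if (n_genes < 2 || n_samples < 2) stop("need n_genes >= 2 and n_samples >= 2")
  with_local_seed(seed, {
    mu <- if (is.null(gene_means))
      stats::runif(n_genes, mean_range[1], mean_range[2])
    else {
      if (length(gene_means) != n_genes)
        stop("`gene_means` must have length n_genes")
      gene_means
    }
    s <- if (is.null(sensitivities))
      sensitivity_coef[1] + sensitivity_coef[2] * mu
    else rep_len(sensitivities, n_genes)
    if (any(s <= 0))
      stop("sensitivity coefficients yield nonpositive s_g over the mean range")
    sig <- if (is.null(noise_sd))
      noise_coef[1] + noise_coef[2] * mu
    else rep_len(noise_sd, n_genes)
    if (any(sig < 0) || (is.null(noise_sd) && any(sig <= 0)))
      stop("noise coefficients yield nonpositive sigma_g over the mean range")
    delta <- stats::rnorm(n_samples, 0, offset_sd)
    delta <- delta - mean(delta)
    eps <- matrix(stats::rnorm(n_genes * n_samples, 0, sig),
                  n_genes, n_samples)   # sig recycles down columns: per gene
    ct <- mu + outer(s, delta) + eps
    dimnames(ct) <- list(sprintf("gene%03d", seq_len(n_genes)),
                         sprintf("sample%02d", seq_len(n_samples)))
    truth <- list(gene_means = stats::setNames(mu, rownames(ct)),
                  sample_offsets = stats::setNames(delta, colnames(ct)),
                  sensitivities = stats::setNames(s, rownames(ct)),
                  noise_sd = stats::setNames(sig, rownames(ct)),
                  sensitivity_coef = sensitivity_coef,
                  noise_coef = noise_coef, offset_sd = offset_sd, seed = seed)
    structure(list(matrix = ct_matrix(ct, drop_undetected = FALSE),
                   truth = truth),
              class = "ct_sim")
  })
}

#' @export
print.ct_sim <- function(x, ...) {
  cat("ct_sim: synthetic CT matrix with recorded truth\n")
  print(x$matrix)
  cat(sprintf("  seed %s; offset sd %.3g cycles; sensitivity in [%.2f, %.2f]\n",
              format(x$truth$seed), x$truth$offset_sd,
              min(x$truth$sensitivities), max(x$truth$sensitivities)))
  invisible(x)
}

#' Simulate paired microarray intensities for a synthetic CT matrix
#'
#' Intensities follow `2^(K - mu_g + noise)`: log2 intensity is linear in
#' `-mu_g` (high CT = low abundance = low intensity) plus Gaussian noise, so
#' with zero noise the true cross-platform relation is perfectly monotone
#' decreasing.
#'
#' @param truth the `truth` element of a [simulate_ct()] result.
#' @param concordance_noise sd (in log2 units) of the per-gene, per-array
#'   noise; 0 gives an exact monotone relation. Default 0.5.
#' @param n_arrays number of array columns; default 1.
#' @param K fixed log2 offset setting the intensity scale; default 40.
#' @param seed integer seed; default `truth$seed + 1000`.
#' @return numeric matrix of positive intensities, genes x arrays.
#' @export
simulate_paired <- function(truth, concordance_noise = 0.5, n_arrays = 1,
                            K = 40, seed = NULL) {
  mu <- truth$gene_means
  if (is.null(seed)) seed <- truth$seed + 1000
  with_local_seed(seed, {
    noise <- matrix(stats::rnorm(length(mu) * n_arrays, 0, concordance_noise),
                    length(mu), n_arrays)
    intens <- 2^(K - mu + noise)
    dimnames(intens) <- list(names(mu), sprintf("array%02d", seq_len(n_arrays)))
    intens
  })
}

#' Spike undetected wells into a CT matrix
#'
#' Sets a fixed fraction of wells to the undetected sentinel, optionally with
#' probability increasing in the gene's mean CT — emulating the reality that
#' low-abundance assays are the ones that fail to cross threshold. The count
#' of spiked cells is exactly `round(fraction * n_cells)`.
#'
#' @param x a [ct_matrix()].
#' @param fraction fraction of cells to spike, in [0, 1).
#' @param bias_toward_high_ct if `TRUE`, cells are chosen with probability
#'   proportional to the rank of their gene's mean CT.
#' @param as_missing if `TRUE` (default) spiked cells become `NA` (and are
#'   flagged); if `FALSE` they hold the sentinel value and are flagged.
#' @param seed integer seed.
#' @return a [ct_matrix()] with the spiked cells flagged in `$undetected`.
#' @export
spike_undetected <- function(x, fraction, bias_toward_high_ct = FALSE,
                             as_missing = TRUE, seed = 1L) {
  stopifnot(inherits(x, "ct_matrix"))
  if (fraction < 0 || fraction >= 1) stop("`fraction` must be in [0, 1)")
  n_cells <- length(x$values)
  n_spike <- round(fraction * n_cells)
  if (n_spike == 0) return(x)
  with_local_seed(seed, {
    prob <- if (bias_toward_high_ct) {
      r <- rank(rowMeans(x$values, na.rm = TRUE), ties.method = "average")
      rep(r, times = ncol(x$values))   # column-major cell order
    } else NULL
    cells <- sample.int(n_cells, n_spike, prob = prob)
    out <- x
    out$values[cells] <- if (as_missing) NA_real_ else x$undetected_ct
    out$undetected[cells] <- TRUE
    out
  })
}
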