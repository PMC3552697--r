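# Small fixture builders shared across the suite. All fixtures are built in
# code; nothing is read from disk except where the test is about file I/O.

# quick ct_matrix from a plain matrix, auto-naming genes/samples
ctm <- function(values, ..., genes = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- matrix(values, ...)
  if (is.null(rownames(values)))
    rownames(values) <- if (is.null(genes))
      paste0("g", seq_len(nrow(values))) else genes
  if (is.null(colnames(values)))
    colnames(values) <- if (is.null(samples))
      paste0("s", seq_len(ncol(values))) else samples
  ct_matrix(values)
}

# seeded random CT matrix with no structure (pure noise around gene means)
random_ctm <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  v <- matrix(runif(n_genes * n_samples, 15, 35), n_genes, n_samples)
  ctm(v)
}

# independent brute-force geNorm M: enumerate all pairs, sd of differences
brute_genorm <- function(values) {
  n <- nrow(values)
  sapply(seq_len(n), function(j) {
    mean(sapply(setdiff(seq_len(n), j), function(k)
      sd(values[j, ] - values[k, ])))
  })
}
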