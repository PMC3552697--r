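#' CT matrix: raw RT-PCR cycle-threshold values, genes x samples
#'
#' The universal input container of the package. Rows are genes (miRNAs),
#' columns are samples; cells hold CT values in PCR cycles. Wells that never
#' crossed the detection threshold are conventionally exported at the
#' instrument's maximum cycle count (usually 40); any value at or above
#' `undetected_ct` is treated as undetected and, by default, marked missing
#' (`NA`) rather than used as a measurement, because such values are censored
#' rather than observed.
#'
#' @param values numeric matrix of CT values with rownames (gene ids) and
#'   colnames (sample ids). Both id sets must be unique and non-empty.
#' @param undetected_ct sentinel cycle value at or above which a well is
#'   treated as undetected. Default 40.
#' @param drop_undetected logical; if `TRUE` (default) cells with
#'   `values >= undetected_ct` are set to `NA`. If `FALSE` they are retained
#'   but flagged in the `undetected` slot.
#' @return an object of class `ct_matrix`: a list with elements `values`
#'   (numeric matrix), `undetected` (logical matrix flagging undetected
#'   wells) and `undetected_ct`.
#' @examples
#' m <- matrix(c(20, 25, 40, 21, 26, 33), nrow = 3,
#'             dimnames = list(c("mir-a", "mir-b", "mir-c"), c("s1", "s2")))
#' x <- ct_matrix(m)
#' x$values  # the CT-40 well is NA
#' @export
ct_matrix <- function(values, undetected_ct = 40, drop_undetected = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(is.infinite(values)))
    stop("CT values must be finite or NA")
  if (any(values <= 0, na.rm = TRUE))
    stop("CT values must be positive (cycles)")
  undetected <- !is.na(values) & values >= undetected_ct
  if (drop_undetected) values[undetected] <- NA_real_
  structure(
    list(values = values, undetected = undetected,
         undetected_ct = undetected_ct),
    class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  ng <- nrow(x$values); ns <- ncol(x$values)
  nmiss <- sum(is.na(x$values))
  cat(sprintf("ct_matrix: %d genes x %d samples\n", ng, ns))
  cat(sprintf("  undetected sentinel: CT >= %g (%d wells flagged)\n",
              x$undetected_ct, sum(x$undetected)))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss,
              100 * nmiss / (ng * ns)))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  CT range: %.2f .. %.2f cycles\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.ct_matrix <- function(x) dim(x$values)

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Read a CT matrix from delimited text
#'
#' Two layouts are supported. `wide`: first column gene ids, header row sample
#' ids, one CT column per sample. `long`: three columns `gene_id`,
#' `sample_id`, `ct`, one row per well. Long input is canonicalized by sorting
#' gene and sample ids lexicographically, so any row order of the same records
#' parses to the same matrix.
#'
#' @param path path to a delimited text file.
#' @param layout `"wide"` (default) or `"long"`.
#' @param sep field delimiter; default `","`, use `"\t"` for TSV.
#' @param missing_token string read as missing; empty cells and this token
#'   (default `"NA"`) become `NA`.
#' @param undetected_ct,drop_undetected passed to [ct_matrix()].
#' @return a [ct_matrix()].
#' @export
read_ct_matrix <- function(path, layout = c("wide", "long"), sep = ",",
                           missing_token = "NA", undetected_ct = 40,
                           drop_undetected = TRUE) {
  num <- read_values(path, match.arg(layout), sep, missing_token)
  ct_matrix(num, undetected_ct = undetected_ct,
            drop_undetected = drop_undetected)
}

#' Read a normalized (delta-CT or adjusted-CT) matrix from delimited text
#'
#' Same layouts as [read_ct_matrix()], but without the positivity and
#' undetected-well rules of raw CT data, so negative delta-CT values round
#' trip unchanged.
#'
#' @inheritParams read_ct_matrix
#' @param scale `"delta_ct"` or `"adjusted_ct"` label for the result.
#' @return a `ct_norm` object with method `"file"`.
#' @export
read_norm_matrix <- function(path, layout = c("wide", "long"), sep = ",",
                             missing_token = "NA",
                             scale = c("delta_ct", "adjusted_ct")) {
  num <- read_values(path, match.arg(layout), sep, missing_token)
  new_ct_norm(num, method = "file", scale = match.arg(scale))
}

read_values <- function(path, layout, sep, missing_token) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (layout == "wide") {
    if (ncol(raw) < 2) stop("wide layout needs a gene-id column plus >= 1 sample column")
    gid <- raw[[1]]
    vals <- as.matrix(raw[, -1, drop = FALSE])
    num <- parse_ct_cells(vals, missing_token, gid, colnames(vals))
    dimnames(num) <- list(gid, colnames(vals))
  } else {
    if (ncol(raw) < 3) stop("long layout needs columns gene_id, sample_id, ct")
    g <- raw[[1]]; s <- raw[[2]]; ct <- raw[[3]]
    key <- paste(g, s, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate (gene, sample) pair in long input: ",
           paste(head(sub("\r", " / ", key[duplicated(key)]), 3), collapse = "; "))
    gid <- sort(unique(g)); sid <- sort(unique(s))
    num <- matrix(NA_real_, length(gid), length(sid), dimnames = list(gid, sid))
    ctn <- parse_ct_cells(matrix(ct, ncol = 1), missing_token, g, rep("ct", length(g)))
    num[cbind(match(g, gid), match(s, sid))] <- ctn
  }
  num
}

# strict numeric parsing: anything that is not a number and not the declared
# missing token is a hard error naming the offending cell
parse_ct_cells <- function(chr, missing_token, row_labels, col_labels) {
  chr[chr == "" | chr == missing_token] <- NA_character_
  suppressWarnings(num <- array(as.numeric(chr), dim = dim(chr)))
  bad <- !is.na(chr) & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric CT value %s at gene '%s', column '%s'",
                 dQuote(chr[bad][1]), row_labels[idx[1]], col_labels[idx[2]]))
  }
  num
}

#' Write a CT or normalized matrix to delimited text
#'
#' Values are written at full precision so that a write/read round trip
#' reproduces ids and values exactly. Missing cells are written as `"NA"`.
#'
#' @param x a [ct_matrix()] or a `ct_norm` object (see [delta_ct()]).
#' @param path output file path.
#' @param layout `"wide"` or `"long"`.
#' @param sep field delimiter.
#' @export
write_ct_matrix <- function(x, path, layout = c("wide", "long"), sep = ",") {
  layout <- match.arg(layout)
  v <- if (inherits(x, c("ct_matrix", "ct_norm"))) x$values else x
  if (!is.matrix(v)) stop("`x` must be a ct_matrix, ct_norm or matrix")
  if (layout == "wide") {
    df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       na = "NA")
  } else {
    df <- data.frame(gene_id = rep(rownames(v), times = ncol(v)),
                     sample_id = rep(colnames(v), each = nrow(v)),
                     ct = as.vector(v), stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                       na = "NA")
  }
  invisible(path)
}

#' Filter genes by missingness
#'
#' Undetected wells carry no quantitative signal, and downstream stability
#' weighting requires per-gene standard deviations, so genes with too many
#' missing wells are dropped before normalization.
#'
#' @param x a [ct_matrix()].
#' @param policy one of `"drop_any_missing"` (keep only fully observed genes),
#'   `"drop_all_missing"` (drop genes missing everywhere), or
#'   `"max_missing_fraction"` (keep genes whose missing fraction is `<= f`,
#'   boundary inclusive).
#' @param f maximum missing fraction, used only for `"max_missing_fraction"`.
#' @return a [ct_matrix()] restricted to passing genes; the input is untouched.
#' @export
filter_genes <- function(x, policy = c("drop_any_missing", "drop_all_missing",
                                       "max_missing_fraction"), f = 0.5) {
  stopifnot(inherits(x, "ct_matrix"))
  policy <- match.arg(policy)
  miss <- rowMeans(is.na(x$values))
  keep <- switch(policy,
    drop_any_missing = miss == 0,
    drop_all_missing = miss < 1,
    max_missing_fraction = {
      if (!is.numeric(f) || f < 0 || f > 1)
        stop("`f` must be in [0, 1]")
      miss <= f
    })
  if (!any(keep))
    stop("policy '", policy, "' removes all genes; relax the threshold ",
         "or use a more permissive policy")
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out$undetected <- x$undetected[keep, , drop = FALSE]
  out
}
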