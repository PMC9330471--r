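#' Construct an expression matrix
#'
#' An expression matrix is the package's universal input: a numeric matrix of
#' normalized expression values with genes in rows and samples in columns,
#' carrying unique gene and sample identifiers as dimnames. The constructor
#' validates shape, uniqueness and finiteness; downstream functions assume a
#' validated object.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   `rownames(values)`).
#' @param sample_ids character vector of unique sample identifiers (defaults
#'   to `colnames(values)`).
#' @return a numeric matrix of class `expression_matrix` with gene row names
#'   and sample column names.
#' @export
#' @examples
#' m <- expression_matrix(matrix(1:4, 2, 2), c("g1", "g2"), c("s1", "s2"))
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stopf("expression values must be numeric")
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stopf("gene and sample identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stopf("%d gene ids for %d rows", length(gene_ids), nrow(values))
  }
  if (length(sample_ids) != ncol(values)) {
    stopf("%d sample ids for %d columns", length(sample_ids), ncol(values))
  }
  if (anyDuplicated(gene_ids)) {
    stopf("duplicate gene identifiers: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample identifiers: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyNA(values) || !all(is.finite(values))) {
    stopf("expression values contain missing or non-finite entries")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read an expression table
#'
#' Reads a delimited genes-x-samples table: first column gene identifiers,
#' header row sample identifiers, numeric body. Duplicated gene identifiers
#' and non-numeric cells are rejected with a message naming the offending
#' row/column.
#'
#' @param path file path.
#' @param delimiter field delimiter; `"auto"` (default) infers tab vs comma
#'   from the file extension and header.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, delimiter = "auto") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sep <- if (identical(delimiter, "auto")) "auto" else delimiter
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  if (ncol(dt) < 2) stopf("expression table needs a gene column plus >=1 sample column")
  gene_ids <- dt[[1]]
  if (anyDuplicated(gene_ids)) {
    stopf("duplicate gene identifiers in %s: %s", path,
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  body <- dt[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1]
      stopf("non-numeric value in column '%s', row %d (gene %s)",
            names(body)[j], bad, gene_ids[bad])
    }
  }
  expression_matrix(as.matrix(body), gene_ids, colnames(body))
}

#' Write an expression table
#'
#' Inverse of [read_expression_table()]: writes a delimited table with a
#' `gene_id` first column and sample columns, at full double precision so a
#' write/read round trip is lossless.
#'
#' @param m an [expression_matrix()].
#' @param path output file path.
#' @param delimiter field delimiter, default tab.
#' @export
write_expression_table <- function(m, path, delimiter = "\t") {
  body <- apply(unclass(m), 2, sprintf, fmt = "%.17g")  # round-trip precision
  df <- data.frame(gene_id = rownames(m), body, check.names = FALSE)
  data.table::fwrite(df, path, sep = delimiter, quote = FALSE)
  invisible(path)
}

#' Per-gene normalization to a standard Gaussian
#'
#' Rescales every gene row to an N(0, 1) profile across samples, either by
#' z-scoring (subtract the row mean, divide by the population standard
#' deviation) or by a rank-based inverse-normal transform
#' (qnorm((rank - 0.5) / n)). Z-scoring is the default because it preserves
#' the linear covariance structure that a linear autoencoder represents.
#' Zero-variance rows cannot be standardized; they are set to all zeros (so
#' gene indices remain aligned across cohort subsets) with a warning.
#'
#' @param m an [expression_matrix()].
#' @param method `"zscore"` (default) or `"rank_inverse_normal"`.
#' @return an [expression_matrix()] of identical shape.
#' @export
normalize_genes <- function(m, method = c("zscore", "rank_inverse_normal")) {
  method <- match.arg(method)
  if (ncol(m) < 2) stopf("normalization needs >=2 samples (variance undefined)")
  v <- unclass(m)
  if (method == "zscore") {
    mu <- rowMeans(v)
    centered <- v - mu
    # population (1/n) variance: rows end up with exactly unit second moment
    sd_pop <- sqrt(rowMeans(centered^2))
    zero_var <- sd_pop == 0
    sd_pop[zero_var] <- 1
    out <- centered / sd_pop
    out[zero_var, ] <- 0
  } else {
    n <- ncol(v)
    out <- t(apply(v, 1, function(row) {
      if (max(row) == min(row)) return(rep(0, n))
      qnorm((rank(row, ties.method = "average") - 0.5) / n)
    }))
    zero_var <- apply(v, 1, function(row) max(row) == min(row))
  }
  if (any(zero_var)) {
    warnf("%d zero-variance gene(s) set to 0: %s", sum(zero_var),
          paste(head(rownames(m)[zero_var], 5), collapse = ", "))
  }
  expression_matrix(out, rownames(m), colnames(m))
}

#' Construct a cohort label table
#'
#' Clinical labels for the samples of a companion expression matrix:
#' chemotherapy response (`pCR` = pathological complete response,
#' chemosensitive; `RD` = residual disease, chemoresistant) and
#' disease relapse-free survival (DRFS) in days. The prognosis class
#' (good/poor) is derived from DRFS by [split_cohort()] via a median cutoff
#' and is not stored here.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param response character vector in `{pCR, RD, unknown}` (NA treated as
#'   unknown).
#' @param drfs_days nonnegative numeric vector of survival days, NA allowed.
#' @return a `data.frame` of class `cohort_labels`.
#' @export
cohort_labels <- function(sample_ids, response = NULL, drfs_days = NULL) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  if (anyDuplicated(sample_ids)) stopf("duplicate sample identifiers in labels")
  response <- as.character(response %||% rep("unknown", n))
  response[is.na(response)] <- "unknown"
  if (!all(response %in% c("pCR", "RD", "unknown"))) {
    stopf("response must be one of pCR, RD, unknown")
  }
  drfs_days <- as.numeric(drfs_days %||% rep(NA_real_, n))
  if (length(response) != n || length(drfs_days) != n) {
    stopf("label columns must all have length %d", n)
  }
  if (any(drfs_days < 0, na.rm = TRUE)) stopf("drfs_days must be nonnegative")
  out <- data.frame(sample_id = sample_ids, response = response,
                    drfs_days = drfs_days, stringsAsFactors = FALSE)
  class(out) <- c("cohort_labels", class(out))
  out
}

#' Read a label table
#'
#' Tab-separated table with columns `sample_id`, `response`, `drfs_days`.
#'
#' @param path file path.
#' @return a [cohort_labels()] table.
#' @export
read_labels_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c("sample_id", "response", "drfs_days")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stopf("label table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  cohort_labels(dt$sample_id, dt$response, dt$drfs_days)
}

#' Write a label table
#' @param labels a [cohort_labels()] table.
#' @param path output path.
#' @export
write_labels_table <- function(labels, path) {
  data.table::fwrite(as.data.frame(unclass(labels)), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Derive good/poor prognosis classes from survival times
#'
#' The cohort median of DRFS (computed over samples with a recorded value)
#' is the cutoff: samples with DRFS >= median are `good`, below are `poor`,
#' missing DRFS is `unknown`. Samples exactly at the median fall in the good
#' class ("survives at least the cutoff").
#'
#' @param labels a [cohort_labels()] table.
#' @return the table with a `prognosis` column added and the cutoff stored in
#'   `attr(, "drfs_cutoff")`.
#' @export
assign_prognosis <- function(labels) {
  d <- labels$drfs_days
  if (all(is.na(d))) stopf("no DRFS values; prognosis undefined")
  cutoff <- median(d, na.rm = TRUE)
  prog <- ifelse(is.na(d), "unknown", ifelse(d >= cutoff, "good", "poor"))
  labels$prognosis <- prog
  attr(labels, "drfs_cutoff") <- cutoff
  labels
}

#' Split a cohort into per-class expression matrices
#'
#' Partitions the samples of an expression matrix by phenotype class, the
#' grouping under which one autoencoder per class is trained. Two schemes:
#' `chemosensitivity` splits on the pCR/RD response; `prognosis` splits on
#' good/poor derived from the DRFS median cutoff ([assign_prognosis()]).
#' Samples with an unknown label are dropped and counted in the attached log.
#'
#' @param m an [expression_matrix()].
#' @param labels a [cohort_labels()] table covering the matrix's samples.
#' @param scheme `"chemosensitivity"` or `"prognosis"`.
#' @return named list of [expression_matrix()] objects, one per class, with
#'   attributes `excluded` (dropped sample ids) and, for prognosis,
#'   `drfs_cutoff`.
#' @export
split_cohort <- function(m, labels, scheme = c("chemosensitivity", "prognosis")) {
  scheme <- match.arg(scheme)
  unknown_ids <- setdiff(labels$sample_id, colnames(m))
  if (length(unknown_ids)) {
    stopf("labeled sample(s) absent from expression matrix: %s",
          paste(head(unknown_ids, 5), collapse = ", "))
  }
  cutoff <- NULL
  if (scheme == "chemosensitivity") {
    cls <- labels$response
    class_levels <- c("pCR", "RD")
  } else {
    labels <- assign_prognosis(labels)
    cls <- labels$prognosis
    cutoff <- attr(labels, "drfs_cutoff")
    class_levels <- c("good", "poor")
  }
  keep <- cls %in% class_levels
  excluded <- labels$sample_id[!keep]
  out <- lapply(class_levels, function(cl) {
    ids <- labels$sample_id[keep & cls == cl]
    if (length(ids) == 0) stopf("class '%s' is empty under scheme '%s'", cl, scheme)
    expression_matrix(unclass(m)[, ids, drop = FALSE], rownames(m), ids)
  })
  names(out) <- class_levels
  attr(out, "excluded") <- excluded
  if (!is.null(cutoff)) attr(out, "drfs_cutoff") <- cutoff
  out
}
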