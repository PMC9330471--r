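#' Specification of a synthetic two-class cohort
#'
#' Describes a cohort whose two phenotype classes differ in low-rank
#' covariance (factor) structure: within each class, every sample is a sum
#' of factor contributions (loading vector times a standard-normal factor
#' score) plus i.i.d. Gaussian noise, so genes sharing a factor are
#' correlated with a sign known from the loading signs. Disease relapse-free
#' survival times are drawn from a class-specific exponential so a median
#' split recovers the classes with a known error rate.
#'
#' Defaults are the package's reference simulation: 40 genes, 500 samples
#' per class, two disjoint 5-gene factors per class (classes on disjoint
#' gene blocks), loading magnitude 1 with a +,+,+,-,- sign pattern, noise
#' standard deviation 0.1, and exponential DRFS scales of 2000 days (pCR)
#' vs 800 days (RD).
#'
#' @param n_genes total gene count.
#' @param n_samples_per_class samples per class.
#' @param factors_per_class named list (one entry per class) of factor
#'   lists; each factor is `list(genes = indices, signs = +/-1 vector,
#'   magnitude = loading magnitude)`. Blocks within a class must be
#'   disjoint.
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param drfs_scale_per_class named numeric: exponential mean DRFS (days)
#'   per class.
#' @param seed integer seed.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 40,
                           n_samples_per_class = 500,
                           factors_per_class = NULL,
                           noise_sd = 0.1,
                           drfs_scale_per_class = c(pCR = 2000, RD = 800),
                           seed = 1L) {
  if (is.null(factors_per_class)) {
    signs <- c(1, 1, 1, -1, -1)
    factors_per_class <- list(
      pCR = list(list(genes = 1:5, signs = signs, magnitude = 1),
                 list(genes = 6:10, signs = signs, magnitude = 1)),
      RD = list(list(genes = 11:15, signs = signs, magnitude = 1),
                list(genes = 16:20, signs = signs, magnitude = 1)))
  }
  stopifnot(n_genes >= 1, n_samples_per_class >= 2, noise_sd > 0)
  if (is.null(names(factors_per_class)) ||
      !setequal(names(factors_per_class), names(drfs_scale_per_class))) {
    stopf("factors_per_class and drfs_scale_per_class must name the same classes")
  }
  for (cl in names(factors_per_class)) {
    blocks <- lapply(factors_per_class[[cl]], `[[`, "genes")
    all_idx <- unlist(blocks)
    if (any(all_idx < 1 | all_idx > n_genes)) {
      stopf("class '%s': factor gene index out of range", cl)
    }
    if (anyDuplicated(all_idx)) {
      stopf("class '%s': factor gene blocks overlap", cl)
    }
    for (f in factors_per_class[[cl]]) {
      if (length(f$signs) != length(f$genes) || !all(f$signs %in% c(-1, 1))) {
        stopf("class '%s': signs must be +/-1, one per block gene", cl)
      }
    }
  }
  structure(list(n_genes = n_genes,
                 n_samples_per_class = n_samples_per_class,
                 factors_per_class = factors_per_class,
                 noise_sd = noise_sd,
                 drfs_scale_per_class = drfs_scale_per_class,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic cohort
#'
#' Draws the cohort described by a [synthetic_spec()]: for each class,
#' sample vectors are the sum over factors of (loading vector x N(0,1)
#' factor score) plus N(0, noise_sd^2) noise; DRFS days are exponential with
#' the class scale; finally every gene is z-scored across the full cohort so
#' generated matrices satisfy the normalized-expression invariants directly.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `expression` (an [expression_matrix()]) and `labels`
#'   (a [cohort_labels()] table with `response` = class and `drfs_days`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    classes <- names(spec$factors_per_class)
    gene_ids <- sprintf("G%03d", seq_len(spec$n_genes))
    mats <- list(); ids <- list(); drfs <- list()
    for (cl in classes) {
      n_s <- spec$n_samples_per_class
      x <- matrix(rnorm(spec$n_genes * n_s, 0, spec$noise_sd),
                  spec$n_genes, n_s)
      for (f in spec$factors_per_class[[cl]]) {
        loading <- numeric(spec$n_genes)
        loading[f$genes] <- f$signs * f$magnitude
        scores <- rnorm(n_s)
        x <- x + loading %*% t(scores)
      }
      mats[[cl]] <- x
      ids[[cl]] <- sprintf("%s_S%03d", cl, seq_len(n_s))
      drfs[[cl]] <- rexp(n_s, rate = 1 / spec$drfs_scale_per_class[[cl]])
    }
    values <- do.call(cbind, mats)
    colnames(values) <- unlist(ids)
    rownames(values) <- gene_ids
    m <- expression_matrix(values)
    m <- suppressWarnings(normalize_genes(m, "zscore"))
    labels <- cohort_labels(unlist(ids),
                            response = rep(classes, each = spec$n_samples_per_class),
                            drfs_days = unlist(drfs))
    list(expression = m, labels = labels)
  })
}

#' Planted ground-truth gene pairs
#'
#' The recovery oracle: all within-block gene pairs of a class's factors,
#' undirected, with sign equal to the product of the two genes' loading
#' signs. Disjoint blocks contribute no cross-block pairs.
#'
#' @param spec a [synthetic_spec()].
#' @param class class label.
#' @return data.frame with columns `gene_a`, `gene_b` (gene ids,
#'   `gene_a < gene_b`), `sign`.
#' @export
ground_truth_pairs <- function(spec, class) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!class %in% names(spec$factors_per_class)) {
    stopf("unknown class '%s'", class)
  }
  gene_ids <- sprintf("G%03d", seq_len(spec$n_genes))
  rows <- list()
  for (f in spec$factors_per_class[[class]]) {
    g <- f$genes; s <- f$signs
    if (length(g) < 2) next
    cmb <- utils::combn(seq_along(g), 2)
    rows[[length(rows) + 1]] <- data.frame(
      gene_a = gene_ids[g[cmb[1, ]]],
      gene_b = gene_ids[g[cmb[2, ]]],
      sign = as.integer(s[cmb[1, ]] * s[cmb[2, ]]))
  }
  if (length(rows) == 0) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      sign = integer(0)))
  }
  out <- do.call(rbind, rows)
  swap <- out$gene_a > out$gene_b
  tmp <- out$gene_a[swap]; out$gene_a[swap] <- out$gene_b[swap]
  out$gene_b[swap] <- tmp
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Write the synthetic cohort and its ground truth to a directory
#'
#' Emits `expression.tsv`, `labels.tsv` and one
#' `truth_pairs_<class>.tsv` per class.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(spec)
  write_expression_table(cohort$expression, file.path(dir, "expression.tsv"))
  write_labels_table(cohort$labels, file.path(dir, "labels.tsv"))
  for (cl in names(spec$factors_per_class)) {
    data.table::fwrite(ground_truth_pairs(spec, cl),
                       file.path(dir, sprintf("truth_pairs_%s.tsv", cl)),
                       sep = "\t", quote = FALSE)
  }
  invisible(dir)
}
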