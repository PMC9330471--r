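#' Read a GMT gene-set collection
#'
#' Standard tab-delimited gene-set format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer than
#' three fields are a parse error (reported with the line number); duplicate
#' members within a set are dropped with a warning. Member identifiers are
#' uppercased by default for consistent matching.
#'
#' @param path GMT file path.
#' @param uppercase uppercase member identifiers (default TRUE).
#' @return named list of class `gene_set_collection` mapping set name to a
#'   character vector of members; descriptions kept in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path, uppercase = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descr <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stopf("GMT line %d has %d field(s); need name, description, members",
            i, length(fields))
    }
    name <- fields[1]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (uppercase) members <- toupper(members)
    if (anyDuplicated(members)) {
      warnf("set '%s': %d duplicate member(s) dropped", name,
            sum(duplicated(members)))
      members <- unique(members)
    }
    if (length(members) == 0) stopf("GMT line %d: set '%s' is empty", i, name)
    sets[[name]] <- members
    descr[name] <- fields[2]
  }
  attr(sets, "description") <- descr
  class(sets) <- c("gene_set_collection", class(sets))
  sets
}

#' Write a GMT file
#' @param sets named list of gene sets (a `gene_set_collection`).
#' @param path output path.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "description") %||%
    setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Rank genes by their encoder weight into a hidden node
#'
#' Per-hidden-node gene ranking used for preranked enrichment: the metric
#' for gene i is the trained encoder weight from input node i into the given
#' hidden node, ranked descending (signed by default). Ties are broken by
#' gene identifier so the ranking is deterministic.
#'
#' @param model an `autoencoder_model` (or `trained_autoencoder`) carrying
#'   gene ids.
#' @param node hidden-node index (1-based).
#' @param absolute rank by absolute weight instead of signed weight.
#' @return named numeric vector of metrics, names = gene ids, in rank order.
#' @export
rank_genes_for_node <- function(model, node, absolute = FALSE) {
  if (inherits(model, "trained_autoencoder")) model <- model$model
  node <- as.integer(node)
  if (node < 1 || node > nrow(model$W_enc)) {
    stopf("hidden node %d out of range 1..%d", node, nrow(model$W_enc))
  }
  genes <- model$gene_ids %||% as.character(seq_len(ncol(model$W_enc)))
  w <- model$W_enc[node, ]
  if (absolute) w <- abs(w)
  ord <- order(-w, genes)
  setNames(w[ord], genes[ord])
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The preranked GSEA statistic: walking down the ranked list, hits
#' increment the running sum by `|metric|^p / sum over hits of |metric|^p`
#' and misses decrement it by `1 / (N - N_hit)`. The enrichment score is the
#' signed maximum deviation of the running sum from zero; the sum returns to
#' zero after the last position and `|ES| <= 1`.
#'
#' @param ranked named numeric vector of metrics in descending rank order
#'   (as from [rank_genes_for_node()]).
#' @param set character vector of member genes; must intersect the ranked
#'   genes but not cover them all.
#' @param p weight exponent (default 1, the weighted statistic; 0 gives the
#'   classic unweighted KS statistic).
#' @return list with `es` and `running` (the length-N running sum).
#' @export
enrichment_score <- function(ranked, set, p = 1) {
  genes <- names(ranked)
  if (is.null(genes)) stopf("ranked metrics must be named by gene")
  hit <- genes %in% set
  es_from_hits(as.numeric(ranked), hit, p)
}

## core running-sum computation shared with the permutation null
es_from_hits <- function(metrics, hit, p) {
  n <- length(metrics)
  n_hit <- sum(hit)
  if (n_hit == 0) stopf("gene set does not intersect the ranked list")
  if (n_hit == n) stopf("gene set covers every ranked gene; miss penalty undefined")
  w <- abs(metrics)^p
  n_r <- sum(w[hit])
  inc <- numeric(n)
  if (n_r > 0) {
    inc[hit] <- w[hit] / n_r
  } else {
    inc[hit] <- 1 / n_hit  # all hit metrics zero: fall back to uniform steps
  }
  inc[!hit] <- -1 / (n - n_hit)
  running <- cumsum(inc)
  hi <- max(running)
  lo <- min(running)
  # signed maximum deviation; an exact tie between the positive and negative
  # extremum resolves to the positive one
  es <- if (hi >= -lo) hi else lo
  list(es = es, running = running)
}

#' Permutation statistics for one ranked list
#'
#' For every gene set passing the size filter, computes the observed
#' enrichment score and a gene-label permutation null (random positions of
#' the set's genes in the list; the only admissible null for a preranked
#' list). NES is the ES divided by the mean |null ES| of matching sign; the
#' nominal p-value is the matching-sign tail frequency with `(k+1)/(n+1)`
#' smoothing; the FDR q-value follows the NES-pooling procedure (ratio of
#' the null and observed tail fractions at the record's NES, computed within
#' sign and clipped to [0, 1]).
#'
#' @param ranked named metric vector in rank order.
#' @param sets a `gene_set_collection` (or named list of gene sets).
#' @param n_perm number of permutations (default 1000).
#' @param p weight exponent (default 1).
#' @param seed integer seed.
#' @param min_size,max_size set-size filter after intersection with the
#'   ranked genes (defaults 15 and 500).
#' @param keep_null also return the per-set null ES matrix.
#' @return data.frame with columns `set`, `size`, `es`, `nes`, `p_value`,
#'   `fdr_q`, `nes_defined`; when `keep_null`, the null ES matrix (sets x
#'   permutations) is in `attr(, "null_es")`.
#' @export
permutation_stats <- function(ranked, sets, n_perm = 1000, p = 1, seed = 1L,
                              min_size = 15, max_size = 500,
                              keep_null = FALSE) {
  stopifnot(n_perm >= 1)
  genes <- names(ranked)
  n <- length(genes)
  metrics <- as.numeric(ranked)
  sizes <- vapply(sets, function(s) sum(genes %in% s), integer(1))
  keep <- sizes >= min_size & sizes <= max_size & sizes < n
  if (!any(keep)) stopf("no gene set passes the size filter [%d, %d]", min_size, max_size)
  sets <- sets[keep]
  sizes <- sizes[keep]

  obs_es <- vapply(names(sets), function(nm) {
    enrichment_score(ranked, sets[[nm]], p)$es
  }, numeric(1))

  with_seed(seed, {
    null_es <- matrix(NA_real_, length(sets), n_perm,
                      dimnames = list(names(sets), NULL))
    for (si in seq_along(sets)) {
      sz <- sizes[si]
      for (j in seq_len(n_perm)) {
        hit <- logical(n)
        hit[sample.int(n, sz)] <- TRUE
        null_es[si, j] <- es_from_hits(metrics, hit, p)$es
      }
    }
    NULL
  })

  nes <- numeric(length(sets)); p_val <- numeric(length(sets))
  nes_def <- logical(length(sets))
  null_nes <- null_es * NA
  for (si in seq_along(sets)) {
    nulls <- null_es[si, ]
    pos_mean <- mean(nulls[nulls >= 0])
    neg_mean <- mean(abs(nulls[nulls < 0]))
    # normalize every null by its own sign's mean magnitude -> pooled null NES
    null_nes[si, nulls >= 0] <- nulls[nulls >= 0] / pos_mean
    null_nes[si, nulls < 0] <- nulls[nulls < 0] / neg_mean
    same_sign <- if (obs_es[si] >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
    if (length(same_sign) == 0 || !is.finite(mean(abs(same_sign))) ||
        mean(abs(same_sign)) == 0) {
      nes[si] <- NA_real_; p_val[si] <- NA_real_; nes_def[si] <- FALSE
    } else {
      nes[si] <- obs_es[si] / mean(abs(same_sign))
      k_tail <- sum(abs(same_sign) >= abs(obs_es[si]))
      p_val[si] <- (k_tail + 1) / (length(same_sign) + 1)
      nes_def[si] <- TRUE
    }
  }

  pool <- null_nes[is.finite(null_nes)]
  fdr <- vapply(seq_along(sets), function(si) {
    if (!nes_def[si]) return(NA_real_)
    v <- nes[si]
    if (v >= 0) {
      num_base <- sum(pool >= 0); den_base <- sum(nes >= 0, na.rm = TRUE)
      num <- if (num_base > 0) sum(pool >= v) / num_base else 1
      den <- if (den_base > 0) sum(nes >= v, na.rm = TRUE) / den_base else 1
    } else {
      num_base <- sum(pool < 0); den_base <- sum(nes < 0, na.rm = TRUE)
      num <- if (num_base > 0) sum(pool <= v) / num_base else 1
      den <- if (den_base > 0) sum(nes <= v, na.rm = TRUE) / den_base else 1
    }
    min(1, max(0, if (den > 0) num / den else 1))
  }, numeric(1))

  out <- data.frame(set = names(sets), size = as.integer(sizes),
                    es = unname(obs_es), nes = unname(nes),
                    p_value = unname(p_val), fdr_q = unname(fdr),
                    nes_defined = unname(nes_def), row.names = NULL)
  if (keep_null) attr(out, "null_es") <- null_es
  out
}

#' Enrichment over all hidden nodes
#'
#' Runs [rank_genes_for_node()] + [permutation_stats()] for every hidden
#' node of a trained model, producing the node-by-set enrichment table
#' behind node-annotation heat maps. Per-node permutation seeds are derived
#' from `seed` + node index.
#'
#' @param model a trained model carrying gene ids.
#' @param sets a `gene_set_collection`.
#' @param nodes hidden-node indices (default all).
#' @param absolute rank by absolute weight (default FALSE, signed).
#' @inheritParams permutation_stats
#' @return data.frame of class `enrichment_table`: `node`, `set`, `size`,
#'   `es`, `nes`, `p_value`, `fdr_q`, `nes_defined`.
#' @export
gsea_hidden_nodes <- function(model, sets, nodes = NULL, n_perm = 1000,
                              p = 1, seed = 1L, min_size = 15, max_size = 500,
                              absolute = FALSE) {
  if (inherits(model, "trained_autoencoder")) model <- model$model
  nodes <- nodes %||% seq_len(nrow(model$W_enc))
  rows <- lapply(nodes, function(nd) {
    ranked <- rank_genes_for_node(model, nd, absolute = absolute)
    tab <- permutation_stats(ranked, sets, n_perm = n_perm, p = p,
                             seed = seed + nd, min_size = min_size,
                             max_size = max_size)
    cbind(node = nd, tab)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enrichment_table", class(out))
  out
}

#' Filter an enrichment table for reporting
#'
#' Keeps records with `|NES| >` the NES threshold and FDR q below the cutoff
#' (defaults 1.5 and 0.05); the unfiltered table should always be persisted
#' alongside.
#'
#' @param table an `enrichment_table` (or [permutation_stats()] output).
#' @param nes_threshold absolute NES threshold (default 1.5).
#' @param fdr_threshold FDR q cutoff (default 0.05).
#' @return the filtered subset.
#' @export
significant_enrichment <- function(table, nes_threshold = 1.5,
                                   fdr_threshold = 0.05) {
  keep <- table$nes_defined & abs(table$nes) > nes_threshold &
    table$fdr_q < fdr_threshold
  table[keep, , drop = FALSE]
}

#' Write an enrichment table (TSV)
#' @param table an `enrichment_table`.
#' @param path output path.
#' @export
write_enrichment_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Node-by-set NES matrix
#'
#' Reshapes an [gsea_hidden_nodes()] table into a sets x nodes NES matrix
#' for heat-map tools; missing records are NA.
#'
#' @param table an `enrichment_table` with a `node` column.
#' @param path optional TSV output path.
#' @return numeric matrix, rows = sets, columns = nodes.
#' @export
nes_matrix <- function(table, path = NULL) {
  sets <- sort(unique(table$set))
  nodes <- sort(unique(table$node))
  m <- matrix(NA_real_, length(sets), length(nodes),
              dimnames = list(sets, paste0("node", nodes)))
  m[cbind(match(table$set, sets), match(table$node, nodes))] <- table$nes
  if (!is.null(path)) {
    df <- data.frame(set = rownames(m), m, check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  }
  m
}
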