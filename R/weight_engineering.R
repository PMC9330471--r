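#' Gene-gene association scores from trained weights
#'
#' Decodes a trained single-hidden-layer model into a dense association
#' matrix: the score of input gene i predicting output gene o is the sum
#' over all hidden-node paths of the products of the path's two weights,
#' \deqn{S_{o,i} = \sum_h w_{o,h} \, w_{h,i},}
#' i.e. the matrix product of decoder and encoder weights. Biases are
#' excluded. For a linear model with zero biases this is exactly the
#' end-to-end input-to-output Jacobian, so the sign of an entry is the sign
#' of the predictive effect of gene i on gene o.
#'
#' @param model an `autoencoder_model` (or `trained_autoencoder`).
#' @return matrix of class `association_matrix` (output genes in rows, input
#'   genes in columns) with gene dimnames when the model carries gene ids.
#' @export
association_scores <- function(model) {
  if (inherits(model, "trained_autoencoder")) model <- model$model
  if (ncol(model$W_dec) != nrow(model$W_enc)) {
    stopf("decoder/encoder hidden dimensions disagree")
  }
  s <- model$W_dec %*% model$W_enc
  if (!is.null(model$gene_ids)) dimnames(s) <- list(model$gene_ids, model$gene_ids)
  class(s) <- c("association_matrix", class(s))
  s
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d x %d gene scores in [%.4g, %.4g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Select the top gene pairs by absolute association score
#'
#' Ranks off-diagonal entries (self-pairs excluded) by absolute score,
#' descending, and returns the top `k` directed pairs with their signed
#' scores. Each direction of a gene pair counts separately. Ties at the
#' boundary are broken by (|score| desc, source id asc, target id asc) for
#' determinism.
#'
#' @param s an [association_scores()] matrix.
#' @param k number of directed pairs (default 200); at most `n * (n - 1)`.
#' @return data.frame with columns `source` (input gene), `target` (output
#'   gene), `score`; ordered by rank.
#' @export
select_top_pairs <- function(s, k = 200) {
  s <- unclass(s)
  n <- nrow(s)
  if (n != ncol(s)) stopf("association matrix must be square")
  if (k > n * (n - 1)) stopf("k = %d exceeds the %d off-diagonal pairs", k, n * (n - 1))
  genes <- rownames(s) %||% as.character(seq_len(n))
  off <- which(row(s) != col(s))
  # S[o, i]: input gene i (column) -> output gene o (row)
  src <- genes[col(s)[off]]
  tgt <- genes[row(s)[off]]
  score <- s[off]
  ord <- order(-abs(score), src, tgt)
  top <- ord[seq_len(k)]
  data.frame(source = src[top], target = tgt[top], score = score[top],
             row.names = NULL)
}

#' Build a signed directed network from selected pairs
#'
#' Each pair becomes a directed edge source -> target carrying its signed
#' score (positive or negative predictive effect). Reciprocal pairs (both
#' i -> j and j -> i selected) are flagged `mutual` on both edges.
#'
#' @param pairs data.frame from [select_top_pairs()].
#' @return list of class `decoded_network`: `edges` (data.frame source,
#'   target, score, sign, mutual), `graph` (directed igraph with the same
#'   edge attributes), and NULL `hubs`/`modules` until [assign_modules()].
#' @export
build_network <- function(pairs) {
  if (nrow(pairs) == 0) stopf("no pairs to build a network from")
  key <- paste(pairs$source, pairs$target, sep = "\r")
  rev_key <- paste(pairs$target, pairs$source, sep = "\r")
  edges <- data.frame(source = pairs$source, target = pairs$target,
                      score = pairs$score,
                      sign = ifelse(pairs$score >= 0, 1L, -1L),
                      mutual = key %in% rev_key,
                      row.names = NULL)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  structure(list(edges = edges, graph = g, hubs = NULL, modules = NULL),
            class = "decoded_network")
}

#' @export
print.decoded_network <- function(x, ...) {
  cat(sprintf("decoded_network: %d edges over %d genes", nrow(x$edges),
              igraph::vcount(x$graph)))
  if (!is.null(x$hubs)) {
    cat(sprintf("; %d hubs, %d modules", length(x$hubs), length(x$modules)))
  }
  cat("\n")
  invisible(x)
}

#' Hub genes and connectivity modules
#'
#' Hubs are genes recurring in multiple selected pairs: undirected degree
#' (number of distinct partner genes) at least `hub_min_degree`. Modules are
#' the connected components of the undirected projection, each labeled by
#' its maximum-degree gene (ties broken lexicographically); they partition
#' the network's gene set.
#'
#' @param net a [build_network()] result.
#' @param hub_min_degree minimum undirected degree for hub status (default 2).
#' @return the network with `hubs` (character vector) and `modules` (named
#'   list of gene sets) filled in.
#' @export
assign_modules <- function(net, hub_min_degree = 2) {
  und <- igraph::as_undirected(net$graph, mode = "collapse")
  deg <- igraph::degree(und)
  net$hubs <- sort(names(deg)[deg >= hub_min_degree])
  comp <- igraph::components(und)
  modules <- split(names(comp$membership), comp$membership)
  labels <- vapply(modules, function(genes) {
    d <- deg[genes]
    sort(genes[d == max(d)])[1]
  }, character(1))
  names(modules) <- labels
  net$modules <- modules[order(labels)]
  net
}

#' Write an association matrix as TSV
#'
#' Full genes-x-genes matrix, diagonal included, for audit; first column
#' `gene_id` names the output gene of each row.
#'
#' @param s an [association_scores()] matrix.
#' @param path output path.
#' @export
write_association_matrix <- function(s, path) {
  body <- apply(unclass(s), 2, sprintf, fmt = "%.17g")  # round-trip precision
  df <- data.frame(gene_id = rownames(s) %||% as.character(seq_len(nrow(s))),
                   body, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an association matrix written by [write_association_matrix()]
#' @param path file path.
#' @return an `association_matrix`.
#' @export
read_association_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1), data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- dt[[1]]
  class(m) <- c("association_matrix", class(m))
  m
}

#' Export a decoded network
#'
#' SIF (`source <sign> target`, one edge per line, relation `pos`/`neg`) and
#' GraphML with edge attributes `score`, `sign`, `mutual`.
#'
#' @param net a `decoded_network`.
#' @param sif_path,graphml_path output paths (either may be NULL to skip).
#' @export
write_network <- function(net, sif_path = NULL, graphml_path = NULL) {
  if (!is.null(sif_path)) {
    rel <- ifelse(net$edges$sign > 0, "pos", "neg")
    writeLines(paste(net$edges$source, rel, net$edges$target, sep = "\t"),
               sif_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  }
  invisible(net)
}

#' Annotate network genes with local terms
#'
#' Joins a local two-column gene-to-term table onto the network's genes
#' (an offline stand-in for ontology overlays; no database calls).
#'
#' @param net a `decoded_network`.
#' @param term_table data.frame (or TSV path) with columns `gene`, `term`;
#'   a gene may carry several terms.
#' @return the network with a `terms` element: named list gene -> character
#'   vector of terms (genes without annotation omitted).
#' @export
annotate_terms <- function(net, term_table) {
  if (is.character(term_table)) {
    term_table <- data.table::fread(term_table, header = TRUE, data.table = FALSE)
  }
  if (!all(c("gene", "term") %in% names(term_table))) {
    stopf("term table needs columns 'gene' and 'term'")
  }
  genes <- igraph::V(net$graph)$name
  tt <- term_table[term_table$gene %in% genes, , drop = FALSE]
  net$terms <- split(as.character(tt$term), tt$gene)
  net
}
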