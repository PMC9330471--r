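#' Read a pipeline run configuration
#'
#' JSON (always available) or YAML (if the yaml package is installed) file
#' of [run_pipeline()] arguments.
#'
#' @param path config file path (`.json`, `.yaml`/`.yml`).
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("no such config file: %s", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("YAML config requires the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

pipeline_train_config <- function(train, seed) {
  train <- train %||% list()
  train_config(hidden_size = train$hidden_size %||% 8L,
               activation = train$activation %||% "linear",
               max_epochs = train$max_epochs %||% 10000L,
               batch_size = train$batch_size %||% 32L,
               learning_rate = train$learning_rate %||% 1e-3,
               patience = train$patience %||% 100L,
               min_delta = train$min_delta %||% 1e-6,
               seed = seed)
}

run_pipeline_one_seed <- function(m, labels, cfg, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tcfg <- pipeline_train_config(cfg$train, seed)
  classes <- split_cohort(m, labels, scheme = cfg$scheme %||% "chemosensitivity")
  gmt <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
  top_k <- cfg$top_k %||% 200L
  artifacts <- list()

  for (cl in names(classes)) {
    tcfg_cl <- tcfg
    tcfg_cl$seed <- seed + match(cl, names(classes)) - 1L
    fit <- train_autoencoder(classes[[cl]], tcfg_cl)
    prefix <- file.path(out_dir, cl)
    save_model(fit, paste0(prefix, "_model.rds"))
    data.table::fwrite(data.frame(epoch = seq_along(fit$loss), mse = fit$loss),
                       paste0(prefix, "_loss.tsv"), sep = "\t", quote = FALSE)
    s <- association_scores(fit$model)
    write_association_matrix(s, paste0(prefix, "_association.tsv"))
    k_eff <- min(as.integer(top_k), nrow(s) * (nrow(s) - 1L))
    net <- assign_modules(build_network(select_top_pairs(s, k_eff)),
                          hub_min_degree = cfg$hub_min_degree %||% 2)
    write_network(net, sif_path = paste0(prefix, "_network.sif"),
                  graphml_path = paste0(prefix, "_network.graphml"))
    if (!is.null(cfg$terms)) net <- annotate_terms(net, cfg$terms)
    if (!is.null(gmt)) {
      gs <- cfg$gsea %||% list()
      tab <- gsea_hidden_nodes(fit, gmt,
                               n_perm = gs$n_perm %||% 1000,
                               p = gs$p %||% 1,
                               seed = tcfg_cl$seed,
                               min_size = gs$min_size %||% 15,
                               max_size = gs$max_size %||% 500)
      write_enrichment_table(tab, paste0(prefix, "_enrichment.tsv"))
    }
    artifacts[[cl]] <- list(final_loss = unname(tail(fit$loss, 1)),
                            epochs_run = fit$epochs_run,
                            n_samples = ncol(classes[[cl]]),
                            top_k = k_eff,
                            hubs = length(net$hubs),
                            modules = length(net$modules))
  }
  artifacts
}

#' Run the full decoding pipeline
#'
#' Chains the whole workflow for each requested seed: split the cohort by
#' phenotype, train one autoencoder per class, decode each model into an
#' association matrix and a signed directed network with hubs and modules,
#' optionally run hidden-node enrichment against a GMT collection, and write
#' every artifact plus a JSON manifest under the output directory. With a
#' vector of seeds, one artifact subdirectory `seed_<s>` is produced per
#' seed (the multi-seed robustness protocol); each is individually
#' reproducible from its seed.
#'
#' @param config named list (or path to a JSON/YAML file of one) with
#'   entries: `expression` (path or [expression_matrix()]), `labels` (path
#'   or [cohort_labels()]), `output_dir`; optional `scheme`
#'   ("chemosensitivity"/"prognosis"), `normalize` ("zscore",
#'   "rank_inverse_normal" or "none"), `train` (list of [train_config()]
#'   fields), `top_k` (default 200), `hub_min_degree`, `gmt` (GMT path),
#'   `gsea` (list: n_perm, p, min_size, max_size), `terms` (gene-term TSV),
#'   `seeds` (integer vector, default 1).
#' @return invisibly, the manifest list. On stage failure a `FAILED` marker
#'   file naming the stage is left in the output directory and the error is
#'   re-signalled.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  out_root <- cfg$output_dir %||% stopf("config needs 'output_dir'")
  dir.create(out_root, showWarnings = FALSE, recursive = TRUE)
  seeds <- as.integer(cfg$seeds %||% 1L)

  stage <- "load"
  tryCatch({
    m <- cfg$expression
    if (is.character(m)) m <- read_expression_table(m)
    if (!inherits(m, "expression_matrix")) m <- expression_matrix(m)
    labels <- cfg$labels
    if (is.character(labels)) labels <- read_labels_table(labels)

    stage <- "normalize"
    norm <- cfg$normalize %||% "zscore"
    if (norm != "none") m <- suppressWarnings(normalize_genes(m, norm))

    stage <- "per-seed run"
    runs <- list()
    for (s in seeds) {
      out_dir <- if (length(seeds) > 1) {
        file.path(out_root, sprintf("seed_%d", s))
      } else out_root
      runs[[as.character(s)]] <- run_pipeline_one_seed(m, labels, cfg, s, out_dir)
    }

    stage <- "manifest"
    manifest <- list(
      package = "aedecode",
      version = as.character(utils::packageVersion("aedecode")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      scheme = cfg$scheme %||% "chemosensitivity",
      normalize = norm,
      train = unclass(pipeline_train_config(cfg$train, seeds[1])),
      top_k = cfg$top_k %||% 200L,
      seeds = seeds,
      n_genes = nrow(m),
      n_samples = ncol(m),
      runs = runs)
    jsonlite::write_json(manifest, file.path(out_root, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }, error = function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(out_root, "FAILED"))
    stop(e)
  })
}
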