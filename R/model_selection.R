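#' Holdout plus k-fold cross-validation splits
#'
#' First sets aside a random `holdout_fraction` of the samples as a holdout
#' set, then partitions the remainder into `k` folds. With `stratify_by`,
#' both the holdout draw and the fold assignment preserve class proportions
#' to within one sample per class (round-robin dealing of shuffled
#' within-class samples).
#'
#' @param sample_ids character vector of sample identifiers.
#' @param k number of folds (>= 2).
#' @param holdout_fraction fraction held out before folding (default 0.1;
#'   0 for no holdout).
#' @param stratify_by optional vector of class labels aligned with
#'   `sample_ids`.
#' @param seed integer seed.
#' @return list with `holdout` (character vector, possibly empty) and
#'   `folds` (list of `k` character vectors partitioning the remainder).
#' @export
make_cv_folds <- function(sample_ids, k, holdout_fraction = 0.1,
                          stratify_by = NULL, seed = 1L) {
  sample_ids <- as.character(sample_ids)
  n <- length(sample_ids)
  stopifnot(k >= 2, holdout_fraction >= 0, holdout_fraction < 1)
  if (!is.null(stratify_by) && length(stratify_by) != n) {
    stopf("stratify_by must align with sample_ids")
  }
  with_seed(seed, {
    if (is.null(stratify_by)) {
      n_hold <- round(holdout_fraction * n)
      shuffled <- sample(sample_ids)
      holdout <- shuffled[seq_len(n_hold)]
      rest <- shuffled[-seq_len(n_hold)]
      if (n_hold == 0) { holdout <- character(0); rest <- shuffled }
      if (length(rest) < k) stopf("k = %d exceeds the %d remaining samples", k, length(rest))
      folds <- split(rest, rep_len(seq_len(k), length(rest)))
    } else {
      classes <- split(sample_ids, as.character(stratify_by))
      # largest-remainder rounding so the total holdout matches the fraction
      target <- holdout_fraction * lengths(classes)
      n_hold <- floor(target)
      short <- round(holdout_fraction * n) - sum(n_hold)
      if (short > 0) {
        extra <- order(target - floor(target), decreasing = TRUE)[seq_len(short)]
        n_hold[extra] <- n_hold[extra] + 1
      }
      holdout <- character(0)
      fold_members <- vector("list", k)
      for (ci in seq_along(classes)) {
        ids <- sample(classes[[ci]])
        h <- seq_len(n_hold[ci])
        if (n_hold[ci] > 0) holdout <- c(holdout, ids[h])
        rest <- if (n_hold[ci] > 0) ids[-h] else ids
        assign_to <- rep_len(seq_len(k), length(rest))
        for (f in seq_len(k)) {
          fold_members[[f]] <- c(fold_members[[f]], rest[assign_to == f])
        }
      }
      folds <- fold_members
      if (any(lengths(folds) == 0)) {
        stopf("k = %d exceeds the remaining samples in some stratum", k)
      }
    }
    names(folds) <- paste0("fold", seq_len(k))
    list(holdout = holdout, folds = folds)
  })
}

#' Hyperparameter grid scan
#'
#' Evaluates every activation x hidden-size combination by k-fold
#' cross-validation: for each combination, one model is trained per fold on
#' the other folds' samples and scored by reconstruction MSE on the held-out
#' fold. The combination with the lowest mean validation MSE is selected
#' (ties broken toward the smaller hidden size, then the activation list
#' order — smaller models are cheaper and easier to interpret). Only after
#' selection is a model fit on all non-holdout samples and scored on the
#' holdout set, which is reported as model performance. Combinations whose
#' training diverges are flagged failed and skipped.
#'
#' @param data an [expression_matrix()].
#' @param hidden_sizes integer vector of hidden-layer sizes.
#' @param activations character vector of activation names.
#' @param cfg a [train_config()] supplying the remaining hyperparameters
#'   (its `hidden_size`/`activation` are overridden per combination).
#' @param k number of CV folds (default 10).
#' @param holdout_fraction holdout fraction (default 0.1).
#' @param stratify_by optional labels for stratified folds.
#' @return list of class `scan_result`: `results` (data.frame with one row
#'   per combination: activation, hidden_size, per-fold and mean validation
#'   MSE, failed flag), `selected` (list with activation, hidden_size,
#'   holdout_mse), `folds`, and `holdout_model` (the final refit).
#' @export
grid_scan <- function(data, hidden_sizes, activations, cfg, k = 10,
                      holdout_fraction = 0.1, stratify_by = NULL) {
  stopifnot(length(hidden_sizes) >= 1, length(activations) >= 1)
  x <- unclass(data)
  splits <- make_cv_folds(colnames(x), k = k,
                          holdout_fraction = holdout_fraction,
                          stratify_by = stratify_by, seed = cfg$seed)
  grid <- expand.grid(hidden_size = as.integer(hidden_sizes),
                      activation = activations, stringsAsFactors = FALSE)
  # evaluate in activation-major order matching the user's list
  grid <- grid[order(match(grid$activation, activations), grid$hidden_size), ]
  rownames(grid) <- NULL

  fold_mse <- matrix(NA_real_, nrow(grid), k,
                     dimnames = list(NULL, names(splits$folds)))
  failed <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg_i <- cfg
    cfg_i$hidden_size <- grid$hidden_size[i]
    cfg_i$activation <- grid$activation[i]
    for (f in seq_len(k)) {
      val_ids <- splits$folds[[f]]
      train_ids <- setdiff(unlist(splits$folds[-f]), splits$holdout)
      fit <- tryCatch(
        train_autoencoder(x[, train_ids, drop = FALSE], cfg_i),
        error = function(e) NULL)
      if (is.null(fit)) { failed[i] <- TRUE; break }
      val <- x[, val_ids, drop = FALSE]
      fold_mse[i, f] <- mse_loss(forward(fit$model, val)$output, val)
    }
  }
  mean_mse <- rowMeans(fold_mse)
  mean_mse[failed] <- NA_real_
  if (all(failed)) stopf("every grid combination failed to train")

  ok <- which(!failed)
  sel <- ok[order(mean_mse[ok], grid$hidden_size[ok],
                  match(grid$activation[ok], activations))][1]

  cfg_sel <- cfg
  cfg_sel$hidden_size <- grid$hidden_size[sel]
  cfg_sel$activation <- grid$activation[sel]
  train_ids <- unlist(splits$folds)
  final_fit <- train_autoencoder(x[, train_ids, drop = FALSE], cfg_sel)
  holdout_mse <- if (length(splits$holdout)) {
    hx <- x[, splits$holdout, drop = FALSE]
    mse_loss(forward(final_fit$model, hx)$output, hx)
  } else NA_real_

  results <- data.frame(activation = grid$activation,
                        hidden_size = grid$hidden_size,
                        as.data.frame(fold_mse),
                        mean_val_mse = mean_mse,
                        failed = failed,
                        selected = seq_len(nrow(grid)) == sel)
  structure(list(results = results,
                 selected = list(activation = grid$activation[sel],
                                 hidden_size = grid$hidden_size[sel],
                                 mean_val_mse = mean_mse[sel],
                                 holdout_mse = holdout_mse),
                 folds = splits,
                 holdout_model = final_fit),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d combinations; selected %s / %d hidden nodes (val MSE %.5g, holdout MSE %.5g)\n",
              nrow(x$results), x$selected$activation, x$selected$hidden_size,
              x$selected$mean_val_mse, x$selected$holdout_mse))
  invisible(x)
}

#' Write a scan report
#'
#' TSV of all combinations plus a JSON file of the selected configuration.
#'
#' @param scan a `scan_result`.
#' @param tsv_path,json_path output paths.
#' @export
write_scan_report <- function(scan, tsv_path, json_path) {
  data.table::fwrite(scan$results, tsv_path, sep = "\t", quote = FALSE)
  jsonlite::write_json(scan$selected, json_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(tsv_path)
}
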