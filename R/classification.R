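#' Per-sample reconstruction error
#'
#' The classification statistic: the sum over genes of squared reconstruction
#' residuals for one sample (the single-sample case of [mse_loss()]).
#'
#' @param model an `autoencoder_model`.
#' @param x numeric vector of length `n_genes`, or a genes-x-samples matrix
#'   (one error per column).
#' @return nonnegative scalar, or vector with one entry per sample.
#' @export
reconstruction_error <- function(model, x) {
  x <- check_model_dims(model, x)
  out <- forward(model, x)$output
  colSums((out - x)^2)
}

#' Build a per-class model ensemble
#'
#' One trained autoencoder per phenotype class, sharing the gene order of the
#' training matrix. A sample is later assigned to the class whose model
#' reconstructs it best.
#'
#' @param class_data named list of [expression_matrix()] objects (output of
#'   [split_cohort()]), all with identical gene ordering.
#' @param cfg a [train_config()].
#' @param class_seeds optional named integer vector of per-class seeds
#'   (default: `cfg$seed` offset by the class index).
#' @return named list of class `classifier_ensemble` mapping class label to
#'   `trained_autoencoder`.
#' @export
train_ensemble <- function(class_data, cfg, class_seeds = NULL) {
  stopifnot(length(class_data) >= 2)
  gene_ref <- rownames(class_data[[1]])
  for (m in class_data) {
    if (!identical(rownames(m), gene_ref)) stopf("class matrices disagree on gene order")
  }
  labels <- names(class_data)
  fits <- lapply(seq_along(class_data), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- if (!is.null(class_seeds)) as.integer(class_seeds[[labels[i]]])
                  else cfg$seed + i - 1L
    train_autoencoder(class_data[[i]], cfg_i)
  })
  names(fits) <- labels
  structure(fits, class = "classifier_ensemble")
}

#' Classify a sample by reconstruction error
#'
#' Computes the reconstruction error of `x` under every class model and
#' assigns the label of the minimum. Exact ties are broken toward the
#' lexicographically first class label, with a warning.
#'
#' @param ensemble a named list of `autoencoder_model` /
#'   `trained_autoencoder` objects (e.g. [train_ensemble()] output).
#' @param x sample vector, or genes-x-samples matrix.
#' @return for a single sample, list(`class`, `errors`); for a matrix, a
#'   data.frame with `sample_id`, `predicted_class` and one error column per
#'   class.
#' @export
classify_samples <- function(ensemble, x) {
  stopifnot(length(ensemble) >= 1)
  labels <- names(ensemble)
  if (is.null(labels) || any(!nzchar(labels))) stopf("ensemble must be a named list")
  models <- lapply(ensemble, function(f) if (inherits(f, "trained_autoencoder")) f$model else f)
  x <- as.matrix(x)
  errs <- vapply(models, function(m) reconstruction_error(m, x),
                 numeric(ncol(x)))
  errs <- matrix(errs, ncol = length(models),
                 dimnames = list(colnames(x), labels))
  ord <- order(labels)  # lexicographic tie-break
  pred <- apply(errs[, ord, drop = FALSE], 1, function(e) {
    labels[ord][which.min(e)]
  })
  ties <- apply(errs, 1, function(e) sum(e == min(e)) > 1)
  if (any(ties)) {
    warnf("%d sample(s) with exactly tied reconstruction errors; assigned to the lexicographically first class", sum(ties))
  }
  if (ncol(x) == 1 && is.null(colnames(x))) {
    return(list(class = unname(pred[1]), errors = errs[1, ]))
  }
  data.frame(sample_id = colnames(x) %||% as.character(seq_len(ncol(x))),
             predicted_class = unname(pred), errs,
             check.names = FALSE, row.names = NULL)
}

#' Misclassification rate under stratified cross-validation
#'
#' The phenotype-prediction protocol: samples are split into `k` stratified
#' folds; for each fold, one autoencoder per class is trained on the fold's
#' training portion with snapshots at the checkpoint epochs, and the held-out
#' samples are classified at each checkpoint by lowest reconstruction error.
#' Rates are pooled over folds (errors / total held-out samples).
#'
#' @param data an [expression_matrix()].
#' @param class_of named vector or factor mapping sample id to class label
#'   (e.g. a response or prognosis vector); samples absent from it are
#'   ignored.
#' @param cfg a [train_config()].
#' @param epoch_checkpoints increasing integer epochs at which to evaluate
#'   (default `c(100, 500, 1000, 5000, 10000)`, truncated at
#'   `cfg$max_epochs`).
#' @param k number of folds (default 10).
#' @return data.frame with columns `epoch`, `errors`, `total`,
#'   `misclassification_rate`; per-sample predictions at the final checkpoint
#'   in `attr(, "predictions")`.
#' @export
misclassification_cv <- function(data, class_of, cfg,
                                 epoch_checkpoints = c(100, 500, 1000, 5000, 10000),
                                 k = 10) {
  x <- unclass(data)
  class_of <- class_of[names(class_of) %in% colnames(x)]
  ids <- names(class_of)
  cls <- as.character(class_of)
  if (length(unique(cls)) < 2) stopf("need >=2 classes")
  epoch_checkpoints <- sort(unique(pmin(as.integer(epoch_checkpoints),
                                        cfg$max_epochs)))
  splits <- make_cv_folds(ids, k = k, holdout_fraction = 0,
                          stratify_by = cls, seed = cfg$seed)
  err_count <- setNames(integer(length(epoch_checkpoints)),
                        as.character(epoch_checkpoints))
  total <- 0L
  final_pred <- character(0)
  for (f in seq_len(k)) {
    test_ids <- splits$folds[[f]]
    train_ids <- setdiff(ids, test_ids)
    train_cls <- cls[match(train_ids, ids)]
    if (!all(unique(cls) %in% train_cls)) {
      stopf("fold %d training portion lacks a class", f)
    }
    fits <- lapply(sort(unique(cls)), function(cl) {
      train_autoencoder(x[, train_ids[train_cls == cl], drop = FALSE], cfg,
                        checkpoint_epochs = epoch_checkpoints)
    })
    names(fits) <- sort(unique(cls))
    truth <- cls[match(test_ids, ids)]
    total <- total + length(test_ids)
    for (ep in as.character(epoch_checkpoints)) {
      snap <- lapply(fits, function(fit) fit$checkpoints[[ep]])
      pred <- classify_samples(snap, x[, test_ids, drop = FALSE])
      err_count[ep] <- err_count[ep] + sum(pred$predicted_class != truth)
      if (ep == as.character(max(epoch_checkpoints))) {
        final_pred <- c(final_pred, setNames(pred$predicted_class, test_ids))
      }
    }
  }
  out <- data.frame(epoch = epoch_checkpoints,
                    errors = as.integer(err_count),
                    total = total,
                    misclassification_rate = err_count / total,
                    row.names = NULL)
  attr(out, "predictions") <- final_pred
  out
}

#' Write a prediction table
#'
#' TSV with `sample_id`, `predicted_class` and per-class reconstruction-MSE
#' columns, as produced by [classify_samples()] on a matrix.
#'
#' @param predictions data.frame from [classify_samples()].
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  data.table::fwrite(predictions, path, sep = "\t", quote = FALSE)
  invisible(path)
}
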