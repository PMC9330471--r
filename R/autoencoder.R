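#' Training configuration for an autoencoder
#'
#' Bundles the hyperparameters of a single training run. Defaults follow the
#' package's standard protocol: adaptive-moment (Adam) gradient descent at
#' learning rate 1e-3, minibatches of 32, early stopping on the training loss
#' when the best loss has not improved by at least `min_delta` for `patience`
#' consecutive epochs, and a hard cap of 10,000 epochs.
#'
#' @param hidden_size number of hidden-layer nodes.
#' @param activation one of `"linear"`, `"elu"`, `"relu"`, `"prelu"`,
#'   `"sigmoid"`, `"tanh"`. PReLU carries one learnable slope per layer,
#'   initialized at 0.25.
#' @param max_epochs epoch cap (default 10000).
#' @param batch_size minibatch size (default 32; capped at the sample count).
#' @param learning_rate Adam step size (default 1e-3).
#' @param patience early-stopping patience in epochs (default 100).
#' @param min_delta minimum loss improvement to reset patience (default 1e-6).
#' @param seed integer seed governing initialization and epoch shuffling.
#' @return a list of class `train_config`.
#' @export
train_config <- function(hidden_size,
                         activation = c("linear", "elu", "relu", "prelu",
                                        "sigmoid", "tanh"),
                         max_epochs = 10000L, batch_size = 32L,
                         learning_rate = 1e-3, patience = 100L,
                         min_delta = 1e-6, seed = 1L) {
  activation <- match.arg(activation)
  hidden_size <- as.integer(hidden_size)
  stopifnot(hidden_size >= 1, max_epochs >= 1, batch_size >= 1,
            learning_rate > 0, patience >= 1, min_delta >= 0)
  structure(list(hidden_size = hidden_size, activation = activation,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, patience = as.integer(patience),
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "train_config")
}

## activation functions: value and derivative, vectorized over matrices.
## For PReLU the slope `alpha` is a learnable scalar per layer.
act_value <- function(name, z, alpha = NULL) {
  switch(name,
    linear  = z,
    relu    = pmax(z, 0),
    elu     = ifelse(z > 0, z, exp(pmin(z, 0)) - 1),
    prelu   = ifelse(z > 0, z, alpha * z),
    sigmoid = 1 / (1 + exp(-z)),
    tanh    = tanh(z),
    stopf("unknown activation '%s'", name))
}

act_deriv <- function(name, z, alpha = NULL) {
  switch(name,
    linear  = array(1, dim = dim(z) %||% length(z)),
    relu    = (z > 0) * 1,
    elu     = ifelse(z > 0, 1, exp(pmin(z, 0))),
    prelu   = ifelse(z > 0, 1, alpha),
    sigmoid = { s <- 1 / (1 + exp(-z)); s * (1 - s) },
    tanh    = 1 - tanh(z)^2)
}

## He-style Gaussian draw: sd = sqrt(2 / fan_in of the receiving layer).
## Consumes the current RNG stream; callers control seeding.
init_params <- function(n_genes, hidden_size, activation) {
  sd_enc <- sqrt(2 / n_genes)
  sd_dec <- sqrt(2 / hidden_size)
  model <- list(
    W_enc = matrix(rnorm(hidden_size * n_genes, 0, sd_enc), hidden_size, n_genes),
    b_enc = rnorm(hidden_size, 0, sd_enc),
    W_dec = matrix(rnorm(n_genes * hidden_size, 0, sd_dec), n_genes, hidden_size),
    b_dec = rnorm(n_genes, 0, sd_dec),
    activation = activation,
    alpha = if (activation == "prelu") c(hidden = 0.25, output = 0.25) else NULL,
    gene_ids = NULL
  )
  class(model) <- "autoencoder_model"
  model
}

#' Initialize an autoencoder model
#'
#' Draws every weight and bias i.i.d. from a zero-mean Gaussian with variance
#' 2 / fan-in of the receiving layer (He initialization): variance
#' `2/n_genes` for the encoder, `2/hidden_size` for the decoder. The input
#' and output layers both have `n_genes` nodes.
#'
#' @param n_genes number of input (= output) nodes.
#' @param cfg a [train_config()]; its `seed` makes the draw reproducible.
#' @param gene_ids optional gene identifiers attached to the model.
#' @return an `autoencoder_model`: encoder weights `W_enc` (hidden x input),
#'   encoder biases `b_enc`, decoder weights `W_dec` (output x hidden),
#'   decoder biases `b_dec`, the activation name, and for PReLU the per-layer
#'   slopes `alpha`.
#' @export
initialize_model <- function(n_genes, cfg, gene_ids = NULL) {
  stopifnot(n_genes >= 1)
  model <- with_seed(cfg$seed,
                     init_params(n_genes, cfg$hidden_size, cfg$activation))
  if (!is.null(gene_ids)) {
    stopifnot(length(gene_ids) == n_genes)
    model$gene_ids <- as.character(gene_ids)
  }
  model
}

#' @export
print.autoencoder_model <- function(x, ...) {
  cat(sprintf("autoencoder_model: %d genes, %d hidden nodes, %s activation\n",
              ncol(x$W_enc), nrow(x$W_enc), x$activation))
  invisible(x)
}

check_model_dims <- function(model, x) {
  n_in <- ncol(model$W_enc)
  x <- as.matrix(x)
  if (nrow(x) != n_in) {
    stopf("input has %d genes but model expects %d", nrow(x), n_in)
  }
  x
}

#' Feedforward pass
#'
#' Propagates one or more samples through the network. Each node's
#' pre-activation is the weighted sum of the previous layer's activations
#' plus a bias; the configured activation function is applied elementwise
#' (identity for `linear`).
#'
#' @param model an `autoencoder_model`.
#' @param x numeric vector of length `n_genes`, or a genes-x-samples matrix.
#' @return list with elements `hidden` and `output` (matrices with one column
#'   per sample; vectors in, vectors out is preserved via drop = FALSE
#'   columns).
#' @export
forward <- function(model, x) {
  x <- check_model_dims(model, x)
  a_h <- model$alpha[["hidden"]] %||% NULL
  a_o <- model$alpha[["output"]] %||% NULL
  z1 <- model$W_enc %*% x + model$b_enc
  h <- act_value(model$activation, z1, a_h)
  z2 <- model$W_dec %*% h + model$b_dec
  out <- act_value(model$activation, z2, a_o)
  list(hidden = h, output = out)
}

#' Mean-squared-error reconstruction loss
#'
#' The training objective: squared reconstruction residuals are summed over
#' genes and averaged over samples,
#' \deqn{MSE = (1/K) \sum_k \sum_i (a_{i,k} - g_{i,k})^2.}
#' Note the asymmetry — mean over the K samples, sum over the I genes — which
#' is honored exactly throughout the package.
#'
#' @param outputs reconstructed genes-x-samples matrix (or vector).
#' @param targets target matrix of identical shape.
#' @return nonnegative scalar.
#' @export
mse_loss <- function(outputs, targets) {
  outputs <- as.matrix(outputs); targets <- as.matrix(targets)
  if (!identical(dim(outputs), dim(targets))) {
    stopf("output and target shapes differ: %s vs %s",
          paste(dim(outputs), collapse = "x"), paste(dim(targets), collapse = "x"))
  }
  sum((outputs - targets)^2) / ncol(targets)
}

#' Analytic loss gradients
#'
#' Backpropagated gradients of [mse_loss()] (reconstruction of `x` against
#' itself) with respect to every parameter, on a batch. Exposed so gradient
#' correctness can be verified against finite differences.
#'
#' @param model an `autoencoder_model`.
#' @param x genes-x-samples batch; each column is both input and target.
#' @return list with `loss` and gradients `W_enc`, `b_enc`, `W_dec`, `b_dec`,
#'   and for PReLU `alpha` (named vector hidden/output).
#' @export
autoencoder_gradients <- function(model, x) {
  x <- check_model_dims(model, x)
  k <- ncol(x)
  act <- model$activation
  a_h <- model$alpha[["hidden"]] %||% NULL
  a_o <- model$alpha[["output"]] %||% NULL

  z1 <- model$W_enc %*% x + model$b_enc
  h <- act_value(act, z1, a_h)
  z2 <- model$W_dec %*% h + model$b_dec
  out <- act_value(act, z2, a_o)

  resid <- out - x
  loss <- sum(resid^2) / k

  d_out <- (2 / k) * resid
  d_z2 <- d_out * act_deriv(act, z2, a_o)
  g_W_dec <- d_z2 %*% t(h)
  g_b_dec <- rowSums(d_z2)
  d_h <- t(model$W_dec) %*% d_z2
  d_z1 <- d_h * act_deriv(act, z1, a_h)
  g_W_enc <- d_z1 %*% t(x)
  g_b_enc <- rowSums(d_z1)

  grads <- list(loss = loss, W_enc = g_W_enc, b_enc = g_b_enc,
                W_dec = g_W_dec, b_dec = g_b_dec)
  if (act == "prelu") {
    grads$alpha <- c(hidden = sum(d_h * z1 * (z1 < 0)),
                     output = sum(d_out * z2 * (z2 < 0)))
  }
  grads
}

adam_state <- function(param) {
  lapply(param, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(value, grad, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  m_hat <- state$m / (1 - beta1^t)
  v_hat <- state$v / (1 - beta2^t)
  list(value = value - lr * m_hat / (sqrt(v_hat) + eps), state = state)
}

#' Train an autoencoder
#'
#' Minimizes the reconstruction loss by minibatch Adam. Samples (the matrix
#' columns) are shuffled every epoch with the run seed; after each epoch the
#' full-data loss is recorded in the trajectory. Training stops when the best
#' loss has not improved by at least `min_delta` for `patience` consecutive
#' epochs, or at `max_epochs`.
#'
#' When `checkpoint_epochs` is supplied, early stopping is disabled and a
#' snapshot of the model is stored at each listed epoch (training runs to the
#' largest checkpoint, capped at `max_epochs`) — the mechanism behind
#' misclassification curves at selected epochs.
#'
#' @param data an [expression_matrix()] (or plain genes-x-samples matrix);
#'   every column is a training vector and its own target.
#' @param cfg a [train_config()].
#' @param checkpoint_epochs optional increasing integer vector of epochs at
#'   which to snapshot the model.
#' @return list of class `trained_autoencoder`: `model` (final), `loss`
#'   (per-epoch trajectory), `checkpoints` (named list of snapshots, if
#'   requested), `cfg`, `epochs_run`, and `stopped_early`.
#' @export
train_autoencoder <- function(data, cfg, checkpoint_epochs = NULL) {
  x_all <- as.matrix(unclass(data))
  if (ncol(x_all) < 2) stopf("training needs >=2 samples")
  n_genes <- nrow(x_all)
  k <- ncol(x_all)
  batch_size <- min(cfg$batch_size, k)

  if (!is.null(checkpoint_epochs)) {
    checkpoint_epochs <- sort(unique(as.integer(checkpoint_epochs)))
    stopifnot(all(checkpoint_epochs >= 1))
    checkpoint_epochs <- pmin(checkpoint_epochs, cfg$max_epochs)
    checkpoint_epochs <- sort(unique(checkpoint_epochs))
    n_epochs <- max(checkpoint_epochs)
    use_early_stop <- FALSE
  } else {
    n_epochs <- cfg$max_epochs
    use_early_stop <- TRUE
  }

  with_seed(cfg$seed, {
    model <- init_params(n_genes, cfg$hidden_size, cfg$activation)
    if (!is.null(rownames(x_all))) model$gene_ids <- rownames(x_all)

    params <- c("W_enc", "b_enc", "W_dec", "b_dec",
                if (cfg$activation == "prelu") "alpha")
    opt <- adam_state(model[params])
    t_step <- 0L
    loss_trace <- numeric(0)
    checkpoints <- list()
    best <- Inf
    stall <- 0L
    stopped_early <- FALSE
    epoch <- 0L

    while (epoch < n_epochs) {
      epoch <- epoch + 1L
      order_idx <- sample.int(k)
      starts <- seq(1, k, by = batch_size)
      for (s in starts) {
        idx <- order_idx[s:min(s + batch_size - 1, k)]
        g <- autoencoder_gradients(model, x_all[, idx, drop = FALSE])
        if (!is.finite(g$loss)) {
          stopf("non-finite training loss at epoch %d; reduce the learning rate",
                epoch)
        }
        t_step <- t_step + 1L
        for (p in params) {
          upd <- adam_step(model[[p]], g[[p]], opt[[p]], cfg$learning_rate, t_step)
          model[[p]] <- upd$value
          opt[[p]] <- upd$state
        }
      }
      epoch_loss <- mse_loss(forward(model, x_all)$output, x_all)
      if (!is.finite(epoch_loss)) {
        stopf("non-finite training loss at epoch %d; reduce the learning rate",
              epoch)
      }
      loss_trace[epoch] <- epoch_loss
      if (!is.null(checkpoint_epochs) && epoch %in% checkpoint_epochs) {
        checkpoints[[as.character(epoch)]] <- model
      }
      if (use_early_stop) {
        if (best - epoch_loss >= cfg$min_delta) {
          best <- epoch_loss
          stall <- 0L
        } else {
          best <- min(best, epoch_loss)
          stall <- stall + 1L
          if (stall >= cfg$patience) {
            stopped_early <- TRUE
            break
          }
        }
      }
    }

    structure(list(model = model, loss = loss_trace,
                   checkpoints = if (length(checkpoints)) checkpoints else NULL,
                   cfg = cfg, epochs_run = epoch,
                   stopped_early = stopped_early),
              class = "trained_autoencoder")
  })
}

#' @export
print.trained_autoencoder <- function(x, ...) {
  cat(sprintf(
    "trained_autoencoder: %d epochs, final loss %.6g%s\n",
    x$epochs_run, tail(x$loss, 1),
    if (x$stopped_early) " (early stop)" else ""))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file binary (RDS) holding weights, biases,
#' activation and config, with a JSON sidecar (`<path>.json`) of run
#' metadata for inspection without R.
#'
#' @param fit a `trained_autoencoder` (or bare `autoencoder_model`).
#' @param path checkpoint file path.
#' @return `path`, invisibly; `load_model()` returns the saved object.
#' @export
save_model <- function(fit, path) {
  saveRDS(fit, path)
  meta <- if (inherits(fit, "trained_autoencoder")) {
    list(type = "trained_autoencoder",
         activation = fit$model$activation,
         n_genes = ncol(fit$model$W_enc),
         hidden_size = nrow(fit$model$W_enc),
         epochs_run = fit$epochs_run,
         final_loss = unname(tail(fit$loss, 1)),
         stopped_early = fit$stopped_early,
         config = unclass(fit$cfg))
  } else {
    list(type = "autoencoder_model", activation = fit$activation,
         n_genes = ncol(fit$W_enc), hidden_size = nrow(fit$W_enc))
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
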