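test_that("initialization is Gaussian with He variance 2/fan_in and reproducible", {
  cfg <- train_config(hidden_size = 2000, seed = 123)
  m1 <- initialize_model(50, cfg)
  m2 <- initialize_model(50, cfg)
  expect_identical(m1$W_enc, m2$W_enc)
  expect_identical(m1$b_dec, m2$b_dec)

  draws <- as.numeric(m1$W_enc)  # 1e5 draws at fan-in 50
  expect_gte(length(draws), 1e5)
  expect_lt(abs(var(draws) - 2 / 50) / (2 / 50), 0.05)
  expect_lt(abs(mean(draws)), 3 * sqrt(2 / 50) / sqrt(length(draws)))
  # decoder fan-in is the hidden size
  expect_lt(abs(var(as.numeric(m1$W_dec)) - 2 / 2000) / (2 / 2000), 0.05)
})

test_that("the feedforward pass evaluates the affine map plus activation", {
  cfg <- train_config(2, activation = "linear", seed = 1)
  m <- initialize_model(2, cfg)
  m$W_enc <- diag(2); m$W_dec <- diag(2)
  m$b_enc <- c(0, 0); m$b_dec <- c(0, 0)
  x <- c(0.3, -1.2)
  expect_equal(as.numeric(forward(m, x)$output), x)

  # zero weights: output is f(b_dec)
  ms <- initialize_model(2, train_config(2, activation = "sigmoid", seed = 1))
  ms$W_enc[] <- 0; ms$W_dec[] <- 0; ms$b_enc <- c(0, 0); ms$b_dec <- c(1, -1)
  expect_equal(as.numeric(forward(ms, x)$output), 1 / (1 + exp(-c(1, -1))))

  # 2-gene, 1-hidden, hand-evaluated
  mh <- initialize_model(2, train_config(1, activation = "linear", seed = 1))
  mh$W_enc <- matrix(c(1, 2), 1, 2); mh$b_enc <- 0.5
  mh$W_dec <- matrix(c(1, -1), 2, 1); mh$b_dec <- c(0, 0)
  fw <- forward(mh, c(1, 1))
  expect_equal(as.numeric(fw$hidden), 3.5)
  expect_equal(as.numeric(fw$output), c(3.5, -3.5))

  expect_error(forward(mh, c(1, 2, 3)), "genes")
})

test_that("the loss averages over samples but sums over genes", {
  expect_equal(mse_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(mse_loss(matrix(c(1, 2), 2, 1), matrix(0, 2, 1)), 5)
  expect_equal(mse_loss(matrix(1, 3, 2), matrix(0, 3, 2)), 3)
  expect_error(mse_loss(matrix(1, 2, 2), matrix(1, 2, 3)), "shape")
})

test_that("analytic gradients match central finite differences for every activation", {
  flatten <- function(m) c(m$W_enc, m$b_enc, m$W_dec, m$b_dec, m$alpha)
  unflatten <- function(m, v) {
    i <- 0
    for (p in c("W_enc", "b_enc", "W_dec", "b_dec", "alpha")) {
      if (is.null(m[[p]])) next
      n <- length(m[[p]]); m[[p]][] <- v[i + seq_len(n)]; i <- i + n
    }
    m
  }
  set.seed(21)
  x <- matrix(rnorm(4 * 3), 4, 3)
  for (act in c("linear", "elu", "relu", "prelu", "sigmoid", "tanh")) {
    m <- initialize_model(4, train_config(2, activation = act, seed = 11))
    g <- autoencoder_gradients(m, x)
    ga <- c(g$W_enc, g$b_enc, g$W_dec, g$b_dec, g$alpha)
    v0 <- flatten(m)
    eps <- 1e-6
    gn <- vapply(seq_along(v0), function(i) {
      vp <- v0; vp[i] <- vp[i] + eps
      vm <- v0; vm[i] <- vm[i] - eps
      (autoencoder_gradients(unflatten(m, vp), x)$loss -
         autoencoder_gradients(unflatten(m, vm), x)$loss) / (2 * eps)
    }, numeric(1))
    rel <- abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-8)
    expect_lt(max(rel), 1e-5, label = sprintf("%s max rel gradient error", act))
  }
})

test_that("training drives rank-1 data to near-zero loss", {
  set.seed(4)
  loading <- rnorm(6)
  x <- loading %*% t(rnorm(40))
  rownames(x) <- sprintf("g%d", 1:6); colnames(x) <- sprintf("s%d", 1:40)
  cfg <- train_config(1, activation = "linear", max_epochs = 2000,
                      batch_size = 40, learning_rate = 1e-2, seed = 9)
  fit <- train_autoencoder(x, cfg)
  init <- initialize_model(6, cfg, gene_ids = rownames(x))
  loss0 <- mse_loss(forward(init, x)$output, x)
  expect_lt(tail(fit$loss, 1), 1e-3 * loss0)
})

test_that("training bookkeeping: trajectory length, running minimum, determinism", {
  set.seed(5)
  x <- matrix(rnorm(5 * 12), 5, 12)
  cfg1 <- train_config(2, max_epochs = 1, seed = 3)
  expect_length(train_autoencoder(x, cfg1)$loss, 1)

  cfg <- train_config(2, max_epochs = 60, seed = 3)
  fit <- train_autoencoder(x, cfg)
  expect_true(all(diff(cummin(fit$loss)) <= 0))

  fit2 <- train_autoencoder(x, cfg)
  expect_identical(fit$model$W_enc, fit2$model$W_enc)
  expect_identical(fit$model$W_dec, fit2$model$W_dec)
  expect_identical(fit$loss, fit2$loss)
})

test_that("early stopping halts once the loss plateaus", {
  set.seed(6)
  x <- rnorm(4) %*% t(rnorm(30))  # rank 1: converges fast
  cfg <- train_config(2, activation = "linear", max_epochs = 10000,
                      batch_size = 30, learning_rate = 1e-2,
                      patience = 25, min_delta = 1e-6, seed = 2)
  fit <- train_autoencoder(x, cfg)
  expect_true(fit$stopped_early)
  expect_lt(fit$epochs_run, 10000)
})

test_that("checkpoint snapshots are taken at the requested epochs", {
  set.seed(7)
  x <- matrix(rnorm(4 * 10), 4, 10)
  cfg <- train_config(2, max_epochs = 50, seed = 8)
  fit <- train_autoencoder(x, cfg, checkpoint_epochs = c(5, 20, 50))
  expect_named(fit$checkpoints, c("5", "20", "50"))
  # a snapshot equals retraining to exactly that many epochs
  cfg5 <- train_config(2, max_epochs = 5, seed = 8)
  fit5 <- train_autoencoder(x, cfg5)
  expect_equal(fit$checkpoints[["5"]]$W_enc, fit5$model$W_enc, tolerance = 1e-12)
})

test_that("model checkpoints survive a save/load round trip", {
  set.seed(8)
  x <- matrix(rnorm(4 * 10), 4, 10,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:10)))
  fit <- train_autoencoder(x, train_config(2, max_epochs = 10, seed = 1))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(back$model$W_enc, fit$model$W_enc)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$hidden_size, 2)
})
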