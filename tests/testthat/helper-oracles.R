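# Independent oracles used across the suite. These deliberately avoid the
# package's fast implementations: the score oracle enumerates every
# input -> hidden -> output path, the ES oracle rebuilds the full running-sum
# vector step by step.

# Association score by explicit path enumeration: for each (output o,
# input i), sum over hidden nodes h of W_dec[o, h] * W_enc[h, i].
path_enumeration_scores <- function(model) {
  n_in <- ncol(model$W_enc)
  n_hid <- nrow(model$W_enc)
  s <- matrix(0, n_in, n_in)
  for (o in seq_len(n_in)) {
    for (i in seq_len(n_in)) {
      acc <- 0
      for (h in seq_len(n_hid)) {
        acc <- acc + model$W_dec[o, h] * model$W_enc[h, i]
      }
      s[o, i] <- acc
    }
  }
  s
}

# Weighted KS enrichment score by naive full-vector recomputation.
brute_force_es <- function(metrics, hit, p = 1) {
  n <- length(metrics)
  n_hit <- sum(hit)
  n_r <- sum(abs(metrics[hit])^p)
  running <- numeric(n)
  acc <- 0
  for (pos in seq_len(n)) {
    if (hit[pos]) {
      acc <- acc + if (n_r > 0) abs(metrics[pos])^p / n_r else 1 / n_hit
    } else {
      acc <- acc - 1 / (n - n_hit)
    }
    running[pos] <- acc
  }
  # same documented tie rule as the implementation: positive extremum wins
  if (max(running) >= -min(running)) max(running) else min(running)
}

random_small_model <- function(n_genes, n_hidden, seed) {
  set.seed(seed)
  m <- initialize_model(n_genes, train_config(n_hidden, seed = seed),
                        gene_ids = sprintf("g%02d", seq_len(n_genes)))
  m
}

# Reference two-class cohort used by several tests: disjoint factor blocks
# per class so the classes are separable and the planted pairs are known.
small_cohort_spec <- function(n_per_class = 120, seed = 5) {
  synthetic_spec(
    n_genes = 20, n_samples_per_class = n_per_class, noise_sd = 0.1,
    factors_per_class = list(
      pCR = list(list(genes = 1:4, signs = c(1, 1, -1, -1), magnitude = 1)),
      RD = list(list(genes = 5:8, signs = c(1, 1, 1, 1), magnitude = 1))),
    seed = seed)
}
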