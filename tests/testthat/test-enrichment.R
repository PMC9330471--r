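test_that("GMT files parse, deduplicate and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tA\tB", "SET2\tdesc2\tc\td\te"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("SET1", "SET2"))
  expect_setequal(sets$SET1, c("A", "B"))
  expect_setequal(sets$SET2, c("C", "D", "E"))  # uppercased

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines("S\td\tA\tB\tA", dup)
  expect_warning(sd <- read_gmt(dup), "duplicate")
  expect_setequal(sd$S, c("A", "B"))

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GOOD\td\tA", "ONLYNAME"), bad)
  expect_error(read_gmt(bad), "line 2")

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_equal(lapply(read_gmt(out), sort), lapply(sets, sort),
               ignore_attr = TRUE)
})

test_that("per-node gene ranking is by signed weight with id tie-breaks", {
  m <- random_small_model(3, 2, seed = 61)
  m$gene_ids <- c("g1", "g2", "g3")
  m$W_enc[1, ] <- c(0.5, -0.2, 0.9)
  ranked <- rank_genes_for_node(m, 1)
  expect_equal(names(ranked), c("g3", "g1", "g2"))
  expect_equal(unname(ranked), c(0.9, 0.5, -0.2))
  expect_length(ranked, 3)

  m$W_enc[2, ] <- c(0.4, 0.4, 0.4)
  expect_equal(names(rank_genes_for_node(m, 2)), c("g1", "g2", "g3"))

  expect_equal(names(rank_genes_for_node(m, 1, absolute = TRUE))[1], "g3")
  expect_error(rank_genes_for_node(m, 5), "out of range")
})

test_that("the running sum reproduces hand-worked enrichment scores", {
  ranked <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  # hits at ranks 1 and 4: N_R = 7, peak after the first hit
  es <- enrichment_score(ranked, c("g1", "g4"), p = 1)
  expect_equal(es$es, 5 / 7, tolerance = 1e-12)
  expect_equal(es$running[5], 0, tolerance = 1e-12)

  # singleton at rank 1 achieves the maximal score of 1
  expect_equal(enrichment_score(ranked, "g1")$es, 1)

  # singleton at the bottom: maximal deviation is negative
  expect_lt(enrichment_score(ranked, "g5")$es, 0)

  expect_error(enrichment_score(ranked, "absent"), "intersect")
  expect_error(enrichment_score(ranked, paste0("g", 1:5)), "covers")
})

test_that("ES obeys its invariants on random instances", {
  set.seed(62)
  for (i in 1:300) {
    n <- sample(5:20, 1)
    metrics <- sort(rnorm(n), decreasing = TRUE)
    genes <- paste0("g", seq_len(n))
    sz <- sample(seq_len(n - 1), 1)
    hitset <- sample(genes, sz)
    es <- enrichment_score(setNames(metrics, genes), hitset, p = 1)
    expect_lte(abs(es$es), 1)
    expect_equal(es$running[n], 0, tolerance = 1e-9)
    # streaming result equals naive full-vector recomputation
    bf <- brute_force_es(metrics, genes %in% hitset)
    expect_equal(abs(es$es), abs(bf), tolerance = 1e-12)
    if (abs(max(es$running) + min(es$running)) > 1e-9) {
      expect_equal(es$es, bf, tolerance = 1e-12)
    }
    # scale invariance at p = 1 (sign can only differ at an exact tie
    # between the positive and negative extremum)
    es2 <- enrichment_score(setNames(metrics * 7.3, genes), hitset, p = 1)
    expect_equal(abs(es2$es), abs(es$es), tolerance = 1e-9)
    if (abs(max(es$running) + min(es$running)) > 1e-9) {
      expect_equal(es2$es, es$es, tolerance = 1e-9)
    }
  }
})

test_that("ES agrees with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(63)
  metrics <- sort(rexp(40) + 0.05, decreasing = TRUE)
  names(metrics) <- paste0("G", 1:40)
  sets <- list(S1 = paste0("G", c(1, 3, 8, 12, 30)),
               S2 = paste0("G", c(35, 37, 39, 40)))
  ref <- suppressWarnings(
    fgsea::fgseaSimple(sets, metrics, nperm = 10, gseaParam = 1))
  for (nm in names(sets)) {
    expect_equal(enrichment_score(metrics, sets[[nm]])$es,
                 ref$ES[ref$pathway == nm], tolerance = 1e-10)
  }
})

test_that("permutation statistics are internally consistent and seeded", {
  set.seed(64)
  metrics <- sort(rnorm(60), decreasing = TRUE)
  names(metrics) <- paste0("G", 1:60)
  sets <- list(TOP = names(metrics)[c(1:6, 9, 11)],
               RAND = sample(names(metrics), 8))
  tab <- permutation_stats(metrics, sets, n_perm = 200, seed = 9,
                           min_size = 3, max_size = 50, keep_null = TRUE)
  expect_equal(nrow(tab), 2)
  nulls <- attr(tab, "null_es")
  for (r in seq_len(nrow(tab))) {
    row <- tab[r, ]
    same <- nulls[row$set, ]
    same <- if (row$es >= 0) same[same >= 0] else same[same < 0]
    # NES normalization and smoothed tail p recomputed from the exposed null
    expect_equal(row$nes, row$es / mean(abs(same)), tolerance = 1e-12)
    expect_equal(row$p_value,
                 (sum(abs(same) >= abs(row$es)) + 1) / (length(same) + 1),
                 tolerance = 1e-12)
    expect_equal(sign(row$nes), sign(row$es))
    expect_true(row$fdr_q >= 0 && row$fdr_q <= 1)
  }
  tab2 <- permutation_stats(metrics, sets, n_perm = 200, seed = 9,
                            min_size = 3, max_size = 50)
  expect_equal(tab$es, tab2$es)
  expect_equal(tab$fdr_q, tab2$fdr_q)
})

test_that("a planted top-ranked set reaches small q at 1000 permutations", {
  set.seed(65)
  metrics <- sort(c(rexp(15) + 2, rnorm(85, 0, 0.3)), decreasing = TRUE)
  names(metrics) <- paste0("G", seq_len(100))
  sets <- list(PLANTED = names(metrics)[1:15],
               NULL1 = sample(names(metrics), 20),
               NULL2 = sample(names(metrics), 25))
  tab <- permutation_stats(metrics, sets, n_perm = 1000, seed = 3)
  planted <- tab[tab$set == "PLANTED", ]
  expect_gt(planted$es, 0)
  expect_lt(planted$fdr_q, 0.05)
  expect_lt(planted$p_value, 0.05)
})

test_that("hidden-node enrichment tables cover nodes x filtered sets", {
  set.seed(66)
  m <- random_small_model(30, 3, seed = 67)
  m$gene_ids <- sprintf("G%02d", 1:30)
  sets <- list(A = sprintf("G%02d", 1:6), B = sprintf("G%02d", 25:30),
               TINY = "G01")
  tab <- gsea_hidden_nodes(m, sets, n_perm = 50, seed = 1,
                           min_size = 3, max_size = 20)
  expect_equal(sort(unique(tab$node)), 1:3)
  expect_setequal(unique(tab$set), c("A", "B"))  # TINY filtered out
  expect_equal(nrow(tab), 6)

  nm <- nes_matrix(tab)
  expect_equal(dim(nm), c(2, 3))

  filt <- significant_enrichment(tab, nes_threshold = 0, fdr_threshold = 1.1)
  expect_equal(nrow(filt), nrow(tab[tab$nes_defined, ]))
})
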