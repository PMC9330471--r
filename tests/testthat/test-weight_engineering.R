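test_that("association scores equal the hand-worked matrix product", {
  m <- random_small_model(2, 2, seed = 1)
  m$W_enc <- matrix(c(1, 0, 2, 1), 2, 2)  # [[1,2],[0,1]]
  m$W_dec <- matrix(c(1, 1, 0, 1), 2, 2)  # [[1,0],[1,1]]
  s <- association_scores(m)
  expect_equal(unname(unclass(s)), matrix(c(1, 1, 2, 3), 2, 2))

  # identity weights decode to the identity
  mi <- random_small_model(3, 3, seed = 2)
  mi$W_enc <- diag(3); mi$W_dec <- diag(3)
  expect_equal(unname(unclass(association_scores(mi))), diag(3))

  # zero encoder kills every score
  mz <- random_small_model(3, 2, seed = 3)
  mz$W_enc[] <- 0
  expect_true(all(association_scores(mz) == 0))
})

test_that("matrix-product scores agree with explicit path enumeration", {
  for (i in 1:25) {
    n_g <- sample(2:10, 1)
    n_h <- sample(1:5, 1)
    m <- random_small_model(n_g, n_h, seed = 1000 + i)
    expect_lt(max(abs(unclass(association_scores(m)) -
                        path_enumeration_scores(m))), 1e-10)
  }
})

test_that("scores act as the end-to-end Jacobian of a linear model", {
  m <- random_small_model(6, 3, seed = 17)  # linear activation
  s <- unclass(association_scores(m))
  set.seed(18)
  x <- rnorm(6)
  base <- forward(m, x)$output
  delta <- 1e-6
  for (i in 1:6) {
    xp <- x; xp[i] <- xp[i] + delta
    fd <- (forward(m, xp)$output - base) / delta
    expect_equal(as.numeric(fd), unname(s[, i]), tolerance = 1e-6)
  }
})

test_that("top-pair selection ranks by absolute score and excludes the diagonal", {
  s <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  s[1, 2] <- -9; s[2, 1] <- 5; s[3, 1] <- 4; s[1, 3] <- -3; s[2, 3] <- 2
  s[3, 2] <- 1
  diag(s) <- c(100, -100, 50)  # never selectable
  class(s) <- c("association_matrix", class(s))
  top2 <- select_top_pairs(s, 2)
  expect_equal(abs(top2$score), c(9, 5))
  expect_equal(top2$source, c("b", "a"))  # S[o,i]: column is the source
  expect_equal(top2$target, c("a", "b"))
  expect_equal(top2$score[1], -9)

  all_pairs <- select_top_pairs(s, 6)
  expect_equal(nrow(all_pairs), 6)
  expect_true(all(all_pairs$source != all_pairs$target))
  expect_error(select_top_pairs(s, 7), "exceeds")
})

test_that("tied scores break deterministically by source then target id", {
  s <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  class(s) <- c("association_matrix", class(s))
  top <- select_top_pairs(s, 3)
  expect_equal(top$source, c("a", "a", "b"))
  expect_equal(top$target, c("b", "c", "a"))
  expect_identical(top, select_top_pairs(s, 3))
})

test_that("networks carry signed directed edges with mutual flags", {
  pairs <- data.frame(source = c("a", "b", "c"), target = c("b", "a", "a"),
                      score = c(2, -1, 0.5))
  net <- build_network(pairs)
  expect_equal(nrow(net$edges), 3)
  expect_equal(net$edges$sign, c(1L, -1L, 1L))
  expect_equal(net$edges$mutual, c(TRUE, TRUE, FALSE))
  expect_equal(sum(net$edges$source == "b" | net$edges$target == "b"), 2)

  # edge signs always follow the score matrix on random models
  m <- random_small_model(6, 3, seed = 23)
  s <- association_scores(m)
  top <- select_top_pairs(s, 10)
  net2 <- build_network(top)
  for (r in seq_len(nrow(net2$edges))) {
    e <- net2$edges[r, ]
    expect_equal(e$sign, unname(sign(unclass(s)[e$target, e$source])))
  }
})

test_that("hubs and modules follow degree and connectivity", {
  star <- data.frame(source = "c", target = paste0("leaf", 1:5),
                     score = rep(1, 5))
  net <- assign_modules(build_network(star), hub_min_degree = 2)
  expect_equal(net$hubs, "c")
  expect_length(net$modules, 1)
  expect_equal(names(net$modules), "c")

  tri2 <- data.frame(
    source = c("a", "b", "c", "x", "y", "z"),
    target = c("b", "c", "a", "y", "z", "x"),
    score = rep(c(1, -1), 3))
  net2 <- assign_modules(build_network(tri2), hub_min_degree = 2)
  expect_length(net2$modules, 2)
  expect_setequal(unlist(net2$modules), c("a", "b", "c", "x", "y", "z"))
  expect_setequal(net2$hubs, c("a", "b", "c", "x", "y", "z"))
})

test_that("decoded modules recover the planted factor blocks", {
  spec <- small_cohort_spec(n_per_class = 150, seed = 31)
  co <- generate_cohort(spec)
  parts <- split_cohort(co$expression, co$labels, "chemosensitivity")
  cfg <- train_config(1, activation = "linear", max_epochs = 3000,
                      batch_size = 150, learning_rate = 1e-2, seed = 41)
  fit <- train_autoencoder(parts$pCR, cfg)
  s <- association_scores(fit)
  net <- assign_modules(build_network(select_top_pairs(s, 12)))
  block <- sprintf("G%03d", 1:4)  # the pCR factor block
  jacc <- vapply(net$modules, function(genes) {
    length(intersect(genes, block)) / length(union(genes, block))
  }, numeric(1))
  expect_gte(max(jacc), 0.9)
})

test_that("association matrices and networks round-trip to disk", {
  m <- random_small_model(5, 2, seed = 51)
  s <- association_scores(m)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_association_matrix(s, tsv)
  back <- read_association_matrix(tsv)
  expect_equal(unclass(back), unclass(s), tolerance = 0)

  net <- assign_modules(build_network(select_top_pairs(s, 6)))
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, sif, gml)
  sif_lines <- readLines(sif)
  expect_length(sif_lines, 6)
  expect_true(all(grepl("\t(pos|neg)\t", sif_lines)))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 6)
  expect_equal(sort(igraph::E(g)$score), sort(net$edges$score),
               tolerance = 1e-6)
})

test_that("local term annotation joins onto network genes", {
  pairs <- data.frame(source = c("a", "b"), target = c("b", "c"),
                      score = c(1, -2))
  net <- build_network(pairs)
  terms <- data.frame(gene = c("a", "a", "c", "zzz"),
                      term = c("immune", "ecm", "immune", "ignored"))
  net <- annotate_terms(net, terms)
  expect_setequal(net$terms$a, c("immune", "ecm"))
  expect_false("zzz" %in% names(net$terms))
})
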