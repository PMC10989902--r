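test_that("perfectly monotone profiles give a rho = 1 edge", {
  n <- 30
  prof <- seq_len(n)
  m <- toy_counts(cbind(b1 = prof, b2 = prof * 2L,
                        b3 = rep(5L, n)))
  colnames(m) <- c("b1", "b2", "b3")
  bac <- count_table(m, "bacteria")
  f <- toy_counts(matrix(rep(3L, n), n, 1)); colnames(f) <- "f1"
  fun <- count_table(f, "fungi")
  net <- build_cooccurrence(bac, fun)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(igraph::E(net)$rho, 1, tolerance = 1e-12)
  expect_equal(igraph::E(net)$sign, "pos")
  # isolated nodes (constant columns) are absent
  expect_false("b3" %in% igraph::V(net)$name)
})

test_that("edges respect the rho threshold regardless of p", {
  # construct a pair with |rho| ~ 0.55 over many samples: significant but
  # below the correlation threshold
  withr::with_seed(4, {
    n <- 200
    z <- rnorm(n)
    a <- rank(0.55 * z + sqrt(1 - 0.55^2) * rnorm(n))
    b <- rank(z)
  })
  rho <- cor(a, b, method = "spearman")
  expect_true(abs(rho) > 0.3 && abs(rho) < 0.6)
  # the correlation is overwhelmingly significant at this sample size
  expect_lt(2 * pt(-abs(rho) * sqrt((n - 2) / (1 - rho^2)), n - 2), 1e-6)
  m <- toy_counts(cbind(x = as.integer(a), y = as.integer(b)))
  bac <- count_table(m, "bacteria")
  f <- toy_counts(matrix(rep(2L, n), n, 1)); colnames(f) <- "f1"
  fun <- count_table(f, "fungi")
  net <- build_cooccurrence(bac, fun, rho_threshold = 0.6)
  expect_equal(igraph::ecount(net), 0)
})

test_that("planted correlated pairs are recovered with few false edges", {
  withr::with_seed(42, {
    n <- 100
    lat <- matrix(rnorm(n * 10), n, 10)
    m <- matrix(rpois(n * 100, 5), n, 100)
    for (j in 1:10) {
      m[, 2 * j - 1] <- rpois(n, exp(2 + lat[, j]))
      m[, 2 * j] <- rpois(n, exp(2 + lat[, j]))
    }
    dimnames(m) <- list(sprintf("s%03d", 1:n), sprintf("T%03d", 1:100))
  })
  bac <- count_table(m[, 1:60], "bacteria")
  fun <- count_table(m[, 61:100], "fungi")
  net <- build_cooccurrence(bac, fun)
  el <- igraph::ends(net, igraph::E(net))
  planted <- sum(apply(el, 1, function(e) {
    i <- as.integer(substr(e[1], 2, 4)); j <- as.integer(substr(e[2], 2, 4))
    ceiling(i / 2) == ceiling(j / 2) && i <= 20 && j <= 20
  }))
  expect_gte(planted, 8)
  expect_lte(igraph::ecount(net) - planted, 1)
})

test_that("spearman p-values match cor.test's t approximation", {
  withr::with_seed(5, {
    m <- matrix(rpois(20 * 4, 6), 20, 4)
  })
  dimnames(m) <- list(sprintf("s%d", 1:20), sprintf("t%d", 1:4))
  bac <- count_table(m[, 1:2], "bacteria")
  fun <- count_table(m[, 3:4], "fungi")
  net <- build_cooccurrence(bac, fun, rho_threshold = 0, p_threshold = 1)
  el <- igraph::ends(net, igraph::E(net))
  merged <- merge_tables(bac, fun)
  for (k in seq_len(nrow(el))) {
    ct <- suppressWarnings(
      cor.test(merged$counts[, el[k, 1]], merged$counts[, el[k, 2]],
               method = "spearman"))
    expect_equal(igraph::E(net)$rho[k], unname(ct$estimate),
                 tolerance = 1e-10)
  }
})

test_that("edge set is invariant under monotone transforms of abundance", {
  ct <- random_table(20, 15, lambda = 6, seed = 9)
  bac <- count_table(ct$counts[, 1:10], "bacteria")
  fun <- count_table(ct$counts[, 11:15], "fungi")
  n1 <- build_cooccurrence(bac, fun, rho_threshold = 0.3, p_threshold = 0.2)
  sq <- ct$counts^2L
  bac2 <- count_table(sq[, 1:10], "bacteria")
  fun2 <- count_table(sq[, 11:15], "fungi")
  n2 <- build_cooccurrence(bac2, fun2, rho_threshold = 0.3, p_threshold = 0.2)
  key <- function(g) {
    e <- igraph::ends(g, igraph::E(g))
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(key(n1), key(n2))
})

test_that("niche preferences are abundance-weighted site means", {
  m <- toy_counts(matrix(c(1L, 3L, 4L, 4L, 0L, 2L), 2, 3))
  ct <- count_table(m)
  env <- data.frame(sample_id = rownames(m), AI = c(0.4, 0.8))
  pref <- niche_preference(ct, env, "AI")
  expect_equal(pref$AI[1], 0.25 * 0.4 + 0.75 * 0.8, tolerance = 1e-12)
  expect_equal(pref$AI[2], 0.5 * 0.4 + 0.5 * 0.8)   # uniform -> plain mean
  expect_equal(pref$AI[3], 0.8)                     # single site
})

test_that("degree-preference correlation recovers planted sign and rejects degeneracy", {
  # planted design: taxa with high aridity preference get fewer partners
  n_tax <- 30
  pref_true <- seq(0.3, 1, length.out = n_tax)
  ids <- sprintf("t%02d", seq_len(n_tax))
  partners <- pmax(0L, round(8 * (1 - (pref_true - 0.3) / 0.7)))
  edges <- list()
  withr::with_seed(8, {
    for (i in seq_len(n_tax)) {
      if (partners[i] > 0) {
        mates <- sample(setdiff(seq_len(n_tax), i), partners[i])
        for (mt in mates) edges[[length(edges) + 1]] <-
            c(ids[min(i, mt)], ids[max(i, mt)])
      }
    }
  })
  el <- unique(do.call(rbind, edges))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$sign <- "pos"
  igraph::V(g)$kingdom <- "bacteria"
  prefs <- data.frame(taxon = ids, AI = pref_true)
  res <- degree_preference_correlation(g, prefs, "AI")
  expect_lt(res$r, 0)
  expect_lt(res$p, 0.05)
  expect_lt(res$slope, 0)
  # degrees identical to preferences give r = 1
  deg <- igraph::degree(g)
  prefs2 <- data.frame(taxon = names(deg), AI = as.numeric(deg))
  expect_equal(degree_preference_correlation(g, prefs2, "AI")$r, 1,
               tolerance = 1e-12)
  prefs$AI <- 1
  expect_error(degree_preference_correlation(g, prefs, "AI"),
               class = "degenerate_input")
})

test_that("subnetwork features match hand counts and conventions", {
  # triangle: 2 bacteria + 1 fungus, one negative edge
  el <- data.frame(from = c("b1", "b1", "b2"), to = c("b2", "f1", "f1"),
                   rho = c(0.9, 0.8, -0.7), p = 0,
                   sign = c("pos", "pos", "neg"))
  g <- igraph::graph_from_data_frame(el, directed = FALSE)
  igraph::V(g)$kingdom <- c("bacteria", "bacteria", "fungi")
  m <- toy_counts(matrix(c(1L, 1L, 1L, 0L, 1L, 0L), 2, 3, byrow = TRUE))
  colnames(m) <- c("b1", "b2", "f1")
  ct <- count_table(m, kingdom = c(b1 = "bacteria", b2 = "bacteria",
                                   f1 = "fungi"))
  ft <- sample_subnetwork_features(g, ct)
  expect_equal(ft$AD[1], 2)
  expect_equal(ft$Neg[1], 1 / 3, tolerance = 1e-12)
  expect_equal(ft$Int[1], 2 / 3, tolerance = 1e-12)
  expect_false(ft$flagged[1])
  # second sample has a single node, no edges: flagged zeros
  expect_equal(ft$AD[2], 0)
  expect_true(ft$flagged[2])
  # relabelling taxa leaves features unchanged
  g2 <- g; igraph::V(g2)$name <- c("x1", "x2", "x3")
  m2 <- m; colnames(m2) <- c("x1", "x2", "x3")
  ct2 <- count_table(m2, kingdom = c(x1 = "bacteria", x2 = "bacteria",
                                     x3 = "fungi"))
  ft2 <- sample_subnetwork_features(g2, ct2)
  expect_equal(ft2[, -1], ft[, -1])
})

test_that("false-edge rate under independence matches the nominal level", {
  # no planted structure: edge count at p < .001 should be near
  # p_threshold * n_pairs once the rho filter is disabled
  n_rep <- 20; n <- 40; n_tax <- 40
  false_edges <- numeric(n_rep)
  for (s in seq_len(n_rep)) {
    ct <- random_table(n, n_tax, lambda = 8, seed = 200 + s)
    bac <- count_table(ct$counts[, 1:30], "bacteria")
    fun <- count_table(ct$counts[, 31:40], "fungi")
    net <- build_cooccurrence(bac, fun, rho_threshold = 0,
                              p_threshold = 0.01)
    false_edges[s] <- igraph::ecount(net)
  }
  pairs <- choose(n_tax, 2)
  expected <- 0.01 * pairs
  # binomial tolerance around the nominal rate (discrete ranks inflate
  # mildly; allow a factor-2 band)
  expect_gt(mean(false_edges), expected * 0.3)
  expect_lt(mean(false_edges), expected * 2.5)
})

test_that("cooccurrence rejects mismatched or tiny sample sets", {
  a <- random_table(6, 5, seed = 1)
  b <- random_table(6, 5, seed = 2)
  colnames(b$counts) <- paste0("f", 1:ncol(b$counts))
  names(b$kingdom) <- colnames(b$counts)
  b$kingdom[] <- "fungi"
  rownames(b$counts)[1] <- "zz"
  expect_error(build_cooccurrence(a, b), class = "label_mismatch")
  small_a <- count_table(a$counts[1:4, , drop = FALSE], "bacteria")
  small_b <- random_table(4, 4, seed = 3)
  colnames(small_b$counts) <- paste0("f", 1:4)
  names(small_b$kingdom) <- colnames(small_b$counts)
  small_b$kingdom[] <- "fungi"
  rownames(small_b$counts) <- rownames(small_a$counts)
  expect_error(build_cooccurrence(small_a, small_b),
               class = "invalid_argument")
})
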