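test_that("mantel_test matches vegan and handles the self-comparison", {
  a <- vec_pm(withr::with_seed(1, rnorm(12)))
  b <- vec_pm(withr::with_seed(2, rnorm(12)))
  got <- mantel_test(a, b, n_perm = 199, seed = 3)
  want <- vegan::mantel(as.dist(unclass(a)), as.dist(unclass(b)),
                        permutations = 199)
  expect_equal(got$r, unname(want$statistic), tolerance = 1e-10)
  self <- mantel_test(a, a, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p, 1 / 100)
  const <- vec_pm(rep(1, 12))
  expect_error(mantel_test(a, const), class = "degenerate_input")
})

test_that("mantel type-I error is calibrated and power is adequate", {
  n_rep <- 200; alpha <- 0.05
  rejections <- 0
  for (s in seq_len(n_rep)) {
    a <- vec_pm(withr::with_seed(2 * s, rnorm(15)))
    b <- vec_pm(withr::with_seed(2 * s + 1, rnorm(15)))
    p <- mantel_test(a, b, n_perm = 99, seed = s,
                     alternative = "greater")$p
    if (p <= alpha) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
  # power at a planted shared gradient
  hits <- 0
  for (s in 1:20) {
    g <- withr::with_seed(900 + s, rnorm(15))
    a <- vec_pm(g + withr::with_seed(950 + s, rnorm(15, 0, 0.5)))
    b <- vec_pm(g + withr::with_seed(980 + s, rnorm(15, 0, 0.5)))
    if (mantel_test(a, b, n_perm = 99, seed = s)$p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
})

test_that("partial mantel behaves at its limit cases", {
  labs <- sprintf("x%02d", 1:14)
  g <- withr::with_seed(7, rnorm(14))
  a <- vec_pm(g + withr::with_seed(8, rnorm(14, 0, 0.4)), labels = labs)
  b <- vec_pm(g + withr::with_seed(9, rnorm(14, 0, 0.4)), labels = labs)
  c_ind <- vec_pm(withr::with_seed(10, rnorm(14)), labels = labs)
  # independent conditioning matrix barely changes r
  r_plain <- mantel_test(a, b, n_perm = 99, seed = 1)$r
  r_part <- partial_mantel(a, b, c_ind, n_perm = 99, seed = 1)$r
  expect_lt(abs(r_plain - r_part), 0.15)
  # controlling for itself removes everything
  expect_equal(partial_mantel(a, b, b, n_perm = 99, seed = 1)$r, 0)
  # a = b with random c: r near 1, minimal p
  r_self <- partial_mantel(a, a, c_ind, n_perm = 99, seed = 1)
  expect_gt(r_self$r, 0.95)
  expect_equal(r_self$p, 1 / 100)
})

test_that("partial mantel type-I error is calibrated", {
  n_rep <- 200
  rejections <- 0
  for (s in seq_len(n_rep)) {
    a <- vec_pm(withr::with_seed(3 * s, rnorm(15)))
    b <- vec_pm(withr::with_seed(3 * s + 1, rnorm(15)))
    cc <- vec_pm(withr::with_seed(3 * s + 2, rnorm(15)))
    p <- partial_mantel(a, b, cc, n_perm = 99, seed = s)$p
    if (p <= 0.05) rejections <- rejections + 1
  }
  rate <- rejections / n_rep
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("LMG equals marginal r2 in orthogonal designs and sums to R2", {
  x <- cbind(a = rep(c(1, -1), each = 50), b = rep(c(1, -1), times = 50))
  y <- withr::with_seed(4, 0.6 * x[, 1] + 0.4 * x[, 2] + rnorm(100, 0, 0.8))
  imp <- lmg_importance(x, y)
  r2a <- summary(lm(y ~ x[, 1]))$r.squared
  r2b <- summary(lm(y ~ x[, 2]))$r.squared
  expect_equal(imp$share[imp$predictor == "a"], r2a, tolerance = 1e-9)
  expect_equal(imp$share[imp$predictor == "b"], r2b, tolerance = 1e-9)
  expect_equal(sum(imp$share), attr(imp, "total_r2"), tolerance = 1e-9)
  # single predictor: share equals simple-regression R2
  imp1 <- lmg_importance(x[, 1, drop = FALSE], y)
  expect_equal(imp1$share, r2a, tolerance = 1e-9)
  # collinearity is reported with the offending column
  xx <- cbind(x, a2 = x[, 1])
  expect_error(lmg_importance(xx, y), class = "collinearity")
})

test_that("LMG exact enumeration agrees with direct ordering average", {
  withr::with_seed(6, {
    x <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, c("p", "q", "r")))
    y <- x %*% c(1, 0.5, -0.3) + rnorm(60)
  })
  imp <- lmg_importance(x, y)
  # independent oracle: average sequential R2 gains over all 3! orderings
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), 3:1)
  shares <- numeric(3)
  for (ord in perms) {
    prev <- 0
    for (k in seq_along(ord)) {
      r2 <- summary(lm(y ~ x[, ord[1:k], drop = FALSE]))$r.squared
      shares[ord[k]] <- shares[ord[k]] + (r2 - prev) / length(perms)
      prev <- r2
    }
  }
  expect_equal(imp$share[match(colnames(x), imp$predictor)], shares,
               tolerance = 1e-9)
  # invariance to predictor order
  imp_rev <- lmg_importance(x[, 3:1], y)
  expect_equal(imp_rev$share[match(colnames(x), imp_rev$predictor)],
               imp$share[match(colnames(x), imp$predictor)],
               tolerance = 1e-12)
  # sampling estimator approximates the exact shares
  imp_mc <- lmg_importance(x, y, n_orderings = 500, seed = 2)
  expect_equal(imp_mc$share[match(colnames(x), imp_mc$predictor)],
               imp$share[match(colnames(x), imp$predictor)],
               tolerance = 0.05)
})

test_that("dominant taxa selection applies both thresholds strictly", {
  n <- 100
  m <- matrix(0L, n, 4,
              dimnames = list(sprintf("s%03d", 1:n), paste0("t", 1:4)))
  m[1:49, 1] <- 1000L    # abundant but only 49% occupancy
  m[1:60, 2] <- 1000L    # abundant and ubiquitous
  m[1:60, 3] <- 1L       # ubiquitous but rare
  m[, 4] <- 5L           # keeps all rows non-empty
  ct <- count_table(m)
  picked <- dominant_taxa_select(ct, prevalence_min = 0.5,
                                 abundance_top = 0.5)
  expect_false("t1" %in% picked)
  expect_true("t2" %in% picked)
  # sample order invariance
  ct2 <- count_table(m[rev(seq_len(n)), ])
  expect_setequal(dominant_taxa_select(ct2, 0.5, 0.5), picked)
})

test_that("taxon driver models find planted drivers and order nested R2", {
  withr::with_seed(11, {
    n <- 60
    drv <- data.frame(sample_id = sprintf("s%02d", 1:n),
                      pH = rnorm(n), AI = rnorm(n), AD = rnorm(n),
                      Neg = rnorm(n))
    m <- matrix(rpois(n * 5, 20), n, 5,
                dimnames = list(drv$sample_id, paste0("t", 1:5)))
    # taxon t1 driven by the biotic feature AD
    m[, 1] <- as.integer(round(200 + 80 * scale(drv$AD) + rnorm(n, 0, 4)))
  })
  ct <- count_table(m)
  res <- taxon_driver_models(ct, drv, taxa = paste0("t", 1:5),
                             abiotic = c("pH", "AI"),
                             biotic = c("AD", "Neg"))
  expect_equal(res$per_taxon$best_predictor[res$per_taxon$taxon == "t1"],
               "AD")
  expect_true(all(res$per_taxon$r2_bio >= res$per_taxon$r2_nonbio - 1e-12))
  expect_true(res$wilcoxon_p >= 0 && res$wilcoxon_p <= 1)
})

test_that("dbrda forward selection admits real structure and resists noise", {
  cfg <- sim_config(n_samples = 30, regime = "variable_filtering", seed = 2)
  sim <- simulate_dataset(cfg)
  bc <- bray_curtis(sim$bacteria)
  pc <- cmdscale(sqrt(unclass(bc)), k = 3)
  drv <- data.frame(sample_id = rownames(bc),
                    good = pc[, 1] + withr::with_seed(1, rnorm(30, 0, 0.01)),
                    junk1 = withr::with_seed(2, rnorm(30)),
                    junk2 = withr::with_seed(3, rnorm(30)))
  sel <- dbrda_forward(bc, drv, n_perm = 99, seed = 1)
  expect_equal(sel$variable[1], "good")
  expect_true(all(diff(sel$cum_r2) >= -1e-12))
  expect_true(all(sel$cum_r2 <= 1 + 1e-9))
  expect_identical(sel, dbrda_forward(bc, drv, n_perm = 99, seed = 1))
  # pure-noise drivers: rarely more than one admission
  n_adm <- integer(10)
  for (s in 1:10) {
    noise <- data.frame(sample_id = rownames(bc),
                        a = withr::with_seed(100 + s, rnorm(30)),
                        b = withr::with_seed(200 + s, rnorm(30)),
                        c = withr::with_seed(300 + s, rnorm(30)))
    n_adm[s] <- nrow(dbrda_forward(bc, noise, n_perm = 99, seed = s))
  }
  expect_gte(mean(n_adm <= 1), 0.9)
})

test_that("random-forest importance flags the true predictor reproducibly", {
  withr::with_seed(13, {
    x <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("v", 1:5)))
    y <- 2 * x[, 1] + rnorm(40, 0.5)
  })
  rf <- rf_importance(x, y, n_trees = 150, n_perm = 30, seed = 1)
  expect_equal(rf$predictor[1], "v1")
  expect_lt(rf$p[rf$predictor == "v1"], 0.05)
  rf2 <- rf_importance(x, y, n_trees = 150, n_perm = 30, seed = 1)
  expect_identical(rf, rf2)
  expect_error(rf_importance(x, rep(1, 40)), class = "degenerate_input")
  expect_error(rf_importance(x[1:10, ], y[1:10]),
               class = "invalid_argument")
})
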