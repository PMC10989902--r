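# Statistical attribution machinery: Mantel / partial Mantel permutation
# tests, LMG variance decomposition, dominant-taxon driver models,
# forward-selected distance-based ordination, random-forest importance.

mantel_triangles <- function(a_pm, b_pm) {
  labels <- rownames(a_pm)
  if (length(labels) < 4) sa_stop("need at least 4 samples",
                                  "invalid_argument")
  b_pm <- pm_align(b_pm, labels)
  list(a = unclass(a_pm), b = unclass(b_pm), n = length(labels))
}

#' Mantel permutation test between two pairwise matrices
#'
#' Pearson correlation of the strict upper triangles; significance by
#' simultaneous row/column permutation of the second matrix. The p-value
#' uses the add-one estimator `(1 + #(perm >= obs)) / (1 + n_perm)`
#' (one-tailed positive by default). Pairs whose value in either matrix is
#' not finite (e.g. NaN bNTI entries) are excluded.
#'
#' @param a,b [pair_matrix()] objects over the same samples.
#' @param n_perm Number of permutations (999 by default).
#' @param seed Integer seed.
#' @param alternative `"greater"` (conventional for Mantel) or
#'   `"two.sided"`.
#' @param method Correlation of the triangles: `"pearson"` (default) or
#'   `"spearman"`.
#' @return A list of class `mantel_result`: `r`, `p`, `n_perm`, `method`.
#' @export
mantel_test <- function(a, b, n_perm = 999, seed = 1L,
                        alternative = c("greater", "two.sided"),
                        method = c("pearson", "spearman")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  tr <- mantel_triangles(a, b)
  ut <- upper.tri(tr$a)
  av <- tr$a[ut]
  mask <- is.finite(av)
  bv <- tr$b[ut]
  if (any(!is.finite(bv))) sa_stop("second matrix has non-finite pairs",
                                   "invalid_argument")
  if (stats::var(av[mask]) == 0 || stats::var(bv[mask]) == 0) {
    sa_stop("zero variance in a matrix triangle", "degenerate_input")
  }
  obs <- stats::cor(av[mask], bv[mask], method = method)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (r in seq_len(n_perm)) {
      idx <- sample.int(tr$n)
      pv <- tr$b[idx, idx][ut]
      rp <- stats::cor(av[mask], pv[mask], method = method)
      hit <- if (alternative == "greater") rp >= obs else abs(rp) >= abs(obs)
      if (isTRUE(hit)) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(r = obs, p = (1 + exceed) / (1 + n_perm),
                 n_perm = as.integer(n_perm), method = "standard",
                 alternative = alternative, cor_method = method),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel: r = %.4f, p = %.4g (%d permutations, %s)\n",
              x$method, x$r, x$p, x$n_perm, x$alternative))
  invisible(x)
}

#' Partial Mantel test controlling for a third matrix
#'
#' Partial Pearson correlation of the triangles of `a` and `b` given `c`,
#' with significance by permuting the matrix of residuals of `b` on `c`
#' (method of residuals): the residual matrix keeps its symmetric pair
#' structure and its sample labels are permuted.
#'
#' @inheritParams mantel_test
#' @param c Conditioning [pair_matrix()].
#' @return A `mantel_result` with `method = "partial"`.
#' @export
partial_mantel <- function(a, b, c, n_perm = 999, seed = 1L,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  tr <- mantel_triangles(a, b)
  cm <- unclass(pm_align(c, rownames(a)))
  ut <- upper.tri(tr$a)
  av <- tr$a[ut]; bv <- tr$b[ut]; cv <- cm[ut]
  mask <- is.finite(av) & is.finite(bv) & is.finite(cv)
  if (stats::var(av[mask]) == 0 || stats::var(bv[mask]) == 0 ||
      stats::var(cv[mask]) == 0) {
    sa_stop("zero variance in a matrix triangle", "degenerate_input")
  }
  ares_v <- rep(NA_real_, length(av)); bres_v <- rep(NA_real_, length(bv))
  fit_a <- stats::lm(av[mask] ~ cv[mask])
  fit_b <- stats::lm(bv[mask] ~ cv[mask])
  ares_v[mask] <- stats::residuals(fit_a)
  bres_v[mask] <- stats::residuals(fit_b)
  if (stats::var(bres_v[mask]) < 1e-12 * stats::var(bv[mask]) ||
      stats::var(ares_v[mask]) < 1e-12 * stats::var(av[mask])) {
    # conditioning matrix explains a or b (near-)completely: nothing left
    # to correlate
    return(structure(list(r = 0, p = 1, n_perm = as.integer(n_perm),
                          method = "partial", alternative = alternative,
                          cor_method = "pearson"),
                     class = "mantel_result"))
  }
  obs <- stats::cor(ares_v[mask], bres_v[mask])
  # rebuild the residuals of b|c as a symmetric matrix for permutation
  bres_m <- matrix(0, tr$n, tr$n)
  bres_m[ut] <- bres_v
  bres_m <- bres_m + t(bres_m)
  mask_m <- matrix(FALSE, tr$n, tr$n)
  mask_m[ut] <- mask
  mask_m <- mask_m | t(mask_m)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (r in seq_len(n_perm)) {
      idx <- sample.int(tr$n)
      pv <- bres_m[idx, idx][ut]
      pm_ok <- mask_m[idx, idx][ut] & is.finite(ares_v)
      if (sum(pm_ok) < 3 || stats::var(pv[pm_ok]) == 0) next
      rp <- stats::cor(ares_v[pm_ok], pv[pm_ok])
      hit <- if (alternative == "greater") rp >= obs else abs(rp) >= abs(obs)
      if (isTRUE(hit)) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(r = obs, p = (1 + exceed) / (1 + n_perm),
                 n_perm = as.integer(n_perm), method = "partial",
                 alternative = alternative, cor_method = "pearson"),
            class = "mantel_result")
}

# R^2 of y on the predictor subset, from the correlation structure.
subset_r2 <- function(rxx, rxy, subset) {
  if (!length(subset)) return(0)
  r_s <- rxx[subset, subset, drop = FALSE]
  c_s <- rxy[subset]
  as.numeric(crossprod(c_s, solve(r_s, c_s)))
}

#' LMG relative importance of regression predictors
#'
#' Decomposes the R-squared of the multiple regression of `y` on the
#' columns of `x` into non-negative per-predictor shares: the LMG share of
#' predictor j is the increase in R-squared when j enters the model,
#' averaged over all orderings of the predictors (computed by exact
#' enumeration over subsets with combinatorial weights). Shares sum to the
#' full-model R-squared, and equal the marginal r-squared in orthogonal
#' designs.
#'
#' @param x Numeric matrix or data frame of predictors (p <= 12 for exact
#'   enumeration; use `n_orderings` for a Monte-Carlo estimate beyond
#'   that).
#' @param y Numeric response.
#' @param n_orderings If not `NULL`, estimate shares by averaging over this
#'   many random predictor orderings instead of exact enumeration
#'   (required for p > 12); Monte-Carlo error scales as 1/sqrt(n_orderings).
#' @param seed Seed for the Monte-Carlo estimator.
#' @return Data frame (`predictor`, `share`, `rank`) with attribute
#'   `total_r2`.
#' @export
lmg_importance <- function(x, y, n_orderings = NULL, seed = 1L) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  p <- ncol(x); n <- nrow(x)
  if (n <= p + 1) sa_stop("need n > p + 1 observations", "invalid_argument")
  if (p > 12 && is.null(n_orderings)) {
    sa_stop("exact LMG enumeration is limited to 12 predictors; set n_orderings for the sampling estimator",
            "invalid_argument")
  }
  qr_x <- qr(cbind(1, scale(x)))
  if (qr_x$rank < p + 1) {
    bad <- colnames(x)[setdiff(seq_len(p), qr_x$pivot[seq_len(qr_x$rank)] - 1)]
    sa_stop(sprintf("predictors are collinear (offending: %s)",
                    paste(bad, collapse = ", ")), "collinearity")
  }
  rxx <- stats::cor(x)
  rxy <- as.numeric(stats::cor(x, y))
  if (stats::var(y) == 0) sa_stop("response is constant", "degenerate_input")

  shares <- stats::setNames(numeric(p), colnames(x))
  if (is.null(n_orderings)) {
    # exact: enumerate all 2^p subsets once, then combine with weights
    r2 <- numeric(2^p)
    for (code in 0:(2^p - 1)) {
      subset <- which(bitwAnd(code, bitwShiftL(1L, 0:(p - 1))) > 0)
      r2[code + 1] <- subset_r2(rxx, rxy, subset)
    }
    fact <- factorial(0:p)
    for (j in seq_len(p)) {
      bit_j <- bitwShiftL(1L, j - 1L)
      acc <- 0
      for (code in 0:(2^p - 1)) {
        if (bitwAnd(code, bit_j) > 0) next
        k <- sum(bitwAnd(code, bitwShiftL(1L, 0:(p - 1))) > 0)
        w <- fact[k + 1] * fact[p - k] / fact[p + 1]
        acc <- acc + w * (r2[code + bit_j + 1] - r2[code + 1])
      }
      shares[j] <- acc
    }
  } else {
    shares[] <- 0
    with_seed(seed, {
      for (r in seq_len(n_orderings)) {
        ord <- sample.int(p)
        prev <- 0
        for (k in seq_len(p)) {
          cur <- subset_r2(rxx, rxy, ord[seq_len(k)])
          shares[ord[k]] <- shares[ord[k]] + (cur - prev)
          prev <- cur
        }
      }
    })
    shares <- shares / n_orderings
  }
  total <- subset_r2(rxx, rxy, seq_len(p))
  out <- data.frame(predictor = colnames(x), share = as.numeric(shares),
                    rank = rank(-shares, ties.method = "first"))
  attr(out, "total_r2") <- total
  out
}

#' Select dominant taxa (ubiquitous and abundant)
#'
#' Taxa detected in strictly more than `prevalence_min` of the samples AND
#' whose mean relative abundance lies in the top `abundance_top` quantile
#' across all taxa.
#'
#' @param table A [count_table()].
#' @param prevalence_min Occupancy fraction threshold (strict), default
#'   0.5.
#' @param abundance_top Upper abundance quantile, default 0.10 (top 10%).
#' @return Character vector of taxon IDs.
#' @export
dominant_taxa_select <- function(table, prevalence_min = 0.5,
                                 abundance_top = 0.10) {
  stopifnot(inherits(table, "count_table"))
  if (prevalence_min <= 0 || prevalence_min >= 1 ||
      abundance_top <= 0 || abundance_top > 1) {
    sa_stop("thresholds must be in (0, 1)", "invalid_argument")
  }
  m <- table$counts
  occ <- colSums(m > 0)
  rel <- m / rowSums(m)
  mra <- colMeans(rel)
  cut <- stats::quantile(mra, 1 - abundance_top, type = 7)
  keep <- occ > prevalence_min * nrow(m) & mra >= cut
  colnames(m)[keep]
}

#' Per-taxon driver models with biotic vs abiotic comparison
#'
#' For each selected taxon, regresses its relative abundance on (i) the
#' abiotic predictors only and (ii) abiotic plus biotic predictors
#' (subnetwork features and fungal richness), reports LMG shares from the
#' full model, the best predictor, and a one-sided Wilcoxon signed-rank
#' comparison of the paired R-squared values across taxa.
#'
#' @param table A [count_table()] (rarefied).
#' @param drivers Data frame keyed by `sample_id` containing all predictor
#'   columns; predictors are z-standardised internally.
#' @param taxa Taxa to model (e.g. from [dominant_taxa_select()]).
#' @param abiotic,biotic Character vectors naming the two predictor sets.
#' @param n_orderings Passed to [lmg_importance()] when the full set
#'   exceeds 12 predictors.
#' @return A list: `per_taxon` data frame (`taxon`, `best_predictor`,
#'   `r2_bio`, `r2_nonbio`), `lmg` (named list of share tables),
#'   `wilcoxon_p`.
#' @export
taxon_driver_models <- function(table, drivers, taxa, abiotic, biotic,
                                n_orderings = NULL) {
  stopifnot(inherits(table, "count_table"))
  sids <- sample_ids(table)
  drv <- drivers[match(sids, drivers$sample_id), , drop = FALSE]
  if (anyNA(drv$sample_id)) sa_stop("drivers missing some samples",
                                    "label_mismatch")
  all_vars <- c(abiotic, biotic)
  keep <- vapply(all_vars, function(v) stats::var(drv[[v]]) > 0, TRUE)
  if (!all(keep)) {
    sa_warn(sprintf("dropping constant predictor(s): %s",
                    paste(all_vars[!keep], collapse = ", ")),
            "predictors_dropped")
    abiotic <- intersect(abiotic, all_vars[keep])
    biotic <- intersect(biotic, all_vars[keep])
    all_vars <- c(abiotic, biotic)
  }
  x_full <- scale(as.matrix(drv[, all_vars, drop = FALSE]))
  x_ab <- x_full[, abiotic, drop = FALSE]
  rel <- table$counts / rowSums(table$counts)
  rows <- list(); lmg_list <- list()
  for (tx in taxa) {
    y <- rel[, tx]
    r2_of <- function(xm) summary(stats::lm(y ~ xm))$r.squared
    r2_nonbio <- r2_of(x_ab)
    r2_bio <- r2_of(x_full)
    imp <- lmg_importance(x_full, y, n_orderings = n_orderings)
    best <- imp$predictor[which.min(imp$rank)]
    lmg_list[[tx]] <- imp
    rows[[tx]] <- data.frame(taxon = tx, best_predictor = best,
                             r2_bio = r2_bio, r2_nonbio = r2_nonbio)
  }
  per_taxon <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(0), best_predictor = character(0),
               r2_bio = numeric(0), r2_nonbio = numeric(0))
  rownames(per_taxon) <- NULL
  wp <- if (nrow(per_taxon) >= 2 &&
            any(per_taxon$r2_bio != per_taxon$r2_nonbio)) {
    stats::wilcox.test(per_taxon$r2_bio, per_taxon$r2_nonbio,
                       paired = TRUE, alternative = "greater",
                       exact = FALSE)$p.value
  } else NA_real_
  list(per_taxon = per_taxon, lmg = lmg_list, wilcoxon_p = wp)
}

#' Forward selection on a distance-based ordination
#'
#' Embeds the (square-root-transformed) Bray-Curtis matrix by principal
#' coordinates (the square root makes the dissimilarity Euclidean-
#' embeddable, avoiding negative eigenvalues), then greedily adds the
#' standardised driver with the largest increase in explained variance,
#' admitting it while its permutation p-value is at most `alpha`.
#'
#' @param bc A [pair_matrix()] of kind `bray_curtis`.
#' @param drivers Data frame keyed by `sample_id` with numeric candidate
#'   columns.
#' @param vars Candidate column names (default: all numeric columns except
#'   `sample_id`).
#' @param alpha Admission threshold on the permutation p-value.
#' @param n_perm Permutations per candidate test.
#' @param seed Integer seed.
#' @return Data frame in selection order: `variable`, `delta_r2`,
#'   `cum_r2`, `p`. Zero rows when nothing is admitted.
#' @export
dbrda_forward <- function(bc, drivers, vars = NULL, alpha = 0.05,
                          n_perm = 199, seed = 1L) {
  if (!identical(pm_kind(bc), "bray_curtis")) {
    sa_stop("bc must be a pair_matrix of kind 'bray_curtis'",
            "invalid_argument")
  }
  labels <- rownames(bc)
  drv <- drivers[match(labels, drivers$sample_id), , drop = FALSE]
  if (anyNA(drv$sample_id)) sa_stop("drivers missing some samples",
                                    "label_mismatch")
  if (is.null(vars)) {
    vars <- setdiff(names(drv)[vapply(drv, is.numeric, TRUE)], "sample_id")
  }
  x <- scale(as.matrix(drv[, vars, drop = FALSE]))
  pc <- stats::cmdscale(sqrt(unclass(bc)), k = length(labels) - 1,
                        eig = TRUE)
  keep <- pc$eig > 1e-8
  keep <- keep[seq_len(ncol(pc$points))]
  y <- pc$points[, keep, drop = FALSE]
  eig <- pc$eig[seq_len(ncol(pc$points))][keep]
  total_ss <- sum(eig)

  # explained SS of the (centred) PCoA cloud under the predictor set
  explained <- function(sel_x) {
    q <- qr.Q(qr(cbind(1, sel_x)))
    fitted <- q %*% crossprod(q, y)
    sum(fitted^2)
  }

  selected <- integer(0)
  rows <- list()
  cum <- 0
  set_r2 <- function(cols) {
    if (!length(cols)) 0 else explained(x[, cols, drop = FALSE]) / total_ss
  }
  repeat {
    remaining <- setdiff(seq_along(vars), selected)
    if (!length(remaining)) break
    gains <- vapply(remaining,
                    function(j) set_r2(c(selected, j)) - cum, numeric(1))
    j_best <- remaining[which.max(gains)]
    gain <- max(gains)
    # permutation test: permute the candidate column, refit
    exceed <- with_seed(seed + length(selected), {
      cnt <- 0L
      for (r in seq_len(n_perm)) {
        xp <- x
        xp[, j_best] <- x[sample.int(nrow(x)), j_best]
        g <- explained(xp[, c(selected, j_best), drop = FALSE]) /
          total_ss - cum
        if (g >= gain) cnt <- cnt + 1L
      }
      cnt
    })
    p <- (1 + exceed) / (1 + n_perm)
    if (p > alpha) break
    selected <- c(selected, j_best)
    cum <- cum + gain
    rows[[length(rows) + 1]] <- data.frame(variable = vars[j_best],
                                           delta_r2 = gain, cum_r2 = cum,
                                           p = p)
    if (length(selected) >= min(length(vars), nrow(x) - 2)) break
  }
  if (!length(rows)) {
    return(data.frame(variable = character(0), delta_r2 = numeric(0),
                      cum_r2 = numeric(0), p = numeric(0)))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Random-forest importance with permutation significance
#'
#' Fits a random-forest regression and reports the permutation importance
#' (%IncMSE) of each predictor; significance comes from refitting the
#' forest on response-permuted data `n_perm` times and comparing each
#' observed importance with its null distribution (add-one p-values).
#'
#' @param x Numeric predictor matrix or data frame (n >= 20 rows).
#' @param y Numeric response (non-constant).
#' @param n_trees Trees per forest.
#' @param n_perm Response permutations for the null distribution.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @return Data frame (`predictor`, `incMSE_pct`, `p`) sorted by decreasing
#'   importance.
#' @export
rf_importance <- function(x, y, n_trees = 500, n_perm = 99, seed = 1L) {
  x <- as.data.frame(x)
  if (nrow(x) < 20) sa_stop("need at least 20 observations",
                            "invalid_argument")
  if (stats::var(y) == 0) sa_stop("response is constant", "degenerate_input")
  fit_imp <- function(yy) {
    fit <- randomForest::randomForest(x, yy, ntree = n_trees,
                                      importance = TRUE)
    randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  }
  obs <- with_seed(seed, fit_imp(y))
  nulls <- with_seed(seed + 1L, {
    vapply(seq_len(n_perm), function(r) fit_imp(sample(y)),
           numeric(length(obs)))
  })
  nulls <- matrix(nulls, nrow = length(obs))
  p <- (1 + rowSums(nulls >= obs)) / (1 + n_perm)
  out <- data.frame(predictor = names(obs), incMSE_pct = as.numeric(obs),
                    p = p)
  out[order(-out$incMSE_pct), , drop = FALSE]
}
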