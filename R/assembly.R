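#' Cophenetic distance matrix of a phylogeny
#'
#' Patristic distance between every pair of tips (sum of branch lengths on
#' the connecting path), ordered by the tree's tip labels.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return Symmetric numeric matrix with zero diagonal, tips as labels.
#' @export
cophenetic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) sa_stop("tree must be a phylo object",
                                        "invalid_tree")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    sa_stop("tree must have complete branch lengths", "invalid_tree")
  }
  d <- stats::cophenetic(tree)
  d[tree$tip.label, tree$tip.label]
}

# fast row minima via max.col (C code); x must have >= 1 column
row_mins <- function(x) x[cbind(seq_len(nrow(x)), max.col(-x, ties.method = "first"))]

# Relative-abundance (or presence) weight matrix, samples x taxa
bmntd_weights <- function(counts, weighted) {
  if (weighted) {
    counts / rowSums(counts)
  } else {
    pa <- (counts > 0) * 1
    pa / rowSums(pa)
  }
}

# All-pairs beta-MNTD given weight matrix F (S x T) and taxon distance d
# (T x T, same column order as F). For each sample m, M[, m] holds
# min_{j present in m} d[i, j] over all taxa i; then
# bMNTD(k, m) = 0.5 * ((F M)[k, m] + (F M)[m, k]).
bmntd_engine <- function(f, d) {
  pres <- f > 0
  t_n <- ncol(f)
  m <- matrix(0, t_n, nrow(f))
  for (s in seq_len(nrow(f))) {
    cols <- which(pres[s, ])
    m[, s] <- if (length(cols) == 1L) d[, cols] else
      row_mins(d[, cols, drop = FALSE])
  }
  a <- f %*% m
  0.5 * (a + t(a))
}

#' Abundance-weighted beta mean nearest taxon distance
#'
#' For samples k and m,
#' `bMNTD = 0.5 * (sum_i f_ik min_j d_ij + sum_j f_jm min_i d_ij)`,
#' where the minima run over taxa present in the other sample (a shared
#' taxon contributes distance 0) and `f` are within-sample relative
#' abundances (`weighted = TRUE`) or equal presence weights (1/richness).
#'
#' @param table A [count_table()] whose taxa are all tips of the tree
#'   behind `d`.
#' @param d Cophenetic matrix from [cophenetic_matrix()] (may contain more
#'   taxa than the table).
#' @param weighted Use relative abundances (default) or presence weights.
#' @return A [pair_matrix()] of kind `bmntd`.
#' @export
beta_mntd <- function(table, d, weighted = TRUE) {
  stopifnot(inherits(table, "count_table"))
  taxa <- taxon_ids(table)
  if (!all(taxa %in% rownames(d))) {
    sa_stop("all table taxa must appear in the distance matrix",
            "label_mismatch")
  }
  if (any(rowSums(table$counts) == 0)) {
    sa_stop("every sample must be non-empty", "invalid_argument")
  }
  f <- bmntd_weights(table$counts, weighted)
  b <- bmntd_engine(f, d[taxa, taxa, drop = FALSE])
  dimnames(b) <- list(sample_ids(table), sample_ids(table))
  pair_matrix(b, kind = "bmntd")
}

#' Beta nearest taxon index (null-model z-score of beta-MNTD)
#'
#' The null distribution randomises phylogenetic relationships while
#' holding the communities fixed: taxon labels are shuffled across the tips
#' of the (pruned) phylogeny and beta-MNTD is recomputed for every pair,
#' `n_null` times. `bNTI(k, m) = (obs - mean_null) / sd_null`. Pairs whose
#' null spread is zero (e.g. a star phylogeny) are set to `NaN` with a
#' warning. Values below -2 indicate homogeneous selection (less turnover
#' than expected), above +2 variable selection, and `|bNTI| <= 2` is
#' consistent with stochastic assembly.
#'
#' @param table A [count_table()] of (typically rarefied) bacterial counts.
#' @param tree Phylogeny containing every taxon of the table as a tip.
#' @param n_null Number of tip-shuffle null draws (>= 99; 999 in
#'   production use).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param weighted Passed to [beta_mntd()].
#' @return A list of class `bnti_result`: `bnti`, `obs_bmntd`, `null_mean`,
#'   `null_sd` (all [pair_matrix()]-like), `n_null`, `seed`.
#' @export
beta_nti <- function(table, tree, n_null = 999, seed = 1L, weighted = TRUE) {
  stopifnot(inherits(table, "count_table"))
  if (n_null < 99) sa_stop("n_null must be >= 99", "invalid_argument")
  d_full <- cophenetic_matrix(tree)
  taxa <- taxon_ids(table)
  if (!all(taxa %in% rownames(d_full))) {
    sa_stop("all table taxa must be tips of the tree", "label_mismatch")
  }
  d <- d_full[taxa, taxa, drop = FALSE]
  f <- bmntd_weights(table$counts, weighted)
  obs <- bmntd_engine(f, d)

  # The null shuffles taxon labels across ALL tips of the supplied
  # phylogeny: each observed taxon is reassigned to a random distinct tip
  # position, so tips never observed in the table still shape the null
  # (when the table covers every tip this is the usual full shuffle).
  t_n <- length(taxa)
  n_tips <- nrow(d_full)
  sum1 <- matrix(0, nrow(obs), ncol(obs))
  sum2 <- matrix(0, nrow(obs), ncol(obs))
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      idx <- sample.int(n_tips, t_n)
      b <- bmntd_engine(f, d_full[idx, idx, drop = FALSE])
      sum1 <- sum1 + b
      sum2 <- sum2 + b * b
    }
  })
  null_mean <- sum1 / n_null
  null_var <- pmax((sum2 - n_null * null_mean^2) / (n_null - 1), 0)
  null_sd <- sqrt(null_var)

  z <- (obs - null_mean) / null_sd
  degen <- null_sd <= .Machine$double.eps^0.5
  z[degen] <- NaN
  if (any(degen[upper.tri(degen)])) {
    sa_warn(sprintf("%d sample pair(s) have zero null spread; bNTI set to NaN",
                    sum(degen[upper.tri(degen)])), "degenerate_null")
  }
  labels <- sample_ids(table)
  name_pm <- function(m, kind) {
    dimnames(m) <- list(labels, labels)
    pair_matrix(m, kind = kind)
  }
  structure(list(bnti = name_pm(z, "bnti"),
                 obs_bmntd = name_pm(obs, "bmntd"),
                 null_mean = name_pm(null_mean, "bmntd"),
                 null_sd = name_pm(null_sd, "bnti"),
                 n_null = as.integer(n_null), seed = as.integer(seed)),
            class = "bnti_result")
}

#' @export
print.bnti_result <- function(x, ...) {
  v <- upper_vals(unclass(x$bnti))
  v <- v[is.finite(v)]
  cat(sprintf(
    "bnti_result: %d samples, %d nulls | HS %.2f / Sto %.2f / VS %.2f\n",
    nrow(x$bnti), x$n_null, mean(v < -2), mean(abs(v) <= 2), mean(v > 2)))
  invisible(x)
}

#' Partition sample pairs into assembly-process fractions
#'
#' Within each group, the fraction of pairs under homogeneous selection
#' (`bNTI < -2`), variable selection (`bNTI > 2`) and stochastic processes
#' (`|bNTI| <= 2`). NaN pairs are excluded from the denominator; groups
#' with fewer than two samples are excluded with a warning.
#'
#' @param bnti A [pair_matrix()] of kind `bnti` (e.g. `beta_nti(...)$bnti`).
#' @param groups Named vector (by sample) or vector aligned with the matrix
#'   labels assigning each sample a group label; a single common label
#'   pools all pairs.
#' @return Data frame with columns `group`, `n_pairs`, `HS`, `VS`, `Sto`;
#'   the three fractions sum to 1 per group.
#' @export
classify_fractions <- function(bnti, groups) {
  if (!identical(pm_kind(bnti), "bnti")) {
    sa_stop("bnti must be a pair_matrix of kind 'bnti'", "invalid_argument")
  }
  labels <- rownames(bnti)
  if (length(groups) == 1L) groups <- stats::setNames(rep(groups,
                                                          length(labels)),
                                                      labels)
  if (is.null(names(groups))) names(groups) <- labels
  groups <- groups[labels]
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) {
      sa_warn(sprintf("group '%s' has fewer than 2 samples; excluded", g),
              "group_excluded")
      next
    }
    sub <- unclass(bnti)[idx, idx]
    v <- upper_vals(sub)
    v <- v[is.finite(v)]
    if (!length(v)) next
    out[[g]] <- data.frame(group = g, n_pairs = length(v),
                           HS = mean(v < -2), VS = mean(v > 2),
                           Sto = mean(abs(v) <= 2))
  }
  if (!length(out)) sa_stop("no group with enough samples", "empty_result")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assembly-process fractions along a fungal-richness gradient
#'
#' Samples are ranked by fungal richness (ties broken by position) and cut
#' into `n_groups` contiguous groups of (near-)equal size. Within-group
#' bNTI pairs give per-group process fractions; each fraction is then
#' regressed on group mean richness with a second-order polynomial, and the
#' trend sign is the sign of the fitted first derivative averaged over the
#' observed richness range.
#'
#' @param bnti A [pair_matrix()] of kind `bnti`.
#' @param fungal_richness Numeric vector named by sample (or aligned with
#'   the matrix labels).
#' @param n_groups Number of groups (>= 3; at most half the sample count).
#' @return A list with `fractions` (per-group data frame with
#'   `mean_richness`), `polyfit` (3 coefficients per process) and
#'   `trend_sign` (named -1/0/+1 per process).
#' @export
richness_group_analysis <- function(bnti, fungal_richness, n_groups) {
  if (!identical(pm_kind(bnti), "bnti")) {
    sa_stop("bnti must be a pair_matrix of kind 'bnti'", "invalid_argument")
  }
  labels <- rownames(bnti)
  n <- length(labels)
  if (n_groups < 3) sa_stop("n_groups must be >= 3", "invalid_argument")
  if (n_groups > n / 2) sa_stop("n_groups must allow >= 2 samples per group",
                                "invalid_argument")
  if (is.null(names(fungal_richness))) names(fungal_richness) <- labels
  fr <- fungal_richness[labels]
  if (anyNA(fr)) sa_stop("fungal_richness missing for some samples",
                         "label_mismatch")
  if (diff(range(fr)) == 0) {
    sa_stop("fungal richness is constant; grouping is degenerate",
            "degenerate_input")
  }
  ord <- order(fr, seq_len(n)) # ties broken by sample order
  grp_sizes <- sort(rep_len(seq_len(n_groups), n))
  grp <- stats::setNames(character(n), labels)
  grp[labels[ord]] <- sprintf("G%02d", grp_sizes)
  frac <- classify_fractions(bnti, grp)
  mean_r <- tapply(fr, grp, mean)
  frac$mean_richness <- as.numeric(mean_r[frac$group])
  frac <- frac[order(frac$mean_richness), ]
  rownames(frac) <- NULL

  polyfit <- list(); trend <- c(HS = 0, VS = 0, Sto = 0)
  x <- frac$mean_richness
  for (proc in c("HS", "VS", "Sto")) {
    fit <- stats::lm(frac[[proc]] ~ x + I(x^2))
    cf <- stats::coef(fit)
    cf[is.na(cf)] <- 0
    polyfit[[proc]] <- stats::setNames(as.numeric(cf),
                                       c("intercept", "b1", "b2"))
    deriv <- cf[["x"]] + 2 * cf[["I(x^2)"]] * mean(x)
    trend[proc] <- sign(deriv)
  }
  list(fractions = frac, polyfit = polyfit, trend_sign = trend,
       groups = grp)
}

#' Mantel test of bNTI against the distance matrix of one driver
#'
#' Correlates pairwise bNTI with the absolute difference of a metadata
#' variable between samples, with permutation significance — the standard
#' way to ask which environmental gradients structure assembly processes.
#'
#' @param bnti A [pair_matrix()] of kind `bnti`.
#' @param env Metadata frame with `sample_id` and the variable.
#' @param variable Numeric metadata column name.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `mantel_result` (see [mantel_test()]).
#' @export
bnti_driver_mantel <- function(bnti, env, variable, n_perm = 999, seed = 1L) {
  dd <- driver_distance(env[match(rownames(bnti), env$sample_id), ,
                            drop = FALSE],
                        variable)
  mantel_test(bnti, dd, n_perm = n_perm, seed = seed)
}
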