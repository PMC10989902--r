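#' Rarefy a count table to a fixed sequencing depth
#'
#' Each sample is subsampled without replacement to exactly `depth` reads
#' (a single draw at a fixed seed). Samples whose total falls below `depth`
#' are dropped with a warning listing them, mirroring the usual practice of
#' resampling ASV tables to the minimum common depth before diversity
#' calculations.
#'
#' @param table A [count_table()].
#' @param depth Target depth (reads per sample), `>= 1`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A rarefied `count_table`; every row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  if (depth < 1) sa_stop("depth must be >= 1", "invalid_argument")
  totals <- rowSums(table$counts)
  keep <- totals >= depth
  if (!any(keep)) sa_stop("all samples fall below the rarefaction depth",
                          "empty_result")
  if (!all(keep)) {
    sa_warn(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(rownames(table$counts)[!keep], collapse = ", ")),
            "samples_dropped")
  }
  m <- table$counts[keep, , drop = FALSE]
  # single multivariate-hypergeometric draw per sample (without replacement)
  out <- with_seed(seed, {
    t(apply(m, 1, function(row) {
      if (sum(row) == depth) return(as.integer(row))
      pool <- rep.int(seq_along(row), row)
      tabulate(pool[sample.int(length(pool), depth)], nbins = length(row))
    }))
  })
  dimnames(out) <- dimnames(m)
  count_table(out, kingdom = table$kingdom)
}

#' Shannon diversity per sample (natural log)
#'
#' `H = -sum(p * log(p))` over taxa with positive counts, with `p` the
#' within-sample relative abundances. Reported in nats.
#'
#' @param table A [count_table()].
#' @return Named numeric vector over samples.
#' @export
shannon <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (any(rowSums(table$counts) == 0)) {
    sa_stop("every sample must have a positive total count",
            "invalid_argument")
  }
  vegan::diversity(table$counts, index = "shannon")
}

#' Observed richness per sample
#'
#' Number of taxa with count > 0 ("detected") in each sample.
#'
#' @param table A [count_table()].
#' @return Named integer vector over samples.
#' @export
richness <- function(table) {
  stopifnot(inherits(table, "count_table"))
  rowSums(table$counts > 0)
}

#' Bray-Curtis dissimilarity between all sample pairs
#'
#' `BC(k, m) = sum_i |a_ik - a_im| / sum_i (a_ik + a_im)`, in `[0, 1]`.
#' Intended to be applied to rarefied counts so that depths are equal.
#'
#' @param table A [count_table()] with at least two samples.
#' @return A [pair_matrix()] of kind `bray_curtis`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (nrow(table$counts) < 2) sa_stop("need at least 2 samples",
                                      "invalid_argument")
  if (any(rowSums(table$counts) == 0)) {
    sa_stop("every sample must have a positive total count",
            "invalid_argument")
  }
  d <- vegan::vegdist(table$counts, method = "bray")
  pair_matrix(as.matrix(d), kind = "bray_curtis")
}

#' Drop rare taxa by occupancy
#'
#' Keeps taxa detected (count > 0) in strictly more than
#' `min_fraction * n_samples` samples — e.g. the default keeps taxa present
#' in more than 10% of all samples before network construction.
#'
#' @param table A [count_table()].
#' @param min_fraction Occupancy fraction in `[0, 1)`; strict threshold.
#' @return A filtered `count_table` (possibly with zero taxa, with warning).
#' @export
prevalence_filter <- function(table, min_fraction = 0.10) {
  stopifnot(inherits(table, "count_table"))
  if (min_fraction < 0 || min_fraction >= 1) {
    sa_stop("min_fraction must be in [0, 1)", "invalid_argument")
  }
  occ <- colSums(table$counts > 0)
  keep <- occ > min_fraction * nrow(table$counts)
  if (!any(keep)) {
    sa_warn("prevalence filter removed every taxon", "empty_result")
  }
  out <- table
  out$counts <- table$counts[, keep, drop = FALSE]
  out$kingdom <- table$kingdom[keep]
  out
}
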