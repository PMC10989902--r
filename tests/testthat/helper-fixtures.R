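# Builders shared across test files; everything is generated in code.

toy_counts <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("t%02d", seq_len(ncol(m)))
  m
}

toy_table <- function(m, kingdom = "bacteria") count_table(toy_counts(m), kingdom)

# random count table with guaranteed positive row sums
random_table <- function(n_samples, n_taxa, lambda = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
    m[cbind(seq_len(n_samples), sample.int(n_taxa, n_samples, TRUE))] <-
      m[cbind(seq_len(n_samples), sample.int(n_taxa, n_samples, TRUE))] + 1L
    toy_table(m)
  })
}

# labelled pair_matrix from a numeric vector (abs differences)
vec_pm <- function(v, kind = "euclidean_driver", labels = NULL) {
  if (is.null(labels)) labels <- sprintf("x%02d", seq_along(v))
  d <- abs(outer(v, v, "-"))
  dimnames(d) <- list(labels, labels)
  pair_matrix(d, kind)
}

# Brute-force beta-MNTD oracle: explicit double loop over present taxa,
# written independently of the matrix implementation.
bmntd_oracle <- function(counts, d, weighted = TRUE) {
  n <- nrow(counts)
  out <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  for (k in seq_len(n)) for (m in seq_len(n)) {
    if (k == m) next
    pk <- which(counts[k, ] > 0); pm <- which(counts[m, ] > 0)
    fk <- if (weighted) counts[k, pk] / sum(counts[k, ]) else
      rep(1 / length(pk), length(pk))
    fm <- if (weighted) counts[m, pm] / sum(counts[m, ]) else
      rep(1 / length(pm), length(pm))
    s1 <- 0
    for (i in seq_along(pk)) {
      best <- Inf
      for (j in pm) best <- min(best, d[colnames(counts)[pk[i]],
                                        colnames(counts)[j]])
      s1 <- s1 + fk[i] * best
    }
    s2 <- 0
    for (j in seq_along(pm)) {
      best <- Inf
      for (i in pk) best <- min(best, d[colnames(counts)[i],
                                        colnames(counts)[pm[j]]])
      s2 <- s2 + fm[j] * best
    }
    out[k, m] <- 0.5 * (s1 + s2)
  }
  out
}
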