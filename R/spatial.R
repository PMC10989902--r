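#' Great-circle distance matrix between samples
#'
#' Haversine distance on a sphere of radius 6371 km between every pair of
#' sampling sites.
#'
#' @param env Metadata frame with `sample_id`, `latitude` and `longitude`
#'   columns (decimal degrees).
#' @return A [pair_matrix()] of kind `geographic_km`.
#' @export
haversine_matrix <- function(env) {
  lat <- env$latitude; lon <- env$longitude
  if (is.null(lat) || is.null(lon)) {
    sa_stop("env must have latitude and longitude columns",
            "invalid_argument")
  }
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    sa_stop("coordinates out of range", "invalid_argument")
  }
  n <- nrow(env)
  m <- matrix(0, n, n, dimnames = list(env$sample_id, env$sample_id))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  p <- cbind(lon, lat)
  d <- geosphere::distHaversine(p[idx[, 1], , drop = FALSE],
                                p[idx[, 2], , drop = FALSE],
                                r = 6371000) / 1000
  m[idx] <- d
  m[idx[, c(2, 1), drop = FALSE]] <- d
  pair_matrix(m, kind = "geographic_km")
}

#' Distance-decay relationship per group
#'
#' Per group (e.g. habitat), ordinary least-squares regression of pairwise
#' community similarity (1 - Bray-Curtis) on geographic distance over the
#' within-group pairs. Because pairwise values are not independent, the
#' p-value comes from a Mantel-style permutation of the distance matrix
#' rather than the parametric t-test.
#'
#' @param similarity A [pair_matrix()] of similarities (typically
#'   `1 - bray_curtis(...)`, still a `bray_curtis`-kind matrix is accepted
#'   and converted: pass `similarity = TRUE` matrices as-is).
#' @param distance A [pair_matrix()] of kind `geographic_km` (any distance
#'   works).
#' @param groups Named vector assigning each sample a group label; a single
#'   label pools all samples.
#' @param log10_distance Regress on `log10(distance)` instead of raw km
#'   (zero-distance pairs are dropped with a warning).
#' @param n_perm Permutations for the slope p-value.
#' @param seed Integer seed.
#' @return Data frame with `group`, `slope`, `intercept`, `r2`, `p`,
#'   `n_pairs`, `n_samples`; groups with fewer than 3 samples are excluded
#'   with a warning.
#' @export
ddr_fit <- function(similarity, distance, groups, log10_distance = FALSE,
                    n_perm = 999, seed = 1L) {
  labels <- rownames(similarity)
  distance <- pm_align(distance, labels)
  if (length(groups) == 1L) groups <- stats::setNames(rep(groups,
                                                          length(labels)),
                                                      labels)
  if (is.null(names(groups))) names(groups) <- labels
  groups <- groups[labels]
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 3) {
      sa_warn(sprintf("group '%s' has fewer than 3 samples; excluded", g),
              "group_excluded")
      next
    }
    s <- unclass(similarity)[idx, idx]
    d <- unclass(distance)[idx, idx]
    y <- upper_vals(s)
    x <- upper_vals(d)
    keep <- rep(TRUE, length(x))
    if (log10_distance) {
      keep <- x > 0
      if (!all(keep)) sa_warn(sprintf(
        "group '%s': dropping %d zero-distance pair(s) for log10 axis",
        g, sum(!keep)), "pairs_dropped")
    }
    xk <- if (log10_distance) log10(x[keep]) else x[keep]
    yk <- y[keep]
    if (stats::var(xk) == 0) {
      sa_warn(sprintf("group '%s' has no distance variation; excluded", g),
              "group_excluded")
      next
    }
    fit <- stats::lm(yk ~ xk)
    slope <- stats::coef(fit)[["xk"]]
    r2 <- summary(fit)$r.squared
    # permutation of sample labels of the distance matrix
    nperm_ge <- with_seed(seed, {
      cnt <- 0L
      for (r in seq_len(n_perm)) {
        pidx <- sample(seq_along(idx))
        dp <- d[pidx, pidx]
        xp <- upper_vals(dp)
        xpk <- if (log10_distance) {
          kp <- xp > 0
          if (sum(kp) < 3 || stats::var(log10(xp[kp])) == 0) next
          log10(xp[kp])
        } else xp
        ypk <- if (log10_distance) y[xp > 0] else y
        if (stats::var(xpk) == 0) next
        sp <- stats::cov(xpk, ypk) / stats::var(xpk)
        if (abs(sp) >= abs(slope)) cnt <- cnt + 1L
      }
      cnt
    })
    out[[g]] <- data.frame(group = g, slope = slope,
                           intercept = stats::coef(fit)[["(Intercept)"]],
                           r2 = r2, p = (1 + nperm_ge) / (1 + n_perm),
                           n_pairs = length(xk), n_samples = length(idx))
  }
  if (!length(out)) sa_stop("no group with enough samples", "empty_result")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
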