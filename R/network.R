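#' Cross-kingdom Spearman co-occurrence network
#'
#' Computes Spearman's rank correlation between every taxon pair (within
#' and across kingdoms) over the shared samples and keeps an edge when
#' `|rho| > rho_threshold` and the two-sided p-value (t-approximation on
#' average ranks, no multiplicity correction) is below `p_threshold`.
#' Isolated nodes are removed. Both tables should already be rarefied and
#' prevalence-filtered.
#'
#' @param bacteria,fungi [count_table()] objects over identical sample
#'   sets (>= 5 samples).
#' @param rho_threshold Absolute correlation threshold (strict), default
#'   0.6.
#' @param p_threshold Significance threshold (strict), default 0.001.
#' @return An [igraph::graph] with vertex attributes `name` and `kingdom`,
#'   and edge attributes `rho`, `p`, `sign` (`"pos"`/`"neg"`).
#' @export
build_cooccurrence <- function(bacteria, fungi, rho_threshold = 0.6,
                               p_threshold = 0.001) {
  merged <- merge_tables(bacteria, fungi)
  n <- nrow(merged$counts)
  if (n < 5) sa_stop("need at least 5 samples for the p approximation",
                     "invalid_argument")
  m <- merged$counts
  ranks <- apply(m, 2, rank) # average ranks for ties
  rho <- suppressWarnings(stats::cor(ranks))
  rho[!is.finite(rho)] <- 0 # constant columns have no correlation
  # two-sided p via the t-approximation
  r_clip <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_clip * sqrt((n - 2) / (1 - r_clip^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0

  hit <- abs(rho) > rho_threshold & p < p_threshold
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  taxa <- taxon_ids(merged)
  edges <- data.frame(from = taxa[idx[, 1]], to = taxa[idx[, 2]],
                      rho = rho[idx], p = p[idx],
                      sign = ifelse(rho[idx] > 0, "pos", "neg"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$kingdom <- unname(merged$kingdom[igraph::V(g)$name])
  g
}

#' Niche preferences of taxa (abundance-weighted environmental means)
#'
#' For each taxon and variable, the mean of the variable over the samples
#' where the taxon is detected, weighted by the taxon's relative abundance
#' at those samples:
#' `pref_i = sum_s w_is x_s` with `w_is = a_is / sum_s a_is` over detected
#' samples.
#'
#' @param table A [count_table()].
#' @param env Metadata frame with `sample_id` and the variables.
#' @param variables Character vector of numeric metadata columns.
#' @return Data frame, one row per taxon, one column per variable (plus
#'   `taxon`). Taxa detected nowhere are excluded with a warning.
#' @export
niche_preference <- function(table, env, variables) {
  stopifnot(inherits(table, "count_table"))
  sids <- sample_ids(table)
  ev <- env[match(sids, env$sample_id), , drop = FALSE]
  if (anyNA(ev$sample_id)) sa_stop("env missing some samples",
                                   "label_mismatch")
  m <- table$counts
  detected <- colSums(m) > 0
  if (!all(detected)) {
    sa_warn(sprintf("%d taxa detected nowhere; excluded", sum(!detected)),
            "taxa_excluded")
    m <- m[, detected, drop = FALSE]
  }
  # per-taxon weights over samples: w[s, i] = a_si / sum_s a_si
  w <- sweep(m, 2, colSums(m), "/")
  out <- data.frame(taxon = colnames(m))
  for (v in variables) {
    x <- env_variable(ev, v)
    out[[v]] <- as.numeric(crossprod(w, x))
  }
  out
}

#' Correlation between node degree and niche preference
#'
#' Pearson correlation (with two-sided p) and OLS slope of network degree
#' on the taxon's preference for one environmental variable — the standard
#' way to ask whether taxa adapted to one end of a gradient are more or
#' less connected.
#'
#' @param net Network from [build_cooccurrence()].
#' @param prefs Data frame from [niche_preference()].
#' @param variable Preference column to use.
#' @return List with `r`, `p`, `slope`, `n`.
#' @export
degree_preference_correlation <- function(net, prefs, variable) {
  deg <- igraph::degree(net)
  common <- intersect(names(deg), prefs$taxon)
  if (length(common) < 3) sa_stop("need >= 3 network nodes with preference",
                                  "invalid_argument")
  d <- deg[common]
  x <- prefs[[variable]][match(common, prefs$taxon)]
  if (stats::var(d) == 0 || stats::var(x) == 0) {
    sa_stop("zero variance in degree or preference", "degenerate_input")
  }
  ct <- stats::cor.test(x, d, method = "pearson")
  slope <- stats::coef(stats::lm(d ~ x))[[2]]
  list(r = unname(ct$estimate), p = ct$p.value, slope = slope,
       n = length(common))
}

#' Per-sample subnetwork features (AD, Neg, Int)
#'
#' For each sample, induces the subgraph of the global network on the taxa
#' detected in that sample and reports: average degree `AD = 2E/N`, the
#' proportion of negative edges `Neg`, and the proportion of cross-kingdom
#' (bacterium-fungus) edges `Int`. Samples with no edges get all features
#' 0 and are flagged so downstream regressions can keep or drop them.
#'
#' @param net Network from [build_cooccurrence()].
#' @param table A [count_table()] (typically the merged rarefied table;
#'   any table whose taxa overlap the network works).
#' @return Data frame keyed by `sample_id` with `n_nodes`, `n_edges`,
#'   `AD`, `Neg`, `Int`, `flagged`.
#' @export
sample_subnetwork_features <- function(net, table) {
  stopifnot(inherits(table, "count_table"))
  nodes <- igraph::V(net)$name
  sids <- sample_ids(table)
  out <- data.frame(sample_id = sids, n_nodes = 0L, n_edges = 0L,
                    AD = 0, Neg = 0, Int = 0, flagged = TRUE)
  for (i in seq_along(sids)) {
    present <- taxon_ids(table)[table$counts[i, ] > 0]
    sub_nodes <- intersect(nodes, present)
    out$n_nodes[i] <- length(sub_nodes)
    if (!length(sub_nodes)) next
    sg <- igraph::induced_subgraph(net, sub_nodes)
    e <- igraph::ecount(sg)
    out$n_edges[i] <- e
    if (e == 0) next
    out$AD[i] <- 2 * e / igraph::vcount(sg)
    out$Neg[i] <- sum(igraph::E(sg)$sign == "neg") / e
    ends <- igraph::ends(sg, igraph::E(sg))
    kdm <- stats::setNames(igraph::V(sg)$kingdom, igraph::V(sg)$name)
    out$Int[i] <- sum(kdm[ends[, 1]] != kdm[ends[, 2]]) / e
    out$flagged[i] <- FALSE
  }
  out
}

#' Write the network edge list as TSV
#'
#' Columns: `taxonA`, `taxonB`, `rho`, `p`, `sign`, `kingdomA`,
#' `kingdomB`.
#'
#' @param net Network from [build_cooccurrence()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  ends <- igraph::ends(net, igraph::E(net))
  kdm <- stats::setNames(igraph::V(net)$kingdom, igraph::V(net)$name)
  df <- data.frame(taxonA = ends[, 1], taxonB = ends[, 2],
                   rho = igraph::E(net)$rho, p = igraph::E(net)$p,
                   sign = igraph::E(net)$sign,
                   kingdomA = unname(kdm[ends[, 1]]),
                   kingdomB = unname(kdm[ends[, 2]]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
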