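#' Labelled symmetric matrix over samples
#'
#' Carrier for pairwise quantities: Bray-Curtis dissimilarity, geographic
#' distance in km, beta-NTI, or Euclidean distance of a single driver.
#' Distance-like kinds have a zero diagonal; `bnti` has an undefined (NA)
#' diagonal because a sample has no turnover with itself under the null.
#'
#' @param values Square numeric matrix with matching row/column names.
#' @param kind One of `"bray_curtis"`, `"geographic_km"`, `"bnti"`,
#'   `"euclidean_driver"`, `"bmntd"` (distance-like, zero diagonal) or
#'   `"similarity"` (unit diagonal, e.g. 1 - Bray-Curtis).
#' @return A matrix of class `pair_matrix` with attribute `kind`.
#' @export
pair_matrix <- function(values,
                        kind = c("bray_curtis", "geographic_km", "bnti",
                                 "euclidean_driver", "bmntd",
                                 "similarity")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) sa_stop("matrix must be square",
                                            "invalid_argument")
  if (is.null(rownames(values))) sa_stop("labels required", "invalid_argument")
  if (anyDuplicated(rownames(values))) sa_stop("labels must be unique",
                                               "invalid_argument")
  colnames(values) <- rownames(values)
  off <- values[upper.tri(values)]
  tol <- 1e-8
  if (any(abs(values - t(values)) > tol, na.rm = TRUE)) {
    sa_stop("matrix must be symmetric", "invalid_argument")
  }
  values <- (values + t(values)) / 2
  if (kind == "bnti") {
    diag(values) <- NA_real_
  } else if (kind == "similarity") {
    # self-similarity is 1 by definition; no constraint enforced
  } else {
    if (any(abs(diag(values)) > tol)) {
      sa_stop("distance-kind pair_matrix must have zero diagonal",
              "invalid_argument")
    }
    diag(values) <- 0
  }
  structure(values, kind = kind, class = c("pair_matrix", "matrix"))
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix (%s): %d samples\n", attr(x, "kind"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

pm_kind <- function(x) attr(x, "kind")

# reorder a pair_matrix to a given label order (must be a permutation)
pm_align <- function(x, labels) {
  if (!setequal(rownames(x), labels)) {
    sa_stop("pair_matrix labels do not match", "label_mismatch")
  }
  pair_matrix(unclass(x)[labels, labels], kind = pm_kind(x))
}

#' @rdname pair_matrix
#' @param x A `pair_matrix`.
#' @param path File path for the square labelled TSV.
#' @export
write_pair_matrix <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname pair_matrix
#' @export
read_pair_matrix <- function(path, kind) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  pair_matrix(as.matrix(df), kind = kind)
}

#' Community similarity from a Bray-Curtis matrix
#'
#' `1 - dissimilarity`, the quantity distance-decay regressions are fit on.
#'
#' @param bc A [pair_matrix()] of kind `bray_curtis`.
#' @return A `pair_matrix` of kind `similarity`.
#' @export
bray_similarity <- function(bc) {
  if (!identical(pm_kind(bc), "bray_curtis")) {
    sa_stop("bc must be a pair_matrix of kind 'bray_curtis'",
            "invalid_argument")
  }
  pair_matrix(1 - unclass(bc), kind = "similarity")
}

#' Euclidean (absolute-difference) distance matrix of one sample variable
#'
#' @param env Data frame of per-sample metadata with a `sample_id` column.
#' @param variable Name of a numeric column.
#' @return A `pair_matrix` of kind `euclidean_driver`.
#' @export
driver_distance <- function(env, variable) {
  x <- env_variable(env, variable)
  m <- abs(outer(x, x, "-"))
  dimnames(m) <- list(env$sample_id, env$sample_id)
  pair_matrix(m, kind = "euclidean_driver")
}

env_variable <- function(env, variable) {
  if (!variable %in% names(env)) {
    sa_stop(sprintf("variable '%s' not found in metadata", variable),
            "invalid_argument")
  }
  x <- env[[variable]]
  if (!is.numeric(x)) sa_stop(sprintf("variable '%s' is not numeric", variable),
                              "invalid_argument")
  stats::setNames(x, env$sample_id)
}
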