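#' Sample-by-taxon count table
#'
#' The universal community object: a non-negative integer matrix with samples
#' as rows and taxa (ASVs) as columns, plus a kingdom label per taxon.
#' Taxa that are absent from every sample are dropped at construction time,
#' so a `count_table` never carries all-zero columns.
#'
#' @param counts Integer matrix, samples x taxa, with unique row and column
#'   names. Entries must be non-negative whole numbers.
#' @param kingdom Either a single string (`"bacteria"` or `"fungi"`) applied
#'   to every taxon, or a character vector named by taxon ID.
#' @return An object of class `count_table`: a list with elements `counts`
#'   (integer matrix) and `kingdom` (named character vector over the taxa).
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 3L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("t1", "t2")))
#' ct <- count_table(m, kingdom = "bacteria")
#' @export
count_table <- function(counts, kingdom = "bacteria") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    sa_stop("counts must have sample (row) and taxon (column) names",
            "invalid_argument")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    sa_stop("sample and taxon IDs must be unique", "invalid_argument")
  }
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    sa_stop("counts must be finite non-negative integers", "invalid_argument")
  }
  storage.mode(counts) <- "integer"
  keep <- colSums(counts) > 0L
  if (!all(keep)) counts <- counts[, keep, drop = FALSE]
  taxa <- colnames(counts)
  if (length(kingdom) == 1L && is.null(names(kingdom))) {
    kingdom <- stats::setNames(rep(kingdom, length(taxa)), taxa)
  }
  if (!all(taxa %in% names(kingdom))) {
    sa_stop("kingdom must name every taxon", "invalid_argument")
  }
  kingdom <- kingdom[taxa]
  if (!all(kingdom %in% c("bacteria", "fungi"))) {
    sa_stop("kingdom values must be 'bacteria' or 'fungi'", "invalid_argument")
  }
  structure(list(counts = counts, kingdom = kingdom), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d samples x %d taxa (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(table(x$kingdom)),
                            table(x$kingdom)), collapse = ", ")))
  invisible(x)
}

#' @rdname count_table
#' @param x A `count_table`.
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname count_table
#' @export
taxon_ids <- function(x) colnames(x$counts)

#' Combine bacterial and fungal tables over a shared sample set
#'
#' @param bacteria,fungi `count_table` objects over identical sample sets
#'   (order may differ; the result follows `bacteria`).
#' @return A single `count_table` whose kingdom labels are retained.
#' @export
merge_tables <- function(bacteria, fungi) {
  if (!setequal(sample_ids(bacteria), sample_ids(fungi))) {
    sa_stop("bacteria and fungi tables must share the same sample set",
            "label_mismatch")
  }
  if (length(intersect(taxon_ids(bacteria), taxon_ids(fungi)))) {
    sa_stop("taxon IDs collide between the two tables", "label_mismatch")
  }
  f <- fungi$counts[sample_ids(bacteria), , drop = FALSE]
  count_table(cbind(bacteria$counts, f),
              kingdom = c(bacteria$kingdom, fungi$kingdom))
}

#' Read / write count tables as TSV
#'
#' Dialect: tab-separated, first column the sample ID, header row the taxon
#' IDs.
#'
#' @param path File path.
#' @param kingdom Kingdom label(s) passed to [count_table()].
#' @return `read_count_table` returns a `count_table`; `write_count_table`
#'   returns `path` invisibly.
#' @export
read_count_table <- function(path, kingdom = "bacteria") {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  count_table(as.matrix(df), kingdom = kingdom)
}

#' @rdname read_count_table
#' @param table A `count_table`.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(sample_id = sample_ids(table), table$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
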