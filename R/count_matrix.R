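#' Protein-by-sample spectral-count matrix
#'
#' Lightweight container tying a nonnegative protein x sample count matrix to
#' the sample-to-group assignment (bait pulldown \code{"WT"} vs empty-vector
#' control \code{"EV"}) and a flag recording whether the counts are raw
#' integer spectral counts or between-sample normalized counts (N-SC).
#'
#' @param counts numeric matrix, rows = proteins, columns = samples; must
#'   carry row and column names and contain no negative or missing values.
#'   Raw matrices must be integer-valued.
#' @param groups named character vector mapping every sample (column) name to
#'   \code{"WT"} or \code{"EV"}.
#' @param normalized logical; \code{TRUE} once per-sample totals have been
#'   equalized by [normalize_counts()].
#' @return an object of class \code{count_matrix}: a list with elements
#'   \code{counts}, \code{groups}, \code{normalized}.
#' @seealso [normalize_counts()], [compute_spectral_counts()],
#'   [read_count_matrix()]
#' @export
count_matrix <- function(counts, groups, normalized = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("`counts` must have protein row names", call. = FALSE)
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("`counts` must have sample column names", call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("`counts` must be nonnegative and complete", call. = FALSE)
  groups <- unlist(groups)
  if (is.null(names(groups)) || !all(colnames(counts) %in% names(groups)))
    stop("every sample must have a group in `groups`", call. = FALSE)
  if (!all(groups %in% c("WT", "EV")))
    stop("groups must be 'WT' or 'EV'", call. = FALSE)
  if (!normalized && nrow(counts) > 0 &&
      any(abs(counts - round(counts)) > 1e-9))
    stop("raw counts must be integers", call. = FALSE)
  structure(
    list(counts = counts,
         groups = groups[colnames(counts)],
         normalized = isTRUE(normalized)),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d proteins x %d samples (%d WT, %d EV), %s\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "WT"), sum(x$groups == "EV"),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

wt_samples <- function(x) names(x$groups)[x$groups == "WT"]
ev_samples <- function(x) names(x$groups)[x$groups == "EV"]

#' Write / read a count matrix and its group map as TSV
#'
#' The matrix TSV has a leading \code{protein} column followed by one column
#' per sample; the group map is a two-column TSV (\code{sample_id},
#' \code{group}).
#'
#' @param x a [count_matrix()].
#' @param counts_file,groups_file file paths.
#' @param normalized logical; whether the file being read holds normalized
#'   counts.
#' @return \code{write_count_matrix} returns its input invisibly;
#'   \code{read_count_matrix} returns a [count_matrix()].
#' @export
write_count_matrix <- function(x, counts_file, groups_file = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(protein = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(groups_file))
    utils::write.table(
      data.frame(sample_id = names(x$groups), group = unname(x$groups)),
      groups_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_file, groups_file, normalized = FALSE) {
  df <- utils::read.delim(counts_file, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m, read_group_map(groups_file), normalized = normalized)
}

#' @rdname write_count_matrix
#' @export
read_group_map <- function(groups_file) {
  g <- utils::read.delim(groups_file, stringsAsFactors = FALSE)
  stats::setNames(g$group, g$sample_id)
}
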