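#' Case-overlap percentage for one gene
#'
#' Percentage of a gene's tumour cases that are shared with NF1-associated
#' cases, \code{100 * overlap_cases / total_cases}, rounded
#' half-away-from-zero to one decimal (so 471/862 prints as 54.6).
#'
#' @param overlap_cases nonnegative integer, cases shared with NF1.
#' @param total_cases positive integer, all cases associated with the gene.
#' @return percentage in [0, 100] with one decimal.
#' @export
compute_overlap_percent <- function(overlap_cases, total_cases) {
  if (length(overlap_cases) != 1 || length(total_cases) != 1 ||
      is.na(overlap_cases) || is.na(total_cases))
    stop("overlap_cases and total_cases must be single numbers",
         call. = FALSE)
  if (total_cases < 1) stop("total_cases must be >= 1", call. = FALSE)
  if (overlap_cases < 0 || overlap_cases > total_cases)
    stop("overlap_cases must be between 0 and total_cases", call. = FALSE)
  round_half_up(100 * overlap_cases / total_cases, 1)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Case-overlap table for a set of genes
#'
#' @param rows data frame with columns \code{gene}, \code{overlap_cases},
#'   \code{total_cases}; gene ids must be unique.
#' @return the input plus a \code{percent} column, sorted by descending
#'   percent with ties broken by gene id.
#' @export
overlap_table <- function(rows) {
  need <- c("gene", "overlap_cases", "total_cases")
  if (!all(need %in% names(rows)))
    stop("rows must have columns gene, overlap_cases, total_cases",
         call. = FALSE)
  if (anyDuplicated(rows$gene))
    stop("duplicate gene id: ", rows$gene[duplicated(rows$gene)][1],
         call. = FALSE)
  if (nrow(rows) == 0)
    return(data.frame(gene = character(), overlap_cases = integer(),
                      total_cases = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  rows$percent <- mapply(compute_overlap_percent, rows$overlap_cases,
                         rows$total_cases)
  rows <- rows[order(-rows$percent, rows$gene), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Read / write a gene-level case-overlap TSV
#'
#' Input columns: \code{gene}, \code{overlap_cases}, \code{total_cases};
#' the writer adds the computed \code{percent}.
#'
#' @param file file path.
#' @param rows table as accepted by [overlap_table()].
#' @export
read_overlap_table <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' @rdname read_overlap_table
#' @export
write_overlap_table <- function(rows, file) {
  utils::write.table(overlap_table(rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rows)
}

#' Published NF1 interactor case-overlap fractions
#'
#' The printed per-gene case fractions for the 20 high-confidence NF1
#' interactors that carry one (one keratin's cell is blank in the published
#' table and is left absent), shipped as a plain-text fixture.
#'
#' @return data frame with columns \code{gene}, \code{overlap_cases},
#'   \code{total_cases}.
#' @export
table1_overlaps <- function() {
  read_overlap_table(system.file("extdata", "table1_overlaps.tsv",
                                 package = "apmscall", mustWork = TRUE))
}
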