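# TCR-beta clonotype summaries: frequencies, the >2% expansion filter, and
# matching of TIL-clone TCR sequences into tissue repertoires.

#' Annotate a clonotype table with repertoire frequencies
#'
#' `frequency = count / sum(count)`, with stable ordering by descending
#' count and then lexicographic CDR3.
#'
#' @param table Data frame with at least `cdr3_aa` and `count` (positive
#'   integers); V/D/J/C gene columns are carried through.
#' @return The table with a `frequency` column, reordered.
#' @export
clonotype_frequencies <- function(table) {
  if (!nrow(table)) stop("empty clonotype table", call. = FALSE)
  stopifnot(all(c("cdr3_aa", "count") %in% names(table)))
  if (any(table$count < 1)) stop("clonotype counts must be positive",
                                 call. = FALSE)
  table$frequency <- table$count / sum(table$count)
  table <- table[order(-table$count, table$cdr3_aa), , drop = FALSE]
  rownames(table) <- NULL
  table
}

#' Expanded clonotypes above a repertoire-frequency threshold
#'
#' Keeps clonotypes whose frequency is strictly greater than `threshold`
#' ("over 2%" semantics: a clone at exactly 2% is excluded).
#'
#' @param table Clonotype table; frequencies are computed if absent.
#' @param threshold Frequency threshold (default 0.02).
#' @return Subset of the annotated table.
#' @export
expanded_clonotypes <- function(table, threshold = 0.02) {
  if (!"frequency" %in% names(table)) table <- clonotype_frequencies(table)
  out <- table[table$frequency > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

field_present <- function(x) {
  !is.null(x) && !is.na(x) && nzchar(as.character(x))
}

#' Match a TCR clonotype into a repertoire
#'
#' A match requires equality on `cdr3_aa`, `v_gene` and `j_gene`, and on
#' `d_gene`/`c_gene` whenever the field is present (non-missing, non-empty)
#' on both sides. Returns every matching repertoire record with its count
#' and frequency.
#'
#' @param query A single clonotype (list or one-row data frame) with at
#'   least `cdr3_aa`, `v_gene`, `j_gene`.
#' @param repertoire Clonotype table (frequencies computed if absent).
#' @return Subset of the repertoire table (possibly empty).
#' @export
match_clonotype <- function(query, repertoire) {
  if (is.data.frame(query)) query <- as.list(query[1L, ])
  for (f in c("cdr3_aa", "v_gene", "j_gene")) {
    if (!field_present(query[[f]])) {
      stop(sprintf("query clonotype lacks required field '%s'", f),
           call. = FALSE)
    }
  }
  if (!"frequency" %in% names(repertoire)) {
    repertoire <- clonotype_frequencies(repertoire)
  }
  keep <- repertoire$cdr3_aa == query$cdr3_aa &
    repertoire$v_gene == query$v_gene &
    repertoire$j_gene == query$j_gene
  for (f in c("d_gene", "c_gene")) {
    if (field_present(query[[f]]) && f %in% names(repertoire)) {
      both <- vapply(repertoire[[f]], field_present, TRUE)
      keep <- keep & (!both | repertoire[[f]] == query[[f]])
    }
  }
  out <- repertoire[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
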