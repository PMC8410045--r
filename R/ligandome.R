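# Tumor-vs-normal immunopeptidome comparison: sharing summaries, motif
# structure, and selection of nonmutated TAA candidates by tumor restriction
# plus expression fold-change.

as_peptide_sets <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("sample", "peptide") %in% names(x)))
    lapply(split(x$peptide, x$sample), unique)
  } else {
    lapply(x, unique)
  }
}

#' Summarize peptide sharing across ligandome samples
#'
#' Reports the nonredundant union size, the number and percentage of
#' peptides found in two or more samples, and the private (single-sample)
#' peptide count per sample. Sample order does not affect the result.
#'
#' @param sets Named list of peptide character vectors, or a long data frame
#'   with columns `sample` and `peptide`.
#' @return List with `union_size`, `shared_ge2`, `shared_ge2_pct`,
#'   `private` (named integer vector).
#' @export
overlap_summary <- function(sets) {
  sets <- as_peptide_sets(sets)
  if (length(sets) < 2L) stop("need at least 2 ligandome sets", call. = FALSE)
  all_pep <- unlist(sets, use.names = FALSE)
  counts <- table(all_pep)
  union_size <- length(counts)
  shared <- sum(counts >= 2L)
  private <- vapply(sets, function(s) sum(counts[s] == 1L), 0L)
  list(union_size = union_size,
       shared_ge2 = shared,
       shared_ge2_pct = 100 * shared / union_size,
       private = private)
}

#' Partition a tumor ligandome against the normal ligandomes
#'
#' A tumor peptide is "shared/normal" when present in any normal set; the
#' remainder is the tumor-only candidate set. The two parts always sum to
#' the tumor set size.
#'
#' @param tumor_set Character vector of tumor peptides (deduplicated).
#' @param normal_sets List of character vectors (or a single vector) of
#'   normal-tissue peptides.
#' @return List with `n_tumor`, `shared_or_normal`, `shared_or_normal_pct`,
#'   `tumor_only` (character vector).
#' @export
tumor_normal_partition <- function(tumor_set, normal_sets) {
  tumor_set <- unique(tumor_set)
  normal_union <- unique(unlist(normal_sets, use.names = FALSE))
  in_normal <- tumor_set %in% normal_union
  list(n_tumor = length(tumor_set),
       shared_or_normal = sum(in_normal),
       shared_or_normal_pct = if (length(tumor_set)) {
         100 * sum(in_normal) / length(tumor_set)
       } else NA_real_,
       tumor_only = tumor_set[!in_normal])
}

#' Select nonmutated TAA candidates from tumor-only ligands
#'
#' Keeps tumor-only peptides whose source gene is overexpressed in the tumor
#' by more than `fold_threshold` relative to the matched normal tissue.
#' Fold change is `tumor_tpm / max(normal_tpm, pseudocount)`; peptides mapped
#' to several genes use the maximal fold. Peptides whose normal TPM is zero
#' are flagged `normal_zero`.
#'
#' @param peptide_genes Data frame mapping `peptide` to `gene` (one row per
#'   pair; a peptide may appear with several genes).
#' @param tpm_tumor,tpm_normal Named numeric vectors of gene-level TPM.
#' @param fold_threshold Strict lower bound on the fold change (default 20).
#' @param pseudocount Denominator floor in TPM (default 0.1).
#' @return Data frame with `peptide`, `source_gene`, `tumor_tpm`,
#'   `normal_tpm`, `fold_change`, `normal_zero`, sorted by decreasing fold.
#' @export
select_taa <- function(peptide_genes, tpm_tumor, tpm_normal,
                       fold_threshold = 20, pseudocount = 0.1) {
  stopifnot(all(c("peptide", "gene") %in% names(peptide_genes)))
  genes <- unique(peptide_genes$gene)
  missing <- genes[!(genes %in% names(tpm_tumor) & genes %in% names(tpm_normal))]
  if (length(missing)) {
    stop(sprintf("missing expression record for source gene(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(split(peptide_genes$gene, peptide_genes$peptide),
                 function(gs) {
    tt <- tpm_tumor[gs]
    nn <- tpm_normal[gs]
    fc <- tt / pmax(nn, pseudocount)
    i <- which.max(fc)
    data.frame(source_gene = gs[i], tumor_tpm = unname(tt[i]),
               normal_tpm = unname(nn[i]), fold_change = unname(fc[i]),
               normal_zero = unname(nn[i]) == 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(peptide = names(rows), stringsAsFactors = FALSE), out)
  out <- out[out$fold_change > fold_threshold, , drop = FALSE]
  out <- out[order(-out$fold_change, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length histogram and position-frequency matrix of a peptide set
#'
#' @param peptides Character vector of peptides.
#' @param length Peptide length for the position-frequency matrix
#'   (default 9).
#' @return List with `length_counts` (named integer vector) and `pfm`
#'   (20 x length matrix; each column sums to 1; all-zero when no peptide of
#'   that length is present).
#' @export
motif_summary <- function(peptides, length = 9L) {
  if (!base::length(peptides)) stop("empty peptide set", call. = FALSE)
  lens <- nchar(peptides)
  length_counts <- table(lens)
  sel <- peptides[lens == length]
  pfm <- matrix(0, nrow = 20L, ncol = length, dimnames = list(AA20, NULL))
  if (base::length(sel)) {
    chars <- matrix(unlist(strsplit(sel, "", fixed = TRUE)),
                    ncol = length, byrow = TRUE)
    for (p in seq_len(length)) {
      tab <- table(factor(chars[, p], levels = AA20))
      pfm[, p] <- as.numeric(tab) / sum(tab)
    }
  }
  list(length_counts = length_counts, pfm = pfm)
}
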