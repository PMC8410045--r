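# Personalized proteogenomic search database construction:
# canonical proteome plus mutation-altered windows, expression-gated (TPM > 0).

#' Minigene inserts encoding the RAF9 neoantigen and its wild-type counterpart
#'
#' 27-nt coding inserts for the HLA-A24-restricted 9-mer neoantigen RAF9
#' (RYLAVAAVF, carrying the TUBB p.T332A substitution at peptide position 4)
#' and its wild-type counterpart RTF9 (RYLTVAAVF). Useful as worked examples
#' for [translate_cds()] and for validating minigene constructs.
#'
#' @format Character scalars of 27 nucleotides.
#' @examples
#' translate_cds(raf9_insert)
#' translate_cds(rtf9_insert)
#' @export
raf9_insert <- "CGATACCTCGCCGTGGCTGCTGTCTTC"

#' @rdname raf9_insert
#' @export
rtf9_insert <- "CGATACCTCACCGTGGCTGCTGTCTTC"

# translate and report whether a stop codon terminated the reading frame
translate_info <- function(cds, from_codon = 1L) {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) {
    stop("CDS contains non-ACGT characters", call. = FALSE)
  }
  start_nt <- (as.integer(from_codon) - 1L) * 3L + 1L
  if (nchar(cds) - start_nt + 1L < 3L) {
    stop("fewer than one complete codon from the start offset", call. = FALSE)
  }
  last_full <- start_nt + 3L * ((nchar(cds) - start_nt + 1L) %/% 3L) - 1L
  starts <- seq.int(start_nt, last_full - 2L, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  stop_at <- which(aas == "*")
  stop_found <- length(stop_at) > 0L
  if (stop_found) aas <- aas[seq_len(stop_at[1L] - 1L)]
  list(protein = paste(aas, collapse = ""), stop_found = stop_found)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Translation starts at `from_codon` (1-based codon index) and stops at,
#' and excludes, the first stop codon; if no stop codon is present all
#' complete codons are translated.
#'
#' @param cds Nucleotide string (A/C/G/T only).
#' @param from_codon 1-based codon offset at which translation begins.
#' @return Amino-acid string (possibly empty if the first codon is a stop).
#' @examples
#' translate_cds("CGATACCTCGCCGTGGCTGCTGTCTTC")  # "RYLAVAAVF"
#' translate_cds("ATGTAA")                        # "M"
#' @export
translate_cds <- function(cds, from_codon = 1L) {
  translate_info(cds, from_codon)$protein
}

check_variant_ref <- function(cds, cds_pos, ref) {
  if (cds_pos < 1L || cds_pos > nchar(cds)) {
    stop(sprintf("cds_pos %d outside CDS of length %d", cds_pos, nchar(cds)),
         call. = FALSE)
  }
  found <- substr(cds, cds_pos, cds_pos + nchar(ref) - 1L)
  if (!identical(found, ref)) {
    stop(sprintf(
      "reference allele mismatch at CDS position %d: expected '%s', CDS has '%s' (coordinate or dialect error?)",
      cds_pos, ref, found), call. = FALSE)
  }
  invisible(TRUE)
}

# replace `ref` at cds_pos by `alt`
mutate_cds <- function(cds, cds_pos, ref, alt) {
  paste0(substr(cds, 1L, cds_pos - 1L), alt,
         substr(cds, cds_pos + nchar(ref), nchar(cds)))
}

#' Apply a missense SNV to a transcript CDS
#'
#' Substitutes a single nucleotide, retranslates, and reports the altered
#' residue. The residue index follows HGVS-style arithmetic:
#' `residue = ceiling(cds_pos / 3)`, so c.994 maps to residue 332.
#' Synonymous outcomes, stop-gain/stop-loss and start-loss are rejected —
#' they are not missense inputs.
#'
#' @param cds Transcript coding sequence.
#' @param cds_pos 1-based CDS coordinate of the substituted nucleotide.
#' @param ref,alt Single-nucleotide reference and alternate alleles.
#' @return List with `protein` (full mutant translation), `residue_index`,
#'   `wt_aa` and `mut_aa`.
#' @export
apply_missense <- function(cds, cds_pos, ref, alt) {
  cds_pos <- as.integer(cds_pos)
  if (nchar(ref) != 1L || nchar(alt) != 1L || identical(ref, alt)) {
    stop("missense variant requires distinct single-nucleotide ref and alt",
         call. = FALSE)
  }
  check_variant_ref(cds, cds_pos, ref)
  residue_index <- (cds_pos + 2L) %/% 3L
  wt <- translate_info(cds)
  if (residue_index > nchar(wt$protein)) {
    stop("variant position lies beyond the first stop codon of the transcript",
         call. = FALSE)
  }
  codon_start <- (residue_index - 1L) * 3L + 1L
  wt_codon <- substr(cds, codon_start, codon_start + 2L)
  mut_codon <- wt_codon
  substr(mut_codon, cds_pos - codon_start + 1L, cds_pos - codon_start + 1L) <- alt
  wt_aa <- unname(Biostrings::GENETIC_CODE[wt_codon])
  mut_aa <- unname(Biostrings::GENETIC_CODE[mut_codon])
  if (identical(wt_aa, mut_aa)) {
    stop("synonymous substitution is not a valid missense variant", call. = FALSE)
  }
  if (identical(mut_aa, "*")) {
    stop("stop-gain (nonsense) substitutions are not handled", call. = FALSE)
  }
  if (identical(wt_aa, "*")) {
    stop("stop-loss substitutions are not handled", call. = FALSE)
  }
  if (residue_index == 1L) {
    stop("start-loss substitutions are not handled", call. = FALSE)
  }
  mutant <- translate_cds(mutate_cds(cds, cds_pos, ref, alt))
  list(protein = mutant, residue_index = residue_index,
       wt_aa = wt_aa, mut_aa = mut_aa)
}

#' Extract the 61-residue window around a missense substitution
#'
#' The window runs from 30 residues upstream to 30 residues downstream of the
#' altered residue, truncated at the protein termini. `mut_start == mut_end`
#' marks the altered residue's 1-based position within the window (31 in the
#' interior case).
#'
#' @param protein Mutant protein sequence.
#' @param residue_index 1-based index of the altered residue.
#' @return List with `sequence`, `mut_start`, `mut_end`.
#' @export
missense_window <- function(protein, residue_index) {
  residue_index <- as.integer(residue_index)
  L <- nchar(protein)
  if (residue_index < 1L || residue_index > L) {
    stop("residue_index outside protein", call. = FALSE)
  }
  a <- max(1L, residue_index - 30L)
  b <- min(L, residue_index + 30L)
  list(sequence = substr(protein, a, b),
       mut_start = residue_index - a + 1L,
       mut_end = residue_index - a + 1L)
}

#' Extract the frameshift neo-ORF window
#'
#' Applies a frame-disrupting indel, retranslates from the first codon, finds
#' the first residue at which the mutant translation diverges from wild type,
#' and returns the mutant sequence from 30 residues upstream of that point to
#' the novel stop codon (stop excluded). The novel residues from the first
#' divergence onward form `mut_start..mut_end`. Returns `NULL` when the
#' shifted frame terminates before producing any novel residue — such entries
#' carry no mutation-specific sequence.
#'
#' @param cds Transcript coding sequence.
#' @param cds_pos 1-based CDS coordinate where `ref` is replaced by `alt`.
#' @param ref,alt Allele strings whose length difference is not a multiple
#'   of 3.
#' @return `NULL`, or a list with `sequence`, `mut_start`, `mut_end` and
#'   `stop_found` (`FALSE` flags an open reading frame that ran off the
#'   transcript end without a novel stop).
#' @export
frameshift_window <- function(cds, cds_pos, ref, alt) {
  cds_pos <- as.integer(cds_pos)
  shift <- abs(nchar(ref) - nchar(alt))
  if (shift %% 3L == 0L) {
    stop("indel length difference is a multiple of 3: not a frameshift",
         call. = FALSE)
  }
  check_variant_ref(cds, cds_pos, ref)
  wt <- translate_info(cds)$protein
  mut_info <- translate_info(mutate_cds(cds, cds_pos, ref, alt))
  mut <- mut_info$protein
  # first residue where the mutant diverges from wild type
  n_common <- min(nchar(wt), nchar(mut))
  p <- NA_integer_
  if (n_common > 0L) {
    wt_chars <- str_residues(substr(wt, 1L, n_common))
    mut_chars <- str_residues(substr(mut, 1L, n_common))
    diffs <- which(wt_chars != mut_chars)
    if (length(diffs)) p <- diffs[1L]
  }
  if (is.na(p)) {
    # identical over the common prefix; novel residues only if mutant longer
    if (nchar(mut) > nchar(wt)) p <- nchar(wt) + 1L else return(NULL)
  }
  if (p > nchar(mut)) return(NULL)
  a <- max(1L, p - 30L)
  list(sequence = substr(mut, a, nchar(mut)),
       mut_start = p - a + 1L,
       mut_end = nchar(mut) - a + 1L,
       stop_found = mut_info$stop_found)
}

variant_id <- function(transcript_id, cds_pos, ref, alt) {
  sprintf("%s:c.%d%s>%s", transcript_id, cds_pos, ref, alt)
}

#' Build the personalized proteogenomic search database for one sample
#'
#' The database is the union of (a) canonical translations of all transcripts
#' expressed in the sample and (b) mutation windows (missense 61-mers,
#' frameshift neo-ORFs) of expressed transcripts. The expression gate is
#' strict: transcripts with TPM = 0 contribute to neither set. Entries whose
#' sequences are exact duplicates are collapsed with merged provenance.
#'
#' @param transcripts Data frame with columns `transcript_id`, `gene`, `cds`.
#' @param variants Data frame with columns `transcript_id`, `cds_pos`, `ref`,
#'   `alt`, `vtype` (`"missense"` or `"frameshift"`); extra columns such as
#'   `alt_reads`/`depth` are carried through unused.
#' @param tpm Data frame with columns `transcript_id`, `sample`, `tpm`.
#' @param sample Sample identifier selecting the TPM column to gate on.
#' @return Data frame of database entries with columns `entry_id`,
#'   `sequence`, `provenance` (comma-joined when collapsed), `transcript_id`,
#'   `variant` (`NA` for canonical), `mut_start`, `mut_end`, `gene`.
#' @export
build_database <- function(transcripts, variants, tpm, sample) {
  stopifnot(all(c("transcript_id", "gene", "cds") %in% names(transcripts)))
  tpm_s <- tpm[tpm$sample == sample, , drop = FALSE]
  if (!nrow(tpm_s)) stop(sprintf("no TPM records for sample '%s'", sample),
                         call. = FALSE)
  expr <- setNames(tpm_s$tpm, tpm_s$transcript_id)
  missing_expr <- setdiff(transcripts$transcript_id, names(expr))
  if (length(missing_expr)) {
    stop(sprintf("missing TPM records for transcript(s): %s",
                 paste(missing_expr, collapse = ", ")), call. = FALSE)
  }
  if (nrow(variants)) {
    unknown <- setdiff(variants$transcript_id, transcripts$transcript_id)
    if (length(unknown)) {
      stop(sprintf("variants reference unknown transcript(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  expressed <- transcripts[expr[transcripts$transcript_id] > 0, , drop = FALSE]
  if (!nrow(expressed)) {
    stop("empty database: no transcript is expressed (all TPM = 0)",
         call. = FALSE)
  }

  rows <- vector("list", nrow(expressed) + nrow(variants))
  k <- 0L
  for (i in seq_len(nrow(expressed))) {
    tr <- expressed[i, ]
    prot <- translate_cds(tr$cds)
    if (!nchar(prot)) next
    k <- k + 1L
    rows[[k]] <- data.frame(
      sequence = prot, provenance = "canonical",
      transcript_id = tr$transcript_id, variant = NA_character_,
      mut_start = NA_integer_, mut_end = NA_integer_, gene = tr$gene,
      stringsAsFactors = FALSE)
  }
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, ]
      if (expr[[v$transcript_id]] <= 0) next
      tr <- transcripts[transcripts$transcript_id == v$transcript_id, ][1, ]
      if (v$vtype == "missense") {
        m <- apply_missense(tr$cds, v$cds_pos, v$ref, v$alt)
        w <- missense_window(m$protein, m$residue_index)
        prov <- "missense_window"
      } else if (v$vtype == "frameshift") {
        w <- frameshift_window(tr$cds, v$cds_pos, v$ref, v$alt)
        if (is.null(w)) next
        prov <- "frameshift_window"
      } else {
        stop(sprintf("unknown variant type '%s'", v$vtype), call. = FALSE)
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        sequence = w$sequence, provenance = prov,
        transcript_id = v$transcript_id,
        variant = variant_id(v$transcript_id, v$cds_pos, v$ref, v$alt),
        mut_start = w$mut_start, mut_end = w$mut_end, gene = tr$gene,
        stringsAsFactors = FALSE)
    }
  }
  db <- do.call(rbind, rows[seq_len(k)])
  if (is.null(db) || !nrow(db)) {
    stop("empty database after filtering", call. = FALSE)
  }

  # collapse exact-duplicate sequences, merging provenance and variant links
  db <- db[order(db$sequence, db$provenance, db$transcript_id), , drop = FALSE]
  grp <- split(seq_len(nrow(db)), db$sequence)
  merged <- lapply(grp, function(idx) {
    g <- db[idx, , drop = FALSE]
    vs <- unique(g$variant[!is.na(g$variant)])
    first_var <- which(!is.na(g$mut_start))
    data.frame(
      sequence = g$sequence[1L],
      provenance = paste(sort(unique(g$provenance)), collapse = ","),
      transcript_id = paste(sort(unique(g$transcript_id)), collapse = ","),
      variant = if (length(vs)) paste(sort(vs), collapse = ";") else NA_character_,
      mut_start = if (length(first_var)) g$mut_start[first_var[1L]] else NA_integer_,
      mut_end = if (length(first_var)) g$mut_end[first_var[1L]] else NA_integer_,
      gene = paste(sort(unique(g$gene)), collapse = ","),
      stringsAsFactors = FALSE)
  })
  db <- do.call(rbind, merged)
  rownames(db) <- NULL
  # stable ordering: canonical-first, then by transcript and sequence
  db <- db[order(db$provenance != "canonical", db$transcript_id, db$sequence), ,
           drop = FALSE]
  db$entry_id <- sprintf("%s|%s|%s|%s|mutreg=%s-%s",
                         sample, db$provenance, db$transcript_id,
                         ifelse(is.na(db$variant), "NA", db$variant),
                         ifelse(is.na(db$mut_start), "NA", db$mut_start),
                         ifelse(is.na(db$mut_end), "NA", db$mut_end))
  rownames(db) <- NULL
  db[, c("entry_id", "sequence", "provenance", "transcript_id", "variant",
         "mut_start", "mut_end", "gene")]
}

#' Write / read a search database as FASTA
#'
#' Headers use the dialect
#' `>{sample}|{provenance}|{transcript}|{variant-or-NA}|mutreg={a}-{b}`,
#' which is bit-stable so that a round trip preserves every entry field the
#' search stage needs.
#'
#' @param db Database data frame from [build_database()].
#' @param path Output FASTA path.
#' @return `path`, invisibly (writer); the database data frame (reader).
#' @export
write_database_fasta <- function(db, path) {
  seqs <- Biostrings::AAStringSet(db$sequence)
  names(seqs) <- db$entry_id
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' @rdname write_database_fasta
#' @export
read_database_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 5L
  if (any(bad)) {
    stop("malformed database FASTA header(s): ", ids[which(bad)[1L]],
         call. = FALSE)
  }
  fld <- function(i) vapply(parts, `[[`, "", i)
  mutreg <- sub("^mutreg=", "", fld(5L))
  mm <- strsplit(mutreg, "-", fixed = TRUE)
  data.frame(
    entry_id = ids,
    sequence = as.character(seqs),
    provenance = fld(2L),
    transcript_id = fld(3L),
    variant = ifelse(fld(4L) == "NA", NA_character_, fld(4L)),
    mut_start = suppressWarnings(as.integer(vapply(mm, `[[`, "", 1L))),
    mut_end = suppressWarnings(as.integer(vapply(mm, function(x) x[min(2L, length(x))], ""))),
    gene = NA_character_,
    stringsAsFactors = FALSE)
}
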