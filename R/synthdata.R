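# Seeded synthetic-data generators. Each generator emulates one input of the
# analysis (CDS transcripts with expression, somatic variants, ligandomes
# with controlled overlap, b/y-ion spectra, dose-response curves, clonotype
# tables) with the statistical structure the downstream stages assume, so the
# whole pipeline is testable without external data. All generators are
# byte-deterministic under a fixed seed and restore the caller's RNG state.

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Generate a synthetic transcript reference with per-sample expression
#'
#' Each CDS starts with ATG, ends with a stop codon and contains no internal
#' in-frame stop (body codons are drawn from the 61 sense codons), so every
#' transcript is translatable by construction. TPM values are drawn
#' log-normally per sample, with an exact `round(fraction_zero_tpm * n)`
#' transcripts set to TPM = 0 (the same transcripts in every sample, so the
#' expression gate acts consistently). Genes named in `fold_change` get
#' `tumor = fold * normal` expression, emulating tumor-overexpressed TAA
#' source genes; they are never zeroed.
#'
#' @param n_transcripts Number of transcripts.
#' @param cds_length_range Min/max CDS length in nt (rounded down to
#'   multiples of 3; minimum 120 nt).
#' @param tpm_meanlog,tpm_sdlog Log-normal TPM parameters.
#' @param fraction_zero_tpm Fraction of transcripts with TPM exactly 0.
#' @param samples Sample names; `fold_change` applies to samples named
#'   `"tumor"` vs `"normal"`.
#' @param fold_change Optional data frame with `gene` (an index into the
#'   generated genes, 1-based) and `fold`.
#' @param seed Integer seed.
#' @return List with `transcripts` (`transcript_id`, `gene`, `cds`) and
#'   `tpm` (`transcript_id`, `sample`, `tpm`).
#' @export
gen_reference <- function(n_transcripts = 60L,
                          cds_length_range = c(300L, 600L),
                          tpm_meanlog = 3, tpm_sdlog = 1.5,
                          fraction_zero_tpm = 0.1,
                          samples = c("tumor", "normal"),
                          fold_change = NULL,
                          seed = 1L) {
  if (min(cds_length_range) < 120L) {
    stop("degenerate CDS length range: minimum below 120 nt", call. = FALSE)
  }
  if (fraction_zero_tpm < 0 || fraction_zero_tpm > 1) {
    stop("fraction_zero_tpm must lie in [0, 1]", call. = FALSE)
  }
  sc <- sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  with_seed(stage_seed(seed, "gen_reference"), {
    lens <- 3L * sample(seq.int(cds_length_range[1L] %/% 3L,
                                cds_length_range[2L] %/% 3L),
                        n_transcripts, replace = TRUE)
    cds <- vapply(lens, function(L) {
      body <- sample(sc, L %/% 3L - 2L, replace = TRUE)
      paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
    }, "")
    ids <- sprintf("TX%04d", seq_len(n_transcripts))
    genes <- sprintf("GENE%04d", seq_len(n_transcripts))
    transcripts <- data.frame(transcript_id = ids, gene = genes, cds = cds,
                              stringsAsFactors = FALSE)
    fc_genes <- character(0)
    if (!is.null(fold_change) && nrow(fold_change)) {
      fc_genes <- genes[fold_change$gene]
    }
    n_zero <- round(fraction_zero_tpm * n_transcripts)
    eligible <- which(!(genes %in% fc_genes))
    if (n_zero > length(eligible)) {
      stop("fraction_zero_tpm incompatible with fold_change design",
           call. = FALSE)
    }
    zero_idx <- sort(sample(eligible, n_zero))
    base <- stats::rlnorm(n_transcripts, tpm_meanlog, tpm_sdlog)
    tpm_rows <- lapply(samples, function(s) {
      tpm <- base * stats::rlnorm(n_transcripts, 0, 0.2)
      tpm[zero_idx] <- 0
      data.frame(transcript_id = ids, sample = s, tpm = tpm,
                 stringsAsFactors = FALSE)
    })
    tpm <- do.call(rbind, tpm_rows)
    if (length(fc_genes)) {
      for (i in seq_len(nrow(fold_change))) {
        g <- genes[fold_change$gene[i]]
        tr <- ids[fold_change$gene[i]]
        nrm <- tpm$sample == "normal" & tpm$transcript_id == tr
        tmr <- tpm$sample == "tumor" & tpm$transcript_id == tr
        if (any(nrm) && any(tmr)) {
          tpm$tpm[tmr] <- tpm$tpm[nrm] * fold_change$fold[i]
        }
      }
    }
    rownames(tpm) <- NULL
    list(transcripts = transcripts, tpm = tpm)
  })
}

# pick an alternate nucleotide making a nonsynonymous, non-stop, non-start
# substitution at cds position pos; NA when no such alternate exists
valid_missense_alt <- function(cds, pos) {
  codon_i <- (pos + 2L) %/% 3L
  cstart <- (codon_i - 1L) * 3L + 1L
  wt_codon <- substr(cds, cstart, cstart + 2L)
  wt_aa <- unname(Biostrings::GENETIC_CODE[wt_codon])
  if (wt_aa == "*" || codon_i == 1L) return(NA_character_)
  ref <- substr(cds, pos, pos)
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  ok <- vapply(alts, function(a) {
    mc <- wt_codon
    substr(mc, pos - cstart + 1L, pos - cstart + 1L) <- a
    aa <- unname(Biostrings::GENETIC_CODE[mc])
    aa != wt_aa && aa != "*"
  }, TRUE)
  if (!any(ok)) return(NA_character_)
  alts[ok][1L]
}

#' Generate somatic variants on a transcript set
#'
#' Missense SNVs are verified nonsynonymous against the genetic code (stop
#' gains and start losses are never emitted); frameshifts are 1- or 2-nt
#' insertions/deletions placed away from the first and last codons.
#' Supporting read counts are drawn per variant with
#' `depth ~ Poisson(mean_depth)` and `alt_reads ~ Binomial(depth, vaf_mean)`.
#'
#' @param transcripts Transcript data frame from [gen_reference()].
#' @param n_missense,n_frameshift Requested variant counts.
#' @param mean_depth,vaf_mean Read-count model parameters.
#' @param seed Integer seed.
#' @return Variant data frame (`transcript_id`, `cds_pos`, `ref`, `alt`,
#'   `vtype`, `alt_reads`, `depth`).
#' @export
gen_variants <- function(transcripts, n_missense = 30L, n_frameshift = 10L,
                         mean_depth = 200, vaf_mean = 0.25, seed = 1L) {
  if (!nrow(transcripts)) stop("empty transcript set", call. = FALSE)
  with_seed(stage_seed(seed, "gen_variants"), {
    used <- character(0)
    rows <- list()
    draw_reads <- function() {
      depth <- max(10L, stats::rpois(1L, mean_depth))
      c(alt = stats::rbinom(1L, depth, vaf_mean), depth = depth)
    }
    tries <- 0L
    max_tries <- 200L * (n_missense + n_frameshift + 1L)
    while (length(rows) < n_missense) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("requested missense count exceeds available non-degenerate sites",
             call. = FALSE)
      }
      i <- sample(nrow(transcripts), 1L)
      cds <- transcripts$cds[i]
      pos <- sample(seq.int(4L, nchar(cds) - 3L), 1L)
      key <- paste(transcripts$transcript_id[i], pos)
      if (key %in% used) next
      alt <- valid_missense_alt(cds, pos)
      if (is.na(alt)) next
      used <- c(used, key)
      rd <- draw_reads()
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = transcripts$transcript_id[i], cds_pos = pos,
        ref = substr(cds, pos, pos), alt = alt, vtype = "missense",
        alt_reads = unname(rd["alt"]), depth = unname(rd["depth"]),
        stringsAsFactors = FALSE)
    }
    n_fs <- 0L
    while (n_fs < n_frameshift) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("requested frameshift count exceeds available sites",
             call. = FALSE)
      }
      i <- sample(nrow(transcripts), 1L)
      cds <- transcripts$cds[i]
      pos <- sample(seq.int(4L, nchar(cds) - 9L), 1L)
      key <- paste(transcripts$transcript_id[i], pos)
      if (key %in% used) next
      used <- c(used, key)
      d <- sample(1:2, 1L)
      if (stats::runif(1L) < 0.5) {
        ref <- substr(cds, pos, pos + d)  # deletion of d nt
        alt <- substr(cds, pos, pos)
      } else {
        ref <- substr(cds, pos, pos)      # insertion of d nt
        alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), d,
                                        replace = TRUE), collapse = ""))
      }
      rd <- draw_reads()
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = transcripts$transcript_id[i], cds_pos = pos,
        ref = ref, alt = alt, vtype = "frameshift",
        alt_reads = unname(rd["alt"]), depth = unname(rd["depth"]),
        stringsAsFactors = FALSE)
      n_fs <- n_fs + 1L
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# draw n distinct 8-11mer substrings from a set of protein sequences
sample_peptides <- function(proteins, n, lengths = 8:11, exclude = character(0)) {
  long_enough <- proteins[nchar(proteins) >= max(lengths)]
  if (!length(long_enough)) stop("no protein long enough", call. = FALSE)
  got <- character(0)
  tries <- 0L
  while (length(got) < n) {
    tries <- tries + 1L
    if (tries > 200L * n + 1000L) {
      stop("requested peptide count exceeds substring diversity",
           call. = FALSE)
    }
    p <- long_enough[sample.int(length(long_enough), 1L)]
    k <- lengths[sample.int(length(lengths), 1L)]  # sample() misreads a scalar
    if (nchar(p) < k) next
    s <- sample(nchar(p) - k + 1L, 1L)
    pep <- substr(p, s, s + k - 1L)
    if (pep %in% got || pep %in% exclude) next
    got <- c(got, pep)
  }
  got
}

#' Generate tumor and normal ligandome peptide tables with controlled overlap
#'
#' Draws 8-11mer substrings of the supplied proteome and realizes the
#' configured sharing design exactly: `n_shared` peptides appear in both the
#' tumor and the normal sample, the remainders are private. Peptides of
#' genes listed in `taa_genes` are planted into the tumor-only set (one
#' 9-mer per gene), emulating tumor-restricted ligands from overexpressed
#' source genes.
#'
#' @param proteins Data frame with `gene` and `sequence` (canonical
#'   translations).
#' @param n_tumor,n_normal,n_shared Set sizes; the intersection is exactly
#'   `n_shared`.
#' @param taa_genes Character vector of gene names to plant tumor-only
#'   peptides from.
#' @param seed Integer seed.
#' @return Data frame (`sample`, `tissue`, `peptide`) with attribute
#'   `planted_taa` (data frame `peptide`, `gene`).
#' @export
gen_ligandomes <- function(proteins, n_tumor = 100L, n_normal = 100L,
                           n_shared = 40L, taa_genes = character(0),
                           seed = 1L) {
  if (!nrow(proteins)) stop("empty proteome", call. = FALSE)
  if (n_shared > min(n_tumor, n_normal)) {
    stop("n_shared exceeds a set size", call. = FALSE)
  }
  with_seed(stage_seed(seed, "gen_ligandomes"), {
    planted <- data.frame(peptide = character(0), gene = character(0),
                          stringsAsFactors = FALSE)
    for (g in taa_genes) {
      seqs <- proteins$sequence[proteins$gene == g]
      if (!length(seqs)) stop(sprintf("taa gene '%s' not in proteome", g),
                              call. = FALSE)
      pep <- sample_peptides(seqs[1L], 1L, lengths = 9L,
                             exclude = planted$peptide)
      planted <- rbind(planted, data.frame(peptide = pep, gene = g,
                                           stringsAsFactors = FALSE))
    }
    n_planted <- nrow(planted)
    if (n_planted > n_tumor - n_shared) {
      stop("tumor-only capacity too small for the planted TAA design",
           call. = FALSE)
    }
    # exclude TAA-gene proteins from the general draw so planted peptides
    # stay tumor-restricted
    other <- proteins$sequence[!(proteins$gene %in% taa_genes)]
    n_draw <- n_tumor + n_normal - n_shared - n_planted
    pool <- sample_peptides(other, n_draw, exclude = planted$peptide)
    shared <- pool[seq_len(n_shared)]
    tumor_only <- c(planted$peptide,
                    pool[n_shared + seq_len(n_tumor - n_shared - n_planted)])
    normal_only <- pool[n_tumor - n_planted + seq_len(n_normal - n_shared)]
    out <- rbind(
      data.frame(sample = "tumor1", tissue = "tumor",
                 peptide = c(shared, tumor_only), stringsAsFactors = FALSE),
      data.frame(sample = "normal1", tissue = "normal",
                 peptide = c(shared, normal_only), stringsAsFactors = FALSE))
    rownames(out) <- NULL
    attr(out, "planted_taa") <- planted
    out
  })
}

#' Generate MS/MS spectra with ground truth
#'
#' One spectrum per input peptide at a sampled charge in \{1, 2, 3\}:
#' precursor m/z exact for the peptide, all singly-protonated b/y fragments
#' with Gaussian m/z jitter (keep `jitter_sd` at or below a third of the
#' fragment tolerance), log-normal fragment intensities and uniform noise
#' peaks. A fraction of "foreign" spectra is generated from shuffled copies
#' of the input peptides — peptides absent from any database but with
#' identical composition, which makes target-decoy competition nontrivial.
#'
#' @param true_peptides Character vector of 8-11mers (e.g. database
#'   substrings).
#' @param n_foreign Number of additional foreign spectra.
#' @param jitter_sd Fragment m/z jitter standard deviation in Da.
#' @param n_noise_peaks Noise peaks per spectrum.
#' @param seed Integer seed.
#' @return List with `spectra` (list, see [search_spectra()]) and `truth`
#'   (`spectrum_id`, `peptide`, `charge`, `is_foreign`).
#' @export
gen_spectra <- function(true_peptides, n_foreign = 0L, jitter_sd = 0.004,
                        n_noise_peaks = 10L, seed = 1L) {
  lens <- nchar(true_peptides)
  if (any(lens < 8L | lens > 11L)) {
    stop("peptides must be 8-11 residues", call. = FALSE)
  }
  with_seed(stage_seed(seed, "gen_spectra"), {
    shuffle_new <- function(p) {
      for (i in 1:50) {
        s <- paste(sample(str_residues(p)), collapse = "")
        if (s != p) return(s)
      }
      p  # homopolymer; caller tolerates
    }
    foreign <- if (n_foreign > 0L) {
      vapply(sample(true_peptides, n_foreign, replace = TRUE), shuffle_new, "")
    } else character(0)
    peps <- c(true_peptides, foreign)
    is_foreign <- c(rep(FALSE, length(true_peptides)),
                    rep(TRUE, length(foreign)))
    spectra <- vector("list", length(peps))
    truth <- data.frame(spectrum_id = sprintf("scan%04d", seq_along(peps)),
                        peptide = peps, charge = NA_integer_,
                        is_foreign = is_foreign, stringsAsFactors = FALSE)
    for (i in seq_along(peps)) {
      p <- peps[i]
      z <- sample(1:3, 1L, prob = c(0.2, 0.5, 0.3))
      truth$charge[i] <- z
      ions <- fragment_ions(p)
      theo <- c(ions$b, ions$y)
      mz <- theo + stats::rnorm(length(theo), 0, jitter_sd)
      inten <- stats::rlnorm(length(theo), log(100), 0.4)
      if (n_noise_peaks > 0L) {
        nm <- stats::runif(n_noise_peaks, 100, max(theo) + 50)
        mz <- c(mz, nm)
        inten <- c(inten, stats::runif(n_noise_peaks, 1, 20))
      }
      ord <- order(mz)
      spectra[[i]] <- list(
        spectrum_id = truth$spectrum_id[i],
        precursor_mz = precursor_mz(peptide_mass(p), z),
        charge = z, mz = mz[ord], intensity = inten[ord])
    }
    list(spectra = spectra, truth = truth)
  })
}

#' Generate a 4PL dose-response table
#'
#' Responses follow `bottom + (top - bottom) / (1 + (ec50/x)^hill)` plus
#' Gaussian noise, with `replicates` independent wells per dose (titration
#' assays are read out in replicate wells; the default of 3 mirrors the
#' usual triplicate design). An EC50 outside the concentration range is
#' flagged with a warning (the fit is then poorly constrained).
#'
#' @param ec50,hill,top,bottom 4PL parameters (EC50 in concentration units).
#' @param concentrations Strictly positive dose vector (distinct doses).
#' @param noise_sd Gaussian noise standard deviation (response units,
#'   per well).
#' @param replicates Wells per dose.
#' @param seed Integer seed.
#' @return Data frame (`concentration`, `response`), one row per well.
#' @export
gen_dose_response <- function(ec50 = 1.5, hill = 1, top = 100, bottom = 0,
                              concentrations = 10^seq(-2, 2, length.out = 8),
                              noise_sd = 0, replicates = 3L, seed = 1L) {
  if (any(concentrations <= 0)) stop("concentrations must be positive",
                                     call. = FALSE)
  if (ec50 < min(concentrations) || ec50 > max(concentrations)) {
    warning("ec50 lies outside the concentration range")
  }
  conc <- rep(concentrations, each = replicates)
  with_seed(stage_seed(seed, "gen_dose_response"), {
    mu <- bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
    data.frame(concentration = conc,
               response = mu + stats::rnorm(length(mu), 0, noise_sd))
  })
}

#' Generate a TCR-beta clonotype table with planted expanded clones
#'
#' Background clonotypes get random CDR3s and V/D/J/C gene calls with
#' expected frequencies from a heavy-tailed weight distribution; planted
#' clones get their configured expected frequencies. Counts are multinomial
#' over `total_counts` reads, so a planted frequency f has binomial sampling
#' error sqrt(f(1-f)/total_counts).
#'
#' @param n_clones Number of background clonotypes.
#' @param planted Optional data frame with `frequency` (expected) and
#'   optionally `cdr3_aa`, `v_gene`, `d_gene`, `j_gene`, `c_gene`.
#' @param total_counts Total repertoire read count.
#' @param seed Integer seed.
#' @return Clonotype data frame (`cdr3_aa`, `v_gene`, `d_gene`, `j_gene`,
#'   `c_gene`, `count`) with attribute `planted` (CDR3s of planted clones).
#' @export
gen_clonotypes <- function(n_clones = 200L, planted = NULL,
                           total_counts = 100000L, seed = 1L) {
  p_freq <- if (is.null(planted)) numeric(0) else planted$frequency
  if (sum(p_freq) > 1) stop("planted frequencies sum above 1", call. = FALSE)
  with_seed(stage_seed(seed, "gen_clonotypes"), {
    rand_cdr3 <- function(n) {
      vapply(seq_len(n), function(i) {
        paste0("CASS", paste(sample(AA20, sample(4:8, 1L), replace = TRUE),
                             collapse = ""), "QYF")
      }, "")
    }
    cdr3 <- unique(rand_cdr3(n_clones * 2L))[seq_len(n_clones)]
    vg <- sprintf("TRBV%d-1", sample(2:30, n_clones, replace = TRUE))
    dg <- sprintf("TRBD%d", sample(1:2, n_clones, replace = TRUE))
    jg <- sprintf("TRBJ%d-%d", sample(1:2, n_clones, replace = TRUE),
                  sample(1:7, n_clones, replace = TRUE))
    cg <- sprintf("TRBC%d", sample(1:2, n_clones, replace = TRUE))
    tab <- data.frame(cdr3_aa = cdr3, v_gene = vg, d_gene = dg, j_gene = jg,
                      c_gene = cg, stringsAsFactors = FALSE)
    probs <- stats::rexp(n_clones)
    probs <- probs / sum(probs) * (1 - sum(p_freq))
    planted_cdr3 <- character(0)
    if (length(p_freq)) {
      np <- length(p_freq)
      pl <- data.frame(
        cdr3_aa = if ("cdr3_aa" %in% names(planted)) planted$cdr3_aa else
          rand_cdr3(np),
        v_gene = if ("v_gene" %in% names(planted)) planted$v_gene else
          sprintf("TRBV%d-1", sample(2:30, np, replace = TRUE)),
        d_gene = if ("d_gene" %in% names(planted)) planted$d_gene else
          sprintf("TRBD%d", sample(1:2, np, replace = TRUE)),
        j_gene = if ("j_gene" %in% names(planted)) planted$j_gene else
          sprintf("TRBJ%d-%d", sample(1:2, np, replace = TRUE),
                  sample(1:7, np, replace = TRUE)),
        c_gene = if ("c_gene" %in% names(planted)) planted$c_gene else
          sprintf("TRBC%d", sample(1:2, np, replace = TRUE)),
        stringsAsFactors = FALSE)
      planted_cdr3 <- pl$cdr3_aa
      tab <- rbind(pl, tab)
      probs <- c(p_freq, probs)
    }
    counts <- as.integer(stats::rmultinom(1L, total_counts, probs))
    tab$count <- counts
    tab <- tab[tab$count > 0L, , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "planted") <- planted_cdr3
    tab
  })
}

#' Write / read a transcript reference as FASTA
#'
#' Headers carry the gene symbol as `>{transcript_id} gene={gene}`.
#'
#' @param transcripts Transcript data frame (`transcript_id`, `gene`,
#'   `cds`).
#' @param path FASTA path.
#' @return `path` invisibly (writer); transcript data frame (reader).
#' @export
write_transcripts_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(transcripts$cds)
  names(seqs) <- sprintf("%s gene=%s", transcripts$transcript_id,
                         transcripts$gene)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' @rdname write_transcripts_fasta
#' @export
read_transcripts_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub(" .*$", "", names(seqs))
  gene <- sub("^.* gene=", "", names(seqs))
  data.frame(transcript_id = unname(ids), gene = unname(gene),
             cds = unname(as.character(seqs)), stringsAsFactors = FALSE)
}
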