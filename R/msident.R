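# Simplified no-enzyme MS/MS identification: theoretical b/y fragments,
# tolerant matching, hyperscore-style scoring, concatenated target-decoy
# q-values and FDR filtering.

#' Monoisotopic residue masses and mass constants
#'
#' Standard monoisotopic masses (Da) of the 20 amino-acid residues, plus the
#' proton, water and methionine-oxidation (+15.994915 Da) constants used in
#' all mass arithmetic.
#' @format Named numeric vector (`AA_MONO`) and numeric scalars.
#' @export
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

#' @rdname AA_MONO
#' @export
MASS_PROTON <- 1.00727646688

#' @rdname AA_MONO
#' @export
MASS_WATER <- 18.0105646863

#' @rdname AA_MONO
#' @export
MASS_OX <- 15.994915

#' Monoisotopic peptide mass and precursor m/z
#'
#' `peptide_mass()` sums residue masses plus one water, adding +15.994915 Da
#' per methionine oxidation; `precursor_mz()` converts a neutral mass to m/z
#' at charge `z`, and `neutral_mass()` inverts it.
#'
#' @param peptide Amino-acid string (standard 20 residues).
#' @param n_ox Number of oxidized methionines (must not exceed the Met
#'   count).
#' @param mass Neutral monoisotopic mass (Da).
#' @param mz Observed precursor m/z (Th).
#' @param z Charge state (>= 1).
#' @return Mass in Da, or m/z in Th.
#' @export
peptide_mass <- function(peptide, n_ox = 0L) {
  assert_aa(peptide)
  res <- str_residues(peptide)
  n_met <- sum(res == "M")
  if (n_ox > n_met) stop("more oxidations than methionines", call. = FALSE)
  sum(AA_MONO[res]) + MASS_WATER + n_ox * MASS_OX
}

#' @rdname peptide_mass
#' @export
precursor_mz <- function(mass, z) {
  stopifnot(z >= 1)
  (mass + z * MASS_PROTON) / z
}

#' @rdname peptide_mass
#' @export
neutral_mass <- function(mz, z) {
  z * mz - z * MASS_PROTON
}

#' Singly-protonated b- and y-ion ladders
#'
#' For a peptide of length L, returns the L-1 b-ions (prefix mass + proton)
#' and L-1 y-ions (suffix mass + water + proton). Oxidized methionines add
#' +15.994915 Da to every fragment containing them.
#'
#' @param peptide Amino-acid string, length >= 2.
#' @param ox_positions Integer positions (1-based) of oxidized methionines.
#' @return List with numeric vectors `b` and `y` (index k = ion number).
#' @export
fragment_ions <- function(peptide, ox_positions = integer(0)) {
  assert_aa(peptide)
  res <- str_residues(peptide)
  L <- length(res)
  if (L < 2L) stop("fragmentation requires length >= 2", call. = FALSE)
  m <- unname(AA_MONO[res])
  if (length(ox_positions)) {
    if (any(res[ox_positions] != "M")) {
      stop("oxidation on a non-methionine residue", call. = FALSE)
    }
    m[ox_positions] <- m[ox_positions] + MASS_OX
  }
  pre <- cumsum(m)
  b <- pre[seq_len(L - 1L)] + MASS_PROTON
  y <- (pre[L] - pre[seq_len(L - 1L)]) + MASS_WATER + MASS_PROTON
  list(b = b, y = rev(y)[seq_len(L - 1L)])
}

# all combinations of up to max_ox oxidations over the Met positions of a
# peptide; returns a list of integer vectors (first element = no oxidation)
ox_combinations <- function(peptide, max_ox = 2L) {
  mpos <- which(str_residues(peptide) == "M")
  combos <- list(integer(0))
  k_max <- min(length(mpos), max_ox)
  if (k_max >= 1L) {
    for (k in seq_len(k_max)) {
      # index-based combn: combn(x, k) misreads a length-1 x as seq_len(x)
      cc <- utils::combn(seq_along(mpos), k, simplify = FALSE)
      combos <- c(combos, lapply(cc, function(ii) mpos[ii]))
    }
  }
  combos
}

#' Build the no-enzyme peptide index over a concatenated target-decoy database
#'
#' Enumerates every distinct 8-11mer substring of every database entry
#' (no-enzyme digestion), together with 0..`max_ox` methionine-oxidation
#' variants, and does the same for decoy entries formed by reversing each
#' database sequence. A peptide found in both the target and the decoy set is
#' assigned to the target set. Each target peptide keeps its source entries
#' so accepted peptides can later be classified as neoantigen
#' (all sources are variant entries and the peptide overlaps the mutated
#' region) or wild type.
#'
#' @param db Database data frame from [build_database()] (or
#'   [read_database_fasta()]).
#' @param lengths Peptide lengths to index (default 8-11).
#' @param max_ox Maximum variable methionine oxidations per peptide.
#' @return An object of class `peptide_index`: a mass-sorted table of
#'   (peptide, oxidation variant, neutral mass, decoy flag) rows plus
#'   per-peptide source annotation.
#' @export
build_index <- function(db, lengths = 8:11, max_ox = 2L) {
  if (!nrow(db)) stop("empty database", call. = FALSE)
  enumerate <- function(seqs, ids) {
    out <- list()
    for (i in seq_along(seqs)) {
      s <- seqs[i]
      L <- nchar(s)
      for (k in lengths) {
        if (L < k) next
        starts <- seq_len(L - k + 1L)
        out[[length(out) + 1L]] <- data.frame(
          peptide = substring(s, starts, starts + k - 1L),
          entry = ids[i], start = starts, stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(peptide = character(0), entry = character(0),
                 start = integer(0), stringsAsFactors = FALSE)
  }

  tgt_occ <- enumerate(db$sequence, db$entry_id)
  is_var <- !is.na(db$mut_start)
  names(is_var) <- db$entry_id
  ms <- setNames(db$mut_start, db$entry_id)
  me <- setNames(db$mut_end, db$entry_id)

  # per-occurrence: does the placement overlap the entry's mutated region?
  occ_var <- is_var[tgt_occ$entry]
  occ_ov <- rep(FALSE, nrow(tgt_occ))
  vi <- which(occ_var)
  if (length(vi)) {
    a <- ms[tgt_occ$entry[vi]]
    b <- me[tgt_occ$entry[vi]]
    s <- tgt_occ$start[vi]
    k <- nchar(tgt_occ$peptide[vi])
    occ_ov[vi] <- (s <= b) & (s + k - 1L >= a)
  }
  # aggregate per peptide
  pep_split <- split(seq_len(nrow(tgt_occ)), tgt_occ$peptide)
  tgt_peps <- names(pep_split)
  any_canonical <- vapply(pep_split, function(idx) any(!occ_var[idx]), TRUE)
  any_overlap <- vapply(pep_split, function(idx) any(occ_ov[idx]), TRUE)
  sources <- vapply(pep_split, function(idx) {
    paste(sort(unique(tgt_occ$entry[idx])), collapse = ";")
  }, "")

  dec_occ <- enumerate(vapply(db$sequence, function(s) {
    paste(rev(str_residues(s)), collapse = "")
  }, ""), paste0("DECOY_", db$entry_id))
  dec_peps <- setdiff(unique(dec_occ$peptide), tgt_peps)

  # vectorized neutral masses (base, no modification)
  base_mass <- function(peptides) {
    out <- numeric(length(peptides))
    lens <- nchar(peptides)
    for (L in unique(lens)) {
      ii <- which(lens == L)
      aidx <- match(unlist(strsplit(peptides[ii], "", fixed = TRUE)),
                    names(AA_MONO))
      if (anyNA(aidx)) stop("unknown residue symbol in database", call. = FALSE)
      out[ii] <- rowSums(matrix(AA_MONO[aidx], ncol = L, byrow = TRUE)) +
        MASS_WATER
    }
    out
  }

  expand_ox <- function(peptides, is_decoy) {
    bm <- base_mass(peptides)
    mpos_list <- gregexpr("M", peptides, fixed = TRUE)
    has_m <- which(vapply(mpos_list, function(x) x[1L] != -1L, TRUE))
    extra <- vector("list", length(has_m))
    for (j in seq_along(has_m)) {
      i <- has_m[j]
      mp <- as.integer(mpos_list[[i]])
      kmax <- min(length(mp), max_ox)
      combos <- list()
      for (k in seq_len(kmax)) {
        cc <- utils::combn(seq_along(mp), k, simplify = FALSE)
        combos <- c(combos, lapply(cc, function(ii) mp[ii]))
      }
      extra[[j]] <- list(
        pep = rep(peptides[i], length(combos)),
        nox = lengths(combos),
        pos = vapply(combos, paste, "", collapse = ","),
        mass = bm[i] + lengths(combos) * MASS_OX)
    }
    data.frame(
      peptide = c(peptides, unlist(lapply(extra, `[[`, "pep"))),
      n_ox = c(rep(0L, length(peptides)),
               as.integer(unlist(lapply(extra, `[[`, "nox")))),
      ox_pos = c(rep("", length(peptides)),
                 as.character(unlist(lapply(extra, `[[`, "pos")))),
      mass = c(bm, as.numeric(unlist(lapply(extra, `[[`, "mass")))),
      is_decoy = is_decoy, stringsAsFactors = FALSE)
  }
  tab <- rbind(expand_ox(tgt_peps, FALSE),
               if (length(dec_peps)) expand_ox(dec_peps, TRUE))
  tab <- tab[order(tab$mass, tab$peptide, tab$n_ox), , drop = FALSE]
  rownames(tab) <- NULL
  ann <- data.frame(peptide = tgt_peps, any_canonical = unname(any_canonical),
                    any_overlap = unname(any_overlap),
                    sources = unname(sources), stringsAsFactors = FALSE)
  structure(list(table = tab, annotation = ann, lengths = lengths,
                 max_ox = max_ox, n_target = length(tgt_peps),
                 n_decoy = length(dec_peps)),
            class = "peptide_index")
}

#' Search spectra against a peptide index
#'
#' For each spectrum, candidate peptides are index rows whose neutral mass
#' lies within `prec_tol_ppm` of the observed neutral mass (tolerance applied
#' on neutral mass, so behavior is charge independent). Each candidate is
#' scored with a log-hyperscore: `log(sum of matched peak intensities) +
#' log((#matched b)!) + log((#matched y)!)`, matching singly-protonated b/y
#' ions within `frag_tol` Da. The best candidate per spectrum is retained;
#' exact score ties prefer a target over a decoy, then the lexicographically
#' smallest peptide. Spectra with no candidate or no matched ion are recorded
#' as unidentified (absent from the output).
#'
#' @param spectra List of spectra, each a list with `spectrum_id`,
#'   `precursor_mz`, `charge`, `mz`, `intensity` (see [read_mgf()]).
#' @param index [build_index()] result.
#' @param prec_tol_ppm Precursor tolerance in ppm (default 10).
#' @param frag_tol Fragment tolerance in Da (default 0.02).
#' @return Data frame of PSMs: `spectrum_id`, `peptide`, `ox_pos`, `n_ox`,
#'   `is_decoy`, `score`, `matched_b`, `matched_y`, `matched_ions`.
#' @export
search_spectra <- function(spectra, index, prec_tol_ppm = 10, frag_tol = 0.02) {
  tab <- index$table
  masses <- tab$mass
  rows <- list()
  for (sp in spectra) {
    obs <- neutral_mass(sp$precursor_mz, sp$charge)
    tol <- obs * prec_tol_ppm * 1e-6
    lo <- findInterval(obs - tol, masses) + 1L
    hi <- findInterval(obs + tol, masses)
    if (lo > hi) next
    best <- NULL
    for (j in lo:hi) {
      pep <- tab$peptide[j]
      oxp <- if (nzchar(tab$ox_pos[j])) {
        as.integer(strsplit(tab$ox_pos[j], ",", fixed = TRUE)[[1L]])
      } else integer(0)
      ions <- fragment_ions(pep, oxp)
      match_peaks <- function(theo) {
        # nearest observed peak within tolerance, per theoretical ion
        idx <- findInterval(theo, sp$mz)
        pick <- integer(0)
        for (t in seq_along(theo)) {
          cand <- c(idx[t], idx[t] + 1L)
          cand <- cand[cand >= 1L & cand <= length(sp$mz)]
          if (!length(cand)) next
          d <- abs(sp$mz[cand] - theo[t])
          if (min(d) <= frag_tol) pick <- c(pick, cand[which.min(d)])
        }
        unique(pick)
      }
      pb <- match_peaks(ions$b)
      py <- match_peaks(ions$y)
      n_b <- length(pb)
      n_y <- length(py)
      if (n_b + n_y == 0L) next
      inten <- sum(sp$intensity[unique(c(pb, py))])
      score <- log(inten) + lfactorial(n_b) + lfactorial(n_y)
      cand <- list(peptide = pep, ox_pos = tab$ox_pos[j], n_ox = tab$n_ox[j],
                   is_decoy = tab$is_decoy[j], score = score,
                   matched_b = n_b, matched_y = n_y)
      if (is.null(best) || score > best$score ||
          (score == best$score && best$is_decoy && !cand$is_decoy) ||
          (score == best$score && best$is_decoy == cand$is_decoy &&
           pep < best$peptide)) {
        best <- cand
      }
    }
    if (is.null(best)) next
    rows[[length(rows) + 1L]] <- data.frame(
      spectrum_id = sp$spectrum_id, peptide = best$peptide,
      ox_pos = best$ox_pos, n_ox = best$n_ox, is_decoy = best$is_decoy,
      score = best$score, matched_b = best$matched_b,
      matched_y = best$matched_y,
      matched_ions = best$matched_b + best$matched_y,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(spectrum_id = character(0), peptide = character(0),
                      ox_pos = character(0), n_ox = integer(0),
                      is_decoy = logical(0), score = numeric(0),
                      matched_b = integer(0), matched_y = integer(0),
                      matched_ions = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Target-decoy q-values and FDR filtering
#'
#' `compute_qvalues()` annotates PSMs with q-values from concatenated
#' target-decoy competition: at score threshold s, the raw FDR estimate is
#' `#decoys >= s / max(1, #targets >= s)`, and the q-value is the minimum raw
#' FDR over all thresholds at or below s (monotonized, so q is nonincreasing
#' in score). `filter_fdr()` keeps target PSMs with `q <= alpha`, collapses
#' them to best-PSM-per-peptide, and classifies each accepted peptide as
#' neoantigen when every database source is a variant entry and the peptide
#' overlaps the mutated region.
#'
#' @param psms PSM data frame from [search_spectra()].
#' @param alpha Peptide acceptance threshold on the q-value (default 0.01).
#' @param index The [build_index()] used for the search (source annotation).
#' @return `compute_qvalues()`: the PSM data frame with a `q_value` column.
#'   `filter_fdr()`: list with `psms` (accepted target PSMs) and `peptides`
#'   (best PSM per accepted peptide with `is_neoantigen`).
#' @export
compute_qvalues <- function(psms) {
  if (!nrow(psms)) {
    psms$q_value <- numeric(0)
    return(psms)
  }
  if (!any(!psms$is_decoy)) stop("no target PSMs", call. = FALSE)
  ord <- order(-psms$score)
  dec <- psms$is_decoy[ord]
  cum_dec <- cumsum(dec)
  cum_tgt <- cumsum(!dec)
  fdr <- cum_dec / pmax(1L, cum_tgt)
  # score ties share one threshold: every PSM in a tie group gets the
  # counts accumulated at the end of the group
  s <- psms$score[ord]
  fdr <- stats::ave(fdr, s, FUN = function(x) x[length(x)])
  q <- rev(cummin(rev(fdr)))
  psms$q_value <- NA_real_
  psms$q_value[ord] <- q
  psms
}

#' @rdname compute_qvalues
#' @export
filter_fdr <- function(psms, alpha = 0.01, index = NULL) {
  if (!"q_value" %in% names(psms)) psms <- compute_qvalues(psms)
  acc <- psms[!psms$is_decoy & psms$q_value <= alpha, , drop = FALSE]
  if (nrow(acc)) {
    ord <- order(-acc$score, acc$peptide)
    acc <- acc[ord, , drop = FALSE]
    pep <- acc[!duplicated(acc$peptide), , drop = FALSE]
  } else {
    pep <- acc
  }
  if (!is.null(index) && nrow(pep)) {
    ann <- index$annotation
    m <- match(pep$peptide, ann$peptide)
    pep$is_neoantigen <- !is.na(m) & !ann$any_canonical[m] & ann$any_overlap[m]
    pep$sources <- ifelse(is.na(m), NA_character_, ann$sources[m])
  } else if (nrow(pep)) {
    pep$is_neoantigen <- NA
    pep$sources <- NA_character_
  } else {
    pep$is_neoantigen <- logical(0)
    pep$sources <- character(0)
  }
  rownames(acc) <- NULL
  rownames(pep) <- NULL
  list(psms = acc, peptides = pep)
}

#' Write and read MGF spectrum files
#'
#' Minimal MGF dialect: `BEGIN IONS` / `TITLE=` / `PEPMASS=` / `CHARGE=n+` /
#' one `mz intensity` pair per line / `END IONS`. Peaks are kept sorted by
#' m/z.
#'
#' @param spectra List of spectra (see [search_spectra()] for the fields).
#' @param path File path.
#' @return `path` invisibly (writer); list of spectra (reader).
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    ord <- order(sp$mz)
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", sp$spectrum_id),
      paste0("PEPMASS=", format(sp$precursor_mz, digits = 12)),
      paste0("CHARGE=", sp$charge, "+"),
      paste(format(sp$mz[ord], digits = 12),
            format(sp$intensity[ord], digits = 8)),
      "END IONS", ""), con)
  }
  invisible(path)
}

#' @rdname write_mgf
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends)) stop("malformed MGF", call. = FALSE)
  lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    hdr <- block[kv]
    get <- function(key) {
      hit <- hdr[startsWith(hdr, paste0(key, "="))]
      if (!length(hit)) return(NA_character_)
      sub(paste0("^", key, "="), "", hit[1L])
    }
    peaks <- do.call(rbind, strsplit(trimws(block[!kv & nzchar(block)]),
                                     "[ \t]+"))
    mz <- as.numeric(peaks[, 1L])
    ord <- order(mz)
    list(spectrum_id = get("TITLE"),
         precursor_mz = as.numeric(strsplit(get("PEPMASS"), " ")[[1L]][1L]),
         charge = as.integer(sub("\\+$", "", get("CHARGE"))),
         mz = mz[ord],
         intensity = as.numeric(peaks[, 2L])[ord])
  })
}
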