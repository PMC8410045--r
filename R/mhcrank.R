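# Peptide-MHC binding with percentile-rank semantics through a pluggable
# scorer, plus mutant 8-11mer enumeration and the in-silico prediction stage.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Position-weight-matrix binding scorer with HLA-A24-like anchors
#'
#' A deterministic, versioned stand-in for an MHC binding predictor. One
#' log-weight matrix per supported peptide length (8-11); the primary anchor
#' at P2 favors Tyr/Phe and the C-terminal anchor favors Phe/Leu/Ile/Trp,
#' emulating the HLA-A*24:02 binding motif. Non-anchor weights are small
#' seeded Gaussian perturbations so that scores are continuous. Higher score
#' means stronger predicted binding. Any object with a `score_peptides()`
#' method and a `lengths` field satisfies the scorer contract, so a wrapper
#' around an external predictor can be dropped in.
#'
#' @param seed Integer seed fixing the non-anchor weights.
#' @param anchor_weight Weight given to preferred anchor residues.
#' @return An object of class `pwm_scorer`.
#' @export
hla_a24_scorer <- function(seed = 42L, anchor_weight = 3) {
  lengths <- 8:11
  mats <- with_seed(stage_seed(seed, "pwm_scorer"), {
    lapply(lengths, function(L) {
      w <- matrix(stats::rnorm(20L * L, mean = 0, sd = 0.3), nrow = 20L,
                  dimnames = list(AA20, NULL))
      # P2 anchor: aromatic preference
      w["Y", 2L] <- anchor_weight
      w["F", 2L] <- anchor_weight * 0.75
      w["W", 2L] <- anchor_weight * 0.5
      # C-terminal (P-omega) anchor: hydrophobic/aromatic preference
      w["F", L] <- anchor_weight
      w["L", L] <- anchor_weight * 0.85
      w["I", L] <- anchor_weight * 0.7
      w["W", L] <- anchor_weight * 0.6
      w
    })
  })
  names(mats) <- as.character(lengths)
  structure(list(matrices = mats, lengths = lengths, seed = seed,
                 anchor_weight = anchor_weight),
            class = "pwm_scorer")
}

#' Score peptides with a binding scorer
#'
#' @param scorer A scorer object (see [hla_a24_scorer()]).
#' @param peptides Character vector of peptides of supported lengths.
#' @return Numeric vector of scores (higher = stronger predicted binding).
#' @export
score_peptides <- function(scorer, peptides) UseMethod("score_peptides")

#' @export
score_peptides.pwm_scorer <- function(scorer, peptides) {
  if (!length(peptides)) return(numeric(0))
  lens <- nchar(peptides)
  if (any(!lens %in% scorer$lengths)) {
    stop(sprintf("unsupported peptide length(s): %s (scorer supports %s)",
                 paste(unique(lens[!lens %in% scorer$lengths]), collapse = ","),
                 paste(scorer$lengths, collapse = ",")), call. = FALSE)
  }
  out <- numeric(length(peptides))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    w <- scorer$matrices[[as.character(L)]]
    chars <- matrix(unlist(strsplit(peptides[idx], "", fixed = TRUE)),
                    ncol = L, byrow = TRUE)
    ai <- matrix(match(chars, AA20), ncol = L)
    if (anyNA(ai)) stop("peptide contains a non-standard residue", call. = FALSE)
    sc <- numeric(length(idx))
    for (p in seq_len(L)) sc <- sc + w[cbind(ai[, p], p)]
    out[idx] <- sc
  }
  out
}

#' Build the background score pool for percentile-rank calibration
#'
#' Draws `n_per_length` random peptides per supported length from the given
#' amino-acid frequencies (pass the composition of the proteome under study
#' to mimic random natural peptides), scores them, and stores the sorted
#' score vectors.
#'
#' @param scorer Scorer object.
#' @param aa_freqs Named numeric vector of residue frequencies over the 20
#'   standard residues (need not be normalized). Default: uniform.
#' @param n_per_length Background pool size per length (>= 10000 recommended
#'   for stable ranks; smaller pools are fine for unit testing).
#' @param seed Integer seed.
#' @return An object of class `rank_background`.
#' @export
rank_background <- function(scorer, aa_freqs = NULL, n_per_length = 10000L,
                            seed = 1L) {
  if (is.null(aa_freqs)) aa_freqs <- setNames(rep(1, 20L), AA20)
  probs <- aa_freqs[AA20]
  probs[is.na(probs)] <- 0
  if (sum(probs) <= 0) stop("aa_freqs has no mass on standard residues",
                            call. = FALSE)
  probs <- probs / sum(probs)
  pools <- with_seed(stage_seed(seed, "rank_background"), {
    lapply(scorer$lengths, function(L) {
      peps <- vapply(seq_len(n_per_length), function(i) {
        paste(sample(AA20, L, replace = TRUE, prob = probs), collapse = "")
      }, "")
      sort(score_peptides(scorer, peps))
    })
  })
  names(pools) <- as.character(scorer$lengths)
  structure(list(scores = pools, n = n_per_length, lengths = scorer$lengths),
            class = "rank_background")
}

#' Percentile rank of peptides against the background pool
#'
#' `percent_rank = 100 * #{background peptides of the same length whose score
#' is >= the peptide's score} / N`. Ties count against the peptide
#' (conservative), and lower values mean stronger binding; the conventional
#' binder call is `%rank < 2.0`.
#'
#' @param peptides Character vector of peptides.
#' @param scorer Scorer object.
#' @param background [rank_background()] pool built with the same scorer.
#' @return Numeric vector of percentile ranks in \[0, 100\].
#' @export
percent_rank <- function(peptides, scorer, background) {
  if (!length(peptides)) return(numeric(0))
  scores <- score_peptides(scorer, peptides)
  lens <- nchar(peptides)
  out <- numeric(length(peptides))
  for (L in unique(lens)) {
    pool <- background$scores[[as.character(L)]]
    if (is.null(pool)) stop(sprintf("no background pool for length %d", L),
                            call. = FALSE)
    idx <- which(lens == L)
    # pool is sorted ascending; #(pool >= s) = N - #(pool < s)
    n_less <- findInterval(scores[idx], pool, left.open = TRUE)
    out[idx] <- 100 * (length(pool) - n_less) / length(pool)
  }
  out
}

#' Enumerate mutation-overlapping 8-11mer candidate peptides from an entry
#'
#' All substrings of the entry with length in `lengths` that overlap the
#' mutated region by at least one residue. Duplicate peptide strings arising
#' from different placements are collapsed with the union of their mutated
#' positions.
#'
#' @param entry One database entry (list or single-row data frame) with
#'   `sequence`, `mut_start`, `mut_end`.
#' @param lengths Peptide lengths to enumerate (default 8-11).
#' @return Data frame with columns `peptide`, `length`, `mut_positions`
#'   (comma-joined 1-based positions within the peptide).
#' @export
enumerate_mutant_peptides <- function(entry, lengths = 8:11) {
  seq <- entry$sequence
  a <- as.integer(entry$mut_start)
  b <- as.integer(entry$mut_end)
  if (is.na(a) || is.na(b)) {
    stop("entry has no mutated region; cannot enumerate neoantigen candidates",
         call. = FALSE)
  }
  L <- nchar(seq)
  acc <- list()
  for (k in lengths) {
    lo <- max(1L, a - k + 1L)
    hi <- min(L - k + 1L, b)
    if (lo > hi) next
    starts <- lo:hi
    peps <- substring(seq, starts, starts + k - 1L)
    mut <- vapply(starts, function(s) {
      pos <- seq.int(max(a, s), min(b, s + k - 1L)) - s + 1L
      paste(pos, collapse = ",")
    }, "")
    acc[[length(acc) + 1L]] <- data.frame(
      peptide = peps, length = k, mut_positions = mut,
      stringsAsFactors = FALSE)
  }
  if (!length(acc)) {
    return(data.frame(peptide = character(0), length = integer(0),
                      mut_positions = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, acc)
  # collapse duplicate peptide strings, merging mutated positions
  grp <- split(seq_len(nrow(out)), out$peptide)
  merged <- lapply(grp, function(idx) {
    g <- out[idx, , drop = FALSE]
    pos <- sort(unique(as.integer(unlist(strsplit(g$mut_positions, ",")))))
    data.frame(peptide = g$peptide[1L], length = g$length[1L],
               mut_positions = paste(pos, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$length, out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico neoantigen prediction over a personalized database
#'
#' For every variant entry in the database, enumerates 8-11mer peptides
#' overlapping the mutated region, computes percentile ranks, and keeps
#' candidates with `%rank < rank_threshold` whose source transcript is
#' expressed (TPM > 0; re-checked here even though database construction
#' already gates on expression).
#'
#' @param db Database data frame from [build_database()].
#' @param tpm TPM data frame (`transcript_id`, `sample`, `tpm`).
#' @param sample Sample whose expression gates the prediction.
#' @param scorer,background Scorer and matching background pool.
#' @param rank_threshold Percentile-rank cutoff (default 2.0).
#' @param lengths Peptide lengths (default 8-11).
#' @return List with `candidates` (peptide-level data frame), `per_mutation`
#'   (per-variant candidate counts and the >= 1 indicator) and
#'   `fraction_with_candidate` (share of mutations with at least one
#'   candidate, in percent).
#' @export
predict_neoantigens <- function(db, tpm, sample, scorer, background,
                                rank_threshold = 2.0, lengths = 8:11) {
  var_db <- db[!is.na(db$variant) & db$provenance != "canonical", ,
               drop = FALSE]
  tpm_s <- tpm[tpm$sample == sample, , drop = FALSE]
  expr <- setNames(tpm_s$tpm, tpm_s$transcript_id)
  cand_rows <- list()
  mutations <- character(0)
  for (i in seq_len(nrow(var_db))) {
    e <- var_db[i, ]
    # a collapsed entry can carry several variant links; count each mutation
    vars <- strsplit(e$variant, ";", fixed = TRUE)[[1L]]
    mutations <- c(mutations, vars)
    tr <- strsplit(e$transcript_id, ",", fixed = TRUE)[[1L]][1L]
    tr_tpm <- expr[[tr]] %||% NA_real_
    if (is.na(tr_tpm) || tr_tpm <= 0) next
    peps <- enumerate_mutant_peptides(e, lengths)
    if (!nrow(peps)) next
    pr <- percent_rank(peps$peptide, scorer, background)
    keep <- pr < rank_threshold
    if (!any(keep)) next
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      peptide = peps$peptide[keep], length = peps$length[keep],
      transcript_id = tr, variant = e$variant,
      mut_positions = peps$mut_positions[keep],
      percent_rank = pr[keep], tpm = tr_tpm,
      stringsAsFactors = FALSE)
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(peptide = character(0), length = integer(0),
               transcript_id = character(0), variant = character(0),
               mut_positions = character(0), percent_rank = numeric(0),
               tpm = numeric(0), stringsAsFactors = FALSE)
  rownames(candidates) <- NULL
  mutations <- sort(unique(mutations))
  counts <- vapply(mutations, function(v) {
    sum(vapply(strsplit(candidates$variant, ";", fixed = TRUE),
               function(vs) v %in% vs, TRUE))
  }, 0L)
  per_mutation <- data.frame(variant = mutations, n_candidates = counts,
                             has_candidate = counts > 0L,
                             stringsAsFactors = FALSE)
  rownames(per_mutation) <- NULL
  frac <- if (nrow(per_mutation)) {
    100 * mean(per_mutation$has_candidate)
  } else NA_real_
  list(candidates = candidates, per_mutation = per_mutation,
       fraction_with_candidate = frac)
}
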