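# Personalized database construction: translation, variant application,
# windows, expression gating.

test_that("translate_cds follows the standard code and stops at the first stop", {
  expect_equal(translate_cds("CGATACCTCGCCGTGGCTGCTGTCTTC"), "RYLAVAAVF")
  expect_equal(translate_cds("CGATACCTCACCGTGGCTGCTGTCTTC"), "RYLTVAAVF")
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("ATGAAATTTTAGCCC"), "MKF")
  # no stop codon: all complete codons, trailing incomplete codon ignored
  expect_equal(translate_cds("ATGAAATT"), "MK")
  # codon offset
  expect_equal(translate_cds("CCCATGAAATAA", from_codon = 2L), "MK")
  expect_error(translate_cds("ATGNNN"), "non-ACGT")
  expect_error(translate_cds("AT"), "codon")
})

test_that("apply_missense changes exactly the indexed residue and rejects non-missense inputs", {
  prot <- random_protein(40, seed = 11)
  cds <- cds_for_protein(prot)
  full <- translate_cds(cds)
  # GCT (A) -> GTT (V) at residue 5 of the encoded protein means CDS codon 6
  # (ATG is residue 1); craft directly instead: mutate a known codon
  # mutate second position of codon 10 and check via the string-diff oracle
  pos <- 29L  # codon 10, middle position
  ref <- substr(cds, pos, pos)
  alts <- setdiff(c("A", "C", "G", "T"), ref)
  done <- FALSE
  for (alt in alts) {
    res <- tryCatch(apply_missense(cds, pos, ref, alt), error = function(e) NULL)
    if (is.null(res)) next
    done <- TRUE
    expect_equal(res$residue_index, 10L)
    d <- which(strsplit(full, "")[[1]] != strsplit(res$protein, "")[[1]])
    expect_equal(d, 10L)
  }
  expect_true(done)
  expect_error(apply_missense(cds, 29L, "X", "A"), "mismatch")
  expect_error(apply_missense(cds, 2L, substr(cds, 2, 2),
                              setdiff(c("A","C","G","T"), substr(cds, 2, 2))[1]),
               "start-loss|synonymous|stop")
})

test_that("missense mutate-retranslate-diff oracle agrees over random cases", {
  set.seed(21)
  gc <- Biostrings::GENETIC_CODE
  n_ok <- 0L
  while (n_ok < 200L) {
    prot <- random_protein(sample(30:80, 1))
    cds <- cds_for_protein(prot)
    pos <- sample(4:(nchar(cds) - 3L), 1L)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    res <- tryCatch(apply_missense(cds, pos, ref, alt), error = function(e) NULL)
    if (is.null(res)) next  # synonymous or stop-gain draw
    # oracle: mutate the string, retranslate, diff
    mut_cds <- paste0(substr(cds, 1, pos - 1), alt,
                      substr(cds, pos + 1, nchar(cds)))
    wt <- translate_cds(cds)
    mut <- translate_cds(mut_cds)
    d <- which(strsplit(wt, "")[[1]] != strsplit(mut, "")[[1]])
    expect_equal(res$residue_index, d[1])
    n_ok <- n_ok + 1L
  }
})

test_that("missense windows obey the 30-up/30-down rule with truncation", {
  prot <- random_protein(400, seed = 5)
  w <- missense_window(prot, 332L)
  expect_equal(nchar(w$sequence), 61L)
  expect_equal(w$mut_start, 31L)
  expect_equal(substr(w$sequence, 31, 31), substr(prot, 332, 332))
  # left truncation
  w <- missense_window(prot, 10L)
  expect_equal(nchar(w$sequence), 40L)
  expect_equal(w$mut_start, 10L)
  # right truncation at the C-terminus
  w <- missense_window(prot, 400L)
  expect_equal(nchar(w$sequence), 31L)
  expect_equal(w$mut_start, 31L)
})

test_that("frameshift windows are stop-bounded substrings of the mutant translation", {
  set.seed(31)
  n_checked <- 0L
  n_dropped <- 0L
  while (n_checked + n_dropped < 120L) {
    prot <- random_protein(sample(40:100, 1))
    cds <- cds_for_protein(prot)
    pos <- sample(4:(nchar(cds) - 9L), 1L)
    d <- sample(1:2, 1L)
    if (runif(1) < 0.5) {
      ref <- substr(cds, pos, pos + d); alt <- substr(cds, pos, pos)
    } else {
      ref <- substr(cds, pos, pos)
      alt <- paste0(ref, paste(sample(c("A","C","G","T"), d, replace = TRUE),
                               collapse = ""))
    }
    w <- frameshift_window(cds, pos, ref, alt)
    mut_cds <- paste0(substr(cds, 1, pos - 1), alt,
                      substr(cds, pos + nchar(ref), nchar(cds)))
    mut <- translate_cds(mut_cds)
    if (is.null(w)) {
      # dropped entries must carry no novel residue: mutant is a prefix of
      # (or equal to) the wild-type translation
      expect_true(startsWith(translate_cds(cds), mut))
      n_dropped <- n_dropped + 1L
    } else {
      # oracle containment: the entry is a suffix-aligned substring of the
      # full mutant translation, ending at its C-terminus
      expect_true(grepl(w$sequence, mut, fixed = TRUE))
      expect_equal(substr(mut, nchar(mut) - nchar(w$sequence) + 1L, nchar(mut)),
                   w$sequence)
      expect_equal(w$mut_end, nchar(w$sequence))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 50L)
})

test_that("frameshift with no novel residue is dropped", {
  # deleting one C from the CCC codon leaves MKP unchanged and removes the
  # stop: no mutation-specific sequence
  cds <- "ATGAAACCCTAA"
  expect_null(frameshift_window(cds, 7L, "CC", "C"))
  expect_error(frameshift_window(cds, 4L, "AAA", ""), "not a frameshift")
})

test_that("build_database gates on TPM > 0 and collapses duplicates", {
  ref <- gen_reference(n_transcripts = 10L, cds_length_range = c(150L, 300L),
                       fraction_zero_tpm = 0.2, seed = 17)
  # exactly 2 transcripts at TPM = 0 in the tumor sample
  t_tpm <- ref$tpm[ref$tpm$sample == "tumor", ]
  zero_tx <- t_tpm$transcript_id[t_tpm$tpm == 0]
  expect_length(zero_tx, 2L)
  variants <- gen_variants(ref$transcripts, n_missense = 5L,
                           n_frameshift = 0L, seed = 17)
  db <- build_database(ref$transcripts, variants, ref$tpm, "tumor")
  n_var_on_zero <- sum(variants$transcript_id %in% zero_tx)
  expect_equal(sum(grepl("canonical", db$provenance)), 8L)
  expect_equal(sum(!is.na(db$variant)), 5L - n_var_on_zero)
  # all TPM > 0: same inputs with expression everywhere
  tpm_all <- ref$tpm
  tpm_all$tpm[tpm_all$tpm == 0] <- 1
  db2 <- build_database(ref$transcripts, variants, tpm_all, "tumor")
  expect_equal(sum(grepl("canonical", db2$provenance)), 10L)
  expect_equal(sum(!is.na(db2$variant)), 5L)
  # all-zero expression is a hard error
  tpm0 <- ref$tpm
  tpm0$tpm <- 0
  expect_error(build_database(ref$transcripts, variants, tpm0, "tumor"),
               "empty database")
})

test_that("database build is order-independent and idempotent", {
  fx <- small_db_fixture(seed = 23)
  perm <- fx$variants[rev(seq_len(nrow(fx$variants))), ]
  db2 <- build_database(fx$ref$transcripts, perm, fx$ref$tpm, "tumor")
  expect_identical(fx$db, db2)
})

test_that("an engineered canonical/variant sequence collision merges provenance", {
  # two transcripts: B's canonical translation equals the missense window
  # of a variant on A
  prot_a <- random_protein(50, seed = 41)
  cds_a <- cds_for_protein(prot_a)
  v <- NULL
  for (pos in 40:80) {
    ref <- substr(cds_a, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      res <- tryCatch(apply_missense(cds_a, pos, ref, alt),
                      error = function(e) NULL)
      if (!is.null(res)) { v <- list(pos = pos, ref = ref, alt = alt,
                                     res = res); break }
    }
    if (!is.null(v)) break
  }
  w <- missense_window(v$res$protein, v$res$residue_index)
  cds_b <- cds_for_protein(w$sequence, add_start = FALSE)
  transcripts <- data.frame(
    transcript_id = c("TXA", "TXB"), gene = c("GA", "GB"),
    cds = c(cds_a, cds_b), stringsAsFactors = FALSE)
  variants <- data.frame(transcript_id = "TXA", cds_pos = v$pos, ref = v$ref,
                         alt = v$alt, vtype = "missense",
                         stringsAsFactors = FALSE)
  tpm <- data.frame(transcript_id = c("TXA", "TXB"), sample = "tumor",
                    tpm = c(5, 5), stringsAsFactors = FALSE)
  db <- build_database(transcripts, variants, tpm, "tumor")
  hit <- db[db$sequence == w$sequence, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$provenance, "canonical,missense_window")
})

test_that("database FASTA round trip preserves entries", {
  fx <- small_db_fixture(seed = 29)
  path <- tempfile(fileext = ".fasta")
  write_database_fasta(fx$db, path)
  back <- read_database_fasta(path)
  expect_equal(back$entry_id, fx$db$entry_id)
  expect_equal(back$sequence, fx$db$sequence)
  expect_equal(back$mut_start, fx$db$mut_start)
  expect_equal(back$mut_end, fx$db$mut_end)
  expect_equal(back$provenance, fx$db$provenance)
})
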