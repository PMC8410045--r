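# Generators: determinism, construction guarantees, planted truth.

test_that("gen_reference builds translatable transcripts deterministically", {
  ref <- gen_reference(n_transcripts = 50L, fraction_zero_tpm = 0.2, seed = 1)
  expect_equal(nrow(ref$transcripts), 50L)
  for (cds in ref$transcripts$cds) {
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    prot <- translate_cds(cds)
    expect_equal(nchar(prot), nchar(cds) / 3 - 1)  # stop at the final codon only
  }
  # exactly round(0.2 * 50) = 10 transcripts at TPM 0, per sample
  for (s in unique(ref$tpm$sample)) {
    expect_equal(sum(ref$tpm$tpm[ref$tpm$sample == s] == 0), 10L)
  }
  # byte-identical FASTA under the same seed
  ref2 <- gen_reference(n_transcripts = 50L, fraction_zero_tpm = 0.2, seed = 1)
  f1 <- tempfile(); f2 <- tempfile()
  write_transcripts_fasta(ref$transcripts, f1)
  write_transcripts_fasta(ref2$transcripts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # round trip preserves the table
  expect_equal(read_transcripts_fasta(f1), ref$transcripts)
  expect_error(gen_reference(cds_length_range = c(60L, 90L)), "degenerate")
})

test_that("fold-change design drives tumor/normal expression of chosen genes", {
  fc <- data.frame(gene = c(1, 2), fold = c(25, 40))
  ref <- gen_reference(n_transcripts = 20L, fold_change = fc, seed = 3)
  for (i in 1:2) {
    tx <- ref$transcripts$transcript_id[fc$gene[i]]
    tt <- ref$tpm$tpm[ref$tpm$sample == "tumor" & ref$tpm$transcript_id == tx]
    tn <- ref$tpm$tpm[ref$tpm$sample == "normal" & ref$tpm$transcript_id == tx]
    expect_equal(tt / tn, fc$fold[i])
    expect_gt(tn, 0)
  }
})

test_that("generated variants verify against the genetic code", {
  ref <- gen_reference(n_transcripts = 15L, seed = 7)
  vars <- gen_variants(ref$transcripts, n_missense = 10L, n_frameshift = 4L,
                       seed = 7)
  expect_equal(sum(vars$vtype == "missense"), 10L)
  expect_equal(sum(vars$vtype == "frameshift"), 4L)
  expect_true(all(vars$depth >= vars$alt_reads & vars$alt_reads >= 0))
  cds_of <- setNames(ref$transcripts$cds, ref$transcripts$transcript_id)
  for (i in which(vars$vtype == "missense")) {
    v <- vars[i, ]
    # nonsynonymous by re-translation
    res <- apply_missense(cds_of[[v$transcript_id]], v$cds_pos, v$ref, v$alt)
    expect_true(res$wt_aa != res$mut_aa)
  }
  for (i in which(vars$vtype == "frameshift")) {
    v <- vars[i, ]
    expect_true(abs(nchar(v$ref) - nchar(v$alt)) %% 3 != 0)
  }
  # distinct positions even when piled on few transcripts
  vars2 <- gen_variants(ref$transcripts[1, , drop = FALSE], n_missense = 0L,
                        n_frameshift = 3L, seed = 9)
  expect_equal(nrow(unique(vars2[, c("transcript_id", "cds_pos")])), 3L)
})

test_that("ligandome designs are realized exactly", {
  ref <- gen_reference(n_transcripts = 25L, seed = 11)
  proteins <- data.frame(gene = ref$transcripts$gene,
                         sequence = vapply(ref$transcripts$cds, translate_cds, ""),
                         stringsAsFactors = FALSE)
  lig <- gen_ligandomes(proteins, n_tumor = 100L, n_normal = 100L,
                        n_shared = 40L, seed = 11)
  tum <- lig$peptide[lig$tissue == "tumor"]
  nrm <- lig$peptide[lig$tissue == "normal"]
  expect_length(tum, 100L)
  expect_length(nrm, 100L)
  expect_length(intersect(tum, nrm), 40L)
  # every peptide is a proteome substring of length 8-11
  expect_true(all(nchar(lig$peptide) %in% 8:11))
  expect_true(all(vapply(lig$peptide, function(p) {
    any(grepl(p, proteins$sequence, fixed = TRUE))
  }, TRUE)))
  # zero-sharing design
  lig0 <- gen_ligandomes(proteins, n_tumor = 30L, n_normal = 30L,
                         n_shared = 0L, seed = 12)
  expect_length(intersect(lig0$peptide[lig0$tissue == "tumor"],
                          lig0$peptide[lig0$tissue == "normal"]), 0L)
})

test_that("planted TAA peptides are recoverable end to end", {
  fc <- data.frame(gene = 1:5, fold = 25)
  ref <- gen_reference(n_transcripts = 30L, fold_change = fc, seed = 13)
  proteins <- data.frame(gene = ref$transcripts$gene,
                         sequence = vapply(ref$transcripts$cds, translate_cds, ""),
                         stringsAsFactors = FALSE)
  taa_genes <- ref$transcripts$gene[1:5]
  lig <- gen_ligandomes(proteins, n_tumor = 80L, n_normal = 80L,
                        n_shared = 30L, taa_genes = taa_genes, seed = 13)
  planted <- attr(lig, "planted_taa")
  expect_equal(nrow(planted), 5L)
  part <- tumor_normal_partition(lig$peptide[lig$tissue == "tumor"],
                                 lig$peptide[lig$tissue == "normal"])
  gene_tpm <- function(s) {
    tt <- ref$tpm[ref$tpm$sample == s, ]
    setNames(tt$tpm, ref$transcripts$gene[match(tt$transcript_id,
                                                ref$transcripts$transcript_id)])
  }
  pg <- do.call(rbind, lapply(part$tumor_only, function(p) {
    hit <- proteins$gene[grepl(p, proteins$sequence, fixed = TRUE)]
    data.frame(peptide = p, gene = hit, stringsAsFactors = FALSE)
  }))
  taa <- select_taa(pg, gene_tpm("tumor"), gene_tpm("normal"),
                    fold_threshold = 20)
  expect_true(all(planted$peptide %in% taa$peptide))
})

test_that("synthetic spectra honor exact mass arithmetic", {
  sim <- gen_spectra("RYLAVAAVF", jitter_sd = 0, n_noise_peaks = 0L, seed = 2)
  sp <- sim$spectra[[1]]
  # precursor consistent with the peptide at the sampled charge
  expect_equal(neutral_mass(sp$precursor_mz, sp$charge),
               peptide_mass("RYLAVAAVF"), tolerance = 1e-9)
  ions <- fragment_ions("RYLAVAAVF")
  expect_equal(sort(sp$mz), sort(c(ions$b, ions$y)), tolerance = 1e-9)
  # z = 1 precursor is monoisotopic mass plus one proton: force by redraw
  found_z1 <- FALSE
  for (s in 1:30) {
    sim_s <- gen_spectra("RYLAVAAVF", jitter_sd = 0, n_noise_peaks = 0L,
                         seed = s)
    if (sim_s$spectra[[1]]$charge == 1L) {
      expect_equal(sim_s$spectra[[1]]$precursor_mz,
                   peptide_mass("RYLAVAAVF") + MASS_PROTON, tolerance = 1e-9)
      found_z1 <- TRUE
      break
    }
  }
  expect_true(found_z1)
  # peaks are sorted and foreign spectra differ from every true peptide
  sim2 <- gen_spectra(c("RYLAVAAVF", "KYLEKYYNL"), n_foreign = 2L, seed = 4)
  for (sp in sim2$spectra) expect_true(!is.unsorted(sp$mz))
  foreign <- sim2$truth$peptide[sim2$truth$is_foreign]
  expect_false(any(foreign %in% c("RYLAVAAVF", "KYLEKYYNL")))
})

test_that("dose-response and clonotype generators satisfy their definitions", {
  dr <- gen_dose_response(ec50 = 2, hill = 1.5, top = 80, bottom = 10,
                          concentrations = c(0.1, 1, 2, 10, 100),
                          noise_sd = 0, seed = 1)
  # noiseless response at x = ec50 is (top + bottom) / 2, in every replicate
  expect_equal(unique(dr$response[dr$concentration == 2]), (80 + 10) / 2)
  expect_equal(sum(dr$concentration == 2), 3L)
  expect_warning(gen_dose_response(ec50 = 1000,
                                   concentrations = c(1, 2, 4, 8)), "range")
  cl <- gen_clonotypes(n_clones = 100L,
                       planted = data.frame(frequency = 0.027),
                       total_counts = 100000L, seed = 5)
  f <- clonotype_frequencies(cl)
  planted <- attr(cl, "planted")
  got <- f$frequency[f$cdr3_aa == planted]
  # binomial sd at 2.7% of 100k counts is ~0.05%; +-0.3% absolute is generous
  expect_lt(abs(got - 0.027), 0.003)
  expect_true(planted %in% expanded_clonotypes(f, 0.02)$cdr3_aa)
  # a 1% planted clone is excluded by the 2% filter
  cl1 <- gen_clonotypes(n_clones = 100L,
                        planted = data.frame(frequency = 0.01),
                        total_counts = 100000L, seed = 6)
  expect_false(attr(cl1, "planted") %in%
                 expanded_clonotypes(cl1, 0.02)$cdr3_aa)
  expect_error(gen_clonotypes(planted = data.frame(frequency = c(0.6, 0.5))),
               "sum")
})

test_that("generators restore the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_reference(n_transcripts = 10L, seed = 1))
  invisible(gen_spectra("RYLAVAAVF", seed = 1))
  expect_identical(.Random.seed, before)
})
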