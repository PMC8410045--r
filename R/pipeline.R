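# End-to-end orchestration: simulate -> build-db -> predict -> search ->
# compare -> assays -> repertoire, from one structured config, writing stage
# files and a machine-readable run report.

#' Default pipeline configuration
#'
#' All analysis thresholds default to the study-condition values: %rank
#' cutoffs 2.0 and 0.5, peptide FDR 0.01, TAA fold-change 20, clonotype
#' expansion 2%, precursor/fragment tolerances 10 ppm / 0.02 Da, peptide
#' lengths 8-11. Simulation sizes are chosen so the full run completes in
#' well under a minute on one CPU while every stage still has nontrivial
#' input.
#'
#' @param seed Run seed; every stage derives its own child seed from it.
#' @param ... Overrides for any config entry.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    n_transcripts = 40L, cds_length_range = c(300L, 600L),
    fraction_zero_tpm = 0.1,
    n_missense = 20L, n_frameshift = 6L,
    rank_threshold = 2.0, rank_threshold_strict = 0.5,
    background_n = 3000L,
    n_true_spectra = 40L, n_foreign_spectra = 10L,
    fdr_alpha = 0.01,
    prec_tol_ppm = 10, frag_tol = 0.02,
    n_tumor_ligands = 80L, n_normal_ligands = 80L, n_shared_ligands = 30L,
    taa_fold = 25, n_taa_genes = 3L, fold_threshold = 20,
    expansion_threshold = 0.02,
    ec50 = 1.5, hill = 1, dose_noise_sd = 2,
    n_clones = 150L, planted_clone_freq = 0.027,
    total_clone_counts = 100000L)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Executes every stage against seeded synthetic inputs, writes each stage's
#' output files under `out_dir` (transcripts FASTA, TPM/variant/ligandome/
#' clonotype TSVs, database FASTA, spectra MGF, candidate and PSM TSVs) and
#' a JSON run report whose counts are re-derivable from those files.
#' Deterministic under a fixed config seed.
#'
#' @param config Configuration list from [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run report, invisibly also written to
#'   `file.path(out_dir, "report.json")`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # --- simulate reference + variants -------------------------------------
  fc_design <- data.frame(gene = seq_len(config$n_taa_genes),
                          fold = config$taa_fold)
  ref <- gen_reference(n_transcripts = config$n_transcripts,
                       cds_length_range = config$cds_length_range,
                       fraction_zero_tpm = config$fraction_zero_tpm,
                       fold_change = fc_design, seed = seed)
  variants <- gen_variants(ref$transcripts, n_missense = config$n_missense,
                           n_frameshift = config$n_frameshift, seed = seed)
  write_transcripts_fasta(ref$transcripts,
                          file.path(out_dir, "transcripts.fasta"))
  write_tsv_file(ref$tpm, file.path(out_dir, "tpm.tsv"))
  write_tsv_file(variants, file.path(out_dir, "variants.tsv"))

  # --- personalized database ---------------------------------------------
  db <- build_database(ref$transcripts, variants, ref$tpm, "tumor")
  write_database_fasta(db, file.path(out_dir, "database.fasta"))
  n_canonical <- sum(grepl("canonical", db$provenance))
  n_variant_entries <- sum(!is.na(db$variant))

  # --- in-silico prediction ----------------------------------------------
  scorer <- hla_a24_scorer(seed = seed)
  proteome_freqs <- table(factor(unlist(strsplit(db$sequence, "",
                                                 fixed = TRUE)),
                                 levels = AA20))
  background <- rank_background(scorer, aa_freqs = c(proteome_freqs),
                                n_per_length = config$background_n,
                                seed = seed)
  pred <- predict_neoantigens(db, ref$tpm, "tumor", scorer, background,
                              rank_threshold = config$rank_threshold)
  pred_strict <- predict_neoantigens(db, ref$tpm, "tumor", scorer, background,
                                     rank_threshold = config$rank_threshold_strict)
  write_tsv_file(pred$candidates, file.path(out_dir, "candidates.tsv"))

  # --- MS identification --------------------------------------------------
  index <- build_index(db)
  # spectra: a mix of canonical substrings and mutation-overlapping peptides
  tgt_ann <- index$annotation
  neo_peps <- tgt_ann$peptide[!tgt_ann$any_canonical & tgt_ann$any_overlap]
  can_peps <- tgt_ann$peptide[tgt_ann$any_canonical]
  pick <- with_seed(stage_seed(seed, "pipeline_spectra"), {
    n_neo <- min(length(neo_peps), max(3L, config$n_true_spectra %/% 4L))
    c(sample(neo_peps, n_neo),
      sample(can_peps, config$n_true_spectra - n_neo))
  })
  sim <- gen_spectra(pick, n_foreign = config$n_foreign_spectra, seed = seed)
  write_mgf(sim$spectra, file.path(out_dir, "spectra.mgf"))
  psms <- compute_qvalues(search_spectra(sim$spectra, index,
                                         prec_tol_ppm = config$prec_tol_ppm,
                                         frag_tol = config$frag_tol))
  hits <- filter_fdr(psms, alpha = config$fdr_alpha, index = index)
  write_tsv_file(hits$peptides, file.path(out_dir, "accepted_peptides.tsv"))

  # --- ligandome comparison ----------------------------------------------
  proteins <- data.frame(
    gene = ref$transcripts$gene,
    sequence = vapply(ref$transcripts$cds, translate_cds, ""),
    stringsAsFactors = FALSE)
  taa_genes <- ref$transcripts$gene[fc_design$gene]
  lig <- gen_ligandomes(proteins, n_tumor = config$n_tumor_ligands,
                        n_normal = config$n_normal_ligands,
                        n_shared = config$n_shared_ligands,
                        taa_genes = taa_genes, seed = seed)
  write_tsv_file(lig, file.path(out_dir, "ligandomes.tsv"))
  ov <- overlap_summary(lig)
  part <- tumor_normal_partition(lig$peptide[lig$tissue == "tumor"],
                                 lig$peptide[lig$tissue == "normal"])
  planted <- attr(lig, "planted_taa")
  gene_tpm <- function(s) {
    tt <- ref$tpm[ref$tpm$sample == s, ]
    setNames(tt$tpm, ref$transcripts$gene[match(tt$transcript_id,
                                                ref$transcripts$transcript_id)])
  }
  # map tumor-only peptides to source genes by substring containment
  tumor_only <- part$tumor_only
  pg <- do.call(rbind, lapply(tumor_only, function(p) {
    hit <- proteins$gene[grepl(p, proteins$sequence, fixed = TRUE)]
    if (!length(hit)) return(NULL)
    data.frame(peptide = p, gene = hit, stringsAsFactors = FALSE)
  }))
  taa <- select_taa(pg, gene_tpm("tumor"), gene_tpm("normal"),
                    fold_threshold = config$fold_threshold)
  write_tsv_file(taa, file.path(out_dir, "taa_candidates.tsv"))

  # --- assays --------------------------------------------------------------
  dr <- gen_dose_response(ec50 = config$ec50, hill = config$hill,
                          noise_sd = config$dose_noise_sd, seed = seed)
  fit <- fit_4pl(dr$concentration, dr$response)
  example_vaf <- if (nrow(variants)) {
    vaf(variants$alt_reads[1L], variants$depth[1L])
  } else NA_real_

  # --- repertoire ----------------------------------------------------------
  clones <- gen_clonotypes(n_clones = config$n_clones,
                           planted = data.frame(frequency = config$planted_clone_freq),
                           total_counts = config$total_clone_counts,
                           seed = seed)
  write_tsv_file(clones, file.path(out_dir, "clonotypes.tsv"))
  expanded <- expanded_clonotypes(clones,
                                  threshold = config$expansion_threshold)

  report <- list(
    tool = "neoforge",
    version = as.character(utils::packageVersion("neoforge")),
    seed = seed,
    out_dir = out_dir,
    mutations = list(missense = sum(variants$vtype == "missense"),
                     frameshift = sum(variants$vtype == "frameshift"),
                     total = nrow(variants)),
    database = list(entries = nrow(db), canonical = n_canonical,
                    variant = n_variant_entries),
    prediction = list(
      candidates_rank_lt_default = nrow(pred$candidates),
      candidates_rank_lt_strict = nrow(pred_strict$candidates),
      fraction_mutations_with_candidate = pred$fraction_with_candidate),
    ms_identification = list(
      spectra = length(sim$spectra),
      accepted_peptides = nrow(hits$peptides),
      neoantigen_peptides = sum(hits$peptides$is_neoantigen)),
    ligandome = list(
      union_size = ov$union_size, shared_ge2 = ov$shared_ge2,
      shared_or_normal = part$shared_or_normal,
      tumor_only = length(part$tumor_only),
      taa_candidates = nrow(taa),
      planted_taa_recovered = sum(planted$peptide %in% taa$peptide)),
    assays = list(ec50 = fit$ec50, hill = fit$hill,
                  example_vaf = example_vaf),
    repertoire = list(clonotypes = nrow(clones),
                      expanded = nrow(expanded),
                      planted_expanded_recovered =
                        sum(attr(clones, "planted") %in% expanded$cdr3_aa)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}
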