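# Shared fixture builders. Everything is generated in code under fixed
# seeds; no data files.

# random protein string over the 20 standard residues
random_protein <- function(n, seed = NULL) {
  draw <- function() paste(sample(names(neoforge::AA_MONO), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

# minimal with_seed for helpers (mirrors the package-internal one)
withr_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# a CDS that encodes an arbitrary protein (deterministic codon choice),
# flanked by ATG (optional) and a stop
cds_for_protein <- function(protein, add_start = TRUE) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  codons <- vapply(strsplit(protein, "")[[1]],
                   function(a) by_aa[[a]][1L], "")
  paste0(if (add_start) "ATG" else "", paste(codons, collapse = ""), "TAA")
}

# leucine and isoleucine are isobaric and indistinguishable by fragment
# masses; identification comparisons collapse them
il_collapse <- function(x) chartr("I", "L", x)

# small reference + variants + database used across msident tests
small_db_fixture <- function(seed = 3L, n_transcripts = 12L,
                             n_missense = 6L, n_frameshift = 2L) {
  ref <- gen_reference(n_transcripts = n_transcripts,
                       cds_length_range = c(150L, 300L),
                       fraction_zero_tpm = 0, seed = seed)
  variants <- gen_variants(ref$transcripts, n_missense = n_missense,
                           n_frameshift = n_frameshift, seed = seed)
  db <- build_database(ref$transcripts, variants, ref$tpm, "tumor")
  list(ref = ref, variants = variants, db = db)
}

# transcript whose codons 329..337 encode RYLTVAAVF, so that c.994A>G is
# the p.T332A substitution (codon 332 = ACC at CDS 994-996)
tubb_like_transcript <- function() {
  prefix <- random_protein(327, seed = 99)  # codons 2..328
  cds <- paste0("ATG", paste(vapply(strsplit(prefix, "")[[1]], function(a) {
    by_aa <- split(names(Biostrings::GENETIC_CODE),
                   unname(Biostrings::GENETIC_CODE))
    by_aa[[a]][1L]
  }, ""), collapse = ""), rtf9_insert, "CCCGGGTAA")
  stopifnot(substr(cds, 994, 996) == "ACC")
  cds
}
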