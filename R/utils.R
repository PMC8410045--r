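# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic per-stage child seed so pipeline stages can be rerun
# independently under one run seed. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  ints <- utf8ToInt(stage)
  h <- sum(ints * seq_along(ints))
  as.integer((as.numeric(seed) %% 2147483647 * 7919 + h * 104729) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# split a peptide/protein string into single residues
str_residues <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

assert_aa <- function(peptide, context = "peptide") {
  bad <- setdiff(unique(str_residues(peptide)), names(AA_MONO))
  if (length(bad)) {
    stop(sprintf("unknown residue symbol(s) in %s: %s", context,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
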