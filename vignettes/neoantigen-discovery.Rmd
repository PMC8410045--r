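---
title: "Proteogenomic neoantigen discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic neoantigen discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoforge)
```

## The problem

Tumors accumulate somatic mutations, and a small fraction of the resulting
altered peptides are processed and presented by HLA class I molecules where
CD8^+^ T cells can recognize them. Identifying which mutated peptides are
*actually presented* — as opposed to merely predicted to bind — requires
combining three data types: somatic variants (which peptides could exist),
transcript expression (which source genes are transcribed at all), and
immunopeptidome mass spectrometry (which peptides are physically recovered
from peptide–HLA complexes). `neoforge` implements this analysis as a set of
composable, individually tested stages, together with a seeded
synthetic-data module so that every stage can be exercised and calibrated
without any external download.

The pipeline mirrors the hypermutated (mismatch-repair-deficient,
MSI-high) colorectal tumor setting in which such analyses are most
informative: thousands of missense and frameshift mutations, an
HLA-A\*24:02-restricted ligandome with anchor residues at peptide position
2 and the C-terminus, and a handful of clonally expanded tumor-infiltrating
T cell clonotypes.

## Stage by stage

### Personalized search database (`build_database`)

For one sample, the database is the union of

* **canonical entries** — full translations of every transcript with
  TPM > 0, and
* **variant entries** — mutation windows on expressed transcripts:
  * *missense*: the mutant protein from 30 residues upstream to 30
    residues downstream of the substituted residue (61-mer in the interior;
    truncated at the termini), the altered residue sitting at window
    position 31;
  * *frameshift*: from 30 residues upstream of the first residue at which
    the shifted translation diverges from wild type, down to (and
    excluding) the novel stop codon.

The expression gate is strict (`TPM > 0`) and applies to both sets.
Coordinates follow HGVS-style arithmetic: CDS positions are 1-based and the
affected residue is `ceiling(cds_pos / 3)`, so c.994A>G maps to p.332.
Stop-gain, stop-loss and start-loss substitutions are rejected as inputs —
they are not missense events and produce no well-defined window. A
frameshift whose shifted frame terminates before producing a single novel
residue is dropped: such an entry would contain no mutation-specific
sequence. Where the upstream context of a frameshift should start is
genuinely underdetermined (the indel codon and the first altered residue
can differ when the shifted frame initially reproduces wild-type residues);
we count from the first altered residue, which guarantees the window
contains only verifiable novel sequence plus its context. Exact duplicate
sequences are collapsed with merged provenance, which makes the build
idempotent and order-independent.

### Binding percentile rank (`percent_rank`, `hla_a24_scorer`)

Binding strength is expressed as a *percentile rank* against a background
of random peptides: the percentage of same-length background peptides that
score at least as well. Lower is stronger; the conventional binder call is
`%rank < 2.0`, with `< 0.5` for strong binders. The scorer is a pluggable
contract (any object with a `score_peptides()` method); the bundled default
is a seeded position-weight matrix with HLA-A24-like anchors (Tyr/Phe at
P2, Phe/Leu/Ile/Trp at the C-terminus). Two deliberate choices:

* background peptides are drawn from the amino-acid composition of the
  proteome under study, not uniformly, to mimic "random natural peptide"
  semantics;
* ties count against the query (`>=` in the rank), so a peptide can never
  be declared a binder on tie luck.

Candidate enumeration slides every 8–11-mer across a variant entry and
keeps those overlapping the mutated region by at least one residue; for an
interior single-residue missense that is 8 + 9 + 10 + 11 = 38 candidates.

### Simplified MS/MS identification (`build_index`, `search_spectra`, `compute_qvalues`)

The search is deliberately minimal but structurally faithful to a
no-enzyme immunopeptidome workflow:

* **index**: every distinct 8–11-mer substring of every database entry
  ("no enzyme" digestion), with up to 2 variable methionine oxidations
  (+15.994915 Da each); decoys are whole-entry sequence reversals,
  enumerated the same way, searched concatenated with targets; a peptide
  present on both sides is assigned to the target set;
* **matching**: candidates within ±10 ppm on *neutral* mass (so behavior
  is charge-independent); singly-protonated b/y ladders matched at
  ±0.02 Da; score is a log-hyperscore,
  `log(matched intensity) + log(n_b!) + log(n_y!)`;
* **FDR**: concatenated target-decoy q-values,
  `FDR(s) = #decoys ≥ s / max(1, #targets ≥ s)`, monotonized so q never
  increases with score; peptides are accepted at `q ≤ 0.01` and classified
  as neoantigens when *every* database source is a variant entry and the
  peptide overlaps the mutated region.

Exact score ties prefer targets, then the lexicographically smallest
peptide, making results deterministic. Leucine and isoleucine are isobaric
with identical fragment ladders; no fragment-based search can distinguish
them, and the test suite therefore compares identifications modulo I/L.
The cap of 2 variable oxidations bounds the modification combinatorics; it
is a conventional search-engine default rather than a measured property.

### Ligandome comparison and TAA selection (`overlap_summary`, `select_taa`)

Tumor/normal comparison is set algebra: a tumor peptide found in any
normal sample is "shared/normal", the remainder are tumor-only candidates.
Nonmutated tumor-associated-antigen (TAA) candidates are tumor-only
peptides whose source gene is overexpressed more than 20-fold in tumor,
with fold change computed as `tumor_tpm / max(normal_tpm, 0.1)`. The
0.1-TPM pseudocount is our choice (exposed as an argument): zero normal
expression would otherwise make the fold change undefined, and flagged
`normal_zero` rows let the analyst treat "not expressed in normal" as its
own category. Multi-gene peptides take the maximal fold, the permissive
direction for candidate nomination.

### Assays (`fit_4pl`, `ldh_release_pct`, `delta_mfi`, `vaf`)

The 4PL dose-response model is
`r(x) = bottom + (top - bottom) / (1 + (ec50/x)^hill)`, fitted by
Levenberg–Marquardt on log10 dose from a deterministic multi-start grid
(log-EC50 at the dose quantiles, hill in {0.5, 1, 2} with both signs, best
residual sum of squares wins). A deterministic grid covers the same basins
as seeded start jitter without putting RNG inside a fitting routine. After
fitting, the curve is oriented so `hill > 0`, and a warning is raised when
the fitted EC50 falls outside the dose range or the fitted span
extrapolates more than 1.5× beyond the observed responses — both symptoms
of a titration that failed to reach its plateaus. This is a post-fit
diagnostic because a pre-fit spread heuristic cannot recognize a flat or
one-sided titration without knowing the response scale.

The LDH cytotoxicity percentage is
`100 × (experimental − effector_spontaneous − target_minimal) /
(target_maximal − target_minimal)`, with the spontaneous, minimal and
maximal releases measured from effector-alone, target-alone and
detergent-lysed target wells. The exact placement of the effector
spontaneous term follows the standard LDH correction; we flag this as an
assumption because assay kits vary in whether a separate
effector-background well is subtracted. Values outside [0, 100] are
clipped and flagged rather than silently truncated.

ΔMFI (peptide–HLA stabilization) and VAF (variant allele frequency,
`alt_reads / depth`) are plain arithmetic and exist as named, tested
operations mainly so that the pipeline report can cite them.

### Repertoire (`expanded_clonotypes`, `match_clonotype`)

Clonotype frequencies are counts over total counts. The expansion filter
is *strictly* greater than 2% — "over 2%" semantics, so a clone at exactly
2.0% is excluded. Clonotype matching requires equality on CDR3 (amino-acid
level), V and J gene calls, and on D/C only when both records carry them:
D-segment and constant-gene calls are frequently missing or ambiguous in
short-read-derived tables, and demanding them would fail genuine matches.

## The synthetic-data module

`gen_reference`, `gen_variants`, `gen_ligandomes`, `gen_spectra`,
`gen_dose_response` and `gen_clonotypes` produce inputs with exactly the
structure the stages assume:

* CDS sequences start with ATG, end with a stop and contain no internal
  in-frame stop, so translatability is guaranteed by construction;
  TPM is log-normal with an exact count of zero-expression transcripts;
  fold-change designs plant tumor-overexpressed genes.
* Missense draws are verified nonsynonymous against the genetic code;
  frameshifts are 1–2-nt indels away from the first and last codons.
* Ligandome designs are realized *exactly* (intersection sizes, planted
  tumor-only TAA peptides), so recovery tests have crisp ground truth.
* Spectra carry exact precursor masses at charges 1–3, complete b/y
  ladders with Gaussian jitter (keep the jitter sd at or below a third of
  the fragment tolerance), log-normal intensities, uniform noise peaks,
  and optional "foreign" spectra from shuffled peptides — composition-
  matched sequences absent from the database, which is what makes the
  target-decoy competition honest.
* Dose-response tables default to triplicate wells per dose, matching how
  titration assays are actually read out (means of n = 3); with single
  wells, an eight-dose titration at 5%-of-range noise cannot determine
  EC50 to better than ~15% even for an oracle initialized at the truth.
* Clonotype counts are multinomial around planted frequencies with a
  heavy-tailed background, so a planted 2.7% clone has binomial sampling
  error ~0.05% at 10^5 reads.

Every generator derives a child seed from the run seed plus a stage label,
so stages can be rerun independently and a fixed seed gives byte-identical
output files.

**What passing tests do and do not show.** The generators reproduce the
*structure* of the real data, not its hardness: real spectra contain
co-eluting peptides, isotope envelopes, uncalibrated mass drift and
intensity structure the simulator omits; real ligandomes have acquisition-
dependent missingness; real repertoires have PCR amplification noise. A
calibrated FDR on synthetic spectra shows the target-decoy machinery is
implemented correctly, not that 1% FDR on a real instrument run yields 1%
false identifications. Conversely, the worked-example arithmetic
(translation of the minigene inserts, coordinate mapping, count ratios) is
exact and transfers directly.

## Problem sizes and runtime

The default test and pipeline sizes — tens of transcripts, a few dozen
variants, ~10^2 ligands per sample, ~10^2 spectra per run, 20-seed
calibration loops, 100-seed EC50 recovery — were chosen so the whole suite
runs in about a minute on a single CPU while every estimate it checks
(empirical FDR, recovery rates, rank calibration) still has enough
replication to be meaningful. They are documented here as the package's own
testing design.

## Known limitations

* The binding scorer is a motif stand-in: it reproduces %rank semantics
  and anchor structure but not the accuracy of a trained predictor;
  the `score_peptides()` contract exists precisely so a real predictor can
  be wrapped in.
* The search engine scores only singly-protonated b/y ions and one
  modification type; it is a calibration-faithful simplification, not a
  replacement for a production engine.
* Variants are CDS-coordinate; genomic coordinates, splice isoforms and
  germline phasing are out of scope.
* Frameshift windows flag, but do not specially model, open reading
  frames that run off the transcript end without a novel stop.
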