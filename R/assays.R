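# Functional assay quantifications: pHLA stabilization (delta-MFI), 4PL
# functional-avidity EC50, LDH cytotoxicity percentage, variant allele
# frequency.

#' Peptide-HLA stabilization as a difference in mean fluorescence intensity
#'
#' @param mfi_with_peptide,mfi_without Nonnegative MFI readouts with and
#'   without the peptide pulse.
#' @return `mfi_with_peptide - mfi_without` (negative values reported as-is).
#' @export
delta_mfi <- function(mfi_with_peptide, mfi_without) {
  stopifnot(mfi_with_peptide >= 0, mfi_without >= 0)
  mfi_with_peptide - mfi_without
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `r(x) = bottom + (top - bottom) / (1 + (ec50 / x)^hill)`
#' on log10 dose, via Levenberg-Marquardt with a deterministic multi-start
#' grid (log10-EC50 at dose quantiles, hill in \{0.5, 1, 2\} with both
#' signs). The EC50 is returned in the input concentration units and is the
#' concentration of half-maximal response by construction. A warning is
#' issued when the responses do not clearly span both asymptote regions.
#'
#' @param concentrations Strictly positive dose vector (>= 4 distinct
#'   values).
#' @param responses Response vector of the same length.
#' @return List with `top`, `bottom`, `hill`, `ec50`, `fitted` (function of
#'   concentration) and `rss`.
#' @export
fit_4pl <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (any(concentrations <= 0)) stop("concentrations must be positive",
                                     call. = FALSE)
  if (length(unique(concentrations)) < 4L) {
    stop("need >= 4 distinct concentrations to fit a 4PL", call. = FALSE)
  }
  rng <- range(responses)
  span <- diff(rng)
  lx <- log10(concentrations)
  df <- data.frame(lx = lx, y = responses)
  starts <- expand.grid(
    le = stats::quantile(lx, c(0.25, 0.5, 0.75), names = FALSE),
    hill = c(0.5, 1, 2, -0.5, -1, -2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + 10^(hill * (le - lx))),
        data = df,
        start = list(bottom = rng[1L], top = rng[2L],
                     hill = starts$hill[i], le = starts$le[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("4PL fit failed to converge from every start (responses span: ",
         paste(signif(rng, 4), collapse = ".."), ")", call. = FALSE)
  }
  p <- as.list(stats::coef(best$fit))
  # orient so hill > 0 and top is the high-dose asymptote
  if (p$hill < 0) {
    tmp <- p$top; p$top <- p$bottom; p$bottom <- tmp
    p$hill <- -p$hill
  }
  ec50 <- 10^p$le
  # asymptote coverage: if the fitted midpoint falls outside the dose range
  # or the fitted span extrapolates far beyond the observed responses, the
  # data did not constrain both plateaus
  if (ec50 < min(concentrations) || ec50 > max(concentrations) ||
      (span > 0 && (p$top - p$bottom) > 1.5 * span)) {
    warning("responses may not span both asymptote regions; EC50 poorly constrained")
  }
  fitted_fn <- function(x) {
    p$bottom + (p$top - p$bottom) / (1 + (ec50 / x)^p$hill)
  }
  list(top = p$top, bottom = p$bottom, hill = p$hill, ec50 = ec50,
       fitted = fitted_fn, rss = best$rss)
}

#' Percent LDH release (cytotoxicity)
#'
#' `100 * (experimental - effector_spontaneous - target_minimal) /
#' (target_maximal - target_minimal)`, where the spontaneous, minimal and
#' maximal releases are the T-cell-alone, target-alone and detergent-lysed
#' target absorbances. Values outside \[0, 100\] are clipped and flagged.
#'
#' @param experimental Mean absorbance of the effector + target well.
#' @param effector_spontaneous Mean absorbance of effector cells alone.
#' @param target_minimal Mean absorbance of target cells alone.
#' @param target_maximal Mean absorbance of fully lysed target cells.
#' @return Numeric percent lysis with attribute `clipped` (logical).
#' @export
ldh_release_pct <- function(experimental, effector_spontaneous,
                            target_minimal, target_maximal) {
  denom <- target_maximal - target_minimal
  if (denom <= 0) stop("target_maximal must exceed target_minimal",
                       call. = FALSE)
  pct <- 100 * (experimental - effector_spontaneous - target_minimal) / denom
  clipped <- pct < 0 | pct > 100
  structure(pmin(100, pmax(0, pct)), clipped = clipped)
}

#' Variant allele frequency
#'
#' @param alt_reads Variant-supporting read count.
#' @param depth Total read depth (> 0).
#' @return `alt_reads / depth` in \[0, 1\].
#' @export
vaf <- function(alt_reads, depth) {
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  if (any(alt_reads < 0 | alt_reads > depth)) {
    stop("alt_reads must satisfy 0 <= alt_reads <= depth", call. = FALSE)
  }
  alt_reads / depth
}
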