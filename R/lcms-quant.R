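#' @include utils.R
NULL

# Monoisotopic element masses (u), CODATA/IUPAC 2021 values, and the proton
# mass used for +1 protonation.
MONO_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
               O = 15.9949146196, P = 30.97376163)
PROTON_MASS <- 1.00727646688

#' Parse a molecular formula string into element counts
#'
#' Supports C, H, N, O and P (the elements of nucleosides and NADPH).
#'
#' @param formula character like `"C9H14N2O6"`, or an already-named integer
#'   vector (returned unchanged after validation). An empty string means the
#'   empty formula.
#' @return named integer vector of element counts.
#' @examples
#' parseFormula("C9H14N2O6")
#' @export
parseFormula <- function(formula) {
  if (is.numeric(formula)) {
    bad <- setdiff(names(formula), names(MONO_MASS))
    if (length(bad)) stop("unsupported element(s): ", paste(bad, collapse = ", "))
    if (any(formula < 0) || any(formula != round(formula)))
      stop("element counts must be non-negative integers")
    return(setNames(as.integer(formula), names(formula)))
  }
  counts <- setNames(integer(length(MONO_MASS)), names(MONO_MASS))
  if (!nzchar(formula)) return(counts)
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    if (!el %in% names(MONO_MASS))
      stop("unsupported element: ", el)
    counts[el] <- counts[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  counts
}

monoisotopicMass <- function(counts) sum(MONO_MASS[names(counts)] * counts)

#' MRM transition m/z values from molecular formulas
#'
#' Computes the protonated (+1) precursor ion m/z of a molecule and the
#' product ion after a neutral loss, both monoisotopic and nominal
#' (integer-rounded, matching how triple-quadrupole transitions are
#' written). Nucleosides typically lose the ribose moiety (C5H8O4, 132 u).
#'
#' @param formula molecular formula of the analyte (string or named counts).
#' @param neutral_loss formula of the neutral loss; empty (default) keeps
#'   product = precursor.
#' @return list with `precursor_mz`, `product_mz` (monoisotopic) and
#'   `precursor_nominal`, `product_nominal` (integers).
#' @examples
#' mzTransition("C9H14N2O6", "C5H8O4")   # dihydrouridine: 247 -> 115
#' mzTransition("C21H30N7O17P3", "NH3")  # NADPH: 746 -> 729
#' @export
mzTransition <- function(formula, neutral_loss = "") {
  f <- parseFormula(formula)
  l <- parseFormula(neutral_loss)
  full <- setNames(integer(length(MONO_MASS)), names(MONO_MASS))
  full[names(f)] <- f
  loss <- setNames(integer(length(MONO_MASS)), names(MONO_MASS))
  loss[names(l)] <- l
  if (any(loss > full))
    stop("neutral loss exceeds the molecular formula")
  precursor <- monoisotopicMass(full) + PROTON_MASS
  product <- precursor - monoisotopicMass(loss)
  list(precursor_mz = precursor, product_mz = product,
       precursor_nominal = as.integer(round(precursor)),
       product_nominal = as.integer(round(product)))
}

.areaOf <- function(rows, analyte, channel) {
  sel <- rows$analyte == analyte & rows$channel == channel
  if (!any(sel))
    stop(sprintf("missing (%s, %s) row in nucleoside table", analyte, channel))
  a <- rows$area[sel]
  if (length(a) > 1L) stop("duplicate (analyte, channel) rows in one sample")
  a
}

#' Relative dihydrouridine level of a sample versus a control
#'
#' The dihydrouridine MS peak area is normalised within each sample to the
#' adenosine UV area (injection-amount invariance), and the sample's
#' normalised signal is expressed as percent of the control's:
#' `100 * (D_MS/A_UV)_sample / (D_MS/A_UV)_control`.
#'
#' @param sample_rows,control_rows nucleoside-table rows (columns `analyte`,
#'   `channel`, `area`) for one sample and one control each.
#' @return relative level in percent (control = 100).
#' @export
relativeDLevel <- function(sample_rows, control_rows) {
  ds <- .areaOf(sample_rows, "D", "MS")
  as_ <- .areaOf(sample_rows, "A", "UV254")
  dc <- .areaOf(control_rows, "D", "MS")
  ac <- .areaOf(control_rows, "A", "UV254")
  if (as_ <= 0 || ac <= 0) stop("adenosine UV area must be positive")
  if (dc <= 0) stop("control dihydrouridine area must be positive")
  100 * (ds / as_) / (dc / ac)
}

#' Relative D levels for every sample of a nucleoside table
#'
#' Computes each sample's adenosine-normalised dihydrouridine ratio
#' (`D_MS / A_UV`) and expresses it as percent of the mean ratio over the
#' control samples, so the control group averages 100.
#'
#' @param nuc_table nucleoside table (columns `sample`, `analyte`,
#'   `channel`, `area`) holding one D/MS and one A/UV254 row per sample.
#' @param control_samples character vector of control sample names.
#' @return data.frame with columns `sample`, `ratio`, `relative_percent`.
#' @export
relativeDLevelTable <- function(nuc_table, control_samples) {
  bySample <- split(nuc_table, nuc_table$sample)
  missing <- setdiff(control_samples, names(bySample))
  if (length(missing))
    stop("control sample(s) absent from table: ", paste(missing, collapse = ", "))
  ratio <- vapply(bySample, function(rows)
    .areaOf(rows, "D", "MS") / .areaOf(rows, "A", "UV254"), numeric(1))
  ctrl <- mean(ratio[control_samples])
  if (ctrl <= 0) stop("control ratio must be positive")
  out <- data.frame(sample = names(ratio), ratio = unname(ratio),
                    relative_percent = unname(100 * ratio / ctrl),
                    stringsAsFactors = FALSE)
  out[match(unique(nuc_table$sample), out$sample), , drop = FALSE]
}

#' Replicate summary with Student's t-test against a control group
#'
#' Pooled-variance two-sample two-tailed Student's t-test (the classical
#' flavour; Welch available via `welch = TRUE`). With fewer than two
#' replicates in either group the summary is returned without a p-value and
#' flagged.
#'
#' @param values numeric replicate measurements of the group.
#' @param control_values numeric replicate measurements of the control.
#' @param welch use the Welch (unequal-variance) test instead.
#' @return data.frame row: mean, sd, n, p_value, significance (stars at
#'   0.05 / 0.01 / 0.001, "ns" otherwise), flagged.
#' @export
summarizeReplicates <- function(values, control_values, welch = FALSE) {
  n <- length(values)
  flagged <- n < 2L || length(control_values) < 2L
  p <- NA_real_
  if (!flagged) {
    if (sd(values) == 0 && sd(control_values) == 0) {
      # degenerate: identical constants compare as equal
      p <- if (isTRUE(all.equal(mean(values), mean(control_values)))) 1 else 0
    } else {
      p <- t.test(values, control_values, var.equal = !welch)$p.value
    }
  }
  data.frame(mean = mean(values), sd = if (n > 1L) sd(values) else NA_real_,
             n = n, p_value = p, significance = significanceLabel(p),
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Decompose total dihydrouridine into per-enzyme contributions
#'
#' Each single knockout's fractional decrease relative to wild type is that
#' enzyme's contribution: `contribution(E) = 100 * (1 - level(dE)/level(WT))`.
#' The closure residual `100 - sum(contributions)` is reported, not hidden:
#' a nonzero residual leaves room for redundancy or noise.
#'
#' @param wt_level wild-type relative level (same 100-scale as knockouts).
#' @param knockout_levels named numeric of single-knockout levels, names are
#'   enzymes.
#' @return list with `contributions` (named numeric, percent) and
#'   `residual` (percent).
#' @examples
#' decomposeContributions(100, c(DusA = 45, DusB = 77, DusC = 77))
#' @export
decomposeContributions <- function(wt_level, knockout_levels) {
  if (wt_level <= 0) stop("wild-type level must be positive")
  contrib <- 100 * (1 - knockout_levels / wt_level)
  list(contributions = contrib, residual = 100 - sum(contrib))
}

#' Linear external calibration and quantification
#'
#' Ordinary least squares of `area = a * conc + b` over the standards;
#' sample concentrations are `(area - b) / a`, with negative results
#' clamped to 0 and flagged.
#'
#' @param standard_conc,standard_area calibration standards (>= 2 distinct
#'   concentrations).
#' @param sample_areas areas to quantify.
#' @return list with `slope`, `intercept`, and `samples` (data.frame: area,
#'   conc, clamped).
#' @export
calibrateAndQuantify <- function(standard_conc, standard_area, sample_areas) {
  if (length(unique(standard_conc)) < 2L)
    stop("need at least two distinct standard concentrations")
  fit <- lm(standard_area ~ standard_conc)
  b <- unname(coef(fit)[1L]); a <- unname(coef(fit)[2L])
  conc <- (sample_areas - b) / a
  clamped <- conc < 0
  conc[clamped] <- 0
  list(slope = a, intercept = b,
       samples = data.frame(area = sample_areas, conc = conc,
                            clamped = clamped))
}

#' Fold drop of a metabolite between control and treated samples
#'
#' @param control_conc,treated_conc concentrations on the same scale.
#' @param lod limit of detection; used to bound the fold change when the
#'   treated concentration is 0.
#' @return list with `fold` and `censored` (TRUE when the treated value was
#'   0 and the fold is a lower bound `control/lod`).
#' @export
foldChange <- function(control_conc, treated_conc, lod = NULL) {
  if (treated_conc < 0 || control_conc < 0) stop("concentrations must be >= 0")
  if (treated_conc == 0) {
    if (is.null(lod)) stop("treated concentration is 0; supply lod for a bound")
    return(list(fold = control_conc / lod, censored = TRUE))
  }
  list(fold = control_conc / treated_conc, censored = FALSE)
}
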