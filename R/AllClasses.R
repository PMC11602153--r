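#' @include utils.R
NULL

DUS_ENZYMES <- c("DusA", "DusB", "DusC")

# Canonical D-loop label -> responsible synthase. DusA reduces positions 20
# and 20a, DusB position 17, DusC position 16.
LABEL_TO_ENZYME <- c("16" = "DusC", "17" = "DusB", "20" = "DusA", "20a" = "DusA")

#' Reference bundle: tRNA sequences plus dihydrouridine site annotations
#'
#' Holds a set of tRNA reference sequences (RNA alphabet) together with the
#' sidecar annotation of dihydrouridine sites: for each site the 1-based
#' sequence index, the canonical tRNA position label ("16", "17", "20",
#' "20a") and the synthase responsible. Validity enforces that every
#' annotated index carries a U, indices lie within the sequence, canonical
#' labels are unique per tRNA, and the enzyme matches the label rule.
#'
#' @slot sequences [Biostrings::RNAStringSet] of tRNA references, named by id.
#' @slot sites [S4Vectors::DataFrame] with columns `trna_id`, `seq_index`,
#'   `canonical_label`, `enzyme`.
#' @export
setClass("DReferenceBundle",
  slots = c(sequences = "RNAStringSet", sites = "DataFrame"))

setValidity("DReferenceBundle", function(object) {
  seqs <- object@sequences
  st <- object@sites
  need <- c("trna_id", "seq_index", "canonical_label", "enzyme")
  if (!all(need %in% colnames(st)))
    return(sprintf("sites must have columns %s", paste(need, collapse = ", ")))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    return("sequences must have unique names")
  if (nrow(st) == 0L) return(TRUE)
  if (!all(st$trna_id %in% names(seqs)))
    return(sprintf("annotation references unknown tRNA id(s): %s",
      paste(unique(setdiff(st$trna_id, names(seqs))), collapse = ", ")))
  if (!all(st$canonical_label %in% names(LABEL_TO_ENZYME)))
    return(sprintf("unknown canonical label(s): %s",
      paste(unique(setdiff(st$canonical_label, names(LABEL_TO_ENZYME))), collapse = ", ")))
  if (!all(st$enzyme %in% DUS_ENZYMES))
    return(sprintf("unknown enzyme(s): %s",
      paste(unique(setdiff(st$enzyme, DUS_ENZYMES)), collapse = ", ")))
  if (!all(st$enzyme == unname(LABEL_TO_ENZYME[st$canonical_label])))
    return("enzyme does not match the canonical-label rule (16->DusC, 17->DusB, 20/20a->DusA)")
  lens <- width(seqs)[match(st$trna_id, names(seqs))]
  if (any(st$seq_index < 1L | st$seq_index > lens))
    return("annotated seq_index outside the reference sequence")
  for (id in unique(st$trna_id)) {
    sel <- st[st$trna_id == id, , drop = FALSE]
    if (anyDuplicated(sel$canonical_label))
      return(sprintf("duplicate canonical label for %s", id))
    if (anyDuplicated(sel$seq_index))
      return(sprintf("duplicate seq_index for %s", id))
    base <- substring(as.character(seqs[[id]]), sel$seq_index, sel$seq_index)
    if (any(base != "U"))
      return(sprintf("annotated site is not U (%s position %s is %s)",
        id, paste(sel$seq_index[base != "U"], collapse = ","),
        paste(base[base != "U"], collapse = ",")))
  }
  TRUE
})

#' Per-site dihydrouridine occupancy profile
#'
#' Maps annotated D sites (`trna_id`, `seq_index`) to an occupancy fraction
#' in \[0, 1\]: the ground truth that the simulators encode and the pipeline
#' estimates. Carries the responsible enzyme per site so that strain and
#' treatment logic can act on it.
#'
#' @slot trna_id character vector of tRNA ids.
#' @slot seq_index integer vector of 1-based site indices.
#' @slot occupancy numeric in \[0, 1\].
#' @slot enzyme character, one of DusA/DusB/DusC per site.
#' @export
setClass("ModificationProfile",
  slots = c(trna_id = "character", seq_index = "integer",
            occupancy = "numeric", enzyme = "character"))

setValidity("ModificationProfile", function(object) {
  n <- length(object@trna_id)
  if (length(object@seq_index) != n || length(object@occupancy) != n ||
      length(object@enzyme) != n)
    return("all slots must have equal length")
  if (n && (any(object@occupancy < 0) || any(object@occupancy > 1)))
    return("occupancy must lie in [0, 1]")
  if (n && !all(object@enzyme %in% DUS_ENZYMES))
    return("enzyme must be one of DusA, DusB, DusC")
  if (anyDuplicated(paste(object@trna_id, object@seq_index)))
    return("duplicate (trna_id, seq_index) site")
  TRUE
})

#' Strain and treatment configuration
#'
#' Describes a strain (which Dus enzymes are present) and its growth
#' condition (paraquat concentration, aerobic or anaerobic). The
#' `sensitivity` slot gives, per enzyme, the fraction of its activity
#' retained under aerobic paraquat stress; it is applied only when
#' `paraquat_mM > 0` and `aerobic` is `TRUE`, encoding the observation that
#' paraquat needs oxygen to drain NADPH.
#'
#' @slot name strain label.
#' @slot enzymeActive named logical (DusA, DusB, DusC).
#' @slot paraquat_mM paraquat concentration in mM, >= 0.
#' @slot aerobic logical.
#' @slot sensitivity named numeric in \[0, 1\]: activity retained under
#'   aerobic paraquat.
#' @export
setClass("StrainConfig",
  slots = c(name = "character", enzymeActive = "logical",
            paraquat_mM = "numeric", aerobic = "logical",
            sensitivity = "numeric"))

setValidity("StrainConfig", function(object) {
  if (!identical(sort(names(object@enzymeActive)), sort(DUS_ENZYMES)))
    return("enzymeActive must be named DusA, DusB, DusC")
  if (!identical(sort(names(object@sensitivity)), sort(DUS_ENZYMES)))
    return("sensitivity must be named DusA, DusB, DusC")
  if (any(object@sensitivity < 0) || any(object@sensitivity > 1))
    return("sensitivity (retention) factors must lie in [0, 1]")
  if (object@paraquat_mM < 0) return("paraquat_mM must be >= 0")
  TRUE
})

#' Per-position stop-ratio profile
#'
#' The AlkAnilineSeq score surface: for every reference position, the number
#' of read 5' ends (`n5`), the coverage (`cov`), and the stop ratio
#' `n5/cov` in \[0, 1\]. Positions with coverage below `minCov` carry ratio 0
#' and a `low_coverage` flag rather than an unstable estimate.
#'
#' @slot counts [S4Vectors::DataFrame] with columns `trna_id`, `position`,
#'   `n5`, `cov`, `stop_ratio`, `low_coverage`.
#' @slot minCov numeric, the coverage threshold used.
#' @export
setClass("StopProfile", slots = c(counts = "DataFrame", minCov = "numeric"))

setValidity("StopProfile", function(object) {
  st <- object@counts
  need <- c("trna_id", "position", "n5", "cov", "stop_ratio", "low_coverage")
  if (!all(need %in% colnames(st)))
    return(sprintf("counts must have columns %s", paste(need, collapse = ", ")))
  if (nrow(st)) {
    if (any(st$n5 > st$cov)) return("n5 must not exceed coverage")
    if (any(st$stop_ratio < 0 | st$stop_ratio > 1))
      return("stop ratios must lie in [0, 1]")
    if (any(st$cov < object@minCov & (st$stop_ratio != 0 | !st$low_coverage)))
      return("positions below minCov must have ratio 0 and the low_coverage flag")
  }
  TRUE
})

#' Michaelis-Menten fit of NAD(P)H oxidation
#'
#' @slot Vmax maximal rate, uM/s.
#' @slot Km Michaelis constant, uM.
#' @slot kcat turnover number, 1/s (= Vmax / enzyme concentration).
#' @slot efficiency catalytic efficiency kcat/Km, 1/(uM s).
#' @slot se_Vmax,se_Km asymptotic standard errors.
#' @slot enzymeConc enzyme concentration used, uM.
#' @slot converged logical.
#' @slot detectable logical; `FALSE` when the Vmax confidence interval
#'   includes 0, reported as "no detectable activity".
#' @export
setClass("MMFit",
  slots = c(Vmax = "numeric", Km = "numeric", kcat = "numeric",
            efficiency = "numeric", se_Vmax = "numeric", se_Km = "numeric",
            enzymeConc = "numeric", converged = "logical",
            detectable = "logical"))

setValidity("MMFit", function(object) {
  if (object@converged) {
    if (!(object@Vmax > 0 && object@Km > 0))
      return("converged fits must have positive Vmax and Km")
    if (abs(object@efficiency - object@kcat / object@Km) >
        1e-8 * max(1, abs(object@efficiency)))
      return("efficiency must equal kcat/Km")
  }
  TRUE
})

#' Saturating time-course fit of in vitro dihydrouridylation
#'
#' Model: `D(t) = plateau * (1 - exp(-k t))`, t in minutes.
#'
#' @slot k first-order rate constant, 1/min.
#' @slot plateau saturation level, relative D units.
#' @slot t_half ln(2)/k, minutes.
#' @slot converged logical.
#' @export
setClass("TimecourseFit",
  slots = c(k = "numeric", plateau = "numeric", t_half = "numeric",
            converged = "logical"))

setValidity("TimecourseFit", function(object) {
  if (object@k < 0) return("k must be >= 0")
  if (object@converged && object@k > 0 &&
      abs(object@t_half - log(2) / object@k) > 1e-8 * object@t_half)
    return("t_half must equal ln(2)/k")
  TRUE
})
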