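#' @include AllClasses.R
NULL

#' Map a canonical D-loop position label to its dihydrouridine synthase
#'
#' In *E. coli* each D site is served by one enzyme: DusC reduces position
#' 16, DusB position 17, and DusA positions 20 and 20a.
#'
#' @param canonical_label character vector of labels in
#'   `c("16", "17", "20", "20a")`.
#' @return character vector of enzyme names.
#' @examples
#' enzymeForLabel(c("16", "17", "20a"))
#' @export
enzymeForLabel <- function(canonical_label) {
  label <- as.character(canonical_label)
  bad <- setdiff(unique(label), names(LABEL_TO_ENZYME))
  if (length(bad))
    stop("unknown canonical label(s): ", paste(bad, collapse = ", "))
  unname(LABEL_TO_ENZYME[label])
}

#' Construct a reference bundle from sequences and site annotations
#'
#' @param sequences a [Biostrings::RNAStringSet] (or named character vector
#'   of RNA sequences) of tRNA references.
#' @param sites a data.frame with columns `trna_id`, `seq_index`,
#'   `canonical_label` and optionally `enzyme` (filled in from the label rule
#'   when absent).
#' @return a validated [DReferenceBundle-class].
#' @export
DReferenceBundle <- function(sequences, sites) {
  if (!is(sequences, "RNAStringSet"))
    sequences <- Biostrings::RNAStringSet(sequences)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (nrow(sites)) {
    sites$trna_id <- as.character(sites$trna_id)
    sites$seq_index <- as.integer(sites$seq_index)
    sites$canonical_label <- as.character(sites$canonical_label)
    if (is.null(sites$enzyme) || all(is.na(sites$enzyme)))
      sites$enzyme <- enzymeForLabel(sites$canonical_label)
    sites$enzyme <- as.character(sites$enzyme)
  } else {
    sites <- data.frame(trna_id = character(), seq_index = integer(),
      canonical_label = character(), enzyme = character(),
      stringsAsFactors = FALSE)
  }
  new("DReferenceBundle", sequences = sequences, sites = DataFrame(sites))
}

#' Read a reference bundle from FASTA plus an annotation sidecar
#'
#' The FASTA may use either U or T; T is converted to U with a warning. The
#' sidecar is a 4-column TSV with header `trna_id`, `seq_index` (1-based),
#' `canonical_label`, `enzyme`. An annotation file with a header but no rows
#' yields a bundle with the references and an empty site table.
#'
#' @param fasta_path path to the reference FASTA.
#' @param annotation_tsv_path path to the annotation TSV.
#' @return a validated [DReferenceBundle-class].
#' @export
readReferenceBundle <- function(fasta_path, annotation_tsv_path) {
  raw <- Biostrings::readBStringSet(fasta_path)
  txt <- as.character(raw)
  if (any(grepl("[Tt]", txt))) {
    warning("reference FASTA contains T; converting to U")
    txt <- chartr("Tt", "Uu", txt)
  }
  names(txt) <- sub("\\s.*$", "", names(txt))
  anno <- read.delim(annotation_tsv_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("trna_id", "seq_index", "canonical_label", "enzyme")
  if (!all(need %in% colnames(anno)))
    stop("annotation TSV must have columns ", paste(need, collapse = ", "))
  DReferenceBundle(Biostrings::RNAStringSet(txt), anno[need])
}

#' Write a reference bundle as FASTA plus annotation TSV
#'
#' @param bundle a [DReferenceBundle-class].
#' @param fasta_path,annotation_tsv_path output paths.
#' @return invisibly, the two paths.
#' @export
writeReferenceBundle <- function(bundle, fasta_path, annotation_tsv_path) {
  Biostrings::writeXStringSet(referenceSequences(bundle), fasta_path)
  writeTsv(as.data.frame(dSites(bundle)), annotation_tsv_path)
  invisible(c(fasta_path, annotation_tsv_path))
}

#' @describeIn DReferenceBundle tRNA reference sequences as an RNAStringSet.
#' @param bundle a [DReferenceBundle-class].
#' @export
referenceSequences <- function(bundle) bundle@sequences

#' @describeIn DReferenceBundle annotated D sites as a DataFrame.
#' @export
dSites <- function(bundle) bundle@sites

#' @describeIn DReferenceBundle tRNA identifiers.
#' @export
referenceIds <- function(bundle) names(bundle@sequences)

setMethod("show", "DReferenceBundle", function(object) {
  cat("DReferenceBundle with", length(object@sequences), "tRNA reference(s) and",
      nrow(object@sites), "annotated D site(s)\n")
  if (nrow(object@sites)) {
    tab <- table(object@sites$canonical_label)
    cat("  sites per canonical position:",
        paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = "  "), "\n")
  }
})

#' Construct a per-site occupancy profile
#'
#' @param trna_id,seq_index,occupancy parallel vectors defining the profile.
#' @param enzyme optional enzyme per site; looked up from `bundle` when
#'   omitted.
#' @param bundle optional [DReferenceBundle-class] used to fill in enzymes
#'   and to check that every site is annotated.
#' @return a [ModificationProfile-class].
#' @export
ModificationProfile <- function(trna_id, seq_index, occupancy, enzyme = NULL,
                                bundle = NULL) {
  trna_id <- as.character(trna_id)
  seq_index <- as.integer(seq_index)
  occupancy <- as.numeric(occupancy)
  if (!is.null(bundle)) {
    st <- as.data.frame(dSites(bundle))
    key <- paste(trna_id, seq_index)
    refkey <- paste(st$trna_id, st$seq_index)
    if (!all(key %in% refkey))
      stop("profile site(s) absent from bundle annotation: ",
           paste(setdiff(key, refkey), collapse = "; "))
    if (is.null(enzyme)) enzyme <- st$enzyme[match(key, refkey)]
  }
  if (is.null(enzyme)) stop("enzyme must be given when no bundle is supplied")
  new("ModificationProfile", trna_id = trna_id, seq_index = seq_index,
      occupancy = occupancy, enzyme = as.character(enzyme))
}

#' Baseline wild-type occupancy profile over a bundle's annotated sites
#'
#' Assigns the same occupancy (default 0.90) to every annotated D site.
#'
#' @param bundle a [DReferenceBundle-class].
#' @param occupancy baseline occupancy fraction in \[0, 1\].
#' @return a [ModificationProfile-class].
#' @export
baselineProfile <- function(bundle, occupancy = 0.9) {
  st <- as.data.frame(dSites(bundle))
  ModificationProfile(st$trna_id, st$seq_index,
    rep(occupancy, nrow(st)), enzyme = st$enzyme)
}

#' @describeIn ModificationProfile occupancy values, named by
#'   `trna_id:seq_index`.
#' @param profile a [ModificationProfile-class].
#' @export
occupancies <- function(profile) {
  setNames(profile@occupancy, paste0(profile@trna_id, ":", profile@seq_index))
}

#' @export
#' @describeIn ModificationProfile as a plain data.frame.
#' @param x a [ModificationProfile-class].
#' @param ... unused.
as.data.frame.ModificationProfile <- function(x, ...) {
  data.frame(trna_id = x@trna_id, seq_index = x@seq_index,
    occupancy = x@occupancy, enzyme = x@enzyme, stringsAsFactors = FALSE)
}
setMethod("as.data.frame", "ModificationProfile",
  function(x, ...) as.data.frame.ModificationProfile(x, ...))

setMethod("show", "ModificationProfile", function(object) {
  cat("ModificationProfile over", length(object@trna_id), "site(s)")
  if (length(object@trna_id))
    cat("; mean occupancy", sprintf("%.3f", mean(object@occupancy)))
  cat("\n")
})

#' Construct a strain/treatment configuration
#'
#' @param name strain label, e.g. `"WT"` or `"dusA_KO"`.
#' @param knockouts character vector of knocked-out enzymes (subset of
#'   DusA/DusB/DusC).
#' @param paraquat_mM paraquat concentration (mM).
#' @param aerobic logical; paraquat only acts with oxygen present.
#' @param sensitivity named numeric: activity retained per enzyme under
#'   aerobic paraquat. Defaults encode the qualitative ordering observed in
#'   vivo (DusA insensitive, DusB intermediate, DusC most sensitive); the
#'   numbers are configuration, not measurements.
#' @return a [StrainConfig-class].
#' @examples
#' strainConfig("dusA_KO", knockouts = "DusA")
#' strainConfig("WT_PQ", paraquat_mM = 0.3, aerobic = TRUE)
#' @export
strainConfig <- function(name, knockouts = character(), paraquat_mM = 0,
                         aerobic = TRUE,
                         sensitivity = c(DusA = 1.0, DusB = 0.6, DusC = 0.4)) {
  bad <- setdiff(knockouts, DUS_ENZYMES)
  if (length(bad)) stop("unknown enzyme(s) in knockouts: ", paste(bad, collapse = ", "))
  active <- setNames(!(DUS_ENZYMES %in% knockouts), DUS_ENZYMES)
  new("StrainConfig", name = name, enzymeActive = active,
      paraquat_mM = paraquat_mM, aerobic = aerobic,
      sensitivity = sensitivity[DUS_ENZYMES])
}

setMethod("show", "StrainConfig", function(object) {
  ko <- names(object@enzymeActive)[!object@enzymeActive]
  cat("StrainConfig", object@name, "|",
      if (length(ko)) paste0("knockout: ", paste(ko, collapse = ",")) else "all Dus active",
      "| paraquat", object@paraquat_mM, "mM |",
      if (object@aerobic) "aerobic" else "anaerobic", "\n")
})

#' Effective site occupancies for a strain under its treatment
#'
#' Applies the knockout and redox-stress logic to a baseline profile:
#' `occ(site) = baseline(site) * active(enzyme) * retention(enzyme)`, where
#' the retention factor is applied only under aerobic paraquat treatment
#' (anaerobic paraquat leaves occupancies unchanged, as observed in vivo).
#' A triple knockout therefore yields an all-zero profile regardless of
#' treatment, and no occupancy ever exceeds its baseline.
#'
#' @param baseline a [ModificationProfile-class] of wild-type occupancies.
#' @param strain a [StrainConfig-class].
#' @return a [ModificationProfile-class] with the same sites.
#' @export
effectiveOccupancy <- function(baseline, strain) {
  stopifnot(is(baseline, "ModificationProfile"), is(strain, "StrainConfig"))
  act <- as.numeric(strain@enzymeActive[baseline@enzyme])
  ret <- if (strain@paraquat_mM > 0 && strain@aerobic)
    as.numeric(strain@sensitivity[baseline@enzyme]) else 1
  new("ModificationProfile", trna_id = baseline@trna_id,
      seq_index = baseline@seq_index,
      occupancy = baseline@occupancy * act * ret,
      enzyme = baseline@enzyme)
}
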