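#' @include core-model.R
NULL

.normalizeReads <- function(reads) {
  if (is(reads, "XStringSet")) {
    nm <- names(reads)
    reads <- setNames(as.character(reads), nm)
  } else if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
             grepl("\\.(fastq|fq)$", reads, ignore.case = TRUE)) {
    x <- Biostrings::readDNAStringSet(reads, format = "fastq")
    reads <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  }
  if (!is.character(reads)) stop("reads must be a character vector, XStringSet or FASTQ path")
  if (is.null(names(reads))) names(reads) <- sprintf("read_%06d", seq_along(reads))
  setNames(chartr("Tt", "UU", toupper(reads)), names(reads))
}

#' Map reads end-to-end against the tRNA references
#'
#' Every read is scored at every offset of every reference by end-to-end
#' Hamming mismatch count (no indels; N matches nothing). The best placement
#' wins; reads whose best score exceeds `max_mismatch` are unmapped, and
#' reads with two or more best-score placements anywhere are discarded as
#' multimapped, keeping the output deterministic.
#'
#' @param reads named character vector of read sequences, an
#'   [Biostrings::XStringSet], or the path to a FASTQ file. T and U are
#'   unified.
#' @param bundle a [DReferenceBundle-class].
#' @param max_mismatch maximum tolerated mismatches (default 2).
#' @return list with `alignments` (data.frame: read_id, trna_id,
#'   start_index, end_index, mismatches) and `report` (mapped / unmapped /
#'   multimapped / total counts).
#' @export
mapReads <- function(reads, bundle, max_mismatch = 2) {
  stopifnot(is(bundle, "DReferenceBundle"))
  reads <- .normalizeReads(reads)
  refs <- as.character(referenceSequences(bundle))
  report <- c(mapped = 0L, unmapped = 0L, multimapped = 0L,
              total = length(reads))
  empty <- data.frame(read_id = character(), trna_id = character(),
                      start_index = integer(), end_index = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (!length(reads))
    return(list(alignments = empty, report = as.list(report)))
  uniq <- unique(unname(reads))
  hits <- cpp_map_reads(uniq, unname(refs), as.integer(max_mismatch))
  idx <- match(unname(reads), uniq)
  ref_i <- hits$ref[idx]; start <- hits$start[idx]
  mm <- hits$mismatches[idx]; nb <- hits$n_best[idx]
  unmapped <- is.na(ref_i)
  multi <- !unmapped & nb >= 2L
  keep <- !unmapped & !multi
  aln <- data.frame(read_id = names(reads)[keep],
                    trna_id = names(refs)[ref_i[keep]],
                    start_index = start[keep],
                    end_index = start[keep] + nchar(reads[keep]) - 1L,
                    mismatches = mm[keep], stringsAsFactors = FALSE)
  rownames(aln) <- NULL
  report["mapped"] <- sum(keep)
  report["unmapped"] <- sum(unmapped)
  report["multimapped"] <- sum(multi)
  list(alignments = aln, report = as.list(report))
}

#' Tally read 5' ends and coverage per reference position
#'
#' @param aligned alignments data.frame from [mapReads()] (or the list it
#'   returns).
#' @param bundle a [DReferenceBundle-class].
#' @return data.frame with one row per (trna_id, position): `n5` (reads
#'   whose 5' end sits at the position) and `cov` (reads covering it,
#'   including those starting there). Positions without data are present
#'   with zeros.
#' @export
tallyAlignments <- function(aligned, bundle) {
  stopifnot(is(bundle, "DReferenceBundle"))
  if (is.list(aligned) && !is.data.frame(aligned)) aligned <- aligned$alignments
  lens <- setNames(width(referenceSequences(bundle)), referenceIds(bundle))
  out <- lapply(names(lens), function(id) {
    L <- lens[[id]]
    sel <- aligned[aligned$trna_id == id, , drop = FALSE]
    n5 <- tabulate(sel$start_index, nbins = L)
    cov <- if (nrow(sel)) {
      as.integer(IRanges::coverage(
        IRanges::IRanges(sel$start_index, sel$end_index), width = L))
    } else integer(L)
    data.frame(trna_id = id, position = seq_len(L), n5 = n5, cov = cov,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compute the per-position stop-ratio profile
#'
#' `stop_ratio(i) = n5(i) / cov(i)` wherever coverage reaches `min_cov`;
#' positions below the coverage threshold get ratio 0 and a low-coverage
#' flag rather than an unstable estimate.
#'
#' @param counts data.frame from [tallyAlignments()].
#' @param min_cov minimum coverage for a defined ratio (default 10).
#' @return a [StopProfile-class].
#' @export
stopRatio <- function(counts, min_cov = 10) {
  low <- counts$cov < min_cov
  ratio <- ifelse(low, 0, ifelse(counts$cov > 0, counts$n5 / counts$cov, 0))
  df <- DataFrame(trna_id = counts$trna_id, position = counts$position,
                  n5 = counts$n5, cov = counts$cov, stop_ratio = ratio,
                  low_coverage = low)
  new("StopProfile", counts = df, minCov = min_cov)
}

#' @describeIn StopProfile the per-position table as a data.frame.
#' @param profile a [StopProfile-class].
#' @export
stopCounts <- function(profile) as.data.frame(profile@counts)

setMethod("show", "StopProfile", function(object) {
  st <- object@counts
  cat("StopProfile over", length(unique(st$trna_id)), "reference(s),",
      nrow(st), "positions; minCov =", object@minCov, "\n")
  ok <- !st$low_coverage
  if (any(ok))
    cat(sprintf("  max stop ratio %.4f; %d low-coverage position(s)\n",
                max(st$stop_ratio[ok]), sum(!ok)))
})

#' Infer dihydrouridine positions from a stop profile
#'
#' Cleavage chemistry exposes the ligatable 5'-phosphate one nucleotide
#' after the modified site, so the candidate D index is the stop position
#' minus 1. In `annotated` mode every annotated site is reported with the
#' ratio read at its stop position (site index + 1) and `called` set where
#' the ratio reaches `threshold`; in `discovery` mode any position whose
#' back-shifted index carries a U and whose ratio reaches `threshold` is
#' called.
#'
#' @param profile a [StopProfile-class].
#' @param bundle the [DReferenceBundle-class] the profile was computed on.
#' @param threshold minimum stop ratio for a call (default 0.05, above the
#'   null-library ceiling).
#' @param mode `"annotated"` or `"discovery"`.
#' @return data.frame with columns `trna_id`, `d_index`, `stop_position`,
#'   `canonical_label`, `enzyme`, `stop_ratio`, `low_coverage`, `called`.
#' @export
inferDPositions <- function(profile, bundle, threshold = 0.05,
                            mode = c("annotated", "discovery")) {
  mode <- match.arg(mode)
  stopifnot(is(profile, "StopProfile"), is(bundle, "DReferenceBundle"))
  st <- stopCounts(profile)
  anno <- as.data.frame(dSites(bundle))
  key <- function(id, pos) paste(id, pos)
  if (mode == "annotated") {
    if (!nrow(anno))
      return(data.frame(trna_id = character(), d_index = integer(),
        stop_position = integer(), canonical_label = character(),
        enzyme = character(), stop_ratio = numeric(),
        low_coverage = logical(), called = logical(),
        stringsAsFactors = FALSE))
    stop_pos <- anno$seq_index + 1L
    m <- match(key(anno$trna_id, stop_pos), key(st$trna_id, st$position))
    ratio <- ifelse(is.na(m), 0, st$stop_ratio[m])
    low <- ifelse(is.na(m), TRUE, st$low_coverage[m])
    out <- data.frame(trna_id = anno$trna_id, d_index = anno$seq_index,
      stop_position = stop_pos, canonical_label = anno$canonical_label,
      enzyme = anno$enzyme, stop_ratio = ratio, low_coverage = low,
      called = !low & ratio >= threshold, stringsAsFactors = FALSE)
  } else {
    seqs <- as.character(referenceSequences(bundle))
    cand <- st[st$position >= 2L & !st$low_coverage &
                 st$stop_ratio >= threshold, , drop = FALSE]
    if (nrow(cand)) {
      base <- substring(seqs[cand$trna_id], cand$position - 1L, cand$position - 1L)
      cand <- cand[base == "U", , drop = FALSE]
    }
    m <- if (nrow(cand))
      match(key(cand$trna_id, cand$position - 1L), key(anno$trna_id, anno$seq_index))
    else integer(0)
    out <- data.frame(trna_id = cand$trna_id, d_index = cand$position - 1L,
      stop_position = cand$position,
      canonical_label = ifelse(is.na(m), NA_character_, anno$canonical_label[m]),
      enzyme = ifelse(is.na(m), NA_character_, anno$enzyme[m]),
      stop_ratio = cand$stop_ratio, low_coverage = cand$low_coverage,
      called = rep(TRUE, nrow(cand)), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Compare two stop profiles as percent of control
#'
#' `percent(i) = 100 * ratio_treated(i) / ratio_control(i)` per position.
#' Sites whose control ratio is flagged low-coverage or zero are reported
#' as undefined (`NA`), never as infinity.
#'
#' @param profile_treated,profile_control [StopProfile-class] objects
#'   computed on the same bundle.
#' @return data.frame with columns `trna_id`, `position`, `ratio_treated`,
#'   `ratio_control`, `percent_of_control`, `defined`.
#' @export
compareConditions <- function(profile_treated, profile_control) {
  st_t <- stopCounts(profile_treated)
  st_c <- stopCounts(profile_control)
  m <- match(paste(st_t$trna_id, st_t$position),
             paste(st_c$trna_id, st_c$position))
  if (anyNA(m)) stop("profiles were not computed on the same positions")
  rc <- st_c$stop_ratio[m]
  lowc <- st_c$low_coverage[m]
  defined <- !lowc & rc > 0
  pct <- ifelse(defined, 100 * st_t$stop_ratio / rc, NA_real_)
  data.frame(trna_id = st_t$trna_id, position = st_t$position,
             ratio_treated = st_t$stop_ratio, ratio_control = rc,
             percent_of_control = pct, defined = defined,
             stringsAsFactors = FALSE)
}

#' Summarise a condition comparison per Dus enzyme
#'
#' Joins the percent-of-control table to the annotated stop positions
#' (site index + 1) and reports, per enzyme: the number of defined sites,
#' how many decreased (percent < 100), the decreased fraction, and the mean
#' percent of control.
#'
#' @param comparison data.frame from [compareConditions()].
#' @param bundle the [DReferenceBundle-class] carrying the annotations.
#' @return data.frame with one row per enzyme observed.
#' @export
enzymeLevelSummary <- function(comparison, bundle) {
  anno <- as.data.frame(dSites(bundle))
  empty <- data.frame(enzyme = character(), n_sites = integer(),
    n_decreased = integer(), fraction_decreased = numeric(),
    mean_percent = numeric(), stringsAsFactors = FALSE)
  if (!nrow(comparison) || !nrow(anno)) return(empty)
  m <- match(paste(anno$trna_id, anno$seq_index + 1L),
             paste(comparison$trna_id, comparison$position))
  sel <- !is.na(m) & comparison$defined[m]
  if (!any(sel)) return(empty)
  df <- data.frame(enzyme = anno$enzyme[sel],
                   percent = comparison$percent_of_control[m[sel]],
                   stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, df$enzyme), function(g)
    data.frame(enzyme = g$enzyme[1L], n_sites = nrow(g),
               n_decreased = sum(g$percent < 100),
               fraction_decreased = mean(g$percent < 100),
               mean_percent = mean(g$percent), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$enzyme), , drop = FALSE]
}

#' Write a stop profile as a TSV table (optionally bedGraph tracks)
#'
#' The TSV carries 1-based positions with canonical labels where annotated;
#' bedGraph output converts to that format's 0-based half-open convention.
#'
#' @param profile a [StopProfile-class].
#' @param bundle the [DReferenceBundle-class] (for canonical labels).
#' @param tsv_path output TSV path.
#' @param bedgraph_path optional bedGraph output path.
#' @return invisibly, `tsv_path`.
#' @export
writeStopProfile <- function(profile, bundle, tsv_path, bedgraph_path = NULL) {
  st <- stopCounts(profile)
  anno <- as.data.frame(dSites(bundle))
  m <- match(paste(st$trna_id, st$position),
             paste(anno$trna_id, anno$seq_index + 1L))
  st$canonical_label <- ifelse(is.na(m), "", anno$canonical_label[m])
  writeTsv(st[c("trna_id", "position", "canonical_label", "n5", "cov",
                "stop_ratio", "low_coverage")], tsv_path)
  if (!is.null(bedgraph_path)) {
    bg <- data.frame(chrom = st$trna_id, start = st$position - 1L,
                     end = st$position, value = st$stop_ratio)
    write.table(bg, bedgraph_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}
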