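#' @include core-model.R
NULL

#' Parameters for the AlkAnilineSeq library simulator
#'
#' @param moleculesPerTrna number of tRNA molecules simulated per reference.
#' @param alkCleavageProb probability that a dihydrouridine ring is opened by
#'   alkaline hydrolysis and scissioned by aniline, conditional on the site
#'   being modified. The true yield is unknown; the default 0.50 models
#'   partial cleavage and keeps multiple-cleavage fragment loss between the
#'   closely spaced D-loop sites moderate, so every site retains signal.
#' @param backgroundBreakRate per-inter-nucleotide probability of a residual
#'   ligatable background break (incomplete dephosphorylation); the noise
#'   floor that makes null controls meaningful.
#' @param terminalLigationProb probability that a molecule's intact 5'
#'   terminus is ligation-competent. Mature tRNA carries a 5'-monophosphate,
#'   so the default is 1: essentially every molecule contributes a terminus
#'   read, which is what gives null libraries their high coverage relative
#'   to background stops.
#' @param readLen sequencing read length (nt; 50-bp single-end layout).
#' @param minFragmentLen shortest fragment that survives library prep.
#' @param seqErrorRate per-base uniform substitution rate (default 0: reads
#'   are exact reference substrings).
#' @param seed integer seed for this library.
#' @return a validated parameter list of class `AASLibraryParams`.
#' @export
aasLibraryParams <- function(moleculesPerTrna = 2000, alkCleavageProb = 0.5,
                             backgroundBreakRate = 1e-3,
                             terminalLigationProb = 1.0, readLen = 50,
                             minFragmentLen = 15, seqErrorRate = 0, seed = 1) {
  p <- list(moleculesPerTrna = as.integer(moleculesPerTrna),
            alkCleavageProb = alkCleavageProb,
            backgroundBreakRate = backgroundBreakRate,
            terminalLigationProb = terminalLigationProb,
            readLen = as.integer(readLen),
            minFragmentLen = as.integer(minFragmentLen),
            seqErrorRate = seqErrorRate, seed = as.integer(seed))
  probs <- c(p$alkCleavageProb, p$backgroundBreakRate, p$terminalLigationProb,
             p$seqErrorRate)
  stopifnot(all(probs >= 0 & probs <= 1), p$moleculesPerTrna >= 1,
            p$readLen >= p$minFragmentLen, p$minFragmentLen >= 1)
  class(p) <- "AASLibraryParams"
  p
}

#' Build a seeded fixture bundle of tRNA-like references
#'
#' Generates `n_trnas` 76-nt tRNA-like sequences (random body, CCA 3' end)
#' with dihydrouridine annotations in the D-loop: every tRNA carries sites
#' at canonical positions 16, 17 and 20; about half additionally carry 20a
#' (seeded draw, deterministic given the seed). This composition gives the
#' DusA-served positions (20/20a) roughly half of all sites, matching the
#' enzyme's observed share of total dihydrouridine. Canonical labels map
#' directly onto sequence indices (20a at index 21). Pairwise edit
#' distance >= 5 is enforced by rejection so the references are
#' distinguishable by the mapper.
#'
#' @param n_trnas number of references (>= 1).
#' @param seed integer seed.
#' @return a [DReferenceBundle-class].
#' @export
buildFixtureReferences <- function(n_trnas, seed = 1) {
  stopifnot(n_trnas >= 1)
  L <- 76L
  aa <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
          "Tyr", "Val")
  withSeed(streamSeed(seed, "fixture-references"), {
    has20a <- runif(n_trnas) < 0.5
    seqs <- character(n_trnas)
    for (i in seq_len(n_trnas)) {
      repeat {
        s <- sample(c("A", "C", "G", "U"), L, replace = TRUE)
        s[16:17] <- "U"
        s[20] <- "U"
        if (has20a[i]) s[21] <- "U"
        s[(L - 2):L] <- c("C", "C", "A")
        cand <- paste(s, collapse = "")
        if (i == 1L || all(utils::adist(cand, seqs[seq_len(i - 1L)]) >= 5)) break
      }
      seqs[i] <- cand
    }
    anticodon <- vapply(seq_len(n_trnas), function(i)
      paste(sample(c("A", "C", "G", "U"), 3, replace = TRUE), collapse = ""),
      character(1))
    ids <- sprintf("tRNA-%s-%s-%d", aa[(seq_len(n_trnas) - 1L) %% 20L + 1L],
                   anticodon, (seq_len(n_trnas) - 1L) %/% 20L + 1L)
    ids <- make.unique(ids, sep = "_")
    sites <- do.call(rbind, lapply(seq_len(n_trnas), function(i) {
      idx <- c(16L, 17L, 20L, if (has20a[i]) 21L)
      lab <- c("16", "17", "20", if (has20a[i]) "20a")
      data.frame(trna_id = ids[i], seq_index = idx, canonical_label = lab,
                 stringsAsFactors = FALSE)
    }))
    DReferenceBundle(setNames(seqs, ids), sites)
  })
}

#' Simulate an AlkAnilineSeq read library
#'
#' Per simulated molecule: each modified D site at index `i` is cleaved with
#' probability `occupancy(i) * alkCleavageProb`, exposing a ligatable
#' 5'-phosphate at the N+1 nucleotide (`i + 1`); every inter-nucleotide
#' position independently acquires a ligatable background break with
#' probability `backgroundBreakRate`; the intact 5' terminus is ligatable
#' with probability `terminalLigationProb`. Each ligatable fragment of
#' length >= `minFragmentLen` yields one read: the reference substring from
#' its 5' end, truncated at `readLen` or the next break. A truth table
#' records every read's origin.
#'
#' @param bundle a [DReferenceBundle-class].
#' @param profile a [ModificationProfile-class] on the bundle's sites.
#' @param params an [aasLibraryParams()] list.
#' @return list with `reads` (named character vector, RNA alphabet), `truth`
#'   (data.frame: read_id, molecule, trna_id, start_index, length, cause)
#'   and `params`.
#' @export
simulateAASLibrary <- function(bundle, profile, params = aasLibraryParams()) {
  stopifnot(is(bundle, "DReferenceBundle"), is(profile, "ModificationProfile"),
            inherits(params, "AASLibraryParams"))
  st <- as.data.frame(dSites(bundle))
  pkey <- paste(profile@trna_id, profile@seq_index)
  bkey <- paste(st$trna_id, st$seq_index)
  if (!all(pkey %in% bkey))
    stop("profile site(s) absent from bundle: ",
         paste(setdiff(pkey, bkey), collapse = "; "))
  seqs <- as.character(referenceSequences(bundle))
  withSeed(streamSeed(params$seed, "aas-library"), {
    out_reads <- list(); out_truth <- list()
    mol_offset <- 0L
    for (id in names(seqs)) {
      sq <- seqs[[id]]
      L <- nchar(sq)
      M <- params$moleculesPerTrna
      dIdx <- profile@seq_index[profile@trna_id == id]
      dOcc <- profile@occupancy[profile@trna_id == id]
      keep <- dIdx < L  # a break needs an N+1 nucleotide
      dIdx <- dIdx[keep]; dOcc <- dOcc[keep]
      # breaks: data.frame(mol, pos, cause); pos = inter-nucleotide index
      brk_mol <- integer(0); brk_pos <- integer(0); brk_cause <- character(0)
      if (params$backgroundBreakRate > 0) {
        hits <- which(matrix(runif(M * (L - 1L)) < params$backgroundBreakRate,
                             nrow = M), arr.ind = TRUE)
        brk_mol <- c(brk_mol, hits[, 1L]); brk_pos <- c(brk_pos, hits[, 2L])
        brk_cause <- c(brk_cause, rep("background", nrow(hits)))
      }
      for (k in seq_along(dIdx)) {
        p <- dOcc[k] * params$alkCleavageProb
        if (p <= 0) next
        m <- which(runif(M) < p)
        brk_mol <- c(brk_mol, m); brk_pos <- c(brk_pos, rep(dIdx[k], length(m)))
        brk_cause <- c(brk_cause, rep("d_cleavage", length(m)))
      }
      termOK <- runif(M) < params$terminalLigationProb
      reads <- character(0); truth <- list()
      haveBreaks <- unique(brk_mol)
      # molecules without any break: at most one terminus read each
      noBrk <- if (length(haveBreaks)) setdiff(which(termOK), haveBreaks) else which(termOK)
      if (length(noBrk) && L >= params$minFragmentLen) {
        rd <- substr(sq, 1L, min(params$readLen, L))
        reads <- c(reads, rep(rd, length(noBrk)))
        truth[[length(truth) + 1L]] <- data.frame(
          molecule = mol_offset + noBrk, trna_id = id, start_index = 1L,
          length = nchar(rd), cause = "terminus", stringsAsFactors = FALSE)
      }
      if (length(haveBreaks)) {
        # one break per (molecule, bond); d_cleavage wins over background
        prio <- ifelse(brk_cause == "d_cleavage", 0L, 1L)
        ord <- order(brk_mol, brk_pos, prio)
        brk_mol <- brk_mol[ord]; brk_pos <- brk_pos[ord]; brk_cause <- brk_cause[ord]
        dup <- duplicated(paste(brk_mol, brk_pos))
        brk_mol <- brk_mol[!dup]; brk_pos <- brk_pos[!dup]; brk_cause <- brk_cause[!dup]
        byMol <- split(seq_along(brk_mol), brk_mol)
        for (mol_chr in names(byMol)) {
          idxs <- byMol[[mol_chr]]
          mol <- brk_mol[idxs[1L]]
          pos <- brk_pos[idxs]; cause <- brk_cause[idxs]
          starts <- c(1L, pos + 1L)
          ends <- c(pos, L)
          causes <- c("terminus", cause)
          lig <- c(termOK[mol], rep(TRUE, length(pos)))
          len <- ends - starts + 1L
          sel <- lig & len >= params$minFragmentLen
          if (!any(sel)) next
          rl <- pmin(len[sel], params$readLen)
          rd <- substring(sq, starts[sel], starts[sel] + rl - 1L)
          reads <- c(reads, rd)
          truth[[length(truth) + 1L]] <- data.frame(
            molecule = mol_offset + mol, trna_id = id,
            start_index = starts[sel], length = rl, cause = causes[sel],
            stringsAsFactors = FALSE)
        }
      }
      if (length(truth)) {
        tr <- do.call(rbind, truth)
        out_reads[[id]] <- reads
        out_truth[[id]] <- tr
      }
      mol_offset <- mol_offset + M
    }
    reads <- as.character(unlist(out_reads, use.names = FALSE))
    truth <- if (length(out_truth)) do.call(rbind, out_truth) else
      data.frame(molecule = integer(), trna_id = character(),
                 start_index = integer(), length = integer(),
                 cause = character(), stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    if (nrow(truth)) {
      ord <- order(truth$molecule, truth$start_index)
      truth <- truth[ord, , drop = FALSE]
      reads <- reads[ord]
      rownames(truth) <- NULL
    }
    if (params$seqErrorRate > 0 && length(reads)) {
      reads <- vapply(reads, function(r) {
        ch <- strsplit(r, "")[[1L]]
        err <- runif(length(ch)) < params$seqErrorRate
        if (any(err))
          ch[err] <- vapply(ch[err], function(b)
            sample(setdiff(c("A", "C", "G", "U"), b), 1L), character(1))
        paste(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    ids <- sprintf("read_%06d", seq_along(reads))
    truth <- cbind(read_id = ids, truth, stringsAsFactors = FALSE)
    list(reads = setNames(reads, ids), truth = truth, params = params)
  })
}

#' Write a simulated library as FASTQ (plus optional truth TSV)
#'
#' Reads are written in DNA alphabet (U converted to T, as a sequencer
#' reports them) with constant quality "I".
#'
#' @param library result of [simulateAASLibrary()].
#' @param fastq_path output FASTQ path.
#' @param truth_path optional truth-table TSV path.
#' @return invisibly, `fastq_path`.
#' @export
writeAASLibrary <- function(library, fastq_path, truth_path = NULL) {
  dna <- Biostrings::DNAStringSet(chartr("Uu", "Tt", library$reads))
  qual <- Biostrings::BStringSet(vapply(width(dna), function(w)
    paste(rep("I", w), collapse = ""), character(1)))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(qual)),
    fastq_path)
  if (!is.null(truth_path)) writeTsv(library$truth, truth_path)
  invisible(fastq_path)
}

#' Parameters for the LC-MS nucleoside table simulator
#'
#' @param scale area units per unit signal.
#' @param noiseCv multiplicative coefficient of variation (lognormal).
#' @param noiseFloorFrac dihydrouridine-channel floor, as a fraction of the
#'   baseline (wild-type) D signal; models carry-over/background in the MS
#'   channel that keeps null samples slightly above zero.
#' @param baselineOccupancy occupancy defining the reference D signal for the
#'   floor (matches the wild-type baseline).
#' @param seed integer seed.
#' @return parameter list of class `LcmsSimParams`.
#' @export
lcmsSimParams <- function(scale = 1000, noiseCv = 0.05, noiseFloorFrac = 0.003,
                          baselineOccupancy = 0.9, seed = 1) {
  stopifnot(scale > 0, noiseCv >= 0, noiseFloorFrac >= 0)
  p <- list(scale = scale, noiseCv = noiseCv, noiseFloorFrac = noiseFloorFrac,
            baselineOccupancy = baselineOccupancy, seed = as.integer(seed))
  class(p) <- "LcmsSimParams"
  p
}

#' Simulate one sample's nucleoside peak-area rows
#'
#' The dihydrouridine MS area is proportional to the summed site occupancy
#' over the modeled tRNA pool; the adenosine UV area is proportional to the
#' total adenosine content of the pool. Both carry multiplicative lognormal
#' noise; the D channel additionally receives a constant floor.
#'
#' @param bundle a [DReferenceBundle-class] (defines the tRNA pool).
#' @param profile a [ModificationProfile-class].
#' @param sample_name sample label.
#' @param params an [lcmsSimParams()] list.
#' @return data.frame with columns `sample`, `analyte`, `channel`, `area`
#'   (rows: D/MS and A/UV254).
#' @export
simulateLcmsTable <- function(bundle, profile, sample_name,
                              params = lcmsSimParams()) {
  stopifnot(is(bundle, "DReferenceBundle"), is(profile, "ModificationProfile"))
  nA <- sum(Biostrings::letterFrequency(referenceSequences(bundle), "A"))
  nSites <- nrow(dSites(bundle))
  withSeed(streamSeed(params$seed, paste0("lcms/", sample_name)), {
    eps <- lognormalFactors(2L, params$noiseCv)
    floor <- params$noiseFloorFrac * params$scale *
      params$baselineOccupancy * nSites
    d_area <- params$scale * sum(profile@occupancy) * eps[1L] + floor
    a_area <- params$scale * nA * eps[2L]
    data.frame(sample = sample_name, analyte = c("D", "A"),
               channel = c("MS", "UV254"), area = c(d_area, a_area),
               stringsAsFactors = FALSE)
  })
}

#' Parameters for the Michaelis-Menten dataset simulator
#'
#' Defaults follow the NADPH-oxidase characterisation of DusA
#' (kcat 0.48 1/s, Km 17 uM) with a substrate grid spanning Km.
#'
#' @param kcat turnover number, 1/s.
#' @param Km Michaelis constant, uM.
#' @param enzymeConc enzyme concentration, uM.
#' @param substrateGrid NAD(P)H concentrations, uM.
#' @param reps replicates per substrate concentration.
#' @param noiseCv multiplicative CV on rates.
#' @param noiseFloor additive Gaussian rate noise SD in uM/s (default 0);
#'   models the detection floor of the spectrophotometric assay, which
#'   swamps the signal of a near-inactive enzyme.
#' @param timepoints assay time points in minutes (0, 1, 5, 15, 20, 60).
#' @param seed integer seed.
#' @return parameter list of class `KineticsSimParams`.
#' @export
kineticsSimParams <- function(kcat = 0.48, Km = 17, enzymeConc = 1,
                              substrateGrid = c(1, 2, 5, 10, 17, 34, 100, 250),
                              reps = 3, noiseCv = 0.05, noiseFloor = 0,
                              timepoints = c(0, 1, 5, 15, 20, 60), seed = 1) {
  stopifnot(kcat > 0, Km > 0, enzymeConc > 0, noiseCv >= 0, noiseFloor >= 0,
            reps >= 1)
  p <- list(kcat = kcat, Km = Km, enzymeConc = enzymeConc,
            substrateGrid = substrateGrid, reps = as.integer(reps),
            noiseCv = noiseCv, noiseFloor = noiseFloor,
            timepoints = timepoints, seed = as.integer(seed))
  class(p) <- "KineticsSimParams"
  p
}

#' Kinetic presets for the three Dus enzymes
#'
#' Encodes the qualitative hierarchy DusA > DusB > DusC as simulator
#' presets. DusA uses the measured NADPH-oxidase parameters (kcat 0.48 1/s,
#' Km 17 uM); DusB the measured slow turnover (kcat 0.011 1/s; its Km was
#' not resolvable and is set equal to DusA's); DusC is modelled as activity
#' below the detection floor of the assay. `dusTimecoursePresets()` gives
#' the matching dihydrouridylation time-course rates: DusA near saturation
#' after 1 min, DusB intermediate, DusC only rising after ~20 min.
#'
#' @param seed integer seed shared by the presets.
#' @return named list of [kineticsSimParams()] (or, for the time-course
#'   variant, of `list(k_per_min, plateau)`).
#' @export
dusKineticPresets <- function(seed = 1) {
  list(
    DusA = kineticsSimParams(kcat = 0.48, Km = 17, seed = streamSeed(seed, "mm/DusA")),
    DusB = kineticsSimParams(kcat = 0.011, Km = 17, seed = streamSeed(seed, "mm/DusB")),
    DusC = kineticsSimParams(kcat = 1e-4, Km = 17, noiseFloor = 2e-3,
                             seed = streamSeed(seed, "mm/DusC")))
}

#' @rdname dusKineticPresets
#' @export
dusTimecoursePresets <- function() {
  list(DusA = list(k_per_min = 3.0, plateau = 1.0),
       DusB = list(k_per_min = 0.15, plateau = 1.0),
       DusC = list(k_per_min = 0.02, plateau = 1.0))
}

#' Simulate an initial-rate Michaelis-Menten dataset
#'
#' `v = kcat * E * S / (Km + S)` with multiplicative lognormal noise,
#' `reps` replicates per substrate concentration.
#'
#' @param params a [kineticsSimParams()] list.
#' @return data.frame with columns `S_uM`, `v_uM_per_s`, `rep`.
#' @export
simulateMMDataset <- function(params = kineticsSimParams()) {
  stopifnot(inherits(params, "KineticsSimParams"))
  withSeed(streamSeed(params$seed, "mm-dataset"), {
    S <- rep(params$substrateGrid, each = params$reps)
    v0 <- params$kcat * params$enzymeConc * S / (params$Km + S)
    v <- v0 * lognormalFactors(length(S), params$noiseCv)
    if (params$noiseFloor > 0)
      v <- pmax(0, v + rnorm(length(S), sd = params$noiseFloor))
    data.frame(S_uM = S, v_uM_per_s = v,
               rep = rep(seq_len(params$reps), times = length(params$substrateGrid)))
  })
}

#' Simulate an absorbance-at-343-nm trace of NAD(P)H consumption
#'
#' Beer-Lambert: `A(t) = max(0, A0 - eps343 * rate/1000 * path * t)` plus
#' additive Gaussian noise, with `eps343 = 6.21 /mM/cm` and the rate in
#' uM/s (hence the /1000).
#'
#' @param rate_uM_per_s true NAD(P)H consumption rate, uM/s.
#' @param A0 initial absorbance (AU).
#' @param duration_s,dt_s trace duration and sampling interval, s.
#' @param noise_sd additive Gaussian noise SD (AU).
#' @param epsilon_mM molar absorptivity, 1/mM/cm.
#' @param path_cm optical path length, cm.
#' @param seed integer seed.
#' @return data.frame with columns `t_s`, `A343`.
#' @export
simulateA343Trace <- function(rate_uM_per_s, A0 = 1.0, duration_s = 60,
                              dt_s = 1, noise_sd = 0, epsilon_mM = 6.21,
                              path_cm = 1, seed = 1) {
  stopifnot(A0 > 0)
  t <- seq(0, duration_s, by = dt_s)
  A <- pmax(0, A0 - epsilon_mM * rate_uM_per_s / 1000 * path_cm * t)
  if (noise_sd > 0)
    A <- withSeed(streamSeed(seed, "a343-trace"), A + rnorm(length(A), sd = noise_sd))
  data.frame(t_s = t, A343 = A)
}

#' Simulate a saturating dihydrouridylation time course
#'
#' `D(t) = plateau * (1 - exp(-k t)) * (1 + noise)`, sampled at the assay
#' time points (default 0, 1, 5, 15, 20, 60 min).
#'
#' @param k_per_min first-order rate constant, 1/min (>= 0).
#' @param plateau saturation level, relative D units (>= 0).
#' @param timepoints sampling times, min.
#' @param noise_cv multiplicative CV.
#' @param seed integer seed.
#' @return data.frame with columns `t_min`, `D_level`.
#' @export
simulateDTimecourse <- function(k_per_min, plateau,
                                timepoints = c(0, 1, 5, 15, 20, 60),
                                noise_cv = 0, seed = 1) {
  stopifnot(k_per_min >= 0, plateau >= 0)
  D <- plateau * (1 - exp(-k_per_min * timepoints))
  if (noise_cv > 0)
    D <- withSeed(streamSeed(seed, "d-timecourse"),
                  D * lognormalFactors(length(D), noise_cv))
  data.frame(t_min = timepoints, D_level = D)
}
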