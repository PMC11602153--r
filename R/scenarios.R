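#' @include synthetic-data.R aas-pipeline.R lcms-quant.R
NULL

SCENARIOS <- c("pilot", "aerobic", "anaerobic", "knockout_panel", "polysome")

#' Default configuration for a simulated experimental scenario
#'
#' Encodes the study designs as reusable presets: `pilot` (wild type and
#' triple knockout over a paraquat range), `aerobic` / `anaerobic` (wild
#' type, paraquat 0/0.1/0.3 mM with or without oxygen), `knockout_panel`
#' (wild type and the three single knockouts plus the triple knockout,
#' n = 5 replicates), and `polysome` (free F0 versus polysomal F3
#' fractions, paraquat 0/0.3 mM). Every default parameter lives in this one
#' config object so the choices are auditable in a single place.
#'
#' @param scenario one of `"pilot"`, `"aerobic"`, `"anaerobic"`,
#'   `"knockout_panel"`, `"polysome"`.
#' @param seed top-level integer seed; all per-sample streams derive from
#'   it.
#' @param output_dir where [runScenario()] writes its tables.
#' @return a `ScenarioConfig` list.
#' @export
defaultScenarioConfig <- function(scenario = SCENARIOS, seed = 1,
                                  output_dir = file.path(tempdir(), "scenario")) {
  scenario <- match.arg(scenario)
  strains <- switch(scenario,
    pilot = list(list(name = "WT"), list(name = "dusABC_KO",
      knockouts = c("DusA", "DusB", "DusC"))),
    aerobic = list(list(name = "WT")),
    anaerobic = list(list(name = "WT")),
    knockout_panel = list(list(name = "WT"),
      list(name = "dusA_KO", knockouts = "DusA"),
      list(name = "dusB_KO", knockouts = "DusB"),
      list(name = "dusC_KO", knockouts = "DusC"),
      list(name = "dusABC_KO", knockouts = c("DusA", "DusB", "DusC"))),
    polysome = list(list(name = "WT"),
      list(name = "dusA_KO", knockouts = "DusA"),
      list(name = "dusB_KO", knockouts = "DusB"),
      list(name = "dusC_KO", knockouts = "DusC")))
  cfg <- list(
    scenario = scenario,
    seed = as.integer(seed),
    output_dir = output_dir,
    n_trnas = 20L,
    baseline_occupancy = 0.9,
    replicates = if (scenario == "knockout_panel") 5L else 3L,
    paraquat_mM = switch(scenario,
      knockout_panel = 0, polysome = c(0, 0.3), c(0, 0.1, 0.3)),
    aerobic = scenario != "anaerobic",
    fractions = if (scenario == "polysome") c("F0", "F3") else "total",
    polysome_f3_shift = 1.0,
    sensitivity = c(DusA = 1.0, DusB = 0.6, DusC = 0.4),
    strains = strains,
    aas = list(moleculesPerTrna = 500L, alkCleavageProb = 0.5,
               backgroundBreakRate = 1e-3, terminalLigationProb = 1.0,
               readLen = 50L, minFragmentLen = 15L),
    lcms = list(scale = 1000, noiseCv = 0.05, noiseFloorFrac = 0.003),
    min_cov = 10, call_threshold = 0.05, max_mismatch = 2L)
  class(cfg) <- c("ScenarioConfig", "list")
  cfg
}

#' Read a scenario configuration from YAML
#'
#' The file must name at least `scenario`; every other field overrides the
#' matching default from [defaultScenarioConfig()]. A missing `seed` is an
#' error: silent nondeterminism is not allowed.
#'
#' @param path YAML file path.
#' @return a `ScenarioConfig` list.
#' @export
readScenarioConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  if (is.null(usr$scenario) || !usr$scenario %in% SCENARIOS)
    stop("config must set scenario to one of: ", paste(SCENARIOS, collapse = ", "))
  if (is.null(usr$seed)) stop("config must set an integer seed")
  cfg <- defaultScenarioConfig(usr$scenario, seed = usr$seed)
  for (nm in setdiff(names(usr), c("scenario", "seed"))) {
    if (nm %in% c("aas", "lcms")) cfg[[nm]] <- modifyList(cfg[[nm]], usr[[nm]])
    else cfg[[nm]] <- usr[[nm]]
  }
  if (!is.null(usr$sensitivity)) cfg$sensitivity <- unlist(usr$sensitivity)
  validateScenarioConfig(cfg)
  cfg
}

#' @describeIn defaultScenarioConfig validate a configuration, erroring on
#'   violated invariants.
#' @param config a `ScenarioConfig` list.
#' @export
validateScenarioConfig <- function(config) {
  stopifnot(config$scenario %in% SCENARIOS,
            is.numeric(config$seed), length(config$seed) == 1L,
            config$replicates >= 1L, config$n_trnas >= 1L,
            all(config$paraquat_mM >= 0),
            config$baseline_occupancy >= 0, config$baseline_occupancy <= 1)
  invisible(config)
}

.sampleName <- function(strain, pq, fraction) {
  base <- sprintf("%s_pq%g", strain, pq)
  if (fraction != "total") base <- paste0(base, "_", fraction)
  base
}

#' Run a full simulated scenario end to end
#'
#' Simulates every sample of the configured design, then runs the
#' AlkAnilineSeq scoring chain (one library per condition) and the LC-MS
#' quantification chain (per replicate) with identical machinery for every
#' condition. Writes, under `config$output_dir`: the nucleoside table,
#' per-sample relative D levels, per-group replicate summaries versus the
#' untreated wild-type control, stop-ratio tables, annotated D-site calls,
#' percent-of-control comparisons of each treated condition against its
#' untreated counterpart, per-enzyme summaries, a manifest and a run log.
#' Everything is reproducible from (config, seed) alone.
#'
#' @param config a `ScenarioConfig` list from [defaultScenarioConfig()] or
#'   [readScenarioConfig()].
#' @return invisibly, a list with the bundle, the in-memory tables and the
#'   output paths.
#' @export
runScenario <- function(config) {
  validateScenarioConfig(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  bundle <- buildFixtureReferences(config$n_trnas, seed = streamSeed(seed, "bundle"))
  baseline <- baselineProfile(bundle, config$baseline_occupancy)

  conditions <- list()
  for (strain in config$strains)
    for (pq in config$paraquat_mM)
      for (fr in config$fractions) {
        sc <- strainConfig(strain$name,
          knockouts = if (is.null(strain$knockouts)) character() else strain$knockouts,
          paraquat_mM = pq, aerobic = isTRUE(config$aerobic),
          sensitivity = config$sensitivity)
        eff <- effectiveOccupancy(baseline, sc)
        if (fr == "F3")
          eff@occupancy <- pmin(1, eff@occupancy * config$polysome_f3_shift)
        conditions[[.sampleName(strain$name, pq, fr)]] <-
          list(strain = sc, fraction = fr, profile = eff, pq = pq)
      }

  failSample <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("scenario stage failed for sample '%s': %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- LC-MS chain: replicate nucleoside tables and relative levels
  nuc <- do.call(rbind, lapply(names(conditions), function(cn) {
    do.call(rbind, lapply(seq_len(config$replicates), function(r) {
      sn <- sprintf("%s_rep%d", cn, r)
      failSample(sn, simulateLcmsTable(bundle, conditions[[cn]]$profile, sn,
        lcmsSimParams(scale = config$lcms$scale, noiseCv = config$lcms$noiseCv,
          noiseFloorFrac = config$lcms$noiseFloorFrac,
          baselineOccupancy = config$baseline_occupancy,
          seed = streamSeed(seed, paste0("lcms/", sn)))))
    }))
  }))
  controlName <- .sampleName("WT", 0, config$fractions[1L])
  controlSamples <- sprintf("%s_rep%d", controlName, seq_len(config$replicates))
  levels <- relativeDLevelTable(nuc, controlSamples)
  levels$group <- sub("_rep[0-9]+$", "", levels$sample)
  ctrl_levels <- levels$relative_percent[levels$group == controlName]
  groupSummary <- do.call(rbind, lapply(split(levels, levels$group), function(g) {
    cbind(group = g$group[1L],
          summarizeReplicates(g$relative_percent, ctrl_levels))
  }))
  rownames(groupSummary) <- NULL

  # --- AAS chain: one library per condition
  profiles <- list(); callTables <- list(); stopTables <- list()
  for (cn in names(conditions)) {
    lib <- failSample(cn, simulateAASLibrary(bundle, conditions[[cn]]$profile,
      aasLibraryParams(moleculesPerTrna = config$aas$moleculesPerTrna,
        alkCleavageProb = config$aas$alkCleavageProb,
        backgroundBreakRate = config$aas$backgroundBreakRate,
        terminalLigationProb = config$aas$terminalLigationProb,
        readLen = config$aas$readLen,
        minFragmentLen = config$aas$minFragmentLen,
        seed = streamSeed(seed, paste0("aas/", cn)))))
    aln <- failSample(cn, mapReads(lib$reads, bundle, config$max_mismatch))
    prof <- stopRatio(tallyAlignments(aln, bundle), config$min_cov)
    profiles[[cn]] <- prof
    st <- stopCounts(prof); st <- cbind(sample = cn, st)
    stopTables[[cn]] <- st
    calls <- inferDPositions(prof, bundle, config$call_threshold, "annotated")
    callTables[[cn]] <- cbind(sample = cn, calls)
  }

  comparisons <- list(); enzymeSummaries <- list()
  for (cn in names(conditions)) {
    cond <- conditions[[cn]]
    if (cond$pq == 0) next
    ctrl <- .sampleName(cond$strain@name, 0, cond$fraction)
    if (!ctrl %in% names(profiles)) next
    cmp <- compareConditions(profiles[[cn]], profiles[[ctrl]])
    comparisons[[cn]] <- cbind(sample = cn, control = ctrl, cmp)
    es <- enzymeLevelSummary(cmp, bundle)
    if (nrow(es)) enzymeSummaries[[cn]] <- cbind(sample = cn, es)
  }

  rbindOr <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  out <- list(
    bundle = bundle,
    nucleoside_table = nuc,
    relative_levels = levels,
    group_summary = groupSummary,
    stop_ratios = do.call(rbind, stopTables),
    d_calls = do.call(rbind, callTables),
    comparisons = rbindOr(comparisons, NULL),
    enzyme_summary = rbindOr(enzymeSummaries, NULL))

  paths <- c(reference_fasta = "references.fasta",
             reference_annotation = "d_sites.tsv",
             nucleoside_table = "nucleoside_table.tsv",
             relative_levels = "relative_levels.tsv",
             group_summary = "group_summary.tsv",
             stop_ratios = "stop_ratios.tsv",
             d_calls = "d_calls.tsv")
  if (!is.null(out$comparisons)) paths["comparisons"] <- "comparisons.tsv"
  if (!is.null(out$enzyme_summary)) paths["enzyme_summary"] <- "enzyme_summary.tsv"
  paths[] <- file.path(config$output_dir, paths)
  writeReferenceBundle(bundle, paths["reference_fasta"], paths["reference_annotation"])
  for (nm in setdiff(names(paths), c("reference_fasta", "reference_annotation")))
    writeTsv(out[[nm]], paths[[nm]])

  # hash the scientific configuration only; the output location is not
  # part of the experiment's identity
  hash <- contentHash(unclass(config)[setdiff(names(config), "output_dir")])
  manifest <- data.frame(artifact = names(paths),
    path = basename(unname(paths)), seed = seed, config_hash = hash,
    stringsAsFactors = FALSE)
  writeTsv(manifest, file.path(config$output_dir, "manifest.tsv"))
  logLines <- c(
    sprintf("scenario: %s", config$scenario),
    sprintf("seed: %d", seed),
    sprintf("config_hash: %s", hash),
    sprintf("package_version: %s", as.character(utils::packageVersion("DusProfiler"))),
    sprintf("samples: %s", paste(names(conditions), collapse = ", ")),
    sprintf("outputs: %s", paste(basename(unname(paths)), collapse = ", ")))
  writeLines(logLines, file.path(config$output_dir, "run.log"))
  out$paths <- c(paths, manifest = file.path(config$output_dir, "manifest.tsv"),
                 log = file.path(config$output_dir, "run.log"))
  invisible(out)
}
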