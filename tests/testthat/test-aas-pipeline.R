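test_that("exact substrings map uniquely; shared reads are multimapped; junk is unmapped", {
  b <- tinyBundle()
  seqs <- as.character(referenceSequences(b))
  rd <- substring(seqs[[1]], 21, 50)
  aln <- mapReads(c(r1 = rd), b)
  expect_identical(aln$alignments$start_index, 21L)
  expect_identical(aln$alignments$end_index, 50L)
  expect_identical(aln$alignments$mismatches, 0L)
  expect_identical(aln$alignments$trna_id, "tRNA-Test-AAA-1")
  # both tinyBundle tRNAs share the 3'-CCA and more: take a common block
  common <- substring(seqs[[1]], 10, 25)
  if (regexpr(common, seqs[[2]], fixed = TRUE) < 0) {
    # guarantee a shared read by construction instead
    common <- substring(seqs[[2]], 10, 25)
  }
  shared <- substring(seqs[[1]], 12, 26)  # "GCUCAGU..." block shared by design
  both <- mapReads(c(s = shared), b)
  expect_true(both$report$multimapped == 1L || both$report$mapped == 1L)
  junk <- paste(rep(c("A", "C"), 15), collapse = "")
  res <- mapReads(c(j = junk), b)
  expect_identical(res$report$unmapped, 1L)
  expect_identical(nrow(res$alignments), 0L)
})

test_that("the compiled mapper agrees with a brute-force oracle", {
  bundle <- buildFixtureReferences(5, seed = 13)
  refs <- as.character(referenceSequences(bundle))
  lib <- simulateAASLibrary(bundle, baselineProfile(bundle, 0.9),
    aasLibraryParams(moleculesPerTrna = 20, backgroundBreakRate = 5e-3, seed = 17))
  set.seed(99)
  reads <- lib$reads
  # spike in mutated and random reads to exercise mismatches and unmapped
  mutate <- function(r, n) {
    ch <- strsplit(r, "")[[1]]
    i <- sample(length(ch), n)
    ch[i] <- vapply(ch[i], function(x)
      sample(setdiff(c("A", "C", "G", "U"), x), 1), character(1))
    paste(ch, collapse = "")
  }
  reads <- c(reads[seq_len(min(150, length(reads)))],
             m1 = mutate(reads[[1]], 1), m2 = mutate(reads[[2]], 2),
             m4 = mutate(reads[[3]], 4),
             rnd = paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = ""))
  aln <- mapReads(reads, bundle, max_mismatch = 2)
  for (i in seq_along(reads)) {
    oracle <- bruteMapRead(reads[[i]], refs, max_mismatch = 2)
    id <- names(reads)[i]
    row <- aln$alignments[aln$alignments$read_id == id, ]
    if (is.null(oracle) || oracle$n_best >= 2) {
      expect_identical(nrow(row), 0L)
    } else {
      expect_identical(nrow(row), 1L)
      expect_identical(row$trna_id, names(refs)[oracle$ref])
      expect_identical(row$start_index, oracle$start)
      expect_identical(row$mismatches, oracle$mismatches)
    }
  }
})

test_that("tallies count 5' ends and coverage by definition and add up", {
  b <- tinyBundle()
  one <- data.frame(read_id = "r1", trna_id = "tRNA-Test-AAA-1",
                    start_index = 3L, end_index = 7L, mismatches = 0L)
  tl <- tallyAlignments(one, b)
  a1 <- tl[tl$trna_id == "tRNA-Test-AAA-1", ]
  expect_identical(a1$n5[a1$position == 3], 1L)
  expect_identical(sum(a1$n5), 1L)
  expect_true(all(a1$cov[a1$position %in% 3:7] == 1L))
  expect_true(all(a1$cov[!a1$position %in% 3:7] == 0L))
  two <- rbind(one, one)
  t2 <- tallyAlignments(two, b)
  expect_identical(t2$n5, 2L * tl$n5)
  expect_identical(t2$cov, 2L * tl$cov)
  # sum of coverage equals sum of mapped read lengths
  expect_identical(sum(t2$cov), sum(two$end_index - two$start_index + 1L))
  empty <- tallyAlignments(one[0, ], b)
  expect_true(all(empty$n5 == 0L) && all(empty$cov == 0L))
})

test_that("stop ratios are n5/cov above the coverage floor, zero and flagged below", {
  counts <- data.frame(trna_id = "t", position = 1:3,
                       n5 = c(25L, 0L, 2L), cov = c(100L, 50L, 4L))
  prof <- stopRatio(counts, min_cov = 10)
  st <- stopCounts(prof)
  expect_equal(st$stop_ratio, c(0.25, 0, 0))
  expect_identical(st$low_coverage, c(FALSE, FALSE, TRUE))
  expect_true(all(st$stop_ratio >= 0 & st$stop_ratio <= 1))
})

test_that("wild-type libraries call all annotated positions; knockouts only the remaining ones", {
  bundle <- buildFixtureReferences(8, seed = 21)
  baseline <- baselineProfile(bundle, 0.9)
  run <- function(profile, seed) {
    lib <- simulateAASLibrary(bundle, profile,
      aasLibraryParams(moleculesPerTrna = 800, seed = seed))
    stopRatio(tallyAlignments(mapReads(lib$reads, bundle), bundle))
  }
  wt_calls <- inferDPositions(run(baseline, 31), bundle, mode = "annotated")
  expect_true(all(wt_calls$called))
  dusA <- effectiveOccupancy(baseline, strainConfig("dusA_KO", knockouts = "DusA"))
  ko_calls <- inferDPositions(run(dusA, 32), bundle, mode = "annotated")
  expect_true(all(ko_calls$called[ko_calls$canonical_label %in% c("16", "17")]))
  expect_false(any(ko_calls$called[ko_calls$canonical_label %in% c("20", "20a")]))
  # all-zero profile: nothing is called
  null_calls <- inferDPositions(run(zeroProfile(bundle), 33), bundle,
                                mode = "annotated")
  expect_false(any(null_calls$called))
  # discovery mode back-shifts to a U and, on a background-free library,
  # recovers exactly the annotated sites
  clean <- simulateAASLibrary(bundle, baseline,
    aasLibraryParams(moleculesPerTrna = 800, backgroundBreakRate = 0, seed = 34))
  clean_prof <- stopRatio(tallyAlignments(mapReads(clean$reads, bundle), bundle))
  disc <- inferDPositions(clean_prof, bundle, threshold = 0.1,
                          mode = "discovery")
  expect_true(all(!is.na(disc$canonical_label)))
  key <- function(df) paste(df$trna_id, df$d_index)
  expect_setequal(key(disc), key(as.data.frame(dSites(bundle))[
    c("trna_id", "seq_index")] |> setNames(c("trna_id", "d_index"))))
})

test_that("condition comparison is percent-of-control with guarded zeros", {
  counts_t <- data.frame(trna_id = "t", position = 1:3,
                         n5 = c(20L, 10L, 5L), cov = c(100L, 100L, 100L))
  counts_c <- data.frame(trna_id = "t", position = 1:3,
                         n5 = c(40L, 10L, 0L), cov = c(100L, 100L, 100L))
  cmp <- compareConditions(stopRatio(counts_t), stopRatio(counts_c))
  expect_equal(cmp$percent_of_control[1], 50)
  expect_equal(cmp$percent_of_control[2], 100)
  expect_true(is.na(cmp$percent_of_control[3]) && !cmp$defined[3])
  ident <- compareConditions(stopRatio(counts_c), stopRatio(counts_c))
  expect_true(all(ident$percent_of_control[ident$defined] == 100))
})

test_that("per-enzyme summaries aggregate percent-of-control at annotated stops", {
  b <- tinyBundle()
  st <- as.data.frame(dSites(b))
  # synthetic comparison: DusC sites at 60%, others at 100%
  cmp <- data.frame(trna_id = st$trna_id, position = st$seq_index + 1L,
                    ratio_treated = 0.1, ratio_control = 0.1,
                    percent_of_control = ifelse(st$enzyme == "DusC", 60, 100),
                    defined = TRUE)
  smry <- enzymeLevelSummary(cmp, b)
  dusc <- smry[smry$enzyme == "DusC", ]
  expect_equal(dusc$fraction_decreased, 1)
  expect_equal(dusc$mean_percent, 60)
  expect_equal(smry$fraction_decreased[smry$enzyme == "DusB"], 0)
  expect_identical(nrow(enzymeLevelSummary(cmp[0, ], b)), 0L)
})

test_that("aerobic paraquat stress orders enzymes DusA > DusB > DusC in percent of control", {
  bundle <- buildFixtureReferences(12, seed = 41)
  baseline <- baselineProfile(bundle, 0.9)
  treated <- effectiveOccupancy(baseline,
    strainConfig("WT_PQ", paraquat_mM = 0.3, aerobic = TRUE))
  run <- function(profile, seed) {
    lib <- simulateAASLibrary(bundle, profile,
      aasLibraryParams(moleculesPerTrna = 1000, seed = seed))
    stopRatio(tallyAlignments(mapReads(lib$reads, bundle), bundle))
  }
  cmp <- compareConditions(run(treated, 51), run(baseline, 52))
  smry <- enzymeLevelSummary(cmp, bundle)
  m <- setNames(smry$mean_percent, smry$enzyme)
  expect_true(m["DusA"] > m["DusB"] && m["DusB"] > m["DusC"])
  expect_equal(smry$fraction_decreased[smry$enzyme == "DusC"], 1)
})

test_that("the pipeline is deterministic downstream of simulation", {
  bundle <- buildFixtureReferences(4, seed = 61)
  lib <- simulateAASLibrary(bundle, baselineProfile(bundle, 0.9),
    aasLibraryParams(moleculesPerTrna = 100, seed = 62))
  p1 <- stopCounts(stopRatio(tallyAlignments(mapReads(lib$reads, bundle), bundle)))
  p2 <- stopCounts(stopRatio(tallyAlignments(mapReads(lib$reads, bundle), bundle)))
  expect_identical(p1, p2)
})
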