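test_that("fixture generation is deterministic and satisfies its own invariants", {
  a <- buildFixtureReferences(20, seed = 7)
  b <- buildFixtureReferences(20, seed = 7)
  expect_identical(as.character(referenceSequences(a)),
                   as.character(referenceSequences(b)))
  expect_identical(as.data.frame(dSites(a)), as.data.frame(dSites(b)))
  st <- as.data.frame(dSites(a))
  # annotated bases are U (also enforced by class validity)
  expect_true(validObject(a))
  # every tRNA has 16, 17 and 20; DusA-served sites are about half of all
  for (id in referenceIds(a))
    expect_true(all(c("16", "17", "20") %in% st$canonical_label[st$trna_id == id]))
  dusA_share <- mean(st$enzyme == "DusA")
  expect_gt(dusA_share, 0.35)
  expect_lt(dusA_share, 0.5)
  # pairwise distinguishable references
  d <- utils::adist(as.character(referenceSequences(a)))
  expect_true(all(d[upper.tri(d)] >= 5))
  # minimal case still has >= 2 sites
  one <- buildFixtureReferences(1, seed = 9)
  expect_gte(nrow(dSites(one)), 2L)
})

test_that("forced cleavage sends every non-terminal read to the N+1 position", {
  b <- singleSiteBundle(site = 20L)
  prof <- ModificationProfile("tRNA-Single-AAA-1", 20L, 1.0, bundle = b)
  lib <- simulateAASLibrary(b, prof,
    aasLibraryParams(moleculesPerTrna = 500, alkCleavageProb = 1,
                     backgroundBreakRate = 0, seed = 2))
  nonterm <- lib$truth[lib$truth$cause != "terminus", ]
  expect_gt(nrow(nonterm), 0)
  expect_true(all(nonterm$start_index == 21L))
  expect_true(all(nonterm$cause == "d_cleavage"))
})

test_that("a library with no ligatable ends yields zero reads", {
  b <- singleSiteBundle()
  lib <- simulateAASLibrary(b, zeroProfile(b),
    aasLibraryParams(moleculesPerTrna = 200, backgroundBreakRate = 0,
                     terminalLigationProb = 0, seed = 4))
  expect_length(lib$reads, 0L)
  expect_identical(nrow(lib$truth), 0L)
})

test_that("molecule-level cleavage fraction matches the binomial expectation", {
  b <- singleSiteBundle(site = 16L)
  p <- 0.5; M <- 10000
  prof <- ModificationProfile("tRNA-Single-AAA-1", 16L, p, bundle = b)
  lib <- simulateAASLibrary(b, prof,
    aasLibraryParams(moleculesPerTrna = M, alkCleavageProb = 1,
                     backgroundBreakRate = 0, seed = 6))
  cleaved <- length(unique(lib$truth$molecule[lib$truth$cause == "d_cleavage"]))
  se <- sqrt(p * (1 - p) / M)
  expect_lt(abs(cleaved / M - p), 3 * se)
})

test_that("library simulation is seed-deterministic and conserves molecules", {
  b <- tinyBundle()
  prof <- baselineProfile(b, 0.9)
  params <- aasLibraryParams(moleculesPerTrna = 300, seed = 11)
  l1 <- simulateAASLibrary(b, prof, params)
  l2 <- simulateAASLibrary(b, prof, params)
  expect_identical(l1$reads, l2$reads)
  expect_identical(l1$truth, l2$truth)
  # every read's 5' index is a truth break or the terminus, and every read
  # is an exact substring of its source reference
  seqs <- as.character(referenceSequences(b))
  with(l1$truth, {
    expect_true(all(cause %in% c("terminus", "d_cleavage", "background")))
    expect_true(all(start_index[cause == "terminus"] == 1L))
    expect_true(all(substring(seqs[trna_id], start_index,
                              start_index + length - 1L) ==
                    unname(l1$reads)))
  })
  # molecules partition by tRNA: ids stay within the per-reference blocks
  expect_true(all(l1$truth$molecule >= 1 &
                  l1$truth$molecule <= 2 * params$moleculesPerTrna))
})

test_that("FASTQ output round-trips through the mapper input path", {
  b <- tinyBundle()
  lib <- simulateAASLibrary(b, baselineProfile(b, 0.9),
    aasLibraryParams(moleculesPerTrna = 50, seed = 8))
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "reads.fastq")
  writeAASLibrary(lib, fq, file.path(dir, "truth.tsv"))
  aln <- mapReads(fq, b)
  expect_identical(aln$report$total, length(lib$reads))
  expect_gt(aln$report$mapped / aln$report$total, 0.99)
})

test_that("nucleoside areas are linear in occupancy and seed-stable", {
  b <- tinyBundle()
  noiseless <- lcmsSimParams(noiseCv = 0, noiseFloorFrac = 0, seed = 1)
  half <- baselineProfile(b, 0.45)
  full <- baselineProfile(b, 0.9)
  t_half <- simulateLcmsTable(b, half, "s", noiseless)
  t_full <- simulateLcmsTable(b, full, "s", noiseless)
  area <- function(tab, an) tab$area[tab$analyte == an]
  expect_equal(area(t_full, "D"), 2 * area(t_half, "D"))
  expect_identical(area(t_full, "A"), area(t_half, "A"))
  expect_equal(area(simulateLcmsTable(b, zeroProfile(b), "z", noiseless), "D"), 0)
  noisy <- lcmsSimParams(seed = 5)
  expect_identical(simulateLcmsTable(b, full, "s", noisy),
                   simulateLcmsTable(b, full, "s", noisy))
})

test_that("Michaelis-Menten simulator honours half-saturation and saturation limits", {
  p0 <- kineticsSimParams(kcat = 0.48, Km = 17, enzymeConc = 1, noiseCv = 0,
                          substrateGrid = c(17, 17e6), reps = 1)
  d <- simulateMMDataset(p0)
  expect_equal(d$v_uM_per_s[d$S_uM == 17], 0.24)
  expect_lt(abs(d$v_uM_per_s[d$S_uM == 17e6] - 0.48) / 0.48, 1e-4)
})

test_that("absorbance traces follow Beer-Lambert and recover the rate by least squares", {
  tr <- simulateA343Trace(rate_uM_per_s = 1, A0 = 1, duration_s = 10, dt_s = 1,
                          noise_sd = 0)
  expect_equal(tr$A343[1] - tr$A343[tr$t_s == 10], 0.0621)
  flat <- simulateA343Trace(rate_uM_per_s = 0, A0 = 0.8, duration_s = 20,
                            dt_s = 1, noise_sd = 0)
  expect_true(all(flat$A343 == 0.8))
  # independent least-squares oracle on the noiseless trace
  slope <- unname(coef(lm(A343 ~ t_s, data = tr))[2])
  expect_equal(slope, -6.21 * 1 / 1000, tolerance = 1e-10)
})

test_that("dihydrouridylation time courses start at zero and saturate", {
  tc <- simulateDTimecourse(k_per_min = 0.05, plateau = 2, noise_cv = 0)
  expect_equal(tc$D_level[tc$t_min == 0], 0)
  expect_equal(tc$D_level[tc$t_min == 20], 2 * (1 - exp(-1)))
  fast <- simulateDTimecourse(k_per_min = 5, plateau = 1, noise_cv = 0)
  expect_gt(fast$D_level[fast$t_min == 1], 0.99)
})
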