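# Handcrafted fixtures and independent oracles shared across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny bundle with fully known content: two 76-nt tRNAs, D sites at 16/17
# (both) plus 20 on the first. Bodies are fixed strings so expectations can
# be written by hand.
tinyBundle <- function() {
  base1 <- paste0(
    "GGGCACAUAGCUCAGUUGGGAGAGCACCAGACUGAAAAUCUGGAGGUCCUGUGUUCGAUC",
    "CACAGUGUGCCCCCA")  # 76 nt
  base2 <- paste0(
    "GCCGAGGUAGCUCAGUCGGUAGAGCAGGGGAUUGAAAAUCCCCGUGUCCUUGGUUCGAUU",
    "CCGAGUCCUCGCCCA")  # 76 nt
  s1 <- strsplit(base1, "")[[1]]; s2 <- strsplit(base2, "")[[1]]
  s1[16:17] <- "U"; s1[20] <- "U"
  s2[16:17] <- "U"
  DReferenceBundle(
    stats::setNames(c(paste(s1, collapse = ""), paste(s2, collapse = "")),
                    c("tRNA-Test-AAA-1", "tRNA-Test-CCC-2")),
    data.frame(
      trna_id = c(rep("tRNA-Test-AAA-1", 3), rep("tRNA-Test-CCC-2", 2)),
      seq_index = c(16L, 17L, 20L, 16L, 17L),
      canonical_label = c("16", "17", "20", "16", "17")))
}

# One-tRNA bundle with a single D site at index `site`, everything else
# non-U downstream-controllable; used for the binomial convergence checks.
singleSiteBundle <- function(site = 16L, len = 76L, seed = 42L) {
  set.seed(seed)
  s <- sample(c("A", "C", "G"), len, replace = TRUE)
  s[site] <- "U"
  DReferenceBundle(stats::setNames(paste(s, collapse = ""), "tRNA-Single-AAA-1"),
    data.frame(trna_id = "tRNA-Single-AAA-1", seq_index = site,
               canonical_label = "16"))
}

zeroProfile <- function(bundle) baselineProfile(bundle, 0)

# Pure-R brute-force mapper oracle, independent of the compiled scan:
# all offsets of all references, Hamming mismatches, N never matches.
bruteMapRead <- function(read, refs, max_mismatch = 2) {
  rchars <- strsplit(read, "")[[1]]
  best <- max_mismatch + 1L; nbest <- 0L; bref <- NA; bstart <- NA
  for (j in seq_along(refs)) {
    fchars <- strsplit(refs[[j]], "")[[1]]
    lr <- length(rchars); lf <- length(fchars)
    if (lr > lf) next
    for (off in 0:(lf - lr)) {
      mm <- sum(rchars == "N" | rchars != fchars[(off + 1):(off + lr)])
      if (mm > max_mismatch) next
      if (mm < best) { best <- mm; nbest <- 1L; bref <- j; bstart <- off + 1L }
      else if (mm == best) nbest <- nbest + 1L
    }
  }
  if (best > max_mismatch) return(NULL)
  list(ref = bref, start = bstart, mismatches = best, n_best = nbest)
}

# Write a bundle to temp FASTA/TSV and return the two paths.
writeTempBundle <- function(bundle, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fa <- file.path(dir, "refs.fasta")
  tsv <- file.path(dir, "sites.tsv")
  writeReferenceBundle(bundle, fa, tsv)
  c(fasta = fa, tsv = tsv)
}
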