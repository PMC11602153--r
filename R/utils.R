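# Seeded stream utilities: a single top-level seed spawns independent,
# reproducible sub-streams keyed by stable strings, so adding one generator
# never perturbs another's draws.

.STREAM_MOD <- 2147480009  # large prime < 2^31-1; keeps derived seeds integer

#' Derive a reproducible sub-seed from a top-level seed and a string key
#'
#' Deterministic, order-independent seed derivation: the same `(seed, key)`
#' pair always yields the same sub-seed, and distinct keys give unrelated
#' streams. Used throughout the simulators so that every component draws from
#' its own stream.
#'
#' @param seed integer top-level seed.
#' @param key character scalar naming the stream (e.g. `"aas/WT"`).
#' @return a single integer suitable for [set.seed()].
#' @examples
#' streamSeed(1L, "aas") != streamSeed(1L, "lcms")
#' @export
streamSeed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key), length(key) == 1L)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% .STREAM_MOD
  as.integer((abs(as.numeric(seed)) %% .STREAM_MOD * 48271 + h) %% .STREAM_MOD)
}

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Multiplicative lognormal noise factors with mean 1 and the requested CV.
lognormalFactors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Stable content hash of an R object (config auditing in run logs).
contentHash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (ch in utf8ToInt(txt)) h <- (h * 131 + ch) %% .STREAM_MOD
  sprintf("%08x", as.integer(h))
}

# TSV writers/readers used for every tabular artifact.
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

# Significance stars at the conventional 0.05/0.01/0.001 thresholds.
significanceLabel <- function(p) {
  ifelse(is.na(p), NA_character_,
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}
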