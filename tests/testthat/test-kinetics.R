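test_that("initial rates convert absorbance slopes via Beer-Lambert", {
  tr <- data.frame(t_s = 0:59, A343 = 1 - 6.21e-3 * (0:59))
  r <- initialRateFromTrace(tr)
  expect_equal(r$rate_uM_per_s, 1, tolerance = 1e-10)
  flat <- data.frame(t_s = 0:59, A343 = rep(0.7, 60))
  expect_equal(initialRateFromTrace(flat)$rate_uM_per_s, 0)
  rising <- data.frame(t_s = 0:59, A343 = 0.5 + 1e-4 * (0:59))
  rr <- initialRateFromTrace(rising)
  expect_true(rr$clamped && rr$rate_uM_per_s == 0)
  expect_error(initialRateFromTrace(data.frame(t_s = 1:3, A343 = 1:3)),
               "at least 5")
})

test_that("noisy traces recover the true rate within 5% in >= 95% of runs", {
  ok <- vapply(1:200, function(s) {
    tr <- simulateA343Trace(rate_uM_per_s = 1, A0 = 1, duration_s = 59,
                            dt_s = 1, noise_sd = 1e-4, seed = s)
    abs(initialRateFromTrace(tr, window_frac = 1)$rate_uM_per_s - 1) < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("noiseless Michaelis-Menten data are recovered exactly", {
  d <- simulateMMDataset(kineticsSimParams(kcat = 0.48, Km = 17,
    enzymeConc = 1, noiseCv = 0, reps = 1))
  fit <- fitMichaelisMenten(d$S_uM, d$v_uM_per_s, enzyme_conc = 1)
  expect_true(fit@converged)
  expect_equal(fit@kcat, 0.48, tolerance = 1e-6)
  expect_equal(fit@Km, 17, tolerance = 1e-6)
  # catalytic efficiency matches the printed constant at 2 significant figures
  expect_equal(signif(fit@efficiency, 2), 0.028)
  expect_equal(fit@efficiency, fit@kcat / fit@Km, tolerance = 1e-12)
})

test_that("the NLS fit matches a profiled grid-search oracle on noisy data", {
  # oracle: dense log-spaced Km grid; for fixed Km the optimal Vmax is the
  # closed-form linear least-squares solution
  gridOracle <- function(S, v, km_lo, km_hi, n = 2000) {
    kms <- exp(seq(log(km_lo), log(km_hi), length.out = n))
    best <- c(rss = Inf, Km = NA, Vmax = NA)
    for (km in kms) {
      g <- S / (km + S)
      vmax <- sum(v * g) / sum(g * g)
      rss <- sum((v - vmax * g)^2)
      if (rss < best["rss"]) best <- c(rss = rss, Km = km, Vmax = vmax)
    }
    best
  }
  for (s in 1:20) {
    d <- simulateMMDataset(kineticsSimParams(kcat = 0.48, Km = 17,
      enzymeConc = 1, noiseCv = 0.05, seed = s))
    fit <- fitMichaelisMenten(d$S_uM, d$v_uM_per_s, enzyme_conc = 1)
    oracle <- gridOracle(d$S_uM, d$v_uM_per_s, 17 / 100, 17 * 100)
    expect_lt(abs(fit@Km - oracle["Km"]) / oracle["Km"], 0.01)
    expect_lt(abs(fit@Vmax - oracle["Vmax"]) / oracle["Vmax"], 0.01)
  }
})

test_that("parameter recovery stays within the expected error envelope", {
  relerr <- function(noise) {
    err <- vapply(1:40, function(s) {
      d <- simulateMMDataset(kineticsSimParams(kcat = 0.48, Km = 17,
        enzymeConc = 1, noiseCv = noise, seed = 1000 + s))
      fit <- fitMichaelisMenten(d$S_uM, d$v_uM_per_s, enzyme_conc = 1)
      c(abs(fit@kcat - 0.48) / 0.48, abs(fit@Km - 17) / 17)
    }, numeric(2))
    apply(err, 1, median)
  }
  expect_true(all(relerr(0.05) <= 0.10))
  expect_true(all(relerr(0.01) <= 0.02))
})

test_that("fitted curves are monotone in S and bounded by Vmax", {
  d <- simulateMMDataset(kineticsSimParams(seed = 77))
  fit <- fitMichaelisMenten(d$S_uM, d$v_uM_per_s, enzyme_conc = 1)
  S <- seq(0.1, 500, length.out = 100)
  vhat <- fit@Vmax * S / (fit@Km + S)
  expect_true(all(diff(vhat) > 0))
  expect_true(all(vhat < fit@Vmax))
})

test_that("trace extraction and MM fitting compose end to end", {
  S <- c(2, 5, 10, 17, 34, 100)
  rates <- vapply(seq_along(S), function(i) {
    v_true <- 0.48 * S[i] / (17 + S[i])
    tr <- simulateA343Trace(v_true, A0 = 1.5, duration_s = 59, dt_s = 1,
                            noise_sd = 5e-5, seed = 300 + i)
    initialRateFromTrace(tr, window_frac = 1)$rate_uM_per_s
  }, numeric(1))
  fit <- fitMichaelisMenten(S, rates, enzyme_conc = 1)
  expect_lt(abs(fit@kcat - 0.48) / 0.48, 0.10)
  expect_lt(abs(fit@Km - 17) / 17, 0.10)
})

test_that("saturating time courses recover k and plateau, with degenerate guards", {
  tc <- simulateDTimecourse(0.5, 1, noise_cv = 0)
  fit <- fitSaturatingTimecourse(tc$t_min, tc$D_level)
  expect_equal(fit@k, 0.5, tolerance = 1e-6)
  expect_equal(fit@plateau, 1, tolerance = 1e-6)
  expect_equal(fit@t_half, log(2) / fit@k, tolerance = 1e-10)
  zero <- fitSaturatingTimecourse(c(0, 1, 5, 15), rep(0, 4))
  expect_false(zero@converged)
  expect_identical(zero@k, 0)
  expect_error(fitSaturatingTimecourse(c(1, 5, 15, 20), 1:4), "t = 0")
  # DusA-like preset saturates within the first minute
  pre <- dusTimecoursePresets()
  fastfit <- fitSaturatingTimecourse(
    simulateDTimecourse(pre$DusA$k_per_min, 1, noise_cv = 0)$t_min,
    simulateDTimecourse(pre$DusA$k_per_min, 1, noise_cv = 0)$D_level)
  expect_gte(fastfit@plateau * (1 - exp(-fastfit@k * 1)), 0.95 * fastfit@plateau)
  # slow DusC-like preset fits slower than DusB-like
  fitFor <- function(k, seed) {
    tc <- simulateDTimecourse(k, 1, noise_cv = 0.05, seed = seed)
    fitSaturatingTimecourse(tc$t_min, tc$D_level)
  }
  expect_lt(fitFor(pre$DusC$k_per_min, 5)@k, fitFor(pre$DusB$k_per_min, 6)@k)
})

test_that("enzymes rank DusA > DusB > DusC on the default kinetic presets", {
  fits <- lapply(dusKineticPresets(seed = 2), function(p) {
    d <- simulateMMDataset(p)
    fitMichaelisMenten(d$S_uM, d$v_uM_per_s, enzyme_conc = p$enzymeConc)
  })
  rk <- rankEnzymes(fits, criterion = "efficiency")
  expect_identical(rk$enzyme, c("DusA", "DusB", "DusC"))
  expect_false(rk$usable[rk$enzyme == "DusC"])
  # singleton and tie behaviour
  single <- rankEnzymes(fits["DusA"], criterion = "efficiency")
  expect_identical(nrow(single), 1L)
  tied <- rankEnzymes(list(B = fits$DusA, A = fits$DusA))
  expect_identical(tied$enzyme, c("A", "B"))
  expect_true(all(tied$tie))
})
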