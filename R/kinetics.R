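#' @include AllClasses.R
NULL

#' Initial rate from an absorbance-decay trace
#'
#' Fits a least-squares line over the earliest `window_frac` of the trace
#' (at least 5 points) and converts the slope to a consumption rate via
#' Beer-Lambert: `rate = -slope / (epsilon * path) * 1000` in uM/s for an
#' absorptivity in 1/mM/cm. Negative computed rates are clamped to 0 and
#' flagged.
#'
#' @param trace data.frame with columns `t_s` and `A343` (or any two
#'   numeric columns: time then absorbance).
#' @param epsilon_mM molar absorptivity (default 6.21 /mM/cm for NADPH at
#'   343 nm).
#' @param path_cm optical path length, cm.
#' @param window_frac fraction of the earliest points used (default 0.1).
#' @return list with `rate_uM_per_s`, `slope_AU_per_s`, `n_points`,
#'   `clamped`.
#' @export
initialRateFromTrace <- function(trace, epsilon_mM = 6.21, path_cm = 1,
                                 window_frac = 0.1) {
  t <- trace[[1L]]; A <- trace[[2L]]
  n <- max(5L, ceiling(window_frac * length(t)))
  if (length(t) < 5L) stop("need at least 5 points in the initial window")
  n <- min(n, length(t))
  sel <- order(t)[seq_len(n)]
  slope <- unname(coef(lm(A[sel] ~ t[sel]))[2L])
  rate <- -slope / (epsilon_mM * path_cm) * 1000
  clamped <- rate < 0
  if (clamped) rate <- 0
  list(rate_uM_per_s = rate, slope_AU_per_s = slope, n_points = n,
       clamped = clamped)
}

#' Fit the Michaelis-Menten model to initial-rate data
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)` using multi-start
#' Levenberg-Marquardt: Km seeded on a log-spaced grid spanning the
#' substrate range, Vmax seeded at `max(v)`; the best residual wins.
#' Standard errors come from the local curvature. `kcat = Vmax/E` and
#' `efficiency = kcat/Km` are derived. A fit whose Vmax 95% confidence
#' interval includes 0 is flagged as "no detectable activity"
#' (`detectable = FALSE`).
#'
#' @param S substrate concentrations, uM.
#' @param v initial rates, uM/s (same length as `S`).
#' @param enzyme_conc enzyme concentration, uM (required for kcat).
#' @param n_starts number of Km seeds on the log grid.
#' @return an [MMFit-class].
#' @export
fitMichaelisMenten <- function(S, v, enzyme_conc, n_starts = 12) {
  stopifnot(length(S) == length(v), enzyme_conc > 0)
  if (length(unique(S)) < 4L)
    warning("fewer than 4 distinct substrate concentrations; Km is poorly constrained")
  km_grid <- exp(seq(log(max(min(S[S > 0]), 1e-3) / 10),
                     log(max(S) * 10), length.out = n_starts))
  vmax0 <- max(v)
  best <- NULL; best_rss <- Inf
  for (km0 in km_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
        start = list(Vmax = max(vmax0, 1e-12), Km = km0),
        lower = c(Vmax = 0, Km = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best))
    return(new("MMFit", Vmax = NA_real_, Km = NA_real_, kcat = NA_real_,
               efficiency = NA_real_, se_Vmax = NA_real_, se_Km = NA_real_,
               enzymeConc = enzyme_conc, converged = FALSE,
               detectable = FALSE))
  est <- coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  vmax <- unname(est["Vmax"]); km <- unname(est["Km"])
  kcat <- vmax / enzyme_conc
  detectable <- !is.na(se["Vmax"]) && vmax - 1.96 * se["Vmax"] > 0
  new("MMFit", Vmax = vmax, Km = km, kcat = kcat, efficiency = kcat / km,
      se_Vmax = unname(se["Vmax"]), se_Km = unname(se["Km"]),
      enzymeConc = enzyme_conc, converged = TRUE, detectable = detectable)
}

#' @describeIn MMFit fit parameters as a one-row data.frame.
#' @param fit an [MMFit-class].
#' @export
mmFitTable <- function(fit) {
  data.frame(Vmax_uM_per_s = fit@Vmax, se_Vmax = fit@se_Vmax, Km_uM = fit@Km,
             se_Km = fit@se_Km, kcat_per_s = fit@kcat,
             efficiency_per_uM_s = fit@efficiency,
             enzyme_conc_uM = fit@enzymeConc, converged = fit@converged,
             detectable = fit@detectable)
}

setMethod("show", "MMFit", function(object) {
  if (!object@converged) {
    cat("MMFit: did not converge\n"); return(invisible(NULL))
  }
  cat(sprintf("MMFit: Vmax %.4g +/- %.2g uM/s, Km %.4g +/- %.2g uM\n",
              object@Vmax, object@se_Vmax, object@Km, object@se_Km))
  cat(sprintf("  kcat %.4g 1/s (E = %.3g uM), kcat/Km %.3g 1/(uM s)%s\n",
              object@kcat, object@enzymeConc, object@efficiency,
              if (object@detectable) "" else "  [no detectable activity]"))
})

#' Fit a saturating time course of dihydrouridylation
#'
#' Least squares of `D(t) = plateau * (1 - exp(-k t))` with multi-start
#' over log-spaced k seeds, plateau seeded at `max(D)`. All-zero data
#' return `k = 0, plateau = 0` flagged as non-converged.
#'
#' @param t time points, minutes; must include 0 and have >= 4 points.
#' @param D dihydrouridine levels (relative units).
#' @param n_starts number of k seeds.
#' @return a [TimecourseFit-class].
#' @export
fitSaturatingTimecourse <- function(t, D, n_starts = 10) {
  stopifnot(length(t) == length(D))
  if (length(t) < 4L) stop("need at least 4 time points")
  if (!any(t == 0)) stop("time course must include t = 0")
  if (all(D == 0))
    return(new("TimecourseFit", k = 0, plateau = 0, t_half = Inf,
               converged = FALSE))
  k_grid <- exp(seq(log(0.005), log(20), length.out = n_starts))
  p0 <- max(D)
  best <- NULL; best_rss <- Inf
  for (k0 in k_grid) {
    fit <- tryCatch(
      minpack.lm::nlsLM(D ~ plateau * (1 - exp(-k * t)),
        start = list(plateau = p0, k = k0),
        lower = c(plateau = 0, k = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best))
    return(new("TimecourseFit", k = 0, plateau = 0, t_half = Inf,
               converged = FALSE))
  est <- coef(best)
  k <- unname(est["k"]); plateau <- unname(est["plateau"])
  new("TimecourseFit", k = k, plateau = plateau,
      t_half = if (k > 0) log(2) / k else Inf, converged = TRUE)
}

setMethod("show", "TimecourseFit", function(object) {
  cat(sprintf("TimecourseFit: k %.4g 1/min (t1/2 %.3g min), plateau %.4g%s\n",
              object@k, object@t_half, object@plateau,
              if (object@converged) "" else "  [not converged]"))
})

#' Rank Dus enzymes by catalytic efficiency or time-course rate
#'
#' Orders converged fits descending by the chosen criterion
#' (`"efficiency"` = kcat/Km for [MMFit-class] objects, `"k"` for
#' [TimecourseFit-class] objects). Fits that did not converge or show no
#' detectable activity rank last with a flag; ties keep a stable
#' alphabetical order and are flagged.
#'
#' @param fits named list of [MMFit-class] or [TimecourseFit-class]
#'   objects; names are enzymes.
#' @param criterion `"efficiency"` or `"k"`.
#' @return data.frame with columns `enzyme`, `value`, `usable`, `rank`,
#'   `tie`.
#' @export
rankEnzymes <- function(fits, criterion = c("efficiency", "k")) {
  criterion <- match.arg(criterion)
  stopifnot(length(fits) >= 1L, !is.null(names(fits)))
  val <- vapply(fits, function(f) {
    if (is(f, "MMFit")) {
      if (!f@converged || !f@detectable) return(NA_real_)
      if (criterion == "efficiency") f@efficiency else f@kcat
    } else if (is(f, "TimecourseFit")) {
      if (!f@converged) return(NA_real_)
      f@k
    } else stop("fits must be MMFit or TimecourseFit objects")
  }, numeric(1))
  usable <- !is.na(val)
  ord <- order(!usable, -ifelse(usable, val, -Inf), names(fits))
  out <- data.frame(enzyme = names(fits)[ord], value = val[ord],
                    usable = usable[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  out$tie <- duplicated(out$value, incomparables = NA) |
    duplicated(out$value, incomparables = NA, fromLast = TRUE)
  rownames(out) <- NULL
  out
}
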