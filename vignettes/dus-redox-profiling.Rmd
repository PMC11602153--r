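---
title: "Methods: dihydrouridine mapping, quantification and Dus kinetics"
author: "DusProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dihydrouridine mapping, quantification and Dus kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DusProfiler)
```

# Scope and model

DusProfiler analyses three complementary readouts of tRNA
dihydrouridylation in *E. coli*: cleavage-based sequencing (AlkAnilineSeq,
AAS), adenosine-normalised LC–MS relative quantification of the
dihydrouridine (D) nucleoside, and in vitro enzyme kinetics of the three
dihydrouridine synthases. The central biological assumptions are:

* **One enzyme per site.** DusC serves canonical position 16, DusB
  position 17, DusA positions 20 and 20a. The label→enzyme rule is a fixed
  map (`enzymeForLabel()`), and each annotated site is attributed to
  exactly one synthase. Partial redundancy between enzymes is possible in
  principle; the model deliberately excludes it, which is why the knockout
  decomposition reports its closure residual instead of forcing shares to
  sum to 100%.
* **Occupancy acts multiplicatively.** A strain/treatment turns a baseline
  occupancy profile into an effective one:
  `occ = baseline × active(enzyme) × retention(enzyme)`, where the
  retention factor applies only under *aerobic* paraquat treatment —
  paraquat needs oxygen to redox-cycle and drain NADPH, and anaerobic
  treatment leaves D levels unchanged. The logic is a monotone contraction:
  effective occupancies never exceed baseline, a triple knockout is
  identically zero, and the untreated wild type is a fixed point.

# The AAS chemistry model and its scoring

## What the simulator emulates

Per simulated molecule of each reference:

* every modified D site at index *i* is ring-opened and scissioned with
  probability `occupancy(i) × alkCleavageProb`, exposing a ligatable
  5'-phosphate at *i + 1* (the N+1 rule);
* every inter-nucleotide bond independently acquires a ligatable background
  break with probability `backgroundBreakRate` (residual, incompletely
  dephosphorylated hydrolysis ends — the noise floor);
* the intact 5' terminus is ligation-competent with probability
  `terminalLigationProb`.

Each ligatable fragment at least `minFragmentLen` long yields one read —
the reference substring from its 5' end, truncated at `readLen` or at the
next break. There is no PCR-duplication model and sequencing errors default
to off, so reads are exact reference substrings; a truth table records
every read's molecule, 5' index and cause.

## Parameter choices

| parameter | default | rationale |
|---|---|---|
| `terminalLigationProb` | 1.0 | Mature tRNA carries a 5'-monophosphate, so essentially every intact molecule contributes a terminus read. This is what gives null libraries coverage that dwarfs their stop counts; with a rare-terminus model the stop ratio at D-loop position *i* would converge to ~1/*i* regardless of the background rate, and no null ceiling below ~0.05 would be possible. It is also what makes the stop ratio converge to the molecule-level break fraction (occupancy × cleavage yield). |
| `alkCleavageProb` | 0.50 | The true per-site cleavage yield is not known. The D-loop sites sit 1–5 nt apart, so molecules cleaved at two nearby sites lose the short intervening fragment (below `minFragmentLen`); at high yields this fragment loss visibly suppresses the most 5' site (position 16). 0.50 keeps every site's expected stop ratio comfortably above the call threshold while still modelling incomplete cleavage. |
| `backgroundBreakRate` | 1e-3 per bond | Small enough that null libraries stay far below the 0.04 ceiling, large enough that the null test is non-trivial (stops do occur at D positions in knockout libraries). |
| `readLen` / `minFragmentLen` | 50 / 15 nt | 50-bp single-end layout; 15 nt is a typical lower bound for ligation + mapping. |
| `min_cov` | 10 | Below 10× the ratio estimate is unstable; such positions report 0 with a `low_coverage` flag rather than a noisy value. |
| call `threshold` | 0.05 | Must sit above the empirical null ceiling (≤ 0.04) and below the weakest real site signal (~0.12 at defaults). |

## Scoring decisions

* **Denominator.** The stop ratio uses *per-position coverage*:
  `n5(i)/cov(i)`. A library-wide denominator would make scores depend on
  reference length and library composition; per-position coverage keeps
  the score in [0, 1] with the interpretation "fraction of molecules
  observed at this position that terminate here".
* **Back-shift.** D sites are reported at (stop position − 1), matching the
  N+1 chemistry; call tables carry both indices so either convention can
  be read off.
* **Mapping.** Reads are placed end-to-end by exhaustive Hamming scan over
  every offset of every reference (no indels; `N` never matches), with
  `max_mismatch = 2`. Ties at the best score are discarded as multimapped
  rather than placed randomly — determinism is preferred over coverage,
  and the fixture generator enforces pairwise edit distance ≥ 5 so ties
  are rare. The scan is compiled code; the test suite checks it against an
  independent pure-R brute-force oracle.
* **Terminus artifact.** Position 1 of every reference has stop ratio 1 by
  construction (only reads starting there can cover it). Discovery mode
  therefore only considers stop positions ≥ 2; annotated mode reads ratios
  at site + 1 and is unaffected.
* **Condition comparison.** Treated/control ratios are expressed as
  percent of control per position; positions whose control is flagged or
  zero are reported as undefined (`NA`), never as infinities.

## What the simulator does *not* model

No adapter/quality trimming (reads are clean; real libraries should be
pre-trimmed), no PCR duplicates, no chromatographic or ligation sequence
bias, no indels, and no m7G/m3C signals (the other targets of the
chemistry). Consequently a passing synthetic suite demonstrates the
correctness of the scoring chain, not robustness to real-library artifacts.

# The fixture reference set

`buildFixtureReferences()` generates 76-nt tRNA-like sequences (random
body, CCA 3' end) annotated at canonical 16, 17 and 20 on every tRNA and
20a on about half. With uniform baseline occupancy this gives the
DusA-served positions (20/20a) ≈ 43% of all sites, reflecting that DusA
introduces about half of cellular D and that position 20 is the
predominant D-loop site; single-knockout panels then order
ΔdusA < ΔdusB ≈ ΔdusC < WT, as observed in vivo. Canonical labels map
directly onto sequence indices (20a at index 21) — the generator makes no
attempt at general Sprinzl numbering inference, which is out of scope;
real references carry their numbering in the annotation sidecar.

# LC–MS quantification

The simulator draws the D MS area proportional to summed site occupancy
over the tRNA pool and the adenosine UV area proportional to the pool's
adenosine content, both under multiplicative lognormal noise (areas are
positive and CV-stable; `noiseCv` default 0.05). The D channel adds a
constant floor (`noiseFloorFrac`, default 0.003 of the wild-type D signal)
modelling carry-over/background in the MS channel — this is what keeps a
true-null sample slightly above zero, at ≈ 0.3% of wild type.

Quantification normalises D to the adenosine UV signal *within* each
sample, making the level invariant to injection amount, then expresses it
as percent of the control's normalised signal. Replicate groups are
compared with the classical pooled-variance two-tailed Student's t-test
(Welch behind a flag); significance labels use 0.05/0.01/0.001 stars. No
multiple-testing correction is applied by default, matching per-comparison
reporting practice for small targeted panels.

MRM transitions are computed from molecular formulas with monoisotopic
element masses (C, H, N, O, P) and the proton mass; nominal values are the
integer-rounded protonated masses, e.g. dihydrouridine
C9H14N2O6 + H = 247.0925 → 247, ribose loss C5H8O4 → product 115; NADPH
C21H30N7O17P3 + H = 746.1 → 746, NH3 loss → 729. NADPH concentrations come
from an ordinary least-squares external calibration line, with negative
extrapolations clamped to zero and flagged.

# Enzyme kinetics

* **Initial rates.** A343 traces are converted to rates via Beer–Lambert
  with ε343 = 6.21 mM⁻¹cm⁻¹ and 1 cm path: rate (µM/s) =
  −slope/(ε·path)·1000. The slope is a least-squares line over the
  earliest 10% of points (at least 5) — the window is configuration, since
  the assay's own window is not documented. Negative rates clamp to zero
  with a flag. The assay wavelength is metadata; the stated ε343 is used
  by default.
* **Michaelis–Menten fitting.** Direct nonlinear least squares of
  `v = Vmax·S/(Km+S)` by Levenberg–Marquardt, multi-started from a
  log-spaced grid of Km seeds (12 by default, spanning 0.1×min(S) to
  10×max(S)) with Vmax seeded at max(v); the lowest residual wins.
  Linearising transforms (Lineweaver–Burk) are avoided for estimation —
  they distort the error structure — but a profiled grid search over Km
  serves as an independent oracle in the tests. Standard errors come from
  the local curvature; kcat = Vmax/E requires the enzyme concentration as
  input (it is not inferable from rate data). A fit whose Vmax 95%
  confidence interval includes zero is reported as "no detectable
  activity" rather than as a number — this is how a DusC-like enzyme,
  whose NADPH oxidation sits below the assay's detection floor, is
  handled and why `rankEnzymes()` places such fits last.
* **Time courses.** `D(t) = plateau·(1 − e^(−kt))` fitted the same way
  (multi-start over k); all-zero data short-circuit to k = 0 with a
  non-converged flag; t½ = ln 2/k is derived, and the identity is enforced
  by the class validity.
* **Presets.** `dusKineticPresets()` encodes the enzyme hierarchy as
  simulator settings: DusA kcat 0.48 s⁻¹/Km 17 µM; DusB kcat 0.011 s⁻¹
  (its Km was not resolvable in the slow assay and is set equal to DusA's
  — configuration, not a claim); DusC at 1e-4 s⁻¹ under a 2e-3 µM/s
  additive detection floor, i.e. signal below noise. The time-course
  presets (k = 3, 0.15, 0.02 min⁻¹) put DusA near saturation within 1 min
  and DusC barely above baseline before 20 min.

# Randomness and determinism

A single top-level seed spawns independent sub-streams keyed by stable
strings (`streamSeed(seed, "aas/WT_pq0")`), so adding a generator or a
sample never perturbs another's draws, and every artifact is reproducible
from (config, seed) alone — the suite verifies byte-identical reruns. All
generators restore the caller's RNG state.

# Problem sizes

The defaults are sized for interactive use and continuous testing: 20
fixture tRNAs at 2 000 molecules each (≈ 42 000 reads) for null-ceiling
experiments, 250–1 000 molecules per tRNA in scenario runs and property
tests, 3–5 replicates per group as in the corresponding experimental
designs, 100 seeded datasets for the Michaelis–Menten recovery envelope,
and 200 seeded runs for rate-extraction coverage. At these sizes a full
scenario completes in seconds and the whole suite in about a minute.

# Known limitations

* The AAS mapper is Hamming-only; indel-containing reads are unmapped.
* Scores on real libraries depend on upstream trimming quality, which the
  package does not perform.
* The occupancy model treats sites independently; cooperative modification
  or enzyme redundancy would surface only as a nonzero decomposition
  residual, not be attributed.
* LC–MS simulation produces areas, not chromatograms; peak integration,
  retention-time alignment and isotope-labelled absolute quantification
  are out of scope.
* The paraquat retention factors (DusA 1.0, DusB 0.6, DusC 0.4) encode an
  observed qualitative ordering as configuration; they are not measured
  constants, and conclusions drawn from scenario runs inherit them.
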