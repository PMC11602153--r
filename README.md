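# DusProfiler

DusProfiler is an R package for studying the redox sensitivity of tRNA
dihydrouridylation in *Escherichia coli*. Dihydrouridine (D) — the only
non-aromatic base known in RNA — is installed in the tRNA D-loop by three
flavin-dependent, NADPH-consuming dihydrouridine synthases with strict site
specificity: **DusC** reduces position 16, **DusB** position 17, and
**DusA** positions 20 and 20a. Because catalysis consumes NADPH, redox
stress (e.g. paraquat under aerobic growth) can starve the enzymes and
reshape the tRNA modification landscape. The package implements the three
assay chains needed to dissect this, plus seeded simulators that emulate
each assay's chemistry and noise so the whole pipeline runs and is testable
at desk scale.

## What it computes

**AlkAnilineSeq (AAS) stop-ratio mapping.** Mild alkaline hydrolysis opens
the saturated D ring; after dephosphorylation of background ends, aniline
scission exposes a ligatable 5'-phosphate at the nucleotide *after* the
modified site (N+1). Read 5' ends therefore mark D positions. For every
reference position *i*:

```
stop_ratio(i) = n5(i) / cov(i)        in [0, 1]
```

where `n5(i)` counts reads whose 5' end maps at *i* and `cov(i)` counts
reads covering *i*. A D site is called at the back-shifted index `i - 1`.
Conditions are compared as percent of an untreated control (control = 100%).

**LC–MS relative quantification.** The dihydrouridine MS peak area is
normalised within each sample to the adenosine UV area and expressed
relative to a control:

```
level = 100 * (D_MS / A_UV)_sample / (D_MS / A_UV)_control
```

Knockout decomposition attributes shares of total D to each enzyme,
`contribution(E) = 100 * (1 - level(ΔE) / level(WT))`, reporting the closure
residual. MRM transition masses (e.g. dihydrouridine m/z 247 → 115 by
ribose loss) are computed from molecular formulas and monoisotopic masses,
and NADPH is quantified against an external calibration line.

**Enzyme kinetics.** Initial rates are extracted from A343 traces via
Beer–Lambert (ε343 = 6.21 mM⁻¹cm⁻¹), fitted to the Michaelis–Menten model
`v = Vmax·S/(Km+S)` by multi-start nonlinear least squares (kcat = Vmax/E,
efficiency = kcat/Km), dihydrouridylation time courses to
`D(t) = plateau·(1 − e^(−kt))`, and enzymes ranked by efficiency or rate.

## Worked example

```r
library(DusProfiler)

bundle   <- buildFixtureReferences(10, seed = 7)   # 10 tRNA-like references
baseline <- baselineProfile(bundle, 0.9)           # 90% occupancy everywhere
lib <- simulateAASLibrary(bundle, baseline,
                          aasLibraryParams(moleculesPerTrna = 1000, seed = 1))
aln  <- mapReads(lib$reads, bundle)
prof <- stopRatio(tallyAlignments(aln, bundle))
calls <- inferDPositions(prof, bundle, mode = "annotated")
head(calls[calls$called, c("trna_id", "canonical_label", "enzyme", "stop_ratio")], 5)
#>         trna_id canonical_label enzyme stop_ratio
#>  tRNA-Ala-GGC-1              16   DusC  0.1226891
#>  tRNA-Ala-GGC-1              17   DusB  0.2851485
#>  tRNA-Ala-GGC-1              20   DusA  0.3996790
#>  tRNA-Ala-GGC-1             20a   DusA  0.4448938
#>  tRNA-Arg-GAG-1              16   DusC  0.1348315
```

Every annotated site is recovered at its canonical position; the ratios are
the fraction of molecules cleaved at each site that survive as mappable
fragments. Knockout decomposition on measured relative levels:

```r
decomposeContributions(100, c(DusA = 45, DusB = 77, DusC = 77))
#> $contributions
#> DusA DusB DusC
#>   55   23   23
#> $residual
#> [1] -1
```

DusA carries 55% of total D, DusB and DusC 23% each; the −1% residual is
reported rather than hidden. A Michaelis–Menten fit on simulated noisy
initial-rate data (true kcat 0.48 s⁻¹, Km 17 µM):

```r
mm  <- simulateMMDataset(kineticsSimParams(kcat = 0.48, Km = 17,
                                           enzymeConc = 1, noiseCv = 0.05, seed = 3))
fitMichaelisMenten(mm$S_uM, mm$v_uM_per_s, enzyme_conc = 1)
#> MMFit: Vmax 0.4812 +/- 0.0077 uM/s, Km 16.74 +/- 0.89 uM
#>   kcat 0.4812 1/s (E = 1 uM), kcat/Km 0.0287 1/(uM s)
```

Full experimental designs (knockout panel, aerobic/anaerobic paraquat,
polysome fractions) run end to end from one seeded config via
`runScenario(defaultScenarioConfig("knockout_panel", seed = 1))`, and a thin
CLI wraps the same functions:
`Rscript inst/scripts/dusprofiler.R run-scenario --config inst/extdata/example_scenario.yaml --out out/`.

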