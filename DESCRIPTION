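Package: DusProfiler
Title: Dihydrouridine Mapping, Quantification and Dus Enzyme Kinetics for
    Bacterial tRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the redox sensitivity of tRNA
    dihydrouridylation in Escherichia coli. Implements stop-ratio scoring of
    alkaline-hydrolysis/aniline cleavage sequencing (AlkAnilineSeq) read
    libraries against tRNA references with canonical D-loop numbering,
    adenosine-normalised LC-MS relative quantification of dihydrouridine with
    knockout decomposition, MRM transition mass calculation, NADPH
    calibration, and Michaelis-Menten / saturating time-course enzyme
    kinetics for the three site-specific dihydrouridine synthases (DusA,
    DusB, DusC). Seeded simulators emulate the cleavage chemistry, nucleoside
    peak tables and kinetic assays so every stage of the pipeline is testable
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    Biostrings,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'DusProfiler-package.R'
    'RcppExports.R'
    'core-model.R'
    'aas-pipeline.R'
    'kinetics.R'
    'lcms-quant.R'
    'synthetic-data.R'
    'scenarios.R'
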