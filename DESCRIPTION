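Package: GRNexpand
Title: Expanding Mechanistic ODE Models with Machine-Learned Gene
    Regulatory Associations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts signed gene-gene association networks, such as those
    inferred by penalized regression on multi-omics data, into gene
    regulatory extensions of mechanistic ordinary differential equation
    models. New genes receive mRNA and protein species with transcription,
    translation and degradation kinetics parameterized from copy numbers,
    molecule counts and half-lives; each association becomes a pair of
    Hill-type transcriptional activator/repressor interactions. The package
    simulates the expanded models deterministically, calibrates basal
    transcription rates and half-maximal regulator concentrations by
    sequential log-scale grid search against time-course data, screens
    single-gene knockouts against wild type, reads and writes tab-delimited
    model tables, and exports SBML Level 3.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    igraph,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'GRNexpand-package.R'
    'accessors.R'
    'association.R'
    'calibrate.R'
    'dynamics.R'
    'expand.R'
    'fixtures.R'
    'graph.R'
    'model-io.R'
    'perturb.R'
    'pipeline.R'
    'rates.R'
    'sbml.R'
    'utils.R'
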