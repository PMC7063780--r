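Package: thermoflux
Title: Fermentation Flux Accounting and Genotype-Phenotype Analysis for
    Evolved Cellulolytic Thermophiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing adaptive-laboratory-evolution experiments in
    cellulolytic thermophiles such as Clostridium thermocellum: steady-state
    chemostat carbon and electron flux accounting, hierarchical clustering of
    fermentation phenotypes, pedigree-aware mutation provenance and
    convergent-evolution detection, merodiploid locus genotyping from read
    depth and junction evidence, RPKM normalisation with upstream-mutation to
    expression linkage, and logistic substrate-depletion kinetics.  Includes a
    seeded synthetic-data generator that emulates the study design (strain
    pedigree, fermentation phenotype clusters, replicate expression matrices,
    locus coverage tracks and cellulose solubilization curves) so the whole
    pipeline is testable without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    minpack.lm,
    ape,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
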