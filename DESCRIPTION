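Package: phaseflux
Title: Multi-Phase Constraint-Based Modelling of Microbial Growth on Complex Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simulating the metabolic rewiring of a bacterium growing on a
    nutritionally complex medium, phase by phase. Fed-batch growth curves (optical
    density, growth rate and amino-acid concentrations) are turned into per-phase
    yields and per-amino-acid uptake-flux bounds; each phase is then simulated with
    flux balance analysis (FBA) and flux variability analysis (FVA) on a
    constraint-based metabolic model. Flux changes across phase transitions are
    classified (increasing, decreasing, reversing, switching on or off), a
    minimal-metabolic-adjustment (MOMA) chain across nutrient transitions provides a
    sub-optimal alternative to biomass maximisation, and co-varying reactions are
    clustered from flux-difference correlations and mapped to genes through
    gene-protein-reaction rules. A synthetic-data module generates toy metabolic
    models and fed-batch growth curves with hierarchical substrate depletion so the
    whole pipeline runs self-contained.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
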