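Package: kappabind
Title: Equilibrium Analysis of NF-kB Dimer Binding to Kappa-B DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of transcription factor-DNA
    equilibria of the NF-kB type: ligand-depletion-aware single-site and
    two-site binding models with fluorescence anisotropy readout and global
    least-squares fitting, a finite one-dimensional lattice (footprint)
    model predicting multi-dimer stoichiometries on tandem kappa-B promoter
    DNA including competition between DNA species for a shared protein
    pool, a synthetic-data generator for anisotropy titrations and EMSA
    band fractions, and small-angle X-ray scattering utilities (Guinier
    fitting, Kratky transform, excluded-volume polymer scaling). All
    user-facing functions take data frames and return tibbles.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
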