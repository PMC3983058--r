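Package: casidp
Title: Conformational Ensemble and Single-Molecule Characterization of the
    p130Cas Intrinsically Disordered Substrate Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize proline-rich intrinsically disordered
    protein domains such as the p130Cas substrate domain (CasSD): generation
    of secondary-structure-biased backbone conformer ensembles by Ramachandran
    basin sampling with clash rejection, polymer and hydrodynamic statistics
    (radius-of-gyration distributions, polyproline-II content by ensemble
    size, Kohn scaling, minimal-sphere and friction-ratio arithmetic),
    worm-like-chain analysis of atomic-force-microscopy force-extension
    curves with I27-signature trace classification, and sequence-level
    analysis (YxxP motif maps, composition, molecular weight, disorder
    prediction consensus, alignment conservation). A synthetic-data module
    generates every input the pipeline consumes so all stages run without
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
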