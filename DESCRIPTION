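Package: erpep
Title: Energy-Resolved MS/MS Analysis of Isomeric Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for differentiating isomeric peptides from energy-resolved
    collision-induced dissociation (CID) tandem mass spectra. Provides exact
    monoisotopic mass and m/z arithmetic for peptides containing non-standard
    residues such as beta-alanine, enumeration of theoretical fragment ions
    (conventional b/y ions, internal ions, combinatorial neutral-loss series,
    and scrambled b ions from macrocycle reopening), Survival-Yield and
    breakdown curves across collision voltages, NIPALS principal component
    analysis of TIC-normalised spectra with diagnostic-fragment ranking, peak
    annotation against theoretical catalogues, and a seeded generator of
    synthetic energy-resolved spectrum series for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
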