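Package: muroquant
Title: Muropeptide Quantification, Peptidoglycan Composition Statistics, and
    Penicillin-Binding-Protein Assay Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for bacterial cell-wall (peptidoglycan) studies
    built around three assay families. A theoretical muropeptide library with
    monoisotopic masses and charge-state m/z values supports identification and
    quantification of muramidase digestion products from centroided LC-MS data
    (extracted ion chromatograms, peak integration, molar normalization), from
    which standard peptidoglycan summary statistics are derived: oligomer
    (monomer/dimer/trimer/tetramer) molar percentages, overall crosslinkage, and
    mean glycan chain length from the anhydro-muropeptide fraction. A single-cell
    image module measures rod-shaped cells from paired phase-contrast and
    fluorescence images (principal-axis length and width, rod-model volume,
    normalized-axis fluorescence profiles, width- or area-based population
    grouping, fluorescence-versus-width regression), supporting cell-cycle-resolved
    localization analysis of division proteins in bacteria that widen as they
    divide. A gel-densitometry module quantifies Bocillin-FL binding titrations
    (relative binding versus antibiotic concentration, inhibition/enhancement
    classification, interpolated IC50). Synthetic-data generators with known
    ground truth (glycan strand populations, centroided runs, cell image pairs,
    titration lane tables) make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    pracma,
    EBImage,
    igraph
Suggests:
    mzR,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
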