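Package: ftirqtl
Title: ATR-FTIR Spectral Phenotyping and QTL Mapping in Recombinant Inbred Panels
Version: 0.1.0
Authors@R:
    person("FTIR-QTL", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Turns attenuated-total-reflectance Fourier-transform infrared
    (ATR-FTIR) absorbance spectra of mouse tissues into quantitative
    macromolecular traits (fat, collagen, glycogen band areas and their
    ratios) and maps those traits to genomic loci in a two-allele
    recombinant-inbred panel. Includes spectral preprocessing (water-vapor
    correction, quality testing, min-max normalization, replicate
    averaging), local-baseline band integration with a per-tissue band
    registry, trait statistics (winsorization, strain summaries, Pearson
    correlations, broad-sense heritability, delta-delta-Ct expression),
    single-marker regression QTL scans with permutation-derived genome-wide
    thresholds and LOD-drop support intervals, a candidate-gene filter
    cascade over annotation tables, and a synthetic-data generator with
    planted ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
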