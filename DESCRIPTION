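Package: NRPlinker
Title: Peptidogenomics Engine Linking NRPS Gene Clusters to Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates biosynthetic gene cluster (BGC) adenylation-domain
    substrate predictions with tandem mass spectrometry to identify
    non-ribosomal peptides (NRPs). Generates canonical and non-canonical
    NRPS assembly lines (ORF deletion and tandem ORF duplication), filters
    the combinatorial space of core peptides by a dynamic program over
    additive specificity scores, expands candidates into linear, cyclic and
    branch-cyclic peptide graphs, scores them against spectra with a blind
    modification-tolerant shared-peak-count search, estimates peptide-spectrum
    match p-values by multilevel-splitting Monte Carlo, and groups identified
    spectra into putative NRP families by spectral networking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
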