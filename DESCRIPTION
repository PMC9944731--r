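Package: methnet
Title: Network-Oriented Differential DNA Methylation Analysis for Two-Group Bisulfite Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for network-oriented analysis of CpG methylation in
    small two-group clinical cohorts, as used in studies of circulating
    immune-cell methylomes in pulmonary arterial hypertension. Calls
    differentially methylated CpGs from Bismark-style coverage tables with a
    per-site binomial likelihood-ratio test and Benjamini-Hochberg control,
    annotates sites to promoters, CpG islands and shores, prioritizes
    differentially methylated genes by degree centrality in tissue
    protein-protein interaction subnetworks, builds promoter-restricted
    disease subnetworks against a publication-filtered disease-gene catalog,
    performs hypergeometric overrepresentation analysis, and relates promoter
    methylation scores to hemodynamic parameters, qPCR fold changes and
    cross-platform beta values. A fully seeded synthetic-data generator
    produces every input with planted ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    limma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
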