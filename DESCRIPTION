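Package: tetrakit
Title: Comparative Analysis Toolkit for Allotetraploid Draft Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative analysis of allotetraploid draft
    genome assemblies: synteny-guided scaffold placement against a diploid
    reference and pseudo-chromosome construction with AGP output, greedy
    overlap-based partitioning of homeologous scaffolds into A and B
    pseudo-chromosome sets, Nei-Gojobori (1986) synonymous/non-synonymous
    divergence estimation with Jukes-Cantor correction and Ks-peak
    molecular-clock dating, k-mer spectrum genome-size estimation from the
    coverage peak, microsatellite (SSR) detection with MISA-style minimum
    repeat thresholds, in-silico PCR and genetic-map linking, and exact
    peptide scanning of proteomes for celiac-disease epitopes.  A
    forward-simulation module generates allotetraploid toy genomes with
    complete ground truth so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
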