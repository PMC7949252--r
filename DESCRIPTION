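Package: gsmforge
Title: Evidence-Weighted Reconstruction of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstruction of genome-scale metabolic network models from
    homology evidence. Predicts metabolic pathways, transporters, and
    protein complexes from tabular alignment results, assembles draft
    models with provenance codes, gap-fills them with an evidence-weighted
    linear program derived from parsimonious flux balance analysis, and
    predicts phenotypes (carbon source utilisation, fermentation products,
    gene essentiality). Includes a curated toy biochemistry database and a
    deterministic synthetic-organism generator so that the whole pipeline
    is testable without external downloads, a network-similarity score for
    models built from fragmented (metagenome-derived) genomes, and SBML
    export. Constraint-based analyses (FBA, minimisation of total flux,
    flux variability analysis) run on a built-in bounded-variable simplex
    solver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
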