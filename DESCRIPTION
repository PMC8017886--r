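Package: profex
Title: Two-Step Metaproteomic Peptide Identification Guided by
    High-Abundance Protein Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies peptides from microbial community MS/MS data with a
    two-step database strategy: spectra are first searched against a compact
    database of high-abundance proteins (ribosomal proteins and elongation
    factors) drawn from a large genome collection, the minimal set of genomes
    explaining a target fraction of the identified spectra is chosen by a
    greedy set cover, and a final search is run against all proteins of the
    selected genomes under target-decoy false-discovery-rate control.
    Includes a desk-scale search engine (tryptic digestion, monoisotopic
    mass computation with modifications, b/y fragment matching and
    hyperscore-style scoring), an adapter for externally produced
    peptide-spectrum match tables, spectral-count taxonomic profiling,
    evaluation metrics (consistency rate, identification rate,
    isoleucine/leucine-blind peptide overlap, protein spectral support,
    expressed-operon detection), and a seeded synthetic community and
    spectrum generator with ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
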