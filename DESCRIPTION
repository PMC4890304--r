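Package: uorfrepress
Title: Quantifying uORF-Mediated Translational Repression from Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of upstream open reading frames (uORFs) and
    their repressive effect on coding-sequence translation. Discovers and
    classifies AUG-initiated ORFs on transcript models, quantifies ORF-level
    translational efficiency (TE) and uORF repressiveness from single-nucleotide
    P-site ribosome-profiling densities, builds TE-weighted position-specific
    scoring matrices of initiation contexts (WRENT scores), profiles RNA
    secondary-structure ensemble free energies in sliding windows, measures
    positional trinucleotide bias and shuffle-null depletion of uORF ends near
    the CDS, fits ridge-regression models of uORF repressiveness and CDS TE
    with leave-one-out PRESS statistics, and compares translation and sequence
    features across one-to-one orthologs. Includes a synthetic-data generator
    emulating the statistical structure of the analysis for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: ViennaRNA RNAfold (optional, for the thermodynamic
    folding engine; deterministic toy engines require nothing external)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
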