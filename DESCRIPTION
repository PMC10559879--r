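Package: oxidiff
Title: Integrative Differential Analysis of TMT Proteome, Redoxome and
    Phosphoproteome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a mix-internal differential analysis pipeline for
    tandem-mass-tag (TMT) reporter-ion quantification of three omics layers:
    protein abundance, cysteine oxidation measured by sequential iodoTMT
    labeling (overall and reversible oxidation), and phosphorylation sites.
    Provides reporter-ion impurity correction, peptide-to-site intensity
    rollup, replicate-wise treated-vs-control log2 fold changes, median
    normalization, sign inversion of the free-thiol channel, normalization of
    modification-site changes to protein-level changes, one-sample t tests
    with Benjamini-Hochberg correction, hypergeometric over-representation
    analysis against gene-set collections, cross-timepoint dynamics, overlap
    of multiply modified proteins, and a synthetic-data generator with ground
    truth for calibration and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
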