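Package: splitrace
Title: Split Single-Cell 3'-RACE Simulation and Monoallelic Expression
    Inference for Clustered Protocadherins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing split single-cell 3'-RACE experiments on
    tandem gene clusters such as the mouse protocadherin-beta (Pcdh-beta)
    cluster.  Provides a generative simulator of diploid single-cell isoform
    expression with tube-split amplification and allelic dropout; allele
    calling from strain-discriminating variant sites with a tube-consistency
    QC gate; the statistical core of the assay (single-molecule artifact null
    model, chi-square comparison, per-cell repertoire estimation and
    combinatorial diversity arithmetic); and sequence utilities for pan- and
    isoform-specific probe design, strain-variant discovery and
    polyadenylation-site analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
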