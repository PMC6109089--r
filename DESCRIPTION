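Package: spherophylo
Title: Clonal Evolution Inference from Multi-Region Tumor and Ascites Spheroid Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the clonal evolution of a tumor from multi-region
    low-depth whole-genome and high-depth whole-exome sequencing of primary
    tumor pieces and individual ascites tumor spheroids. Implements copy-number
    profiling by variable-size binning with Lowess GC normalization and
    hierarchical clustering of profiles, a three-caller somatic SNV consensus
    with Fisher-exact rescue that suppresses NGS and whole-genome-amplification
    artifacts, VAF-based tumor purity estimation and a clonality index for
    sample pairs, joint multi-sample segmentation, and maximum-parsimony
    phylogenies from trinary CNA and binary SNV event matrices. A synthetic
    clone-tree data generator with known ground truth drives all stages at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    phangorn,
    cluster,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
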