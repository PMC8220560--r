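Package: hohaplo
Title: Hierarchically Organized Haplotype Analysis of HLA Amino-Acid Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fine-mapping of HLA class II associations by hierarchically
    organized haplotype (HOH) analysis. Alleles of a multi-allelic locus
    (e.g. HLA-DRB1) are organized by protein-sequence similarity into an
    ultrametric tree, amino-acid residues are screened within an allele
    cluster, and residue/motif associations with a binary outcome are
    tested with virtual-reference odds ratios and haplotype score
    statistics. Multi-locus haplotype frequencies are estimated by EM.
    A survival arm derives seroconversion endpoints from longitudinal
    autoantibody panels and fits one-vs-rest and reference-based Cox
    proportional hazards models with the Grambsch-Therneau diagnostic.
    Includes a synthetic-data generator with planted ground truth for
    end-to-end validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
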