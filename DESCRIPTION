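Package: wgdphylo
Title: Phylogenomic Placement and Molecular Dating of Ancient Whole-Genome
    Duplications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Places ancient whole-genome duplication (polyploidy) events on a
    fixed angiosperm species scaffold by scoring gene-tree duplication nodes
    of focal-genome paralog pairs with a bootstrap-support rule, dates the
    accepted duplication nodes by penalized-likelihood rate smoothing with
    fossil calibrations, and characterizes the resulting age and Ks
    distributions with finite normal-mixture models selected by BIC.
    Includes a gene-family simulator that seeds a duplication on a chosen
    scaffold branch so the whole pipeline can be validated on synthetic
    orthogroups, and pairwise Ks estimation under the Goldman-Yang codon
    model with F3x4 frequencies alongside a Nei-Gojobori counting method.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
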