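Package: camelpop
Title: Ploidy Inference, Subgenome Assignment and Population Genomics for
    Camelina GBS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coverage-based inference of genome composition (karyotype) for
    Camelina accessions mapped to the hexaploid C. sativa reference, with
    step-wise inference of the chromosome-to-subgenome map from a diploid and
    a tetraploid relative. Downstream population genomics for
    genotyping-by-sequencing variant calls: variant filtering, gene diversity
    and polymorphic information content, Nei (1983) D_A distances,
    neighbor-joining trees, principal coordinates analysis, distance-based
    AMOVA PhiPT with permutation tests and windowed scans, species-level
    minor-allele cataloguing, and admixture classification from ancestry
    (Q) matrices. Homoeolog-triplet expression-dominance analysis across
    tissues via randomized-block ANOVA. Includes seeded simulators for every
    input so the whole pipeline is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
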