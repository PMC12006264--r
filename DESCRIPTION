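Package: orthostruct
Title: Comparative Sequence and Predicted-Structure Evolution of Orthologous Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing orthologous proteins across species at both the
    sequence and the predicted-structure level. Provides alignment-anchored
    residue-to-column maps and pairwise divergence counting, ancestral-lineage
    substitution inference scored with the Miyata biochemical distance,
    plDDT/ADOPT-based ordered-disordered residue masks, alignment-guided rigid
    superposition with iterative pruning and confidence-gated per-residue
    deviation classing, geometric hydrogen-bond detection and PAE-filtered
    interface contacts, category-stratified Fisher exact comparisons with
    Bonferroni correction, and a fully seeded synthetic-data generator that
    plants known substitutions, displacements and interfaces so every stage of
    the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
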