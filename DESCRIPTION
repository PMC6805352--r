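Package: spiralineage
Title: Cell-Lineage Analysis of the Spiral-to-Bilateral Transition in the
    Annelid Episphere
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for developmental cell-lineage analysis of the annelid
    larval episphere. Provides the standard spiralian blastomere
    nomenclature, a lineage-tree data model with track-table input/output
    and Newick export, a synthetic generator of spiral-cleavage episphere
    embryos with an inter-embryo variability model, cross-embryo
    corresponding-cell identification with censoring-aware difference
    quantification and consensus-tree construction, bilateral-founder
    detection with symmetry classification, and lineage metrics (depth,
    age, cycle length) together with a transcription of the annotated
    differentiated cell types and clonal-projection analysis of gene
    expression labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
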