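Package: gpcrchimera
Title: In-Silico Design of CNO-Responsive DREADD-Based GPCR Chimeras
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-anchored annotation of G protein-coupled receptor
    (GPCR) domain architecture, transmembrane-topology cross-validation by
    hydropathy analysis, and assembly of chemogenetic chimeric receptors at
    the protein and DNA level. Signaling domains (intracellular loops and
    C-terminus) of a GPCR-of-interest are identified by projecting a
    rhodopsin-anchored domain annotation through a protein alignment and
    spliced into a DREADD (Designer Receptor Exclusively Activated by
    Designer Drugs) scaffold, with N-terminal signal-peptide and epitope-tag
    modifications, codon-faithful CDS splicing, restriction-site screening
    and GenBank export. Also provides the cell-type specificity statistic
    (min/max expression ratio with Wilcoxon rank-sum significance) used to
    select candidate receptors from grouped expression matrices, and the
    normalization formulas for luminescence assays, RT-qPCR (ddCq) and
    lentiviral titration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
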