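Package: editoscan
Title: Proteogenomic Detection of A-to-I mRNA Editing from Peptide Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for proteogenomic genome-annotation refinement and for
    detecting single-amino-acid variants (SAAVs) caused by A-to-I mRNA
    editing from mass-spectrometry peptide evidence. Builds annotated,
    six-frame, decoy and hybrid search databases; performs in-silico
    proteolysis (trypsin, Glu-C) and monoisotopic mass arithmetic;
    orchestrates stepped database searches with target-decoy q-values and
    class-specific false discovery rates; maps peptides to proteins and
    genome coordinates with I/L equivalence and exports BED12 and
    proBAM-style SAM; screens de novo peptides for editing-compatible
    substitutions and UAG-to-UGG stop-loss readthrough; applies rule-based
    annotation refinement from peptide plus RNA-Seq evidence; assigns
    phylostratigraphic ages from homology hit tables; and ships a seeded
    synthetic-data generator with full ground truth so the whole pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    rtracklayer,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
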