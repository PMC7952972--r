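Package: pgtcnv
Title: Low-Pass Single-Cell Copy-Number Analysis for Day-3 Preimplantation Genetic Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for next-generation-sequencing based preimplantation
    genetic testing (PGT) of single blastomeres from day-3 embryos in couples carrying
    structural chromosomal rearrangements. Parses ISCN karyotypes (reciprocal and
    Robertsonian translocations, inversions, deletions, duplications, insertions),
    enumerates meiotic gamete classes with segregation probabilities and theoretical
    couple euploidy rates, simulates MALBAC-like low-pass 1 Mb bin read counts with
    known ground truth, calls whole-chromosome and segmental copy-number changes with
    mosaic-fraction estimation, classifies embryo abnormalities as parental-rearrangement
    related versus de novo (Types I-V) with a transfer policy, and aggregates cohort
    rate tables with chi-square and Fisher's exact comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
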