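Package: pedfilter
Title: Pedigree-Based Segregation Filtering of Rare Variants in Family Exome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease-predisposing variants in sequenced
    families, as done in whole-exome studies of hereditary cancer. Variants
    are filtered by maximum minor allele frequency (MMAF) across population
    databases, restricted to protein-affecting consequences, tested for
    co-segregation with disease in the pedigree under strict and
    incomplete-penetrance autosomal-dominant models as well as a recessive
    model, and tiered by CADD deleteriousness scores. Includes screens of a
    64-gene hereditary breast cancer panel and of user-supplied risk SNPs, a
    Mendelian gene-dropping simulator with planted causal variants for
    validation, and built-in fixtures encoding three non-BRCA hereditary
    breast cancer families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
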