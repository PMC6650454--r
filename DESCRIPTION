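Package: redking
Title: Molecular Evolution of Conditionally Expressed Social Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-gene polymorphism and divergence statistics (nucleotide
    diversity, Tajima's D, Fu and Li's D* and F*, Wall's B and Q,
    McDonald-Kreitman test, Direction of Selection, NG86 Ka/Ks) for
    haploid strain panels with a single divergent outgroup, together with
    an expression-based classification of conditionally expressed
    "social" genes, a permutation framework comparing gene classes to
    their genomic backgrounds, and a proportion-matched null model with
    weighted regression for detecting dilution of selection at
    conditionally expressed genes (the Red King process). Includes a
    calibrated synthetic-data generator so the whole pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
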