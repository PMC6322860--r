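Package: segmapper
Title: Bulk Segregant Mapping and Phenotype Quantification for Haploid
    Choanoflagellate Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping causal mutations in haploid crosses of the
    choanoflagellate Salpingoeca rosetta by bulk segregant analysis of pooled
    F1 sequencing data. Implements the variant filter cascade (intersection
    with the mutant parent, subtraction of control strains, quality filtering,
    segregation calling at >99% pooled alternative-allele fraction, and a
    coverage robustness mask at 0.25x of genome-wide mean depth), a meiotic
    cross and pooled-sequencing simulator for validating the cascade,
    cross-genetics statistics (Mendelian and linkage chi-squared tests, the
    Poisson clonal-isolation probability for limiting dilution), an
    ImageJ-style cell-clump quantification pipeline with ground-truth
    synthetic micrographs, and fluorescence line-profile quantification
    around the cell body.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vcfR,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
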