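Package: varsieve
Title: Consecutive Filtering of Exome Variants for Disease-Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate disease variants from multi-sample VCF
    files by consecutive, intersective filtering. Any pedigree and
    inheritance model (autosomal recessive, dominant with complete or
    incomplete penetrance, de novo, case-control) is expressed as
    per-sample allowed-genotype sets with a configurable tolerance for
    missing genotype calls; further filters act on consequence type,
    minor allele frequency across 1000 Genomes and ESP populations,
    genomic regions and gene lists, driven by a local tab-delimited
    annotation table. Includes a family-exome simulator that plants a
    causal variant under a chosen inheritance model on a Hardy-Weinberg
    background, and a command-line interface for summary, filtering and
    simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    tibble,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
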