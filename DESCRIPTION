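Package: famprior
Title: Family-Based Whole-Genome Variant Prioritization in Multiplex Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variant prioritization for two-generation multiplex pedigrees
    sequenced at whole-genome scale. Implements quality filtering of variant
    calls, the coding variants-reduction funnel with a recessive
    (compound-heterozygous) gene model, a non-coding funnel based on
    evolutionary constraint and chromatin states, transmission phasing and
    sibling identity-by-descent segment inference from dense SNP genotypes,
    and copy-number-variant post-filtering with family segregation checks and
    read-level (sequence count / B-allele frequency) deletion evidence. A
    seedable synthetic-family generator with planted causal signals supports
    end-to-end testing without access to protected genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
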