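Package: delscreen
Title: PCR Deletion Screening, Breakpoint Normalization, and Knockout
    Accounting for Nematode Mutant Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for targeted gene-knockout projects that isolate
    deletion alleles from mutagenized Caenorhabditis elegans libraries by
    pooled nested PCR. Implements a deletion breakpoint caller that
    normalizes microhomology-ambiguous and insertion-bearing breaks to a
    canonical reporting form, a stochastic simulator of the grid-pooled
    screening workflow (library construction, row/column pooling, nested
    PCR detection, well addressing, sib selection, and stabilization of
    recessive lethal alleles), array-CGH copy-loss calling and
    diagnostic-PCR logic for deletion validation, and the gene-family
    coverage and worm-yeast essentiality bookkeeping used to summarize
    such projects. Includes seeded synthetic-data generators (amplicons,
    planted deletions, Sanger-like read pairs, probe tracks) so the whole
    pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
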