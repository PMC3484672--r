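# delscreen

Toolkit for PCR-based gene-knockout projects in *Caenorhabditis elegans*:
simulation and analysis of the screening pipeline that isolates deletion
alleles from mutagenized worm libraries, canonical reporting of deletion
breakpoints, validation of isolated strains, and project-level bookkeeping.

Large knockout efforts screen libraries of 10^5–10^6 mutagenized genomes for
deletions at requested target genes: library DNA arrayed in 96-well plates is
pooled by row and column, nested PCR detects a deletion as a faster-running
gel band, positive row x column intersections address the single source well,
and rounds of sib selection at decreasing seed density isolate a single
animal carrying the deletion — or, for essential genes, a persistent
heterozygote that is then balanced. Breakpoints are read from Sanger
sequence of the deletion product, strains are validated by diagnostic PCR or
array CGH, and progress is summarized as gene-family coverage tables and
essentiality overlaps. `delscreen` implements each of these pieces as
testable, seedable code for methodologists, screening facilities, and
teaching.

## The core algorithm: breakpoint normalization

A deletion product aligned to its wild-type amplicon decomposes as

```
product = amplicon[0:L] + insert + amplicon[R:end],   L < R
```

Microhomology between the flanks makes the placement of `(L, R)` ambiguous
(a `h`-base homology gives `h + 1` equivalent placements); inserted bases
make it insertion-bearing. Because a genome browser needs one discrete pair
of flanks per allele, calls are normalized: ambiguous breaks take the
rightmost possible left breakpoint; insertion breaks minimize the insert
(maximizing the matched flanks), then take the rightmost left breakpoint.
`call_breakpoint()` computes the canonical call in closed form from the
longest shared prefix/suffix; `enumerate_decompositions()` is the
brute-force oracle it is tested against, exhaustively.

## Worked example

```r
library(delscreen)

## a synthetic amplicon with a planted deletion, and its canonical call
sp  <- fixture_spec(seed = 42)
pl  <- plant_deletion(make_amplicon(sp), sp)
pl$amplicon
#> <amplicon synamp000042> 2500 bp, internal span [40,2460) = 2420 bp
call_breakpoint(pl$amplicon, pl$product, allele_id = "syn42a")
#> <deletion_allele syn42a> synamp000042:[347,1614) 1267 bp, insertion +3bp insert
#>   placements: 1; flanks 347/886 bp
```

The planted event removed 1,267 bp and left a 3 bp insert between the
flanks; coordinates are 0-based half-open in amplicon space (the TSV writer
emits 1-based inclusive positions). `placements: 1` means no equivalent
alternative placement exists — for a microhomology-ambiguous call it lists
every placement and reports the rightmost-left-breakpoint one.

```r
## simulate one screening campaign: 10 plates, 480,000 genomes
sc  <- screen_scenario(plates = 10, deletion_rate_per_target = 5e-6)
res <- run_screen(sc, seed = 10)
res
#> <screen_result> detected = TRUE, well = P03-H02, recovered = homozygous
#>   reactions used: 479
#>   sib rounds:
#>  round wells_tested positives allele_frequency
#>      1           24         5           0.0244
#>      2           24         8           0.1820
#>      3           24         1           1.0000
count_reactions(res, sc)$baseline_no_pooling
#> [1] 960
```

The screen found the deletion band in pooled DNA, addressed it to well
P03-H02, and enriched it through sib rounds (the allele frequency column
tracks the chosen sub-population: a few percent after capture, rising as
denser rounds pick carrier parents, 1.0 once a homozygous single-parent
population is reached — at which point the run stops, here after round 3 of
the four-round default plan). Grid pooling did it in 479 reactions where
unpooled screening of every well would have cost 960.

```r
## family knockout coverage from a published-style count table
fam <- coverage_report(read_family_table(
  system.file("extdata", "gene_families.tsv", package = "delscreen")))
fam[fam$family %in% c("Kinases", "Innexins"),
    c("family", "total_genes", "mutated_genes", "percent_complete")]
#>      family total_genes mutated_genes percent_complete
#> 13 Innexins          25            25              100
#> 14  Kinases         416           380               91
```

A command-line front end with subcommands (`call-breakpoints`,
`simulate-screen`, `validate-cgh`, `coverage-report`, `essential-overlap`,
`chrom-bins`, `make-fixtures`) is installed at
`system.file("cli", "delscreen.R", package = "delscreen")`.

See `vignettes/deletion-screening-methods.Rmd` for the models, parameter
choices, and limitations.

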