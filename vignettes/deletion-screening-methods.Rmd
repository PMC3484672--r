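---
title: "Deletion screening, breakpoint normalization, and knockout accounting: methods"
author: "delscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deletion screening, breakpoint normalization, and knockout accounting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delscreen)
```

## Scope

`delscreen` models the workflow by which targeted gene knockouts are isolated
from mutagenized *C. elegans* libraries: nested-PCR screening of pooled
library DNA, addressing of positive row x column pool intersections to single
wells, sib selection down to single-parent populations, stabilization of
recessive lethal alleles as persistent heterozygotes, Sanger-based
determination and canonical reporting of deletion breakpoints, validation by
diagnostic PCR and array CGH, and the bookkeeping used to summarize such
projects (gene-family coverage tables, worm-yeast essentiality overlap,
chromosome distributions). Everything operates on synthetic or user-supplied
data; no external accessions are required.

## Coordinates

All internal coordinates are 0-based half-open, so interval arithmetic needs
no `+1` corrections. Report writers (`write_breakpoint_tsv()`) emit 1-based
inclusive positions — the display convention of genome browsers — and every
writer states its convention in a header line. BED output is 0-based
half-open, as BED requires.

## Breakpoint calling and the reporting standard

A deletion product aligned to its wild-type amplicon decomposes as

```
product = amplicon[0:L] + insert + amplicon[R:end],   L < R
```

Three situations arise. If exactly one zero-insert `(L, R)` reproduces the
product, the break is *clean*. If the two flanks share microhomology — the
same bases could be assigned to either side of the break — several
zero-insert placements are equivalent (*ambiguous* breaks); a `h`-base
microhomology yields `h + 1` placements. If no zero-insert placement exists,
novel bases sit between the flanks (*insertion* breaks). Downstream genome
browsers require one discrete pair of flanking sequences per allele, so the
package normalizes every call:

* **ambiguous**: report the *rightmost possible left breakpoint*, i.e. the
  placement that maximizes `L`, pushing the microhomology onto the left
  flank; `ambiguity_width` records the number of equivalent placements and
  `all_placements` lists them.
* **insertion**: minimize the insert length (equivalently, maximize the
  matched flank total), then take the rightmost `L`. The rightmost-`L`
  tie-break is chosen for consistency with the ambiguous rule; since the
  insert length determines the matched total on a fixed product, the two
  leading criteria never actually conflict.

`enumerate_decompositions()` is a brute-force enumeration of *every* valid
`(L, R, insert)`, sorted so the canonical decomposition is row 1. It exists
as an independent oracle: `call_breakpoint()` computes the same answer in
closed form from the longest shared prefix and suffix of product and
amplicon, and the test suite checks the two against each other exhaustively
over tens of thousands of planted events. `normalize_report()` re-derives the
canonical form from any placement and is idempotent.

**Anchoring.** A product is only accepted as a deletion product if its
maximal shared prefix and suffix with the amplicon each reach `k_min` bases
(default 10). On random sequence at amplicon scale, a 10-base exact anchor
arises by chance with probability about `4^-10` per position, which makes
spurious anchors negligible; the threshold is a parameter so that the small
worked examples in the documentation (10–16 bp amplicons) remain runnable
with `k_min = 1`.

**Reads.** `call_from_reads()` merges the two inward Sanger reads taken from
the internal primers (the right read arrives reverse-complemented; the
orientation is auto-detected). The merge scans overlap lengths from largest
to smallest and accepts the first whose mismatch fraction is within
`max_mismatch_rate` (default 0: exact). Where the reads disagree inside the
overlap, each conflicting base is taken from the read whose exact match run
around the conflict — counting its anchored, non-overlapping portion — is
longer: a left read is most reliable near its 5' anchor, a right read near
its 3' anchor. The number of conflicts resolved this way is attached to the
report (`attr(, "merge_conflicts")`), since breakpoints inferred through
disagreeing reads deserve scrutiny. Heterozygous templates are not
deconvolved: unoptimized nested PCR predominantly amplifies the shorter
deletion product, so the assembled sequence is treated as the deletion
allele.

## The silent-allele rule and size checks

A deletion that does not extend across at least one exon boundary (an
intron-only or fully flanking event) is a *silent* allele and is not counted
as a gene knockout. `classify_silent()` implements the crossing predicate
literally: the allele is exonic iff the open deleted interval strictly
contains an exon start or end; abutting a boundary does not count. The rule
uses only boundary coordinates, so it is strand-symmetric. Whether intron
deletions that remove a branch point should ever count as damaging is left
as stated — the boundary rule is applied as written.

Recoverable deletions are bounded by the internal primer span and, by primer
placement, by 3 kb; `check_size_bound()` reports violations as a warning
rather than an error because the bound is empirical, not algorithmic.
`check_band_shift()` compares the implied product length
(`internal span − deletion + insert`) against the gel band within a relative
tolerance (default 15%, about the accuracy of slab-gel sizing).

## The screen simulator

`screen_scenario()` fixes the study conditions. Defaults describe one
screening campaign for a single target: 10 plates of 96 wells, 500
mutagenized genomes per well (480,000 genomes — inside the 125,000 to
1.4 million range typical of such libraries), a per-genome deletion rate of
`5e-6` at the screened target (of order one hit per couple of hundred
thousand genomes), duplicate pool screening, and a sib plan of four rounds
of 24 sub-populations seeded with 50, 10, 1, 1 worms — stepping from tens of
animals down to single-animal picks as real screens do. A 1-in-500 carrier
well needs the gradual schedule: sparser early rounds usually fail to
capture a carrier at all, which is exactly the documented way hits are lost
in sib selection. The published protocol specifies the *number* of
sub-populations per round (sets of 24 single-worm picks) and describes the
seed densities only as "progressively lower", so the two are separate
parameters: `sib_plan` counts
sub-populations tested per round (driving reaction counts), and
`sib_seed_worms` carries the density schedule, validated non-increasing and
ending at 1.

**PCR model.** One reaction samples an aliquot of pool DNA with an expected
`templates_per_reaction` (default 10,000) genome templates. Given that the
pool contains at least one carrier, the mutant template count `m` in the
aliquot is drawn zero-truncated Poisson with mean
`pool mutant fraction x templates_per_reaction`, and the reaction fires with
probability `1 − (1 − s)^m`, `s` being the per-template sensitivity. The
zero truncation encodes the protocol's guarantee that library sampling does
not compromise recovery: a carrier-containing pool always contributes at
least one template to the reaction, so a perfectly sensitive assay (`s = 1`)
never misses a carrier, while for `s < 1` rarer templates in bigger pools
remain genuinely harder to detect. Carrier-free pools never fire — nested
PCR is modeled as fully specific. Duplicate screening runs two independent
reactions and calls a pool positive when either fires (OR), matching the
protocol's bias against losing hits; the AND/OR choice and the aliquot size
are explicit parameters because the protocol does not quantify them.
Heterozygotes and homozygotes are equally detectable (only the deletion band
is scored), so positivity depends on carrier presence, not zygosity.

**Sib selection.** Each round regrows the parent population by one selfing
generation (offspring 1 wild-type : 2 heterozygous : 1 homozygous per
selfing heterozygote, multinomially sampled; growth is capped at 10^6
animals, preserving fractions), seeds the round's sub-populations by
sequential draws without replacement (multivariate hypergeometric), expands
and PCR-tests each, and recurses into a positive one — preferring the
highest homozygote fraction, then the highest carrier frequency, the
in-silico analogue of picking the strongest gel. For recessive lethal
targets homozygotes arrest before reproducing: they neither parent the next
generation nor appear among surviving adults, so surviving offspring of a
selfed heterozygote segregate 2 het : 1 wild-type and a lethal target can
never terminate `homozygous` — the run ends `persistent_heterozygous`, the
entry point for balancer stabilization, which is out of scope beyond this
classification. A round with no positive sub-population ends the run `lost`.

**Reaction accounting.** Pooling is the economic point: a plate of 96 wells
costs `8 + 12 = 20` pool reactions (x2 in duplicate) instead of 96.
`count_reactions()` reconciles the run trace (pool + addressing + sib
reactions) against the no-pooling baseline of one reaction per well.

## CGH validation

`simulate_track()` tiles probes at fixed spacing; neutral probes have mean
log2 ratio 0, heterozygous (one-copy) losses −1, homozygous (two-copy)
losses −4. The −4 is a finite proxy for the hybridization signal floor; only
the ordering hom ≪ het < 0 matters to the caller. `call_losses()` is a
deliberate run/threshold method, not a segmentation algorithm: losses at
these magnitudes are separable by thresholding, so maximal runs of at least
`min_probes = 3` consecutive probes below `het_cut = −0.5` become calls,
graded two-copy when the run mean falls below `hom_cut = −2`. The defaults
sit midway between the expected levels and are standard aCGH heuristics;
they are not calibrated to any particular commercial array design.
`validate_deletion()` confirms a PCR-isolated deletion when some call covers
at least half of the target interval and reports all non-overlapping calls
as extra deletions — the common finding of additional losses elsewhere in a
validated strain, which does not affect confirmation of the target.
`diagnostic_pcr()` implements the older presence/absence test: a primer pair
with one primer wholly inside and one wholly outside the deletion yields
product only from an intact template, so product from a deletion strain
flags a retained wild-type copy (the rare failure mode of PCR isolation).

At the test suite's conditions — probe spacing 500 bp, seven probes per
planted deletion, per-probe noise sd 0.15 (a good modern array; log2 noise
of 0.15–0.25 is array-typical) — recovery is essentially complete with no
false calls. The binding failure mode at higher noise is a single mid-run
probe crossing the threshold, which splits the run and leaves neither
fragment covering half the target; sensitivity therefore degrades
monotonically with noise, which the suite checks by sweep.

## Accounting

Coverage percentages are integer round-half-up (`380/416 → 91`, `11/12 →
92`), matching published coverage tables; plain `round()` in R rounds half
to even and would disagree on half values. One published transcription-
factor row (866/941 shown as 90%) is inconsistent with its own inputs under
any standard rounding; the package reports the computed value (92) and the
tests do not assert that cell. Essentiality sets are compared in
ortholog-pair identifier space so the worm-side and yeast-side sets
intersect directly; ortholog inference itself is an input, not a
computation. `chromosome_bins()` produces the all-genes and lethal-subset
histograms used to ask whether essential genes cluster along chromosomes.

## Synthetic data

`fixture_spec()` fixes the generator: amplicons of 2.5 kb with nested primer
anchors 20/40 bp from each end; deletions of 200–1500 bp (always below the
3 kb primer-placement cap); 27% of events carry an insertion (1097 of 4101
characterized deletions carry inserted or duplicated sequence), insert sizes
mostly 1–10 bp (geometric, mean 3) with an 8% heavy tail uniform on
100–2000 bp (87 of those 1097 exceed 100 bp), capped so the product stays
shorter than the amplicon — a deletion is detected as a faster-running band;
zero-insert breaks draw a flank microhomology of 0–10 bp, mostly short, as
expected from end-joining repair. The generator *engineers* the drawn
microhomology into the sequence and forces the guard bases beyond it to
differ, so the planted event's canonical form — placement count and
rightmost-`L` — is known by construction rather than derived from the
caller; the amplicon returned by `plant_deletion()` (possibly base-edited
around the break) replaces the input for downstream calling. Read pairs are
product prefix and reverse-complemented suffix with independent substitution
errors; indel (true Sanger-like) noise is not modeled.

What passing tests do and do not show: the generator produces uniform-
composition sequence with exactly-controlled break context. Real amplicons
contain repeats and homopolymers that can extend microhomology beyond the
planted guard bases, real Sanger traces degrade near the ends and carry
indels, and real libraries have correlated well occupancies. Perfect planted
recovery therefore demonstrates the correctness of the normalization
arithmetic, not a sequencing-error-robust assembler.

## Problem sizes and determinism

Every stochastic component draws from R's single seeded generator; runs are
bit-reproducible given (configuration, seed), and the suite checks seed
sensitivity by collision. The shipped suites use: exhaustive oracle
comparison over all `(L, R, insert ≤ 3)` events on random amplicons of 20,
30 and 40 bp (tens of thousands of cases); 1,000 seeded planted-recovery
cases on 600 bp amplicons; Mendelian checks at 10,000 offspring; 10,000
mutant-free PCR reactions; 200 seeded CGH tracks. The same computations, at
the same sizes, are what `scripts/acceptance.R` re-runs from scratch.

## Known limitations

* Breakpoint calling is amplicon-scale; there is no whole-genome alignment,
  no inversion or multi-segment event detection, and no chromatogram base
  calling.
* The simulator does not model mutagen dose–response, deletion size
  spectra per mutagen, frozen-library viability loss, or multi-target
  screening economics beyond reaction counting.
* The CGH module calls losses only (no gains), ignores dye-swap/replicate
  structure, and its thresholds are heuristics, not array calibrations.
* Balancer construction for lethal strains is represented only by the
  `persistent_heterozygous` terminal state.
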