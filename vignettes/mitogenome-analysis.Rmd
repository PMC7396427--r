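---
title: "Methods: comparative analysis of circular mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of circular mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocirc)
```

# Scope and model

Metazoan mitochondrial genomes are small circular molecules (~16 kb)
carrying a near-universal gene content: 13 protein-coding genes (PCGs), two
rRNAs and 22 tRNAs, plus at least one noncoding control region (CR) where
replication and transcription initiate. Comparative mitogenomics asks three
kinds of question about such a molecule, and `mitocirc` implements the
corresponding machinery:

1. **Annotation geometry** — gene lengths, intergenic spacers, overlaps,
   noncoding tracts and the putative CR, computed from a feature table with
   1-based inclusive coordinates on a circle.
2. **Composition statistics** — per-region base composition, the strand
   asymmetry statistics AT-skew = (A − T)/(A + T) and
   GC-skew = (G − C)/(G + C), codon counts, relative synonymous codon usage
   (RSCU) and amino-acid usage under explicit genetic codes.
3. **Gene-order comparison** — signed circular permutations compared by
   conserved-block decomposition and breakpoint distance, with a simulator
   for the four classical rearrangement mechanisms (inversion,
   transposition, reverse transposition, tandem duplication–random loss).

The package ships the published annotation and codon-count tables of the
sea cucumber *Phyllophorus liuwutiensis* mitogenome (GenBank MN198190,
15,969 bp) as worked fixtures; every headline number those tables imply is
recomputed, never stored.

# Annotation geometry

Coordinates are kept on the external convention of published annotation
tables: 1-based, inclusive, with `end < start` denoting an origin-spanning
feature on a circular genome (its length is `L - start + 1 + end`).
Internally nothing is re-based, so every reported number is directly
comparable with a published table.

**Adjacency and spacers.** Features are ordered by start coordinate; strand
and transcriptional polarity play no role in adjacency. For consecutive
features the intergenic gap is `next_start - prev_end - 1`, and the
wrap-around pair of a circular genome contributes
`first_start + L - last_end - 1`. This convention reproduces every printed
intergenic value of the fixture annotation, including its negative entries.
Negative gaps are overlaps; only adjacent-pair overlaps are counted (a
feature contained in a *non-adjacent* feature is unusual enough to warrant a
warning rather than a row). An algebraic consequence used as a test
invariant: feature lengths plus signed gaps tile the circle exactly.

**Noncoding regions and the control region.** Published genome descriptions
use two conventions, sometimes in the same paper: the CR counted as a
noncoding region (its length then dominates the noncoding length range) or
as an annotated feature (only inter-gene gaps count). `noncoding_regions()`
exposes this as `include_cr_feature`; the default (`FALSE`) treats CR
features as noncoding sequence and merges them with flanking gaps.
`identify_control_region()` returns the longest noncoding region under that
convention (ties broken by lower start). The CR of a mitogenome is expected
to be AT-rich; when a sequence is supplied, the region's A+T fraction is
reported and checked against `at_threshold`. The default threshold is 0.60
— permissive on purpose, since echinoderm mitogenomes are globally AT-rich
(the fixture genome is 65% AT and its CR 69%), and the check is meant to
flag gross misidentification, not to rank candidates.

# Composition and codon statistics

`skew(x, y) = (x - y)/(x + y)` is scale-invariant, so printed percentages
are as valid an input as raw counts. Note a practical precision limit:
percentages printed to two decimals carry up to ±0.005 of rounding per
base, which propagates to roughly ±0.001 in a skew. Recomputations from
printed percentages can therefore differ from a published skew (computed
from raw counts) by one unit in the third decimal, and the package's tests
use exactly that tolerance for whole-genome skews.

**Two codes, two roles.** A genetic code plays two separable roles here:
its codon-to-amino-acid map labels codons and aggregates amino-acid usage,
while its synonymous-family partition sets RSCU denominators
(`RSCU(c) = count(c) × s / n_F` for a family of size `s` and total `n_F`;
zero-total families report 0). Published mitochondrial codon tables are
routinely mixed: amino-acid labels follow the organelle's code while the
RSCU column was computed by software using standard-code families. The
fixture table is of this kind — its labels are invertebrate-mitochondrial
(AGA/AGG = Ser, AUA = Met, AAA = Lys, UGA = Trp), yet its RSCU values are
reproduced exactly (to the printed 2 decimals) only when AGR is grouped
with CGN into a six-codon arginine family, AUA sits in a three-codon
isoleucine family, and UGA joins UAA/UAG in a three-codon stop family, i.e.
standard-code families. `rscu()` and `aa_usage()` therefore take the code
as an explicit argument, and `report_codon()` takes separate `label_code`
and `family_code` parameters (defaults: invertebrate-mitochondrial labels,
standard families — matching the fixture's provenance). Stop codons are
counted, form their own RSCU family, and are included in the amino-acid
usage denominator as their own row; the fixture's published percentages are
reproduced only under that convention (total 5,323 codons).

**Strand convention.** Composition rows for minus-strand features are
computed on the coding strand (reverse complement), as are extracted CDS.
The per-gene rows of the published composition table cannot be
re-derived without the deposited sequence, so this convention is validated
on synthetic genomes, where the planted truth is known.

**Display rounding.** Percentages are displayed to 2 decimals, skews to 3,
RSCU to 2, ties away from zero (`round_half_up()`); all computation keeps
full precision and tests compare at 0.005 (RSCU, percents) or 0.0005
(skews) except where input rounding dominates, as noted above.

# Gene-order comparison

A genome's gene order is modeled as a signed circular permutation over the
canonical 37-gene alphabet (tRNAs by one-letter code, with S1 (AGN),
S2 (UCN), L1 (CUN), L2 (UUR) distinguished); `normalize_gene_labels()` maps
published naming conventions onto it, and control regions are excluded from
orders. Because a circular DNA molecule has no canonical origin or strand,
all comparisons are invariant under rotation of either order and under
reading either molecule from the other strand (full reversal with sign
flip); this is property-tested.

A signed adjacency (x, y) of order *a* is **conserved** when (x, y), or its
reversal (−y, −x), is adjacent in order *b*. Conserved blocks are maximal
circular runs of *a* whose internal adjacencies are all conserved — for
unique labels this is equivalent to the intuitive definition (maximal runs
contiguous and co-oriented, or fully reversed, in both genomes), and the
implementation is verified against an exhaustive search over all contiguous
runs for hundreds of random signed circles. The breakpoint distance is the
number of non-conserved adjacencies; on circles, every block boundary is a
breakpoint, so block count equals breakpoint count whenever the orders are
not equivalent. Blocks are reported in their order of appearance in the
first genome, starting from the block containing *cox1* when present, with
minus-orientation genes bracketed in linear renderings.

Between two arbitrary orders the package reports the rearrangement
*descriptively* (blocks, singletons, orientation flips, breakpoints) rather
than reconstructing a minimal event scenario: minimal sorting by
inversions/transpositions is a different problem with different guarantees
and is out of scope. The event simulator runs in the forward direction
instead, where ground truth is free: `apply_event()` implements inversion,
transposition, reverse transposition and TDRL (duplicate a run in tandem,
then lose one copy of each duplicated gene at random — label content is
always preserved).

# The synthetic-data generator

`synth_genome()` exists so that every pipeline stage can be tested against
planted truth without downloads. Its defaults are fixed once and emulate
the fixture genome: the packaged 15,969 bp annotation as geometry template;
whole-genome base fractions A 0.356 / T 0.296 / C 0.222 / G 0.126 (the
fixture's composition, rounded so the fractions sum exactly to 1); CR
positions drawn from an AT-boosted composition (+0.05 AT mass, mirroring
the fixture CR's ~4-point AT excess over the genome); PCGs filled with
in-frame CDS — start codon, interior codons drawn from the packaged
codon-count distribution with stops excluded, terminal stop — reverse
complemented onto minus strands and wrapped across the origin where the
template requires; everything else i.i.d. background. A single integer
seed drives one RNG stream in documented order, so output is byte-stable.

Two deliberate simplifications. First, where two coding genes overlap (the
template has one such pair), the gene written later owns the shared bases;
the returned ground-truth CDS are read back from the finished sequence by
direct character indexing — a code path independent of `extract_cds()`, so
recovery tests remain meaningful. Second, the generator makes no attempt at
evolutionary realism: no substitution models, no rate heterogeneity, no
codon-position structure beyond the planted bias. Passing tests on
synthetic genomes therefore demonstrate the correctness of the geometry,
extraction and counting machinery — not that the statistics are powerful on
real data.

`synth_order_pair()` applies `n_events` seeded events (default 2, uniform
mix over the four kinds — modest rearrangement of the kind seen between
related echinoderm families) to the template's order and logs each event,
giving a pre-registered expectation for block structure.

# Numerical and degenerate-input choices

* Skew of a region with zero denominator (e.g. a GC-free tRNA) is `NA` in
  reports and an error when called directly with two zeros.
* CDS whose length is not divisible by 3 lose their trailing 1–2 bases in
  codon counting, with a warning; ambiguous-base codons are skipped, with a
  warning. Empty sequences and zero-count tables are errors, not zeros.
* Duplicate feature names (e.g. two control regions) are suffixed `_2`,
  `_3`, ... in start order, because gene orders need unique labels.
* Annotated start/stop codons are stored verbatim and never validated
  against the sequence: published tables sometimes print positive-strand
  triplets for minus-strand genes (the fixture's *nad6* is such a case),
  and silently "correcting" them would misrepresent the source.
* Problem sizes used by the test suite: the exhaustive block-decomposition
  oracle runs on 500 random signed circles of 3–8 genes; bias-recovery uses
  ~3,000 planted codons; synthetic genomes are full 16 kb. The suite
  completes in well under a minute.

# Known limitations

* GenBank support is a minimal dialect (single-interval and origin-spanning
  joins, complement, `/gene`/`/product` qualifiers) sufficient for
  round-tripping the package's own output and typical mitogenome records;
  it is not a general flat-file parser.
* Duplicated control regions are handled structurally (deduplicated names,
  exclusion from orders) but not detected by sequence similarity.
* Cross-species block counts quoted in the literature are only reproducible
  when both genomes' complete signed orders are available; figures alone
  under-determine them. The comparison engine is therefore validated on the
  focal order and on synthetic pairs with known event logs.
* Minimal rearrangement distances (Hannenhalli–Pevzner and relatives) and
  gene-order phylogenetics are out of scope.
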