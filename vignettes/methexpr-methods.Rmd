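---
title: "Methods: integrative methylome-transcriptome analysis of clonal variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative methylome-transcriptome analysis of clonal variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexpr)
```

## The analytical problem

methexpr implements an integrative desk analysis for a classic two-sample
epigenomics design: two clonal variants of the same organism (labelled
*orange* and *green*), profiled with

* an **MBD pull-down methylome**: genomic DNA is cut with MseI (recognition
  site TTAA, cut T^TAA, leaving CpG dinucleotides intact), heavily
  methylated fragments are captured by a methyl-CpG-binding domain, and the
  captured fragments are pyrosequenced. Identical reads collapse to one
  distinct sequence plus a copy count.
* an **SSH transcriptome**: suppression subtractive hybridization libraries
  per variant, assembled into contigs with read counts. The non-subtracted
  linear background of the protocol survives in both libraries at low,
  similar counts and serves as an internal control for library size.

The pipeline quantifies *methylation enrichment hits* — genomic placements
of methyl reads weighted by their copy counts — never methylation levels
(beta values); that is a deliberate scope decision matching the enrichment
character of the assay.

## Read placement model

`place_reads()` reports **every** location on either strand where a read
matches with Hamming distance at most `floor(f * length)`, with `f = 0.04`
by default (the conventional read-mapper mismatch cutoff). Two choices
matter:

* **No best-hit selection.** Multi-mapping reads keep all their locations.
  The multiplicity spectrum (`multiplicity_spectrum()`), the per-scaffold
  hit counts and the decorated tracks all rely on the full placement set;
  selecting one "best" location would silently distort repeat-associated
  methylation.
* **Indel-free matching.** The model is substitution-only Hamming distance.
  This keeps an exhaustive-scan oracle tractable (the test suite compares
  the seed-indexed engine against a brute-force all-positions scan and
  requires exact equality) and matches the percent-mismatch semantics of
  the cutoff. Reads with more than 10% ambiguous bases are skipped; an `N`
  never matches any base.

The engine is a pigeonhole seed index (10-mers): with at most `mm`
mismatches, one of `mm + 1` disjoint seeds must match exactly. Queries too
short to carry that many seeds fall back to an exhaustive scan, so
sensitivity is exact for every query, not just the typical ones.

Distinct-read statistics (the multiplicity spectrum and cross-variant
occurrence classes) use unweighted distinct sequences; per-scaffold and
per-region *hits* are weighted by the read's copy count. Overlapping reads
of different lengths are distinct sequences and are never merged.

## Region stratification

`build_region_index()` builds eight interval classes: gene bodies, exons,
introns (body minus exons), promoter windows at 0-2 kb and 2-3 kb upstream
of the transcription start (strand-aware), transposon bodies, 1 kb
transposon borders, and a distal 49-51 kb upstream window used as a
background control. Transposon intervals usually carry no strand, in which
case "upstream" means left of the leftmost coordinate. All intervals are
clipped at scaffold edges.

Counting (`count_by_region()`) uses a 1 bp overlap rule and treats classes
independently: a read straddling an exon-intron junction increments the
exon, the intron, and the gene body. The region categories are reported
side by side, not as a partition. Counts are not normalized by CpG density;
the hit counts are reported as-is, which is a documented caveat of the
quantification (an optional sensitivity analysis can divide by CpG counts,
but no default output does).

Per-gene methylation classes (`classify_gene_methylation()`) compare the
two variants' hits in the gene body and the 0-2 kb promoter at a fold
threshold of 2, boundary included (green = 2 x orange counts as a two-fold
increase). Genes whose larger count is below `min_hits = 5` are
`insufficient`; a zero denominator takes the direction of the non-zero side
when it reaches `min_hits`, mirroring the transcriptome's "at least 5 in
one sample and none in the other" convention.

## SSH calibration and expression classes

Contigs are matched to the genome near-exactly (at most 5% substitutions)
and scored `length - 3 * mismatches`; the unique best locus at score >= 60
is kept, so a 100 bp exact match passes comfortably while anything below
~75% identity can never reach a positive score. Ties — for example a
contig matching two identical gene copies — leave the contig unassigned
and flagged ambiguous, which enforces the "unambiguous mapping" rule and
prevents multi-gene counting. The matcher is indel-free by design; for
assembled cDNA contigs against the genome this forgoes splice-aware
alignment, a known limitation discussed below.

Internal controls are reciprocal best matches between the two libraries
(local alignment similarity >= 0.9, normalized by the shorter length) with
both counts at or below `max_count`. The scale factor is the **ratio of
summed control counts** (orange over green), a ratio estimator that is
robust to zero-inflated small counts; a median-of-ratios estimator is
available via `calibrate(..., method = "median")`. Green counts are
multiplied by the scale factor and kept real-valued until reporting.

Gene-level expression classes use calibrated counts: `strong` is >= 20
reads in one variant and none in the other; `slight` is >= 5 and none;
`moderate` requires both sides positive, the larger >= 5, and a two-fold
ratio. The minimum count for the moderate class is not independently
standardized anywhere, so the slight floor (5) is reused and exposed as a
parameter. Requiring both sides positive keeps `moderate` disjoint from
the one-sided classes.

## GO enrichment

Annotations are closed over `is_a` ancestry (the true-path rule) before
testing. For each term carried by at least one query gene the upper-tail
hypergeometric probability is computed: with `N` annotated background
genes, `m` of them carrying the term, and a query list of size `n` with
`k` carriers, `p = P(X >= k)`, evaluated as a log-space sum of binomial
coefficients (stable up to `N` around 1e6; the test suite checks exactness
against exhaustive subset enumeration for all `N <= 12` and against the
reference distribution function at scale).

Design choices: the test is one-sided (enrichment only); raw p-values at
`alpha = 0.05` drive the `enriched` flag because that is the convention of
the toolkit family this mirrors, with Benjamini-Hochberg q-values computed
and reported alongside but never silently applied; the background is the
set of genes with at least one propagated annotation, and query genes
outside it are excluded with a logged message; terms with `k = 0` are not
reported, as they are untestable for enrichment.

Cross lists pair each expression direction with an optional two-fold
methylation filter (increase or decrease, in the gene body or the
promoter), at a cumulative stringency: `strong`, or `slight` (strong +
slight), or `moderate` (all three).

## Scaffold-level integration

Scaffolds are ranked by methylation density — the arithmetic mean of the
two variants' hit totals divided by scaffold length — descending, ties
broken by id. `concordance()` then asks, over the `top_k` densest
scaffolds, how often the methylation direction (which variant has more
hits) opposes the net expression direction (sign of summed calibrated
green-minus-orange gene counts on the scaffold). Scaffold-level expression
direction is not standardized anywhere; the signed-sum operationalization
is this package's documented interpretation. Expression-silent scaffolds
are excluded from the denominator and reported separately, and a
denominator variant that keeps them (`fraction_of_top_k`) is also
returned, since both conventions are defensible.

## The synthetic study

`generate_genome()` + `simulate_methylome_reads()` +
`simulate_ssh_libraries()` produce a complete study with machine-readable
planted truth. The default configuration is the package's reference
simulated study:

| parameter | default | rationale |
|---|---|---|
| scaffolds | 50 x 100 kb | enough scaffolds for rank statistics at desk scale |
| GC fraction | 0.35 | AT-rich insect-like composition; TTAA sites every ~90 bp |
| genes / transposons per scaffold | 8 / 4 | non-overlapping slot layout with promoter margins |
| repeat copy numbers | 1, 2, 5, 50 | spans the multiplicity spectrum incl. one high-copy repeat |
| hot spots | 8 per 100 kb, ~2 kb wide, capture bias 10 | hot spots dominate capture without silencing background |
| shared hot-spot fraction | 0.5 | both shared structure (high r) and variant-specific signal |
| reads per variant | 2e5 | deep enough for per-gene fold calls at min_hits = 5 |
| DE gene fraction / fold | 0.3 / 4 | strong planted DE (>= 20 vs 0 reads) on ~2.4 genes per scaffold |
| control contig pairs | 60 | stable ratio-estimator calibration |
| inverse coupling | 0.9 | planted methylation-up implies expression-down with 10% exceptions |

Hot spots are intervals with a single capture-weight multiplier (not
per-CpG probabilities) — the granularity at which the pipeline measures.
Methylome reads are the MseI fragments themselves: fragments under 30 bp
are dropped (pyrosequencing realism), each remaining fragment has weight 1,
multiplied by the capture bias when it overlaps a hot spot active in the
sampled variant, and read copies are one multinomial draw, so copy totals
are conserved exactly. Non-shared hot spots are assigned to a variant
independently per hot spot; the scaffold's methylation direction is the
emergent weight majority, and planted DE genes oppose it with probability
0.9. Per-hot-spot independence is what makes the two variants' scaffold
profiles uncorrelated when no hot spots are shared — assigning whole
scaffolds to a variant would create a negative cross-variant correlation
instead of none.

Control contigs draw a shared latent count level per pair (uniform on
2-8) with unit jitter per side: the SSH background is *similar* counts in
both libraries, and fully independent draws would make spurious two-fold
calls common among control-covered genes. Control contigs are drawn from
non-DE genes only, so the planted "20 vs 0" condition of strong DE genes
is never contaminated. The planted library-size multiplier scales the
green library with stochastic rounding (floor 1 read).

What the generator does **not** emulate: sequencing errors and quality
scores, adapter/barcode artifacts, assembly of contigs from reads, CpG
density heterogeneity, and polymorphism between variants (the variants are
clonal; only methylation and expression differ). Passing tests therefore
demonstrate the correctness of the quantification and inference machinery
under the planted model, not robustness to real-data artifacts such as
sequencing error or mis-assembly.

## Numerical and procedural choices

* One top-level seed; each stage derives a deterministic child seed, so
  partial reruns reproduce.
* Identical inputs and seed give byte-identical outputs; export ordering
  is fixed (scaffold, start, id) to make diffs meaningful.
* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  and BED conversions happen only in the readers/writers.
* Ties: scaffold ranking breaks density ties by id; reciprocal-best
  pairing breaks similarity ties by id order; ambiguous equal-best contig
  loci are never assigned.
* Degenerate inputs: scaffolds without a TTAA site become one whole
  fragment with a warning; genes without exon records are treated as
  single-exon with a warning; a constant hit vector makes the correlation
  undefined and returns `NA` with a message rather than a value.
* Test problem sizes: the oracle-equivalence and enumeration checks run
  on small fixtures (scaffolds up to a few kb, `N <= 12` for exhaustive
  subset enumeration), while the end-to-end checks run the full default
  study (50 x 100 kb, 2e5 reads per variant), which completes in well
  under a minute per pipeline pass on one CPU.

## Known limitations

* Hamming-only matching: reads or contigs spanning indels or splice
  junctions relative to the genome are not placed.
* Enrichment hits are a relative, capture-biased signal; no absolute
  methylation level is estimated, and no CpG-density normalization is
  applied by default.
* The design has no biological replicates, so expression classes are
  threshold rules, not statistical tests; the hypergeometric test applies
  to GO term membership only.
* Raw p-values drive the default enrichment flag; use the reported
  q-values when the number of terms is large.
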