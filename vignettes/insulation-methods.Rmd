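---
title: "Measuring contact-domain boundaries and their perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring contact-domain boundaries and their perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulatr)
```

## The problem

Chromosomes fold into contact domains: intervals with elevated internal
contact frequency, separated by boundaries at which cross-boundary contacts
are depleted. In *Drosophila*, boundaries coincide with promoters of active
genes or with binding sites of architectural proteins (CTCF, Su(Hw),
BEAF-32, and the common cofactor Cp190), and removing such a protein erases
or weakens a specific subset of boundaries. `insulatr` implements the
quantitative machinery needed to make these statements from data: it turns
Hi-C read pairs into balanced contact matrices, scores per-bin insulation,
calls boundaries at multiple scales, matches boundaries across genotypes,
and classifies each one as lost, weaker, or intact in a mutant. Satellite
modules handle A/B compartment calling, ChIP-peak/boundary colocalization,
Capture-C viewpoint profiles, and insulator-reporter quantification.

Because the sequencing data such analyses are normally run on are large and
external, the package ships a synthetic-data generator that plants known
domains, compartments, peaks, and reporter strengths. Every pipeline stage
is validated against this planted truth or against brute-force oracles.

## The insulation score

All boundary statistics derive from one quantity. For a balanced contact
matrix at bin size 2 kb and a window of `w` bins, the *binSignal* of bin
`i` is the mean normalized contact frequency between the `w` bins upstream
and the `w` bins downstream of `i` — a `w × w` diamond straddling the bin.
The *physical insulation score* is

> score(i) = log2( binSignal(i) / local mean of binSignal over the w bins
> around i )

Lower scores mean stronger insulation; a perfectly uniform matrix scores 0
everywhere, which is the null the implementation is tested against. The
local normalization makes the score comparable along the arm and across
samples regardless of coverage. The denominator is the local *mean*: a raw
sum over the window would shift the null to a w-dependent constant and
break the interpretation of 0 as "no insulation", so the mean is the only
reading consistent with using the score as a relative measure. The local
window spans `i − w/2 < j < i + w/2` (the bin's own value included; bins
with undefined binSignal are dropped from the mean).

Scores are computed at windows of 20, 40, 80 and 160 kb. Candidate
boundaries are strict local minima of each per-window profile with score
≤ −0.1 (plateaus resolve to their leftmost bin); candidates from all
windows are pooled, candidates within 2 kb of each other are collapsed to
the bin with the lowest mean score, each retained boundary gets the mean
score across windows, and boundaries with mean score > −0.1 are dropped.
Since boundaries are 2-kb bins, "within 2 kb of each other" is measured as
the gap between bin intervals: bins at most two indices apart collapse.

## Cross-genotype comparison

Boundary positions fluctuate by a bin or two between window sizes and
genotypes. Before comparing genotypes, boundaries from all genotypes are
pooled and transitively chained when within 2 kb of each other (interval
gap); each chained group is replaced by the single position with the lowest
*global* insulation score — the sum of mean-window scores over the
genotypes that called a boundary in the group — with each such genotype
marked present there and its score re-read at the consensus position. Ties
resolve to the leftmost position.

A boundary present in the wild type is then classified against a mutant:

* **lost** — absent in the mutant;
* **weaker** — present, score increase (mutant − WT) ≥ 0.01;
* **intact** — present, score change < 0.01 (reinforced boundaries with
  negative change included).

## Matrix preparation

Sequencing reads are first split at the four 6-mer re-ligation junction
motifs (`GTATAC`, `TTATAA`, `GTATAA`, `TTATAC`; split at the motif
midpoint, sub-reads trimmed to 60 nt). Pairs are rejected, in order, when
(i) a mate is non-unique, (ii) a read has an indel or more than two
mismatches, (iii) mates are opposite-strand and closer than 2 kb (likely an
undigested fragment), or (iv) the pair duplicates an earlier pair's
(chrom, position, strand) tuple on both mates — the duplicate test uses
base-pair coordinates with mate order canonicalized. Kept cis pairs are
binned at 2 kb; bins with no contacts plus the 5% of non-empty bins with
the smallest contact totals (count rounded up, ties to the lower bin index)
are masked; and the matrix is balanced by iterative correction until the
coefficient of variation of the valid-bin marginals falls below 1e-6
(capped at 200 iterations), then rescaled so the mean valid marginal is
exactly 1. The balancing update divides each entry by both its row and
column relative marginal, so the raw update overshoots; the implementation
uses the square-root-damped form, which has the same fixed point and
converges in a few dozen iterations. Replicate agreement is summarized as
the Pearson correlation of the flattened balanced matrices at 10-kb bins,
using only bin pairs at genomic distance below 1 Mb — the scale at which
domains live.

## Compartments

The observed-over-expected matrix divides each entry by the mean balanced
contact at its genomic distance and clips extreme ratios at the global
99.9th percentile (the plain reading of the clipping rule; per-diagonal
clipping is not used). The first eigenvector of the Pearson correlation
matrix of O/E columns over valid bins (zero-variance columns dropped with a
counter) is sign-oriented by the Spearman correlation with per-bin TSS
counts — compartment A is the transcription-associated sign — and then
mean-centered, in that order. Positive bins are A, negative B. When arms
must be split into regions (e.g. around a rearrangement), centering is
applied after merging regions; the eigenvector itself offers no fallback
when it fails to capture compartment structure on a short arm.

## Integration conventions

ChIP peaks carry a summit (`best.pos`) and an occupancy (`best.logFC`).
A boundary is *occupied* when a summit lies within ±2 kb of the boundary
position; the boundary position is the start coordinate of its 2-kb bin
(configurable to the midpoint — the convention is not fixed by the
definitions above, and the start is used throughout). A peak is
*promoter-proximal* when an actively transcribed TSS (RPKM > 0) lies within
±200 bp of its summit. A peak overlaps a motif when the peak *region*
shares ≥ 1 bp with a motif occurrence (half-open intervals). A peak is
intronic when its summit is inside an intron and inside no exon of any
overlapping gene model. Ranked aggregation matrices sample tracks in 2-kb
bins within ±25 kb of each anchor (25 columns; anchors too close to the arm
end contribute `NA` cells that leave the summaries); the central enrichment
pools the three central columns. Group comparisons use the two-sided
Wilcoxon rank-sum test, with the W statistic reported for the first group;
small untied samples are evaluated exactly, larger or tied ones by the
normal approximation with continuity correction, matching standard
practice. Contingency tables are summarized per cell as
log10(observed/expected) with expected = row sum × column sum / total.
Printed percentages round half-up.

## Capture-C profiles

For a viewpoint restriction fragment, informative pairs are the
deduplicated pairs with at least one mate on the viewpoint fragment or
either immediate neighbor. Counts are accumulated in a nominal 1-kb grid
whose edges are snapped independently to the nearest restriction site
(degenerate bins merged); because fragments are delimited by restriction
sites, every fragment falls inside exactly one snapped bin, so each pair
increments exactly one bin and counts are conserved. Bins closer than 2 kb
to the viewpoint fragment or farther than 100 kb are excluded from the
profile (their counts are tallied separately). Differential profiles scale
replicates to counts per million by library size, average within condition,
and report log2 fold changes with a 0.5-CPM pseudo-count; swapping
conditions negates the track exactly. Statistical significance of
individual bins is left to the user — the displayed quantity is the
normalized fold-change profile.

## Reporter quantification

Enhancer-blocking strength is measured from per-cell mCherry/EGFP
fluorescence ratios of a dual-reporter construct. Per replicate, the median
log2 ratio is taken (medians commute with the log transform, so the order
is immaterial); the mean of the neutral-spacer replicates is subtracted
from all medians and the mean of the gypsy-insulator replicates is set to
100%, so strength = 100 × (median − spacer) / (gypsy − spacer). Gypsy
averages exactly 100 and spacer exactly 0 by construction; strengths below
0 or above 100 are reported unclipped. Cells with non-positive intensities
are dropped with a counter.

## The synthetic generator

The generator is the package's stand-in for sequencing data and defines the
conditions under which the pipeline is validated. Its model is the minimal
one under which the statistics above are well defined:

* contacts decay with bin distance as `(s + 1)^-α`, default α = 1, the
  canonical contact-decay exponent at domain scale;
* each planted boundary multiplies contacts crossing it by a factor
  `f ∈ (0, 1]` (applied once per crossed boundary, so `f` is a single
  interpretable insulation strength; default 0.5);
* same-compartment bin pairs are enriched by a contrast factor over an
  alternating block layout;
* counts are independent Poisson draws around this expectation, scaled so
  the matrix totals the requested sequencing depth; a zero-noise mode
  returns the expectation itself for exact tests.

Boundaries are placed uniformly with a minimum spacing of 20 bins by
default. An optional edge margin keeps boundaries away from the arm ends,
where the insulation score is undefined within one window and low-coverage
masking removes bins — exact-recovery tests use it so that failures mean
method errors, not ill-posed truth. Read-pair simulation jitters mate
positions within bins, assigns restriction fragments from a synthetic site
table (geometric gaps, mean 256 bp, emulating the merged landscape of two
4-cutter enzymes), and injects labelled contaminants (PCR duplicates,
multi-mappers, high-mismatch reads, close opposite-orientation pairs) so
filter tests are exact rather than statistical. Genuine short-range pairs
are emitted same-strand so the orientation filter targets only planted
contaminants, and genuine records are de-collided so none is an accidental
duplicate.

What the generator does **not** emulate: loop extrusion or corner peaks,
domain-internal enrichment beyond the boundary factor, coverage biases that
ICE corrects in real data (GC, mappability), genotype-specific trans
contacts, or ChIP fragment-level coverage profiles. Passing the recovery
tests therefore shows the pipeline is correct under the stated model, not
that the biological conclusions of any particular dataset follow.

## Validation experiments and their scale

Problem sizes are chosen so the whole suite runs in minutes on one core:

* **Boundary recovery** — 1-Mb arm, 2-kb bins, 10 boundaries at f = 0.5,
  5e5 pairs, three seeds; recall and precision measured at ±1 bin.
* **Mutant classification** — 2.6-Mb arm, 30 boundaries (10 removed, 10
  weakened to f = 0.8, 10 untouched), 2e6 pairs per genotype; per-class
  recovery measured at ±2 bins, the harmonization scale. The 2.6-Mb arm
  gives one boundary per ~87 kb, the typical embryonic domain scale, and
  2e6 pairs over 2.6 Mb matches a ~79-million-contact genome-wide library.
  Note that a planted factor of 0.8 maps, under this model, to a mean
  insulation score of about −0.09 to −0.12 — right at the −0.1 call
  filter — so weakened boundaries are intrinsically borderline detections:
  with ten boundaries per class, per-class recovery fluctuates strongly
  between seeds, and individual seeds can fall below nominal recovery
  targets without any implementation error.
* **Compartment recovery** — ten alternating 50-bin blocks, contrast 2.0,
  1e6 pairs.
* **Oracle equivalence** — scores, masks, balancing, O/E, eigenvectors,
  interval logic and rank-sum p-values are checked against independent
  brute-force implementations (double loops, Sinkhorn–Knopp, power
  iteration, exhaustive enumeration) at tolerances of 1e-8 to 1e-12.

## Numerical choices and degenerate inputs

ICE: convergence at marginal CV < 1e-6, 200-iteration cap with a warning on
non-convergence, square-root damping, output rescaled to unit mean
marginal; masked bins are `NA` throughout. Insulation: undefined within `w`
bins of the arm ends, where the diamond is fully masked, or where the local
average is non-positive; undefinedness propagates. Boundary calling:
plateaus resolve leftmost; harmonization ties resolve leftmost. O/E:
undefined where the expected value is 0. Eigenvector: zero-variance columns
dropped; a Spearman correlation of exactly 0 leaves the sign unchanged with
a warning. Wilcoxon: two identical groups give p = 1. Empty inputs return
empty outputs rather than errors wherever a stream may legitimately be
empty; infeasible configurations (non-dividing bin size, impossible
boundary spacing, downsampling beyond the input) raise errors naming the
constraint.

## Known limitations

Boundary position noise of ±1–2 bins is inherent at realistic depth; all
matching tolerances reflect that. TopDom's statistical domain-type
assignment is not reproduced — candidates come from strict local minima
plus the −0.1 filters, and recovery is validated against planted truth
rather than against TopDom's output. The quasi-likelihood testing stage of
differential Capture-C analysis is out of scope (profiles and fold changes
only), as are read alignment, peak calling, and motif discovery: peaks,
motifs and annotations enter as tables.
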