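---
title: "Calling genomic regulatory blocks and topological domains, and measuring their concordance"
author: "grbtad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling genomic regulatory blocks and topological domains, and measuring their concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Vertebrate and insect genomes contain arrays of conserved noncoding
elements (CNEs): short segments that retain high sequence identity
between species separated by hundreds of millions of years. CNEs
cluster densely around genes that control development, and a cluster
together with its target gene is called a genomic regulatory block
(GRB). Independently, chromosome-conformation (Hi-C) maps partition
the genome into topologically associating domains (TADs): regions
whose loci contact each other far more often than they contact
neighbouring regions. This package implements, end to end, the
analysis that asks whether these two independently defined structures
coincide: it detects CNEs from pairwise alignments, calls GRBs from
CNE density, computes the Hi-C directionality index, calls TADs and
A/B compartments, and quantifies GRB-TAD concordance with permutation,
Fisher and binomial statistics. A synthetic-data module plants known
GRB/TAD/CTCF/repeat structure so that every stage can be validated
against ground truth without any external download.

## CNE detection (`scan_alignments` and friends)

A CNE is a maximal alignment region with identity at least `I` over a
window of `L` columns (typical published settings range from 70%/50 bp
for distant comparisons to 96%/50 bp for close ones). The scanner
slides an `L`-column window along each gapped alignment block, keeps
windows whose column identity reaches `I`, and merges overlapping
qualifying windows into elements. Two choices the published procedure
leaves open are pinned here:

* **Gap columns count as mismatches.** This is the conservative
  convention and matches common CNE-scanning practice.
* **Merged elements are re-scored over the merged span.** If the
  merged span falls below `I` it is trimmed, one end column at a time
  (preferring to drop mismatching ends), until it qualifies; if the
  trim bottoms out, the best single qualifying window is kept. This
  keeps the invariant "every reported element has identity >= I"
  testable.

Elements from the two net perspectives are unioned and deduplicated
when two elements overlap reciprocally by at least 50% in both
genomes. Elements overlapping exons or repeats are removed
(`filter_excluded`, any 1 bp overlap counts), and elements whose
sequence places at more than four genomic loci are removed
(`filter_multimapping`; the count provider is pluggable because the
package does not compute alignments itself).

`smooth_density` turns the retained CNEs into a per-chromosome track:
the percentage of each sliding window (width `W` = 300 kb for
vertebrate-scale genomes, 50 kb for fly-scale; step `s = W/10` by
default, a resolution/cost balance) covered by the union of CNE
intervals, with end windows normalised by their truncated width.

## GRB calling (`call_grbs`)

The density track is segmented by an unsupervised two-state hidden
Markov model. Emissions are Gaussian on `log1p(density)` — the raw
track is zero-inflated and right-skewed, and the log transform makes
a two-component Gaussian a reasonable description — with a variance
floor of `1e-6`. The EM fit is restarted 10 times from random
initialisations and the restart with the best (smallest) AIC is kept,
with `AIC = 2p - 2 logLik` and `p = 7` free parameters (2 means, 2
variances, 2 free transition entries, 1 free initial entry).
Convergence is declared when the relative log-likelihood change falls
below `1e-6`, with a 500-iteration cap. A constant track yields a
degenerate flagged fit that downstream code treats as all-background.

After Viterbi decoding (`decode_segments`; the higher-mean state is
"enriched"), CNEs whose midpoint lies outside enriched segments are
dropped — the midpoint rule avoids double-counting elements that
straddle a segment edge. The remaining CNEs are clustered:

1. **Gap-quantile splitting** (`split_by_gaps`). Per chromosome, the
   empirical quantile `q` of inter-CNE gaps (type-7 linear
   interpolation, pinned for reproducibility) becomes a threshold, and
   every gap *strictly* greater than it starts a new region. Strict
   inequality prevents the degenerate all-split when many gaps tie at
   the quantile. Published settings: 0.98 (human-opossum,
   human-chicken), 0.93 (human-spotted gar), 0.97 (fly-fly). The
   recursion is over chromosomes and regions with one global
   per-chromosome threshold, not iterated re-thresholding.
2. **Synteny splitting** (`split_by_query_chrom`). Within each region,
   maximal runs of CNEs sharing a query chromosome become separate
   regions, so `[A, B, A]` yields three regions.
3. **Merge and filter** (`merge_and_filter`). Regions without a
   protein-coding gene are merged into an adjacent region when the gap
   is at most `D` (300 kb human/mouse, 50 kb fly); regions still
   lacking a gene, or holding fewer than `n_min = 10` CNEs, are then
   discarded, and surviving spans are re-derived from member CNEs.

Two merge details are this package's own design, adopted after the
planted-truth experiments exposed pathologies of the naive rule:

* Gene-less regions are processed **largest first**, so that a large
  fragment of a split cluster rejoins its parent region before tiny
  flanking debris (isolated background CNEs) is absorbed. Processing
  smallest-first let debris extend a fragment's span into gene-dense
  flanking territory, making it spuriously "gene-containing" and
  therefore unmergeable.
* When both neighbours are within `D`, the neighbour **sharing the
  region's query chromosome** is preferred (distance decides
  otherwise, left on an exact tie). Merging is the one step that could
  otherwise undo the synteny split by gluing a fragment of one GRB
  onto an adjacent GRB from a different query chromosome.

Gene containment means any overlap between the region span and a gene
body.

## Hi-C processing (`directionality_index`, `call_tads`, compartments)

The directionality index of bin `i` with flank `w` is computed from
`A` (contacts to the `w/b` upstream bins), `B` (downstream) and
`E = (A+B)/2` as

    DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)

positive where downstream contacts dominate; zero when `A = B` or
`A + B = 0`; truncated flanks at chromosome ends. DI scales with
sequencing depth — only its sign pattern is invariant under global
scaling of the matrix, and the package documents rather than
"corrects" this.

TADs are called by a three-state Gaussian HMM (downstream-biased /
none / upstream-biased) on the DI track. One numerical choice matters:
DI is a signed chi-square-like score whose magnitude at domain edges
is orders of magnitude above its interior values, so Gaussian states
fitted on the raw scale separate by *variance* rather than by sign.
The emission model therefore operates on the variance-stabilised
signed root `sign(DI) * sqrt(|DI|)`; the track itself, and TAD
strength, stay on the raw scale. States are mapped to labels by their
means (downstream if the mean exceeds a tenth of the largest absolute
mean, upstream if below its negative — the relative threshold lets
duplicated states share a label instead of fragmenting runs). A TAD
runs from the start of a downstream-biased run to the end of the next
upstream-biased run, must be at least 3 bins long (single-bin calls
are artifacts), and is removed if it spans a supplied centromere mask.
TAD strength is `sum(|DI|)` over the TAD's bins divided by its length
in kb. `collapse_domains` unions domains whose overlap reaches 60% of
the smaller one and keeps outer-most spans.

Compartments come from a PCA of the distance-normalised matrix:
observed/expected with the expected value equal to the mean contact at
each bin separation (per chromosome), then the Pearson correlation
matrix of the normalised columns, then its leading eigenvector. The
correlation-matrix transform is pinned here by decision. The sign is
oriented so that correlation with gene density is non-negative;
zero-coverage bins are masked; a matrix without usable variation
yields a flagged degenerate track with every bin unassigned. A TAD is
compartment A when at least 60% (inclusive) of its unmasked bins have
positive values, B when at least 60% are negative, otherwise
unassigned; a single gene is classified by the same rule over the bins
overlapping TSS ± 2.5 kb (the 5 kb promoter window is not anchored in
the published description; a centred window is the neutral choice,
and makes the label strand-independent).

## Concordance statistics

* `classify_tads_by_grb`: overlap fractions are computed on the TAD's
  length (the denominator is not explicit in the published wording;
  the TAD is the unit being classified). More than 80% covered by a
  single GRB: GRB-TAD; less than 20%: non-GRB-TAD; everything else,
  or any TAD overlapping two or more GRBs, is screened out
  (fly thresholds: 60% / 25%).
* `boundary_distances` / `both_edges_within`: GRB starts are matched
  to TAD starts and ends to ends (a nearest-any-boundary mode exists
  behind a flag).
* `concordance_pvalue`: the null redraws the GRB set as uniformly
  placed non-overlapping intervals of the observed lengths per
  chromosome. Placement uses the uniform-spacings construction (sort
  uniform cut points in the free space and lay the intervals down),
  which is exactly the uniform distribution on non-overlapping
  configurations that rejection sampling would produce, without the
  exponential rejection cost. The p-value is add-one corrected.
* `permutation_test_median`: |median difference| under label
  permutation. The published analyses used 1e6 permutations; the
  package default is 1e4 (the add-one floor `1/(n_perm+1)` is the
  smallest attainable p either way). The hot loop is compiled.
* `compartment_switch_test`: a TAD switches when both A and B occur
  among its per-lineage labels (unassigned ignored); GRB vs non-GRB
  against switch vs stable in a two-sided Fisher test.
* `ctcf_consensus` / `ctcf_boundary_enrichment`: peaks resized to
  400 bp about their midpoints, unioned across samples; occupancy =
  number of contributing samples; specific = 1-2, constitutive =
  N-1..N of N (default 17), intermediate otherwise. Peaks within
  10 kb of a boundary (sweep 10-120 kb supported) are tested per
  category against the category's share of the full consensus with a
  two-sided binomial test — the minimum-likelihood two-sided
  convention of `stats::binom.test`, verified exactly against an
  enumeration oracle. No multiplicity correction by default, matching
  the published reporting; a Bonferroni column is provided.
* `feature_profile`: counts feature midpoints in fixed-width windows
  placed on an anchor-relative scale where the anchor spans [0, 1] and
  equally-sized flanks span [-1, 0] and [1, 2]. Any smoothing is for
  display only and never feeds statistics.
* `grb_size_scaling` / `homologous_span`: the homologous span of a GRB
  in another species is the range of its member CNEs' query
  coordinates after dropping CNEs from a minority query chromosome;
  size ratios are summarised by medians and by least-squares slopes
  through the origin.

All empirical p-values are add-one corrected and lie in (0, 1]. With
an integer-valued statistic (the both-edges count) the add-one p is
conservative under ties; the calibration experiments shipped with the
package therefore use interval sets large enough (400 intervals) that
the count distribution is wide and the discreteness is negligible.

## The synthetic-data generator

`synthetic_config` defaults describe the study conditions used by the
validation experiments: one 50 Mb chromosome, 10 planted GRBs with
log-uniform sizes between 1 and 2 Mb, 20 CNEs per 100 kb inside GRBs
against 0.5 outside (the 40-fold contrast the clustering step
assumes), Pareto-distributed inter-CNE gaps with shape 2 (heavy
tailed with finite mean; the empirical gap law is not characterised in
the literature, so the Pareto tail is a modelling choice), planted TAD
boundaries at GRB edges jittered by up to 10 kb, contact decay
`|i-j|^-1` with a 4-fold within-domain boost and negative-binomial
dispersion 0.1 (real Hi-C is overdispersed; Poisson noise would make
the DI-HMM tests too easy), a 17-sample CTCF panel (20% constitutive
sites placed within 10 kb of domain edges, 40% specific, the rest
intermediate, 400 bp peaks), and SINEs depleted to 0.3 of background
inside GRBs. Gene placement puts one 20 kb target gene at each GRB
centre and background genes only outside GRBs at 5 per Mb — with one
target per 1-2 Mb GRB this realises roughly the 8-fold gene-density
contrast between inter-GRB space and GRB interiors. Each generator
derives its own deterministic stream from the master seed, so a
configuration reproduces bit-identically.

What the generator does *not* emulate: sequence-level alignments
(CNEs are coordinate records; the multi-mapping filter is exercised
through its pluggable count provider), trans-chromosomal contacts,
matrix-balancing artifacts, fragment-length or GC biases, correlated
CTCF occupancy across related tissues, and real gene architecture.
Passing the planted-recovery tests therefore demonstrates the
correctness and internal consistency of the algorithms under the
stated statistical structure, not performance on real alignments or
Hi-C libraries.

## Validation experiments and problem sizes

The package's acceptance checks (also recomputed by
`scripts/acceptance.R`) use these problem sizes, chosen so the whole
battery runs in minutes on one core:

* Viterbi decoding vs exhaustive enumeration on chains of length <= 12.
* Planted-GRB recovery on the default 50 Mb / 10 GRB genome: at least
  90% of planted GRBs must have a called GRB with both edges within
  one smoothing window (300 kb). Across held-out seeds the observed
  recovery is 0.9-1.0.
* DI hand checks: `A=10, B=30` gives exactly +10, with antisymmetry
  and zero cases exact.
* Planted-TAD recovery on a 20 Mb matrix (boost 4, decay 1, 10 kb
  bins, DI flank 250 kb): at least 80% of called boundaries within
  2 bins of a planted domain edge. Because planted domains tile the
  chromosome, its ends count as domain edges.
* Calibration: 1000 null replicates each for the permutation-median
  test (n = 20 + 20, 1e4 permutations) and the concordance p-value
  (400 + 400 intervals of 50-100 kb on 100 Mb, X = 100 kb,
  n_rand = 200); the type-I error at alpha = 0.05 must lie within
  2 Monte-Carlo SE of 0.05. Fisher and binomial p-values must match
  enumeration oracles exactly on small margins.
* Threshold classifications (overlap classes, CTCF categories, the
  60% compartment rule) must reproduce hand-computed labels exactly.

## Known limitations

* One pinned TAD caller. The published comparison ran both HOMER and
  the original DI-HMM pipeline; this package ships a single
  transparent DI-HMM and makes no attempt to replicate HOMER output.
  Absolute TAD counts and widths will differ from either tool.
* Headline numbers from the original study (GRB counts per species
  pair, median TAD widths and strengths, specific p-values) derive
  from whole-genome alignment nets and public Hi-C libraries; they
  are reproducible with this package only after downloading those
  inputs, and deviations driven by the pinned caller are expected and
  should be reported alongside.
* The gap-quantile and the other clustering parameters were tuned
  empirically per species pair in the original work; the package
  exposes them all but cannot decide them for a new comparison.
* DI magnitudes scale with sequencing depth, so TAD strengths are
  comparable only within one matrix.
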