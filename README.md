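# grbtad

Genomic regulatory blocks (GRBs) are clusters of conserved noncoding
elements (CNEs) spanning a developmental gene and its long-range
regulatory elements; topologically associating domains (TADs) are
self-interacting regions of Hi-C contact maps. `grbtad` implements the
full analysis that links the two: CNE detection from pairwise
alignment blocks, GRB calling by HMM segmentation of CNE density,
directionality-index computation and TAD/compartment calling from
binned contact matrices, and the statistics that measure GRB-TAD
concordance. It is aimed at regulatory-genomics researchers who want a
tested, scriptable re-implementation of this pipeline with a
synthetic-data module that makes every stage verifiable against
planted ground truth.

## The methods in brief

**GRB calling.** CNE density in sliding windows (width *W* = 300 kb
vertebrate / 50 kb fly) is segmented by a two-state Gaussian HMM on
log1p density, fitted by EM with 10 restarts and AIC selection
(7 free parameters). CNEs outside enriched segments are dropped;
the rest are split at inter-CNE gaps exceeding the per-chromosome
gap quantile *q* (type-7; 0.93-0.98 in published comparisons), split
again into maximal runs by query chromosome (synteny), and gene-less
regions within *D* (300 kb / 50 kb) are merged back before discarding
regions without a gene or with fewer than 10 CNEs.

**Hi-C.** For bin *i* with flank sums *A* (upstream) and *B*
(downstream) and *E* = (*A*+*B*)/2, the directionality index is

    DI = sign(B - A) * ((A - E)^2/E + (B - E)^2/E)

TADs span from the start of a downstream-biased run to the end of the
next upstream-biased run of a three-state Gaussian HMM fitted on
signed-root DI; TAD strength is the per-kb sum of |DI|. Compartments
are the leading eigenvector of the correlation matrix of the
observed/expected map, oriented by gene density, with the inclusive
60% rule for A/B labels.

**Concordance.** TADs are labelled GRB-TADs (>80% of the TAD covered
by a single GRB), non-GRB-TADs (<20%) or screened; boundary distances
are side-matched; the boundary-concordance null redraws GRB-length
intervals uniformly without overlap; group medians are compared by
label permutation; compartment switching is tested by Fisher's exact
test; CTCF consensus peaks (400 bp, occupancy out of 17 samples:
specific 1-2, constitutive 16-17) are tested for boundary enrichment
with two-sided binomial tests.

## Worked example

Plant four GRBs on a 20 Mb chromosome, call GRBs from the synthetic
CNEs, simulate a Hi-C matrix over the same planted domains, call TADs,
and compare:

```r
library(grbtad)

cfg  <- synthetic_config(chrom_sizes = c(chr1 = 20e6), n_grbs = 4, seed = 7)
gen  <- generate_genome(cfg)
cnes <- generate_cnes(gen$truth)
call <- call_grbs(cnes, gen$genes, cfg$chrom_sizes, seed = 3)
print(call)
#> GRB call
#>   input_cnes                   1149
#>   cnes_in_enriched             1079
#>   regions_after_gap_split      23
#>   regions_after_synteny_split  24
#>   final_grbs                   4
#>   median GRB span: 1362036 bp; median CNE count: 244

M    <- generate_contact_matrix(gen$truth)
di   <- directionality_index(M, w = 25e4)
tads <- call_tads(di, seed = 3)
tads <- classify_tads_by_grb(tads, call$grbs)
table(tads$grb_class)
#>    GRB nonGRB
#>      4      5

be <- both_edges_within(call$grbs, tads, X = 120e3)
#> 2 of 4 GRBs have both edges within 120 kb of a TAD boundary
res <- permutation_test_median(tads$strength[tads$grb_class == "GRB"],
                               tads$strength[tads$grb_class == "nonGRB"],
                               n_perm = 1e4, seed = 3)
#> median strength 4.66 (GRB-TADs) vs 3.70 (non-GRB-TADs), p = 0.32
```

All four planted GRBs are recovered and each coincides with a called
TAD; with only nine TADs the strength contrast is visible but not
significant, as expected at this toy size. `run_pipeline()` chains all
stages (synthetic genome, GRBs, Hi-C, CTCF, repeats, funnel-heatmap
matrix) from one seed and can write every artifact plus a JSON
parameter sidecar.

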