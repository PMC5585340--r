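#' Classify TADs by GRB overlap
#'
#' The overlap fraction is the share of the TAD's length covered by
#' GRBs. A TAD is a GRB-TAD when more than \code{hi} of it is covered by
#' a single GRB; a non-GRB-TAD when less than \code{lo} of it is covered;
#' any TAD overlapping more than one GRB, or with an intermediate
#' fraction, is screened out.
#'
#' @param tads TAD \code{GRanges}.
#' @param grbs GRB \code{GRanges}.
#' @param hi,lo Class thresholds (human 0.8 / 0.2; Drosophila 0.6 / 0.25).
#' @return The TADs with \code{grb_class} (\code{"GRB"}, \code{"nonGRB"},
#'   \code{"screened"}), \code{grb_overlap_frac} and \code{n_grbs}
#'   columns.
#' @export
classify_tads_by_grb <- function(tads, grbs, hi = 0.8, lo = 0.2) {
  stopifnot(lo >= 0, lo < hi, hi <= 1)
  n_ov <- countOverlaps(tads, grbs)
  cov_bp <- numeric(length(tads))
  if (length(grbs)) {
    isect <- pintersect(
      findOverlapPairs(tads, grbs))
    if (length(isect)) {
      hits <- findOverlaps(tads, grbs)
      bp <- tapply(GenomicRanges::width(isect), queryHits(hits), sum)
      cov_bp[as.integer(names(bp))] <- bp
    }
  }
  frac <- cov_bp / GenomicRanges::width(tads)
  cls <- ifelse(n_ov == 1 & frac > hi, "GRB",
                ifelse(n_ov <= 1 & frac < lo, "nonGRB", "screened"))
  cls[n_ov > 1] <- "screened"
  mcols(tads)$grb_class <- cls
  mcols(tads)$grb_overlap_frac <- frac
  mcols(tads)$n_grbs <- n_ov
  tads
}

#' Distances from GRB edges to the nearest TAD boundaries
#'
#' For each GRB, the distance from its start to the nearest TAD start
#' and from its end to the nearest TAD end (side-matched, the default),
#' or to the nearest boundary of either side when
#' \code{match_side = FALSE}.
#'
#' @param grbs,tads \code{GRanges} sets.
#' @param match_side Pair starts with starts and ends with ends
#'   (default TRUE).
#' @return A data.frame with \code{start_dist} and \code{end_dist} (bp;
#'   \code{Inf} when the chromosome has no TAD).
#' @export
boundary_distances <- function(grbs, tads, match_side = TRUE) {
  gch <- as.character(GenomicRanges::seqnames(grbs))
  tch <- as.character(GenomicRanges::seqnames(tads))
  sd_ <- ed_ <- rep(Inf, length(grbs))
  for (ch in unique(gch)) {
    gi <- which(gch == ch)
    ti <- which(tch == ch)
    if (length(ti) == 0) next
    ts <- sort(start0(tads)[ti])
    te <- sort(end0(tads)[ti])
    if (match_side) {
      sd_[gi] <- nearest_dist(start0(grbs)[gi], ts)
      ed_[gi] <- nearest_dist(end0(grbs)[gi], te)
    } else {
      all_b <- sort(c(ts, te))
      sd_[gi] <- nearest_dist(start0(grbs)[gi], all_b)
      ed_[gi] <- nearest_dist(end0(grbs)[gi], all_b)
    }
  }
  data.frame(start_dist = sd_, end_dist = ed_)
}

# distance from each point to the nearest value of a sorted vector
nearest_dist <- function(p, sorted) {
  i <- findInterval(p, sorted)
  lo <- ifelse(i >= 1, p - sorted[pmax(i, 1)], Inf)
  hi <- ifelse(i < length(sorted), sorted[pmin(i + 1, length(sorted))] - p,
               Inf)
  pmin(abs(lo), abs(hi))
}

#' GRBs with both edges near a TAD boundary
#'
#' @param grbs,tads \code{GRanges} sets.
#' @param X Distance threshold in bp.
#' @param match_side See \code{\link{boundary_distances}}.
#' @return List with \code{count} and \code{fraction} of GRBs whose start
#'   and end both lie within \code{X} of the nearest TAD start and end.
#' @export
both_edges_within <- function(grbs, tads, X, match_side = TRUE) {
  d <- boundary_distances(grbs, tads, match_side = match_side)
  cnt <- sum(d$start_dist <= X & d$end_dist <= X)
  list(count = cnt,
       fraction = if (length(grbs)) cnt / length(grbs) else NA_real_)
}

#' Empirical p-value for GRB-TAD boundary concordance
#'
#' The null redraws the GRB set as uniformly-placed non-overlapping
#' intervals of the observed lengths on the same chromosomes (implemented
#' by the uniform-spacings construction, equivalent to rejection sampling
#' to non-overlap) and recomputes the both-edges-within count against the
#' fixed TADs. The p-value uses the add-one correction
#' \code{(1 + #draws >= observed) / (1 + n_rand)}.
#'
#' @param grbs,tads \code{GRanges} sets.
#' @param X Distance threshold in bp.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param n_rand Number of null draws (default 1000).
#' @param seed Integer seed.
#' @return List with \code{observed}, \code{p} and the null counts.
#' @export
concordance_pvalue <- function(grbs, tads, X, chrom_sizes, n_rand = 1000,
                               seed = 1) {
  obs <- both_edges_within(grbs, tads, X)$count
  gch <- as.character(GenomicRanges::seqnames(grbs))
  tch <- as.character(GenomicRanges::seqnames(tads))
  per_chrom <- lapply(unique(gch), function(ch) {
    ti <- which(tch == ch)
    list(chrom = ch, lens = GenomicRanges::width(grbs)[gch == ch],
         L = if (ch %in% names(chrom_sizes)) chrom_sizes[[ch]] else NA,
         ts = sort(start0(tads)[ti]), te = sort(end0(tads)[ti]))
  })
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_rand), function(r) {
      cnt <- 0L
      for (pc in per_chrom) {
        if (length(pc$ts) == 0) next
        st <- place_nonoverlapping(pc$lens, pc$L)
        en <- st + pc$lens
        cnt <- cnt + sum(nearest_dist(st, pc$ts) <= X &
                           nearest_dist(en, pc$te) <= X)
      }
      cnt
    }, integer(1))
  })
  list(observed = obs, p = addone_p(sum(null_counts >= obs), n_rand),
       null_counts = null_counts)
}

#' Label-permutation test for a difference in medians
#'
#' The statistic is the absolute difference of group medians; the null is
#' generated by randomly permuting group labels \code{n_perm} times
#' (the published analyses used 1e6 permutations; the default here is
#' 1e4). The p-value uses the add-one correction, so its smallest
#' attainable value is \code{1 / (n_perm + 1)}.
#'
#' @param a,b Numeric vectors (the two groups).
#' @param n_perm Number of permutations (default 1e4).
#' @param seed Integer seed.
#' @return List with \code{statistic} (observed |median(a) - median(b)|)
#'   and \code{p}.
#' @export
permutation_test_median <- function(a, b, n_perm = 1e4, seed = 1) {
  stopifnot(length(a) >= 1, length(b) >= 1, n_perm >= 1)
  res <- with_seed(seed,
    perm_median_count(c(as.numeric(a), as.numeric(b)), length(a),
                      as.integer(n_perm)))
  list(statistic = res$observed, p = addone_p(res$n_ge, n_perm))
}

#' Compartment-switch enrichment of GRB-TADs
#'
#' A TAD switches compartment when its A/B labels differ between any two
#' lineages (both an A and a B label occur; unassigned labels are
#' ignored). Tests the 2x2 table (GRB vs non-GRB) x (switch vs stable)
#' with a two-sided Fisher's exact test; screened TADs are excluded.
#'
#' @param labels Character matrix, TADs x lineages, entries \code{"A"},
#'   \code{"B"} or \code{"unassigned"}.
#' @param grb_class Character vector per TAD (\code{"GRB"},
#'   \code{"nonGRB"}, \code{"screened"}).
#' @return List with the contingency \code{table}, \code{odds_ratio} and
#'   \code{p}.
#' @export
compartment_switch_test <- function(labels, grb_class) {
  labels <- as.matrix(labels)
  stopifnot(nrow(labels) == length(grb_class))
  switches <- apply(labels, 1, function(r) {
    r <- r[r %in% c("A", "B")]
    length(unique(r)) > 1
  })
  keep <- grb_class %in% c("GRB", "nonGRB")
  tab <- table(factor(grb_class[keep], levels = c("GRB", "nonGRB")),
               factor(ifelse(switches[keep], "switch", "stable"),
                      levels = c("switch", "stable")))
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Cross-sample CTCF consensus peaks
#'
#' Every peak is resized to a fixed width about its midpoint; resized
#' peaks are unioned across samples into consensus intervals, and each
#' consensus interval is scored with the number of samples contributing
#' at least one peak to it. Categories follow the occupancy rule:
#' specific = 1-2 samples, constitutive = N-1 or N samples, intermediate
#' otherwise.
#'
#' @param samples List of per-sample peak \code{GRanges}.
#' @param width Consensus peak width in bp (default 400).
#' @param n_samples Panel size N (default \code{length(samples)}).
#' @return A \code{GRanges} of consensus peaks with \code{occupancy} and
#'   \code{category} columns.
#' @export
ctcf_consensus <- function(samples, width = 400,
                           n_samples = length(samples)) {
  resized <- lapply(samples, function(s) {
    if (length(s) == 0) return(GenomicRanges::GRanges())
    resize(GenomicRanges::granges(s), width, fix = "center")
  })
  all <- do.call(c, unname(resized))
  if (length(all) == 0) return(GenomicRanges::GRanges())
  cons <- reduce(sort(all))
  occ <- Reduce(`+`, lapply(resized, function(s)
    as.integer(countOverlaps(cons, s) > 0)))
  mcols(cons)$occupancy <- as.integer(occ)
  mcols(cons)$category <- ctcf_category(occ, n_samples)
  cons
}

#' Occupancy category of a consensus peak
#'
#' @param occupancy Number of samples carrying the peak.
#' @param n_samples Panel size N.
#' @return \code{"specific"} (1-2), \code{"constitutive"} (N-1 or N) or
#'   \code{"intermediate"}.
#' @export
ctcf_category <- function(occupancy, n_samples) {
  ifelse(occupancy >= n_samples - 1, "constitutive",
         ifelse(occupancy <= 2, "specific", "intermediate"))
}

#' Enrichment of CTCF occupancy categories at boundaries
#'
#' Consensus peaks within \code{d} of a boundary are assigned to the
#' boundary set; for each category, the assigned count is compared to
#' Binomial(n_assigned, p0) with p0 the category's share of the full
#' consensus set, using a two-sided binomial test. Fold = assigned share
#' / p0. No multiplicity correction is applied (a Bonferroni column is
#' provided for reference).
#'
#' @param consensus Consensus peaks from \code{\link{ctcf_consensus}}.
#' @param boundaries \code{GRanges} of boundary points (e.g. width-1
#'   ranges at GRB or TAD edges).
#' @param d Assignment distance in bp (default 10 kb).
#' @return A data.frame with one row per category: \code{n_assigned},
#'   \code{share}, \code{p0}, \code{fold}, \code{p}, \code{p_bonferroni}.
#' @export
ctcf_boundary_enrichment <- function(consensus, boundaries, d = 1e4) {
  stopifnot(length(consensus) > 0)
  cats <- c("specific", "intermediate", "constitutive")
  p0 <- vapply(cats, function(cl)
    mean(mcols(consensus)$category == cl), numeric(1))
  hit <- distanceToNearest(consensus, boundaries)
  assigned <- rep(FALSE, length(consensus))
  assigned[queryHits(hit)] <- mcols(hit)$distance <= d
  n <- sum(assigned)
  if (n == 0)
    return(data.frame(category = character(0), n_assigned = integer(0),
                      share = numeric(0), p0 = numeric(0),
                      fold = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0)))
  x <- vapply(cats, function(cl)
    sum(mcols(consensus)$category[assigned] == cl), numeric(1))
  p <- vapply(seq_along(cats), function(k) {
    if (p0[k] <= 0 || p0[k] >= 1) return(1)
    stats::binom.test(x[k], n, p0[k], alternative = "two.sided")$p.value
  }, numeric(1))
  data.frame(category = cats, n_assigned = as.integer(x), share = x / n,
             p0 = p0, fold = (x / n) / p0, p = p,
             p_bonferroni = pmin(p * length(cats), 1),
             row.names = NULL)
}

#' Sweep of boundary-assignment distances
#'
#' Repeats \code{\link{ctcf_boundary_enrichment}} over a range of
#' assignment distances (default 10-120 kb in 10 kb steps).
#'
#' @param consensus,boundaries See \code{\link{ctcf_boundary_enrichment}}.
#' @param distances Vector of distances in bp.
#' @return A data.frame with a \code{d} column stacked over distances.
#' @export
ctcf_enrichment_sweep <- function(consensus, boundaries,
                                  distances = seq(1e4, 1.2e5, by = 1e4)) {
  do.call(rbind, lapply(distances, function(d) {
    res <- ctcf_boundary_enrichment(consensus, boundaries, d = d)
    if (nrow(res)) res$d <- d
    res
  }))
}

#' Anchor-relative feature profile
#'
#' Counts features (by midpoint) in sliding windows laid out on an
#' anchor-relative coordinate scale: each anchor spans [0, 1] and its
#' equally-sized flanks span [-1, 0] and [1, 2]. Window centres are
#' placed at \code{nbins} evenly-spaced relative positions; windows are
#' a fixed \code{window} bp wide (10 kb with 1 kb-equivalent spacing in
#' the published profiles).
#'
#' @param features Feature \code{GRanges}.
#' @param anchors Anchor \code{GRanges} (e.g. GRBs).
#' @param window Window width in bp (default 10 kb).
#' @param nbins Number of relative positions across [-1, 2]
#'   (default 151).
#' @return A list with \code{profile} (anchors x nbins count matrix),
#'   \code{rel} (relative positions) and \code{mean} (mean profile).
#' @export
feature_profile <- function(features, anchors, window = 1e4,
                            nbins = 151) {
  rel <- seq(-1, 2, length.out = nbins)
  fch <- as.character(GenomicRanges::seqnames(features))
  mids <- mid0(features)
  mat <- matrix(0, length(anchors), nbins)
  for (i in seq_along(anchors)) {
    ch <- as.character(GenomicRanges::seqnames(anchors))[i]
    Lg <- GenomicRanges::width(anchors)[i]
    x <- start0(anchors)[i] + rel * Lg
    m <- sort(mids[fch == ch])
    if (length(m) == 0) next
    lo <- x - window / 2
    hi <- x + window / 2
    mat[i, ] <- findInterval(hi, m) - findInterval(lo, m)
  }
  list(profile = mat, rel = rel, mean = colMeans(mat))
}

#' Homologous GRB span from member-CNE query coordinates
#'
#' CNEs whose query chromosome differs from the most frequent query
#' chromosome of the set are dropped; the span is then
#' \code{[min query_start, max query_end)} of the remainder.
#'
#' @param query_chrom,query_start,query_end Parallel vectors of member-CNE
#'   query coordinates (0-based half-open).
#' @return List with \code{chrom}, \code{start}, \code{end}, \code{size}.
#' @export
homologous_span <- function(query_chrom, query_start, query_end) {
  stopifnot(length(query_chrom) > 0)
  tab <- table(query_chrom)
  major <- names(tab)[which.max(tab)]
  keep <- query_chrom == major
  list(chrom = major, start = min(query_start[keep]),
       end = max(query_end[keep]),
       size = max(query_end[keep]) - min(query_start[keep]))
}

#' Cross-species GRB size scaling
#'
#' Given homologous GRB spans (rows) measured in several species
#' (columns), reports the median pairwise size ratios and a least-squares
#' fit (through the origin) of each species' sizes against the first
#' (reference) column.
#'
#' @param sizes Numeric matrix or data.frame, GRBs x species.
#' @return List with \code{median_ratio} (species x species matrix of
#'   median size ratios, column/row... entry [a, b] = median(b / a)) and
#'   \code{slope} (named vector of regression slopes vs the reference).
#' @export
grb_size_scaling <- function(sizes) {
  sizes <- as.matrix(sizes)
  stopifnot(ncol(sizes) >= 2, nrow(sizes) >= 1)
  sp <- colnames(sizes) %||% paste0("species", seq_len(ncol(sizes)))
  colnames(sizes) <- sp
  ratio <- matrix(NA_real_, ncol(sizes), ncol(sizes),
                  dimnames = list(sp, sp))
  for (a in seq_along(sp)) for (b in seq_along(sp))
    ratio[a, b] <- stats::median(sizes[, b] / sizes[, a])
  slope <- vapply(seq_along(sp), function(b) {
    unname(stats::coef(stats::lm(sizes[, b] ~ sizes[, 1] + 0))[1])
  }, numeric(1))
  names(slope) <- sp
  list(median_ratio = ratio, slope = slope)
}
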