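#' Construct a pairwise alignment block
#'
#' A gapped alignment of a reference-genome interval against a
#' query-genome interval, as found in axt-style net alignment files.
#' Coordinates are 0-based half-open.
#'
#' @param ref_chrom,ref_start Reference chromosome and 0-based start.
#' @param query_chrom,query_start Query chromosome and 0-based start.
#' @param ref_aln,query_aln Aligned sequences of equal length, gaps as
#'   \code{"-"}.
#' @param query_strand Query strand (\code{"+"} or \code{"-"}); coordinates
#'   are taken as given on that strand.
#' @return A list of class \code{alignment_block}.
#' @export
alignment_block <- function(ref_chrom, ref_start, query_chrom, query_start,
                            ref_aln, query_aln, query_strand = "+") {
  if (nchar(ref_aln) != nchar(query_aln))
    stop("malformed block: aligned sequences have different lengths")
  if (nchar(gsub("-", "", ref_aln)) == 0)
    stop("malformed block: reference side is all gaps")
  b <- list(ref_chrom = ref_chrom, ref_start = as.numeric(ref_start),
            query_chrom = query_chrom,
            query_start = as.numeric(query_start),
            ref_aln = ref_aln, query_aln = query_aln,
            query_strand = query_strand)
  class(b) <- "alignment_block"
  b
}

#' Scan alignment blocks for conserved noncoding elements
#'
#' Slides a window of \code{L} alignment columns along each block and
#' keeps windows whose column identity is at least \code{I}; gap columns
#' count as mismatches. Overlapping qualifying windows are merged into
#' maximal runs; a merged run whose overall identity falls below \code{I}
#' is trimmed to the best qualifying sub-span. Blocks from both net
#' perspectives may be supplied; duplicate elements are removed when two
#' elements overlap reciprocally by at least 50% in both genomes.
#'
#' @param blocks A list of \code{\link{alignment_block}} objects.
#' @param I Identity threshold, a fraction in (0, 1].
#' @param L Window length in alignment columns (>= 1).
#' @return A \code{GRanges} of CNEs (reference coordinates) with metadata
#'   columns \code{query_chrom}, \code{query_start}, \code{query_end}
#'   (0-based half-open) and \code{identity}.
#' @export
scan_alignments <- function(blocks, I, L) {
  stopifnot(I > 0, I <= 1, L >= 1)
  if (inherits(blocks, "alignment_block")) blocks <- list(blocks)
  hits <- lapply(blocks, scan_block, I = I, L = L)
  hits <- do.call(rbind, hits)
  if (is.null(hits) || nrow(hits) == 0) return(empty_cnes())
  cnes <- gr0(hits$ref_chrom, hits$ref_start, hits$ref_end,
              query_chrom = hits$query_chrom,
              query_start = hits$query_start,
              query_end = hits$query_end,
              identity = hits$identity)
  dedupe_cnes(sort(cnes))
}

empty_cnes <- function() {
  gr <- GenomicRanges::GRanges()
  mcols(gr) <- S4Vectors::DataFrame(query_chrom = character(0),
                                    query_start = numeric(0),
                                    query_end = numeric(0),
                                    identity = numeric(0))
  gr
}

scan_block <- function(block, I, L) {
  stopifnot(inherits(block, "alignment_block"))
  rc <- strsplit(toupper(block$ref_aln), "")[[1]]
  qc <- strsplit(toupper(block$query_aln), "")[[1]]
  n <- length(rc)
  if (n < L) return(NULL)
  match <- (rc == qc) & rc != "-" & qc != "-"
  cs <- c(0, cumsum(match))
  wsum <- cs[(L + 1):(n + 1)] - cs[1:(n - L + 1)]
  qual <- which(wsum >= I * L - 1e-9)
  if (length(qual) == 0) return(NULL)
  # merge overlapping qualifying windows into runs of columns
  brk <- which(diff(qual) >= L)
  run_from <- qual[c(1, brk + 1)]
  run_to <- qual[c(brk, length(qual))] + L - 1

  ref_off <- c(0, cumsum(rc != "-"))
  q_off <- c(0, cumsum(qc != "-"))
  out <- vector("list", length(run_from))
  for (r in seq_along(run_from)) {
    span <- trim_span(run_from[r], run_to[r], cs, I, L, wsum)
    a <- span[1]; b <- span[2]
    id <- (cs[b + 1] - cs[a]) / (b - a + 1)
    rs <- block$ref_start + ref_off[a]
    re <- block$ref_start + ref_off[b + 1]
    qs <- block$query_start + q_off[a]
    qe <- block$query_start + q_off[b + 1]
    if (re <= rs || qe <= qs) next # span is gap-only on one side
    out[[r]] <- data.frame(ref_chrom = block$ref_chrom, ref_start = rs,
                           ref_end = re, query_chrom = block$query_chrom,
                           query_start = qs, query_end = qe, identity = id)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# Shrink a merged run [a, b] (columns) until identity >= I, dropping one
# end column at a time (prefer dropping a mismatch); if the greedy trim
# bottoms out, fall back to the best single qualifying window in the run.
trim_span <- function(a, b, cs, I, L, wsum) {
  a0 <- a; b0 <- b
  ident <- function(a, b) (cs[b + 1] - cs[a]) / (b - a + 1)
  while (b - a + 1 > L && ident(a, b) < I - 1e-12) {
    m_a <- cs[a + 1] - cs[a] # 1 if column a matches
    m_b <- cs[b + 1] - cs[b]
    if (m_a < m_b) a <- a + 1
    else if (m_b < m_a) b <- b - 1
    else b <- b - 1
  }
  if (ident(a, b) >= I - 1e-12) return(c(a, b))
  w <- a0:(b0 - L + 1)
  best <- w[which.max(wsum[w])]
  c(best, best + L - 1)
}

# Remove duplicates arising from scanning both net perspectives: two
# elements are the same if they overlap reciprocally >= 50% in both
# genomes; the higher-identity copy is kept.
dedupe_cnes <- function(cnes) {
  if (length(cnes) < 2) return(cnes)
  hits <- findOverlaps(cnes, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(hits) == 0) return(cnes)
  i <- queryHits(hits); j <- subjectHits(hits)
  ri <- GenomicRanges::ranges(cnes)
  ov_ref <- pmin(end0(cnes)[i], end0(cnes)[j]) -
    pmax(start0(cnes)[i], start0(cnes)[j])
  w <- GenomicRanges::width(cnes)
  rec_ref <- ov_ref >= 0.5 * w[i] & ov_ref >= 0.5 * w[j]
  qs <- mcols(cnes)$query_start; qe <- mcols(cnes)$query_end
  qch <- mcols(cnes)$query_chrom
  ov_q <- pmin(qe[i], qe[j]) - pmax(qs[i], qs[j])
  qw <- qe - qs
  rec_q <- qch[i] == qch[j] & ov_q >= 0.5 * qw[i] & ov_q >= 0.5 * qw[j]
  dup <- which(rec_ref & rec_q)
  if (length(dup) == 0) return(cnes)
  drop <- unique(ifelse(mcols(cnes)$identity[i[dup]] >=
                          mcols(cnes)$identity[j[dup]],
                        j[dup], i[dup]))
  cnes[-drop]
}

#' Remove CNEs overlapping exon or repeat exclusion intervals
#'
#' A CNE is dropped if its reference interval overlaps any exclusion
#' interval by at least 1 bp.
#'
#' @param cnes CNE \code{GRanges}.
#' @param exclusions \code{GRanges} of excluded intervals (exons, repeats).
#' @return The retained CNEs.
#' @export
filter_excluded <- function(cnes, exclusions) {
  if (length(cnes) == 0 || length(exclusions) == 0) return(cnes)
  hit <- overlapsAny(cnes, exclusions, minoverlap = 1)
  cnes[!hit]
}

#' Remove multi-mapping CNEs
#'
#' Drops CNEs whose reference-side sequence places at more than
#' \code{max_loci} locations in the target genome. The mapping-count
#' provider is pluggable: supply per-CNE counts directly or a function
#' computing them (e.g. exact full-length match counting against a
#' sequence index). A CNE without an available count passes with a
#' warning (its count is treated as 1).
#'
#' @param cnes CNE \code{GRanges}.
#' @param counts Integer vector of mapping counts parallel to \code{cnes},
#'   or \code{NULL}.
#' @param count_provider Function taking \code{cnes} and returning such a
#'   vector; used when \code{counts} is \code{NULL}.
#' @param max_loci Maximum allowed placements (default 4; a CNE mapping to
#'   exactly \code{max_loci} loci is retained).
#' @return The retained CNEs.
#' @export
filter_multimapping <- function(cnes, counts = NULL, count_provider = NULL,
                                max_loci = 4) {
  stopifnot(max_loci >= 1)
  if (length(cnes) == 0) return(cnes)
  if (is.null(counts)) {
    counts <- if (is.null(count_provider)) rep(NA_real_, length(cnes))
              else count_provider(cnes)
  }
  counts <- as.numeric(counts)
  if (length(counts) != length(cnes))
    stop("mapping counts must be parallel to the CNE set")
  if (anyNA(counts)) {
    warning(sum(is.na(counts)),
            " CNE(s) without a mapping count pass the filter (count 1)")
    counts[is.na(counts)] <- 1
  }
  cnes[counts <= max_loci]
}

#' Sliding-window CNE density track
#'
#' Computes, for windows of width \code{W} sliding by step \code{s}, the
#' percentage of the window covered by the union of CNE reference
#' intervals. Windows truncated at chromosome ends are normalised by
#' their truncated width. Window \code{k} is centred at
#' \code{(k - 0.5) * s}; the track for a chromosome of length \code{len}
#' has \code{ceiling(len / s)} values.
#'
#' @param cnes CNE \code{GRanges}.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param W Window width in bp (default 300 kb, the vertebrate setting;
#'   use 50 kb for Drosophila-scale genomes).
#' @param s Step in bp (default \code{W / 10}).
#' @return An object of class \code{density_track}: per-chromosome value
#'   vectors (percent covered, in [0, 100]) plus \code{W}, \code{s} and
#'   the chromosome sizes.
#' @export
smooth_density <- function(cnes, chrom_sizes, W = 3e5, s = W / 10) {
  stopifnot(W >= s, s >= 1)
  vals <- lapply(names(chrom_sizes), function(ch) {
    len <- chrom_sizes[[ch]]
    nwin <- ceiling(len / s)
    ctr <- (seq_len(nwin) - 0.5) * s
    lo <- pmax(ctr - W / 2, 0)
    hi <- pmin(ctr + W / 2, len)
    cc <- cnes[GenomicRanges::seqnames(cnes) == ch]
    if (length(cc) == 0) return(rep(0, nwin))
    r <- IRanges::reduce(GenomicRanges::ranges(cc))
    covered <- cum_coverage(hi, IRanges::start(r) - 1, IRanges::end(r)) -
      cum_coverage(lo, IRanges::start(r) - 1, IRanges::end(r))
    100 * covered / (hi - lo)
  })
  names(vals) <- names(chrom_sizes)
  structure(list(values = vals, W = W, s = s, chrom_sizes = chrom_sizes),
            class = "density_track")
}

# bp of the union of sorted disjoint [starts, ends) below each position t
cum_coverage <- function(t, starts, ends) {
  cumw <- c(0, cumsum(ends - starts))
  i <- findInterval(t, starts)
  pmax(cumw[i + 1] - pmax(ends[pmax(i, 1)] - t, 0) * (i > 0), 0)
}

#' @export
print.density_track <- function(x, ...) {
  cat(sprintf("CNE density track: W = %g bp, step = %g bp, %d chromosome(s)\n",
              x$W, x$s, length(x$values)))
  for (ch in names(x$values))
    cat(sprintf("  %s: %d windows, max %.3f%%\n", ch, length(x$values[[ch]]),
                max(x$values[[ch]])))
  invisible(x)
}
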