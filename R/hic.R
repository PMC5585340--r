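#' Binned Hi-C contact matrix
#'
#' @param counts Square symmetric matrix of non-negative counts.
#' @param chrom Chromosome name.
#' @param binsize Bin size in bp.
#' @param chrom_len Chromosome length (default \code{nrow * binsize}).
#' @return An object of class \code{contact_matrix}.
#' @export
contact_matrix <- function(counts, chrom, binsize,
                           chrom_len = nrow(counts) * binsize) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("contact matrix must be square")
  if (any(counts < 0)) stop("contact matrix must be non-negative")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("contact matrix must be symmetric")
  structure(list(counts = counts, chrom = chrom, binsize = binsize,
                 chrom_len = chrom_len),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("Contact matrix: %s, %d bins of %g bp, %.0f total counts\n",
              x$chrom, nrow(x$counts), x$binsize, sum(x$counts)))
  invisible(x)
}

#' Directionality index of a contact matrix
#'
#' For each bin, let A be the summed contacts to the \code{w / binsize}
#' upstream bins, B the summed contacts downstream, and E = (A + B) / 2.
#' The directionality index is
#' \code{sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)}: positive values
#' mark downstream interaction bias, negative upstream. DI is 0 where
#' A = B or A + B = 0; bins near the chromosome edge use truncated
#' flanks.
#'
#' @param M A \code{\link{contact_matrix}}.
#' @param w Flank window in bp; must be a multiple of the bin size
#'   (published settings: 40 kb on 20 kb bins for human, 20 kb on 10 kb
#'   bins for Drosophila).
#' @return An object of class \code{di_track} with per-bin values.
#' @export
directionality_index <- function(M, w) {
  stopifnot(inherits(M, "contact_matrix"))
  b <- M$binsize
  k <- w / b
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("window must be a positive multiple of the bin size")
  k <- as.integer(round(k))
  n <- nrow(M$counts)
  cs <- cbind(0, t(apply(M$counts, 1, cumsum))) # cs[i, j+1] = sum M[i,1:j]
  i <- seq_len(n)
  lo <- pmax(i - k, 1)
  hi <- pmin(i + k, n)
  A <- cs[cbind(i, i)] - cs[cbind(i, lo)]       # contacts to [i-k, i-1]
  B <- cs[cbind(i, hi + 1)] - cs[cbind(i, i + 1)] # contacts to [i+1, i+k]
  E <- (A + B) / 2
  di <- ifelse(E > 0 & A != B,
               sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E), 0)
  structure(list(values = di, chrom = M$chrom, binsize = b, window = w,
                 chrom_len = M$chrom_len),
            class = "di_track")
}

#' Construct a DI track from per-bin values
#'
#' Mostly useful for tests and for importing externally computed DI
#' tracks; \code{\link{directionality_index}} builds these from a
#' contact matrix.
#'
#' @param values Per-bin DI values.
#' @param chrom Chromosome name.
#' @param binsize Bin size (bp).
#' @param window Flank window the values were computed with (bp).
#' @param chrom_len Chromosome length (default \code{length * binsize}).
#' @return A \code{di_track}.
#' @export
di_track <- function(values, chrom = "chr1", binsize = 1e4,
                     window = 2 * binsize,
                     chrom_len = length(values) * binsize) {
  structure(list(values = as.numeric(values), chrom = chrom,
                 binsize = binsize, window = window,
                 chrom_len = chrom_len),
            class = "di_track")
}

#' @export
print.di_track <- function(x, ...) {
  cat(sprintf("DI track: %s, %d bins of %g bp (flank %g bp), range [%.2f, %.2f]\n",
              x$chrom, length(x$values), x$binsize, x$window,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Call TADs from a directionality-index track
#'
#' Fits a three-state Gaussian HMM (downstream-biased / none /
#' upstream-biased) to the DI values and Viterbi-decodes it. Because DI
#' is a signed chi-square-like score whose magnitude explodes at domain
#' edges, the emission model operates on the variance-stabilised signed
#' root \code{sign(DI) * sqrt(|DI|)}; the track itself (and TAD
#' strength) stay on the raw scale. States are mapped to labels by
#' their emission means (a state is downstream-biased when its mean
#' exceeds a tenth of the largest absolute mean, upstream when below
#' its negative). A TAD runs from the start of a downstream-biased run
#' to the end of the next upstream-biased run.
#' Calls shorter than \code{min_bins} bins are dropped, as are TADs
#' overlapping a centromere mask.
#'
#' @param di A \code{\link{directionality_index}} track.
#' @param restarts,seed HMM restarts (default 10) and seed.
#' @param min_bins Minimum TAD length in bins (default 3).
#' @param centromere Optional \code{GRanges} mask; TADs spanning it are
#'   removed.
#' @return A \code{GRanges} of TADs (non-overlapping) with a
#'   \code{strength} column (see \code{\link{tad_strength}}).
#' @export
call_tads <- function(di, restarts = 10, seed = 1, min_bins = 3,
                      centromere = NULL) {
  stopifnot(inherits(di, "di_track"))
  v <- di$values
  if (length(v) < min_bins || stats::sd(v) < 1e-12)
    return(empty_tads())
  vt <- sign(v) * sqrt(abs(v)) # variance-stabilised for the Gaussian HMM
  model <- fit_gaussian_hmm(vt, k = 3, restarts = restarts, seed = seed)
  if (isTRUE(model$degenerate)) return(empty_tads())
  path <- viterbi_path(model, vt)
  tau <- 0.1 * max(abs(model$means))
  lab <- rep("none", model$k)
  lab[model$means > tau] <- "down"
  lab[model$means < -tau] <- "up"
  states <- lab[path]
  if (!any(states == "down") || !any(states == "up"))
    return(empty_tads())

  r <- rle(states)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  tad_from <- integer(0); tad_to <- integer(0)
  j <- 1
  while (j <= length(r$values)) {
    if (r$values[j] == "down") {
      nxt_up <- which(r$values == "up" & seq_along(r$values) > j)
      if (length(nxt_up) == 0) break
      u <- nxt_up[1]
      tad_from <- c(tad_from, run_start[j])
      tad_to <- c(tad_to, run_end[u])
      j <- u + 1
    } else j <- j + 1
  }
  if (length(tad_from) == 0) return(empty_tads())
  keep <- (tad_to - tad_from + 1) >= min_bins
  tad_from <- tad_from[keep]; tad_to <- tad_to[keep]
  if (length(tad_from) == 0) return(empty_tads())
  tads <- gr0(di$chrom, (tad_from - 1) * di$binsize,
              pmin(tad_to * di$binsize, di$chrom_len))
  if (!is.null(centromere) && length(centromere))
    tads <- tads[!overlapsAny(tads, centromere)]
  if (length(tads) == 0) return(empty_tads())
  mcols(tads)$strength <- tad_strength(tads, di)
  sort(tads)
}

empty_tads <- function() {
  gr <- GenomicRanges::GRanges()
  mcols(gr) <- S4Vectors::DataFrame(strength = numeric(0))
  gr
}

#' TAD strength
#'
#' The sum of absolute directionality-index values over the bins of a TAD
#' divided by the TAD length in kilobases.
#'
#' @param tads A \code{GRanges} of TADs aligned to the DI bin grid.
#' @param di The \code{di_track} they were called on.
#' @return Numeric vector of strengths (one per TAD).
#' @export
tad_strength <- function(tads, di) {
  stopifnot(inherits(di, "di_track"))
  vapply(seq_along(tads), function(i) {
    from <- floor(start0(tads)[i] / di$binsize) + 1
    to <- ceiling(end0(tads)[i] / di$binsize)
    to <- min(to, length(di$values))
    sum(abs(di$values[from:to])) / (GenomicRanges::width(tads)[i] / 1000)
  }, numeric(1))
}

#' Collapse strongly overlapping domains to outer-most spans
#'
#' Iteratively unions any two domains whose overlap is at least
#' \code{min_frac} of the smaller domain, then returns the outer-most
#' (non-contained) spans.
#'
#' @param domains \code{GRanges} of contact domains.
#' @param min_frac Reciprocal-overlap threshold (default 0.6).
#' @return Collapsed \code{GRanges}.
#' @export
collapse_domains <- function(domains, min_frac = 0.6) {
  d <- GenomicRanges::granges(sort(domains))
  repeat {
    if (length(d) < 2) break
    hits <- findOverlaps(d, drop.self = TRUE,
                                        drop.redundant = TRUE)
    if (length(hits) == 0) break
    i <- queryHits(hits); j <- subjectHits(hits)
    ov <- pmin(end0(d)[i], end0(d)[j]) - pmax(start0(d)[i], start0(d)[j])
    small <- pmin(GenomicRanges::width(d)[i], GenomicRanges::width(d)[j])
    cand <- which(ov >= min_frac * small)
    if (length(cand) == 0) break
    a <- i[cand[1]]; b <- j[cand[1]]
    u <- gr0(as.character(GenomicRanges::seqnames(d))[a],
             min(start0(d)[a], start0(d)[b]),
             max(end0(d)[a], end0(d)[b]))
    d <- sort(c(d[-c(a, b)], u))
  }
  # outer-most: drop domains contained in another
  if (length(d) > 1) {
    within <- countOverlaps(d, d, type = "within") > 1
    d <- d[!within]
  }
  d
}

#' A/B compartment eigenvector of a contact matrix
#'
#' Normalises the matrix to observed/expected by distance (expected =
#' mean contact at each bin separation), computes the Pearson correlation
#' matrix of the normalised columns, and takes its first principal
#' component. The sign is oriented so the correlation with gene density
#' is non-negative. Bins with zero coverage are masked (NA). A matrix
#' with no usable variation (e.g. constant) yields a degenerate track
#' with every bin unassigned.
#'
#' @param M A \code{\link{contact_matrix}}.
#' @param gene_density Optional per-bin gene-density vector used to
#'   orient the sign.
#' @return An object of class \code{compartment_track}: per-bin PC1
#'   values (NA where masked), plus \code{degenerate} and
#'   \code{oriented} flags.
#' @export
compartment_eigenvector <- function(M, gene_density = NULL) {
  stopifnot(inherits(M, "contact_matrix"))
  n <- nrow(M$counts)
  mask <- rowSums(M$counts) > 0
  out <- rep(NA_real_, n)
  track <- function(vals, degenerate, oriented)
    structure(list(values = vals, chrom = M$chrom, binsize = M$binsize,
                   chrom_len = M$chrom_len, degenerate = degenerate,
                   oriented = oriented),
              class = "compartment_track")
  if (sum(mask) < 3) return(track(out, TRUE, FALSE))
  idx <- which(mask)
  sub <- M$counts[idx, idx, drop = FALSE]
  D <- abs(outer(idx, idx, "-"))
  exp_by_d <- vapply(split(as.vector(sub), as.vector(D)), mean, numeric(1))
  expd <- exp_by_d[as.character(as.vector(D))]
  oe <- as.vector(sub) / ifelse(expd > 0, expd, 1)
  oe <- matrix(oe, nrow(sub), ncol(sub))
  sds <- apply(oe, 2, stats::sd)
  if (all(sds < 1e-12)) return(track(out, TRUE, FALSE))
  C <- suppressWarnings(stats::cor(oe))
  C[!is.finite(C)] <- 0
  pc1 <- eigen(C, symmetric = TRUE)$vectors[, 1]
  oriented <- FALSE
  if (!is.null(gene_density)) {
    r <- suppressWarnings(stats::cor(pc1, gene_density[idx]))
    if (is.finite(r) && r != 0) {
      if (r < 0) pc1 <- -pc1
      oriented <- TRUE
    }
  }
  out[idx] <- pc1
  track(out, FALSE, oriented)
}

#' Classify TADs into A/B compartments
#'
#' A TAD is compartment A when at least \code{frac} of its (unmasked)
#' bins have positive PC1 values, B when at least \code{frac} are
#' negative, otherwise unassigned.
#'
#' @param tads TAD \code{GRanges}.
#' @param pc1 A \code{\link{compartment_eigenvector}} track.
#' @param frac Required fraction (default 0.6, inclusive).
#' @return The TADs with a \code{compartment} column
#'   (\code{"A"}, \code{"B"} or \code{"unassigned"}).
#' @export
classify_compartments <- function(tads, pc1, frac = 0.6) {
  lab <- vapply(seq_along(tads), function(i) {
    compartment_label(pc1, start0(tads)[i], end0(tads)[i], frac)
  }, character(1))
  mcols(tads)$compartment <- lab
  tads
}

compartment_label <- function(pc1, lo, hi, frac) {
  from <- floor(lo / pc1$binsize) + 1
  to <- min(ceiling(hi / pc1$binsize), length(pc1$values))
  if (isTRUE(pc1$degenerate) || to < from) return("unassigned")
  v <- pc1$values[from:to]
  v <- v[!is.na(v)]
  if (length(v) == 0) return("unassigned")
  if (mean(v > 0) >= frac) return("A")
  if (mean(v < 0) >= frac) return("B")
  "unassigned"
}

#' Compartment of a single gene
#'
#' Applies the compartment fraction rule to the bins overlapping a 5 kb
#' window centred on the gene's TSS (TSS +/- 2.5 kb); the window is
#' strand-independent.
#'
#' @param tss TSS position(s), 0-based bp.
#' @param pc1 A \code{compartment_track}.
#' @param frac Required fraction (default 0.6).
#' @param window Window width in bp (default 5000).
#' @return Character vector of labels.
#' @export
classify_gene_compartment <- function(tss, pc1, frac = 0.6,
                                      window = 5000) {
  vapply(tss, function(p)
    compartment_label(pc1, max(p - window / 2, 0), p + window / 2, frac),
    character(1))
}
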