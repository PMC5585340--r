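#' Fit the two-state CNE-density HMM
#'
#' Fits a two-state Gaussian HMM to the log1p-transformed CNE density
#' track by EM, restarted \code{restarts} times (default 10); the restart
#' with the best (smallest) AIC is kept. A constant track yields a
#' degenerate single-state fallback which downstream code treats as
#' all-background.
#'
#' @param track A \code{\link{smooth_density}} track.
#' @param restarts Number of EM restarts (default 10).
#' @param seed Integer seed for the restarts.
#' @return A \code{\link{fit_gaussian_hmm}} object (class
#'   \code{gaussian_hmm}, k = 2, 7 free parameters).
#' @export
fit_hmm <- function(track, restarts = 10, seed = 1) {
  stopifnot(inherits(track, "density_track"), restarts >= 1)
  obs <- lapply(track$values, log1p)
  fit_gaussian_hmm(obs, k = 2, restarts = restarts, seed = seed)
}

#' Segment a density track into enriched and background regions
#'
#' Viterbi-decodes the fitted two-state HMM on each chromosome; the state
#' with the larger emission mean is the CNE-enriched state. Step-sized
#' tiles are merged into maximal runs so the segments tile each
#' chromosome without overlap.
#'
#' @param model A \code{gaussian_hmm} from \code{\link{fit_hmm}}.
#' @param track The \code{density_track} it was fitted to.
#' @return A \code{GRanges} tiling the genome with a \code{state} column
#'   (\code{"enriched"} or \code{"background"}).
#' @export
decode_segments <- function(model, track) {
  stopifnot(inherits(model, "gaussian_hmm"),
            inherits(track, "density_track"))
  segs <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    len <- track$chrom_sizes[[ch]]
    if (isTRUE(model$degenerate)) {
      lab <- rep("background", length(v))
    } else {
      path <- viterbi_path(model, log1p(v))
      enriched_state <- which.max(model$means)
      lab <- ifelse(path == enriched_state, "enriched", "background")
    }
    r <- rle(lab)
    to <- cumsum(r$lengths)
    from <- to - r$lengths + 1
    gr0(ch, (from - 1) * track$s, pmin(to * track$s, len),
        state = r$values)
  })
  sort(do.call(c, unname(segs)))
}

#' Keep CNEs lying in enriched segments
#'
#' A CNE is retained when its reference-interval midpoint falls inside a
#' segment labelled enriched.
#'
#' @param cnes CNE \code{GRanges}.
#' @param seg Segmentation from \code{\link{decode_segments}}.
#' @return The retained CNEs.
#' @export
filter_to_enriched <- function(cnes, seg) {
  if (length(cnes) == 0) return(cnes)
  enr <- seg[mcols(seg)$state == "enriched"]
  if (length(enr) == 0) return(cnes[0])
  mids <- gr0(as.character(GenomicRanges::seqnames(cnes)), mid0(cnes),
              mid0(cnes) + 1)
  cnes[overlapsAny(mids, enr)]
}

#' Split CNEs into regions at large inter-CNE gaps
#'
#' Per chromosome, the gaps between consecutive CNEs are collected and
#' their empirical quantile \code{q} (type-7 linear interpolation) becomes
#' the split threshold: every gap strictly greater than the threshold
#' starts a new region. A chromosome with fewer than two CNEs forms a
#' single region.
#'
#' @param cnes CNE \code{GRanges}, sorted.
#' @param q Gap quantile in (0, 1]; at 1 nothing splits (the threshold is
#'   the maximum gap and splits are strict). Published settings: 0.98 for
#'   human-opossum and human-chicken, 0.93 for human-spotted gar, 0.97
#'   for D. melanogaster-D. mojavensis.
#' @return An object of class \code{cne_regions}: the (sorted) CNEs plus
#'   an integer region assignment per CNE.
#' @export
split_by_gaps <- function(cnes, q) {
  stopifnot(q > 0, q <= 1)
  cnes <- sort(cnes)
  n <- length(cnes)
  region <- integer(n)
  nxt <- 1L
  for (ch in unique(as.character(GenomicRanges::seqnames(cnes)))) {
    idx <- which(as.character(GenomicRanges::seqnames(cnes)) == ch)
    if (length(idx) < 2) {
      region[idx] <- nxt
      nxt <- nxt + 1L
      next
    }
    gaps <- start0(cnes)[idx][-1] - end0(cnes)[idx][-length(idx)]
    thr <- stats::quantile(gaps, q, type = 7, names = FALSE)
    brk <- gaps > thr
    region[idx] <- nxt + cumsum(c(0L, as.integer(brk)))
    nxt <- max(region[idx]) + 1L
  }
  new_cne_regions(cnes, region)
}

new_cne_regions <- function(cnes, region) {
  structure(list(cnes = cnes, region = as.integer(region)),
            class = "cne_regions")
}

#' Region spans of a \code{cne_regions} object
#'
#' Each region spans its member CNEs: \code{[min start, max end)}.
#'
#' @param regions A \code{cne_regions} object.
#' @return A \code{GRanges} with \code{region_id} and \code{n_cnes}.
#' @export
region_spans <- function(regions) {
  stopifnot(inherits(regions, "cne_regions"))
  if (length(regions$cnes) == 0) return(GenomicRanges::GRanges())
  ids <- sort(unique(regions$region))
  ch <- vapply(ids, function(i)
    as.character(GenomicRanges::seqnames(regions$cnes))[
      which(regions$region == i)[1]], character(1))
  s <- vapply(ids, function(i)
    min(start0(regions$cnes)[regions$region == i]), numeric(1))
  e <- vapply(ids, function(i)
    max(end0(regions$cnes)[regions$region == i]), numeric(1))
  n <- vapply(ids, function(i) sum(regions$region == i), numeric(1))
  gr0(ch, s, e, region_id = ids, n_cnes = n)
}

#' Split regions by query chromosome (synteny)
#'
#' Within each region, maximal runs of consecutive CNEs sharing one query
#' chromosome become separate regions, yielding discrete blocks of
#' conserved synteny.
#'
#' @param regions A \code{cne_regions} object whose CNEs carry a
#'   \code{query_chrom} column.
#' @return A refined \code{cne_regions} object.
#' @export
split_by_query_chrom <- function(regions) {
  stopifnot(inherits(regions, "cne_regions"))
  cnes <- regions$cnes
  if (length(cnes) == 0) return(regions)
  qch <- as.character(mcols(cnes)$query_chrom)
  region <- integer(length(cnes))
  nxt <- 1L
  for (i in sort(unique(regions$region))) {
    idx <- which(regions$region == i)
    r <- rle(qch[idx])
    sub <- rep(seq_along(r$values), r$lengths)
    region[idx] <- nxt + sub - 1L
    nxt <- nxt + length(r$values)
  }
  new_cne_regions(cnes, region)
}

#' Merge gene-less regions and filter to final GRBs
#'
#' A region that contains no protein-coding gene is merged into its
#' nearest adjacent region on the same chromosome when the gap between
#' them is at most \code{D} (300 kb for human/mouse, 50 kb for
#' Drosophila; the nearer neighbour wins, left on an exact tie). After
#' merging, any region still lacking a gene or holding fewer than
#' \code{n_min} CNEs is discarded; survivors become GRBs with spans
#' re-derived from their member CNEs.
#'
#' @param regions A \code{cne_regions} object.
#' @param genes Gene \code{GRanges} (protein-coding gene bodies).
#' @param D Merge distance in bp (default 3e5).
#' @param n_min Minimum CNE count (default 10).
#' @return A \code{GRanges} of GRBs with \code{cne_count},
#'   \code{query_chrom} (most frequent among member CNEs) and
#'   \code{contains_gene} columns.
#' @export
merge_and_filter <- function(regions, genes, D = 3e5, n_min = 10) {
  stopifnot(inherits(regions, "cne_regions"), D >= 0)
  region <- regions$region
  cnes <- regions$cnes
  if (length(cnes) == 0) return(empty_grbs())

  has_gene <- function(sp) overlapsAny(sp, genes)
  qchrom_of <- function(ids) vapply(ids, function(i) {
    tab <- table(as.character(mcols(cnes)$query_chrom)[region == i])
    names(tab)[which.max(tab)]
  }, character(1))
  repeat {
    sp <- region_spans(new_cne_regions(cnes, region))
    if (length(sp) < 2) break
    hg <- has_gene(sp)
    ch <- as.character(GenomicRanges::seqnames(sp))
    qc <- qchrom_of(mcols(sp)$region_id)
    merged <- FALSE
    # process larger gene-less regions first so major fragments rejoin
    # their parent region before small debris is absorbed
    for (k in order(GenomicRanges::width(sp), decreasing = TRUE)) {
      if (hg[k]) next
      same <- which(ch == ch[k])
      pos <- match(k, same)
      left <- if (pos > 1) same[pos - 1] else NA
      right <- if (pos < length(same)) same[pos + 1] else NA
      dl <- if (!is.na(left)) start0(sp)[k] - end0(sp)[left] else Inf
      dr <- if (!is.na(right)) start0(sp)[right] - end0(sp)[k] else Inf
      if (min(dl, dr) > D) next
      # when both neighbours are in range, prefer the one sharing this
      # region's query chromosome (do not undo the synteny split);
      # otherwise the nearer neighbour, left on an exact tie
      ql <- !is.na(left) && dl <= D && qc[left] == qc[k]
      qr <- !is.na(right) && dr <= D && qc[right] == qc[k]
      target <- if (ql && !qr) left
                else if (qr && !ql) right
                else if (dl <= dr) left else right
      from_id <- mcols(sp)$region_id[k]
      to_id <- mcols(sp)$region_id[target]
      region[region == from_id] <- to_id
      merged <- TRUE
      break
    }
    if (!merged) break
  }

  sp <- region_spans(new_cne_regions(cnes, region))
  keep <- has_gene(sp) & mcols(sp)$n_cnes >= n_min
  sp <- sp[keep]
  if (length(sp) == 0) return(empty_grbs())
  qch <- vapply(mcols(sp)$region_id, function(i) {
    tab <- table(as.character(mcols(cnes)$query_chrom)[region == i])
    names(tab)[which.max(tab)]
  }, character(1))
  grbs <- gr0(as.character(GenomicRanges::seqnames(sp)), start0(sp),
              end0(sp), cne_count = as.integer(mcols(sp)$n_cnes),
              query_chrom = qch, contains_gene = TRUE)
  sort(grbs)
}

empty_grbs <- function() {
  gr <- GenomicRanges::GRanges()
  mcols(gr) <- S4Vectors::DataFrame(cne_count = integer(0),
                                    query_chrom = character(0),
                                    contains_gene = logical(0))
  gr
}

#' Call genomic regulatory blocks from a CNE set
#'
#' Runs the full GRB pipeline: sliding-window CNE density, two-state HMM
#' segmentation with AIC restart selection, removal of CNEs outside
#' enriched segments, recursive gap-quantile splitting, synteny
#' splitting by query chromosome, and the merge/filter step. A stage
#' log records the number of CNEs or regions surviving each stage.
#'
#' @param cnes CNE \code{GRanges} with \code{query_chrom} metadata.
#' @param genes Gene \code{GRanges}.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param W,s Density window and step (bp); see \code{\link{smooth_density}}.
#' @param q Gap quantile; see \code{\link{split_by_gaps}}.
#' @param D,n_min Merge distance and minimum CNE count; see
#'   \code{\link{merge_and_filter}}.
#' @param restarts,seed HMM restarts and seed; see \code{\link{fit_hmm}}.
#' @return An object of class \code{grb_call}: list with \code{grbs}
#'   (a \code{GRanges}), \code{log} (stage counts), \code{model},
#'   \code{segmentation} and \code{params}.
#' @export
call_grbs <- function(cnes, genes, chrom_sizes, W = 3e5, s = W / 10,
                      q = 0.98, D = 3e5, n_min = 10, restarts = 10,
                      seed = 1) {
  log <- list(input_cnes = length(cnes))
  if (length(cnes) == 0) {
    out <- list(grbs = empty_grbs(), log = log, model = NULL,
                segmentation = GenomicRanges::GRanges(),
                params = list(W = W, s = s, q = q, D = D, n_min = n_min,
                              restarts = restarts, seed = seed))
    class(out) <- "grb_call"
    return(out)
  }
  track <- smooth_density(cnes, chrom_sizes, W = W, s = s)
  model <- fit_hmm(track, restarts = restarts, seed = seed)
  seg <- decode_segments(model, track)
  enr <- filter_to_enriched(cnes, seg)
  log$cnes_in_enriched <- length(enr)
  if (length(enr) == 0) {
    out <- list(grbs = empty_grbs(), log = log, model = model,
                segmentation = seg,
                params = list(W = W, s = s, q = q, D = D, n_min = n_min,
                              restarts = restarts, seed = seed))
    class(out) <- "grb_call"
    return(out)
  }
  reg <- split_by_gaps(enr, q)
  log$regions_after_gap_split <- length(unique(reg$region))
  reg <- split_by_query_chrom(reg)
  log$regions_after_synteny_split <- length(unique(reg$region))
  grbs <- merge_and_filter(reg, genes, D = D, n_min = n_min)
  log$final_grbs <- length(grbs)
  out <- list(grbs = grbs, log = log, model = model, segmentation = seg,
              params = list(W = W, s = s, q = q, D = D, n_min = n_min,
                            restarts = restarts, seed = seed))
  class(out) <- "grb_call"
  out
}

#' @export
print.grb_call <- function(x, ...) {
  cat("GRB call\n")
  for (nm in names(x$log)) cat(sprintf("  %-28s %d\n", nm, x$log[[nm]]))
  if (length(x$grbs))
    cat(sprintf("  median GRB span: %.0f bp; median CNE count: %.0f\n",
                stats::median(GenomicRanges::width(x$grbs)),
                stats::median(mcols(x$grbs)$cne_count)))
  invisible(x)
}

#' @export
summary.grb_call <- function(object, ...) {
  g <- object$grbs
  data.frame(n_grbs = length(g),
             median_span = if (length(g))
               stats::median(GenomicRanges::width(g)) else NA_real_,
             total_cnes = if (length(g))
               sum(mcols(g)$cne_count) else 0L)
}
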