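# File formats. All on-disk coordinates are 0-based half-open,
# tab-separated, headerless (BED dialect); readers validate per line and
# report the offending line number.

read_tsv_checked <- function(path, n_min_cols) {
  if (file.size(path) == 0)
    return(data.frame())
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < n_min_cols)
    stop("expected at least ", n_min_cols, " columns in ", path)
  df
}

check_coords <- function(start, end, path) {
  bad <- which(!is.finite(start) | !is.finite(end) | end < start |
                 start < 0)
  if (length(bad))
    stop("invalid coordinates in ", path, " at line ", bad[1],
         " (end < start or negative)")
}

#' Read/write intervals in the headerless BED dialect
#'
#' Columns: chrom, start, end (0-based half-open), then any metadata
#' columns given in \code{extra}.
#'
#' @param gr A \code{GRanges}; metadata columns named in \code{extra} are
#'   written after the coordinates.
#' @param path File path.
#' @param extra Names of metadata columns to write / assign on read.
#' @return \code{read_bed} returns a \code{GRanges}; \code{write_bed}
#'   returns \code{path} invisibly.
#' @export
write_bed <- function(gr, path, extra = character(0)) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = format(start0(gr), scientific = FALSE,
                                  trim = TRUE),
                   end = format(end0(gr), scientific = FALSE, trim = TRUE))
  for (cl in extra) df[[cl]] <- mcols(gr)[[cl]]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path, extra = character(0)) {
  df <- read_tsv_checked(path, 3)
  if (nrow(df) == 0) return(GenomicRanges::GRanges())
  check_coords(df[[2]], df[[3]], path)
  gr <- gr0(df[[1]], df[[2]], df[[3]])
  for (k in seq_along(extra)) mcols(gr)[[extra[k]]] <- df[[3 + k]]
  gr
}

#' Read/write CNEs as 7-column paired BED
#'
#' Columns: chrom, start, end, query_chrom, query_start, query_end,
#' identity; both coordinate pairs 0-based half-open.
#'
#' @param cnes CNE \code{GRanges} (as produced by
#'   \code{\link{scan_alignments}} or \code{\link{generate_cnes}}).
#' @param path File path.
#' @return \code{read_pairedbed} returns a CNE \code{GRanges};
#'   \code{write_pairedbed} returns \code{path} invisibly.
#' @export
write_pairedbed <- function(cnes, path) {
  write_bed(cnes, path,
            extra = c("query_chrom", "query_start", "query_end",
                      "identity"))
}

#' @rdname write_pairedbed
#' @export
read_pairedbed <- function(path) {
  df <- read_tsv_checked(path, 7)
  if (nrow(df) == 0) return(empty_cnes())
  check_coords(df[[2]], df[[3]], path)
  check_coords(df[[5]], df[[6]], path)
  gr0(df[[1]], df[[2]], df[[3]], query_chrom = df[[4]],
      query_start = df[[5]], query_end = df[[6]], identity = df[[7]])
}

#' Write a per-bin track as bedGraph
#'
#' Accepts \code{density_track}, \code{di_track} or
#' \code{compartment_track} objects (NA bins are skipped).
#'
#' @param track A track object.
#' @param path File path.
#' @return \code{read_bedgraph} returns a \code{GRanges} with a
#'   \code{score} column; \code{write_bedgraph} returns \code{path}
#'   invisibly.
#' @export
write_bedgraph <- function(track, path) {
  rows <- list()
  for (ch in names(track_chroms(track))) {
    tv <- track_values(track, ch)
    n <- length(tv$values)
    s <- (seq_len(n) - 1) * tv$binwidth
    e <- pmin(seq_len(n) * tv$binwidth, tv$chrom_len)
    keep <- !is.na(tv$values)
    rows[[ch]] <- data.frame(chrom = ch,
                             start = format(s[keep], scientific = FALSE,
                                            trim = TRUE),
                             end = format(e[keep], scientific = FALSE,
                                          trim = TRUE),
                             score = tv$values[keep])
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path) {
  df <- read_tsv_checked(path, 4)
  if (nrow(df) == 0) return(GenomicRanges::GRanges())
  check_coords(df[[2]], df[[3]], path)
  gr0(df[[1]], df[[2]], df[[3]], score = df[[4]])
}

# uniform accessors over the track classes
track_chroms <- function(track) {
  if (inherits(track, "density_track")) return(track$chrom_sizes)
  stats::setNames(track$chrom_len, track$chrom)
}

track_values <- function(track, chrom) {
  if (inherits(track, "density_track"))
    list(values = track$values[[chrom]], binwidth = track$s,
         chrom_len = track$chrom_sizes[[chrom]])
  else
    list(values = track$values, binwidth = track$binsize,
         chrom_len = track$chrom_len)
}

#' Read/write contact matrices
#'
#' Dense format: a headerless tab-separated n x n count table. Triplet
#' format: three columns \code{bin_i}, \code{bin_j}, \code{count}
#' (0-based bins, upper triangle or full). Both carry a
#' \code{<path>.sizes} sidecar with chrom, chromosome length and bin
#' size.
#'
#' @param M A \code{\link{contact_matrix}}.
#' @param path File path.
#' @param format \code{"dense"} or \code{"triplet"}.
#' @return \code{read_contact_matrix} returns a \code{contact_matrix};
#'   \code{write_contact_matrix} returns \code{path} invisibly.
#' @export
write_contact_matrix <- function(M, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.table(M$counts, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    up <- which(upper.tri(M$counts, diag = TRUE) & M$counts != 0,
                arr.ind = TRUE)
    utils::write.table(data.frame(i = up[, 1] - 1, j = up[, 2] - 1,
                                  count = M$counts[up]),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(data.frame(chrom = M$chrom, length = M$chrom_len,
                                binsize = M$binsize),
                     paste0(path, ".sizes"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  sizes <- utils::read.table(paste0(path, ".sizes"), sep = "\t",
                             stringsAsFactors = FALSE)
  chrom <- sizes[[1]][1]; chrom_len <- sizes[[2]][1]
  binsize <- sizes[[3]][1]
  n <- ceiling(chrom_len / binsize)
  if (format == "dense") {
    cnt <- as.matrix(utils::read.table(path, sep = "\t"))
    dimnames(cnt) <- NULL
  } else {
    df <- read_tsv_checked(path, 3)
    cnt <- matrix(0, n, n)
    if (nrow(df)) {
      cnt[cbind(df[[1]] + 1, df[[2]] + 1)] <- df[[3]]
      cnt[cbind(df[[2]] + 1, df[[1]] + 1)] <- df[[3]]
    }
  }
  contact_matrix(cnt, chrom = chrom, binsize = binsize,
                 chrom_len = chrom_len)
}

#' Read axt-format alignment blocks
#'
#' Parses the UCSC axt dialect (summary line, reference sequence line,
#' query sequence line, blank line). axt coordinates are 1-based
#' inclusive and are converted to the package's 0-based half-open
#' convention.
#'
#' @param path axt file path.
#' @return A list of \code{\link{alignment_block}} objects.
#' @export
read_axt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nchar(trimws(lines)) > 0]
  if (length(lines) %% 3 != 0)
    stop("malformed axt file: expected blocks of 3 non-blank lines")
  blocks <- list()
  for (k in seq(1, length(lines), by = 3)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) < 9) stop("malformed axt header at line ", k)
    blocks[[length(blocks) + 1]] <- alignment_block(
      ref_chrom = f[2], ref_start = as.numeric(f[3]) - 1,
      query_chrom = f[5], query_start = as.numeric(f[6]) - 1,
      ref_aln = lines[k + 1], query_aln = lines[k + 2],
      query_strand = f[8])
  }
  blocks
}

#' Species parameter presets
#'
#' Bundles the per-species defaults used throughout the pipeline:
#' density window \code{W} and step \code{s}, Hi-C bin size \code{b} and
#' DI flank \code{w}, gap quantile \code{q}, merge distance \code{D},
#' minimum CNE count \code{n_min}, TAD-overlap class thresholds
#' \code{hi}/\code{lo}, and the funnel-heatmap window and bin. Any field
#' can be overridden via \code{...}.
#'
#' @param species \code{"human"}, \code{"mouse"}, \code{"fly"} or
#'   \code{"custom"}.
#' @param seed Integer seed recorded with the run.
#' @param ... Named overrides of individual fields.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(species = c("human", "mouse", "fly", "custom"),
                       seed = 1, ...) {
  species <- match.arg(species)
  base <- switch(species,
    human = list(W = 3e5, s = 3e4, b = 2e4, w = 4e4, q = 0.98, D = 3e5,
                 n_min = 10, hi = 0.8, lo = 0.2,
                 funnel_window = 8e6, funnel_bin = 5e3),
    mouse = list(W = 3e5, s = 3e4, b = 2e4, w = 4e4, q = 0.98, D = 3e5,
                 n_min = 10, hi = 0.8, lo = 0.2,
                 funnel_window = 8e6, funnel_bin = 5e3),
    fly = list(W = 5e4, s = 5e3, b = 1e4, w = 2e4, q = 0.97, D = 5e4,
               n_min = 10, hi = 0.6, lo = 0.25,
               funnel_window = 2e6, funnel_bin = 1e3),
    custom = list(W = 3e5, s = 3e4, b = 2e4, w = 4e4, q = 0.98, D = 3e5,
                  n_min = 10, hi = 0.8, lo = 0.2,
                  funnel_window = 8e6, funnel_bin = 5e3))
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base$species <- species
  base$seed <- seed
  class(base) <- "run_config"
  base
}

#' Write the run's parameter/seed sidecar
#'
#' Every written artifact can be accompanied by a JSON sidecar recording
#' the full parameter set and seed for reproducibility.
#'
#' @param params A \code{run_config} or plain list.
#' @param path Output path (conventionally \code{<artifact>.run.json}).
#' @return \code{path}, invisibly.
#' @export
write_run_sidecar <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' GRB-centred funnel heatmap matrix
#'
#' Rows are anchors (GRBs) sorted by decreasing length; columns are
#' fixed-width bins tiling a window centred on each anchor's midpoint
#' (8 Mb window / 5 kb bins for human, 2 Mb / 1 kb for Drosophila).
#' Each cell is the mean track value over the bin; bins beyond the
#' chromosome end are NA. Features that track anchor extent form a
#' funnel shape in this matrix; the matrix is the tested artifact, any
#' image rendered from it is a by-product.
#'
#' @param track A \code{density_track}, \code{di_track} or
#'   \code{compartment_track}.
#' @param anchors Anchor \code{GRanges} (e.g. GRBs).
#' @param window Total window width in bp (default 8 Mb).
#' @param bin Column bin width in bp (default 5 kb).
#' @param file Optional path; when given the matrix is written as TSV.
#' @return Numeric matrix (anchors x bins) with anchor names as row
#'   names, ordered by decreasing anchor width; attribute \code{offsets}
#'   holds the bin-centre offsets from the anchor midpoint.
#' @export
funnel_heatmap <- function(track, anchors, window = 8e6, bin = 5e3,
                           file = NULL) {
  ord <- order(GenomicRanges::width(anchors), decreasing = TRUE)
  anchors <- anchors[ord]
  ncol_ <- ceiling(window / bin)
  offs <- (seq_len(ncol_) - 0.5) * bin - window / 2
  mat <- matrix(NA_real_, length(anchors), ncol_)
  chrs <- track_chroms(track)
  for (i in seq_along(anchors)) {
    ch <- as.character(GenomicRanges::seqnames(anchors))[i]
    if (!ch %in% names(chrs)) next
    tv <- track_values(track, ch)
    ctr <- mid0(anchors[i])
    lo <- ctr + offs - bin / 2
    hi <- ctr + offs + bin / 2
    mat[i, ] <- bin_means(tv$values, tv$binwidth, tv$chrom_len, lo, hi)
  }
  rownames(mat) <- paste0("anchor", seq_len(nrow(mat)))
  attr(mat, "offsets") <- offs
  if (!is.null(file))
    utils::write.table(mat, file, sep = "\t", quote = FALSE,
                       col.names = FALSE)
  mat
}

# bp-weighted mean of a binned track over arbitrary [lo, hi) cells
bin_means <- function(values, binwidth, chrom_len, lo, hi) {
  vapply(seq_along(lo), function(k) {
    a <- max(lo[k], 0); b <- min(hi[k], chrom_len)
    if (b <= a) return(NA_real_)
    from <- floor(a / binwidth) + 1
    to <- min(ceiling(b / binwidth), length(values))
    if (to < from) return(NA_real_)
    idx <- from:to
    seg_lo <- pmax((idx - 1) * binwidth, a)
    seg_hi <- pmin(idx * binwidth, b)
    w <- seg_hi - seg_lo
    sum(values[idx] * w, na.rm = TRUE) / sum(w[!is.na(values[idx])])
  }, numeric(1))
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Generates a synthetic genome, calls GRBs from its CNEs, simulates a
#' Hi-C matrix, computes the directionality index, calls TADs and
#' compartments, classifies TADs by GRB overlap, and computes the CTCF,
#' repeat and concordance statistics. One seed (from \code{run$seed})
#' controls every stage.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @param run A \code{\link{run_config}}; the synthetic defaults pair
#'   naturally with \code{run_config("human", b = config$binsize,
#'   w = 2 * config$binsize)}.
#' @param outdir Optional directory; when given, principal artifacts are
#'   written there (paired BED, BED, bedGraph, TSV) with a JSON sidecar.
#' @return A list with the intermediate and final objects.
#' @export
run_pipeline <- function(config = synthetic_config(),
                         run = run_config("human", b = config$binsize,
                                          w = 2 * config$binsize),
                         outdir = NULL) {
  config$seed <- run$seed
  gen <- generate_genome(config)
  cnes <- generate_cnes(gen$truth, config)
  call <- call_grbs(cnes, gen$genes, config$chrom_sizes, W = run$W,
                    s = run$s, q = run$q, D = run$D, n_min = run$n_min,
                    seed = run$seed)
  M <- generate_contact_matrix(gen$truth, config)
  di <- directionality_index(M, w = run$w)
  tads <- call_tads(di, seed = run$seed)
  tads <- classify_tads_by_grb(tads, call$grbs, hi = run$hi, lo = run$lo)
  panel <- generate_ctcf_panel(gen$truth, config)
  cons <- ctcf_consensus(panel$samples, n_samples = config$n_ctcf_samples)
  bnd <- tad_boundary_points(tads)
  enr <- if (length(cons) && length(bnd))
    ctcf_boundary_enrichment(cons, bnd) else NULL
  reps <- generate_repeats(gen$truth, config)
  funnel <- if (length(call$grbs))
    funnel_heatmap(di, call$grbs, window = run$funnel_window,
                   bin = run$funnel_bin) else NULL
  res <- list(truth = gen$truth, genes = gen$genes, cnes = cnes,
              grb_call = call, matrix = M, di = di, tads = tads,
              ctcf = cons, ctcf_enrichment = enr, repeats = reps,
              funnel = funnel, run = run)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_pairedbed(cnes, file.path(outdir, "cnes.pairedbed"))
    write_bed(call$grbs, file.path(outdir, "grbs.bed"),
              extra = c("cne_count", "query_chrom"))
    write_bed(gen$genes, file.path(outdir, "genes.bed"), extra = "type")
    write_bedgraph(di, file.path(outdir, "di.bedgraph"))
    write_bed(tads, file.path(outdir, "tads.bed"),
              extra = c("strength", "grb_class"))
    if (!is.null(funnel))
      utils::write.table(funnel, file.path(outdir, "funnel.tsv"),
                         sep = "\t", quote = FALSE, col.names = FALSE)
    write_run_sidecar(run, file.path(outdir, "run.json"))
  }
  res
}

#' Boundary points of an interval set
#'
#' Width-1 ranges at every start and end, usable as the
#' \code{boundaries} argument of \code{\link{ctcf_boundary_enrichment}}.
#'
#' @param gr A \code{GRanges}.
#' @return A \code{GRanges} of boundary points.
#' @export
tad_boundary_points <- function(gr) {
  if (length(gr) == 0) return(GenomicRanges::GRanges())
  ch <- as.character(GenomicRanges::seqnames(gr))
  sort(gr0(c(ch, ch), c(start0(gr), end0(gr) - 1),
           c(start0(gr) + 1, end0(gr))))
}
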