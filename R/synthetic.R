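#' Configuration for the synthetic genome generator
#'
#' Builds the parameter set used by all synthetic generators. Defaults
#' describe a 50 Mb chromosome carrying 10 planted GRBs of 1-2 Mb
#' (log-uniform), a 40-fold CNE density contrast between GRB interiors and
#' background (20 vs 0.5 CNEs per 100 kb), Pareto-tailed inter-CNE gaps,
#' TADs coinciding with GRBs up to 10 kb of boundary jitter, power-law
#' contact decay with a 4-fold within-domain boost and negative-binomial
#' noise, a 17-sample CTCF panel with a constitutive/specific occupancy
#' mixture concentrated at domain edges, and SINEs depleted 0.3-fold
#' inside planted domains.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp).
#' @param n_grbs Number of planted GRBs.
#' @param grb_size_min,grb_size_max GRB length range (bp); lengths are
#'   drawn log-uniformly.
#' @param cne_rate_in,cne_rate_out CNEs per 100 kb inside / outside GRBs.
#' @param gap_tail Pareto shape parameter for inter-CNE gaps.
#' @param tad_from_grb Logical; plant TAD boundaries at GRB edges.
#' @param tad_jitter Boundary jitter (bp) applied to planted TAD edges.
#' @param decay_alpha Contact distance-decay exponent.
#' @param within_tad_boost Fold-enrichment of intra-domain contacts.
#' @param noise_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param contact_base Expected count at one-bin separation, background.
#' @param binsize Hi-C bin size (bp).
#' @param n_ctcf_samples Number of CTCF samples in the panel.
#' @param n_ctcf_sites Number of distinct CTCF sites.
#' @param ctcf_constitutive_frac,ctcf_specific_frac Mixture fractions of
#'   constitutive and specific sites (remainder intermediate).
#' @param sine_rate_out Background SINE rate per 100 kb.
#' @param sine_depletion Fold-change of SINE rate inside GRBs.
#' @param gene_rate_in,gene_rate_out Background gene rates per Mb inside /
#'   outside GRBs (a target gene is always added inside each GRB, so the
#'   default 0 / 5 realises roughly an 8-fold gene-density contrast given
#'   one target gene per 1-2 Mb GRB).
#' @param seed Master seed; every generator derives its own stream from it.
#' @return An object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(chrom_sizes = c(chr1 = 50e6),
                             n_grbs = 10,
                             grb_size_min = 1e6, grb_size_max = 2e6,
                             cne_rate_in = 20, cne_rate_out = 0.5,
                             gap_tail = 2,
                             tad_from_grb = TRUE, tad_jitter = 10e3,
                             decay_alpha = 1, within_tad_boost = 4,
                             noise_dispersion = 0.1, contact_base = 100,
                             binsize = 10e3,
                             n_ctcf_samples = 17, n_ctcf_sites = 1000,
                             ctcf_constitutive_frac = 0.2,
                             ctcf_specific_frac = 0.4,
                             sine_rate_out = 50, sine_depletion = 0.3,
                             gene_rate_in = 0, gene_rate_out = 5,
                             seed = 1) {
  stopifnot(cne_rate_in > cne_rate_out,
            grb_size_min > 0, grb_size_max >= grb_size_min,
            all(chrom_sizes > 0), n_grbs >= 0,
            n_ctcf_samples >= 1, decay_alpha > 0, within_tad_boost > 0,
            noise_dispersion >= 0,
            ctcf_constitutive_frac + ctcf_specific_frac <= 1)
  if (n_grbs > 0 && max(chrom_sizes) < grb_size_max)
    stop("chromosome too small to host requested GRBs")
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic genome with planted GRBs, TADs and genes
#'
#' Places \code{n_grbs} non-overlapping GRB intervals on the configured
#' chromosomes, plants TAD boundaries at (jittered) GRB edges when
#' \code{tad_from_grb}, and lays down a gene annotation in which every GRB
#' contains one "target" gene while the inter-GRB space is gene-dense
#' relative to GRB interiors.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return A list with elements \code{genes} (a \code{GRanges} with a
#'   \code{type} column, \code{target} or \code{background}) and
#'   \code{truth} (class \code{synthetic_truth}: planted \code{grbs}
#'   \code{GRanges}, per-chromosome sorted \code{tad_boundaries}, and the
#'   config used).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(derive_seed(config$seed, 1), {
    chroms <- names(config$chrom_sizes)
    grb_list <- list()
    if (config$n_grbs > 0) {
      # assign GRBs to chromosomes proportional to size, then place each
      # chromosome's set uniformly at random without overlap
      probs <- config$chrom_sizes / sum(config$chrom_sizes)
      assign <- sample(chroms, config$n_grbs, replace = TRUE, prob = probs)
      for (ch in chroms) {
        n <- sum(assign == ch)
        if (n == 0) next
        L <- config$chrom_sizes[[ch]]
        lens <- round(exp(stats::runif(n, log(config$grb_size_min),
                                       log(config$grb_size_max))))
        if (sum(lens) >= L)
          stop("chromosome ", ch, " too small to host requested GRBs")
        starts <- place_nonoverlapping(lens, L)
        grb_list[[ch]] <- gr0(ch, starts, starts + lens)
      }
    }
    grbs <- if (length(grb_list)) sort(do.call(c, unname(grb_list)))
            else GenomicRanges::GRanges()
    if (length(grbs)) mcols(grbs)$grb_id <- seq_along(grbs)

    tad_boundaries <- lapply(chroms, function(ch) {
      if (!config$tad_from_grb || length(grbs) == 0) return(numeric(0))
      g <- grbs[GenomicRanges::seqnames(grbs) == ch]
      if (length(g) == 0) return(numeric(0))
      b <- sort(c(start0(g), end0(g)))
      b <- b + round(stats::runif(length(b), -config$tad_jitter,
                                  config$tad_jitter))
      sort(unique(pmin(pmax(b, 1), config$chrom_sizes[[ch]] - 1)))
    })
    names(tad_boundaries) <- chroms

    genes <- generate_gene_set(grbs, config)
    truth <- structure(list(grbs = grbs, tad_boundaries = tad_boundaries,
                            config = config),
                       class = "synthetic_truth")
    list(genes = genes, truth = truth)
  })
}

# Uniform non-overlapping placement of intervals of given lengths on [0, L):
# drop the lengths into uniformly-random spacings (equivalent to rejection
# sampling independent uniform starts until none overlap).
place_nonoverlapping <- function(lens, L) {
  free <- L - sum(lens)
  cuts <- sort(stats::runif(length(lens), 0, free))
  round(cuts + cumsum(c(0, lens[-length(lens)])))
}

generate_gene_set <- function(grbs, config) {
  chroms <- names(config$chrom_sizes)
  gene_width <- 20e3
  out <- list()
  for (ch in chroms) {
    L <- config$chrom_sizes[[ch]]
    g <- if (length(grbs)) grbs[GenomicRanges::seqnames(grbs) == ch]
         else GenomicRanges::GRanges()
    # one guaranteed target gene per GRB, centred in it
    if (length(g)) {
      ctr <- mid0(g)
      out[[paste0(ch, "_t")]] <- gr0(ch, pmax(ctr - gene_width / 2, 0),
                                     pmin(ctr + gene_width / 2, L),
                                     type = "target")
    }
    # background genes: sparse inside GRBs, dense outside
    inside_bp <- if (length(g)) sum(GenomicRanges::width(g)) else 0
    n_in <- stats::rpois(1, config$gene_rate_in * inside_bp / 1e6)
    n_out <- stats::rpois(1, config$gene_rate_out * (L - inside_bp) / 1e6)
    pos_in <- sample_positions_in(g, n_in)
    pos_out <- sample_positions_out(g, L, n_out)
    pos <- c(pos_in, pos_out)
    if (length(pos)) {
      s <- pmax(pos - gene_width / 2, 0)
      out[[paste0(ch, "_b")]] <- gr0(ch, s, pmin(s + gene_width, L),
                                     type = "background")
    }
  }
  genes <- if (length(out)) sort(do.call(c, unname(out)))
           else GenomicRanges::GRanges()
  if (length(genes)) mcols(genes)$gene_id <- seq_along(genes)
  genes
}

sample_positions_in <- function(gr, n) {
  if (n == 0 || length(gr) == 0) return(numeric(0))
  w <- GenomicRanges::width(gr)
  pick <- sample(length(gr), n, replace = TRUE, prob = w)
  floor(start0(gr)[pick] + stats::runif(n) * w[pick])
}

sample_positions_out <- function(gr, L, n) {
  if (n == 0) return(numeric(0))
  if (length(gr) == 0) return(floor(stats::runif(n, 0, L)))
  gaps <- setdiff_segments(gr, L)
  if (nrow(gaps) == 0) return(numeric(0))
  w <- gaps$end - gaps$start
  pick <- sample(nrow(gaps), n, replace = TRUE, prob = w)
  floor(gaps$start[pick] + stats::runif(n) * w[pick])
}

# complement of gr within [0, L) as a data.frame of 0-based segments
setdiff_segments <- function(gr, L) {
  if (length(gr) == 0) return(data.frame(start = 0, end = L))
  r <- IRanges::reduce(GenomicRanges::ranges(gr))
  s <- c(0, IRanges::end(r))
  e <- c(IRanges::start(r) - 1, L)
  keep <- e > s
  data.frame(start = s[keep], end = e[keep])
}

#' Generate CNEs with planted clustering and synteny
#'
#' CNE counts inside each planted GRB are Poisson with mean
#' \code{cne_rate_in * len / 100kb} (background: \code{cne_rate_out});
#' inter-CNE gaps inside GRBs follow a Pareto law with shape
#' \code{gap_tail}. Each CNE carries a query-genome interval; all CNEs of
#' one GRB share one query chromosome with preserved order (synteny),
#' while background CNEs scatter across decoy query chromosomes.
#'
#' @param truth A \code{synthetic_truth} from \code{\link{generate_genome}}.
#' @param config The \code{\link{synthetic_config}} used to build it.
#' @return A \code{GRanges} of CNEs with metadata columns
#'   \code{query_chrom}, \code{query_start}, \code{query_end} (0-based
#'   half-open), \code{identity} and \code{grb_id} (0 = background).
#' @export
generate_cnes <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(derive_seed(config$seed, 2), {
    pieces <- list()
    grbs <- truth$grbs
    for (i in seq_along(grbs)) {
      g <- grbs[i]
      ch <- as.character(GenomicRanges::seqnames(g))
      n <- stats::rpois(1, config$cne_rate_in * GenomicRanges::width(g) / 1e5)
      if (n == 0) next
      cne <- lay_cnes(start0(g), end0(g), n, config$gap_tail)
      qscale <- stats::runif(1, 0.8, 1.2)
      qoff <- floor(stats::runif(1, 0, 1e6))
      pieces[[length(pieces) + 1]] <- gr0(
        ch, cne$start, cne$end,
        query_chrom = paste0("chrQ", i),
        query_start = qoff + round((cne$start - start0(g)) * qscale),
        query_end = qoff + round((cne$start - start0(g)) * qscale) +
          (cne$end - cne$start),
        identity = stats::runif(n, 0.7, 1),
        grb_id = i)
    }
    # background CNEs in inter-GRB space
    for (ch in names(config$chrom_sizes)) {
      L <- config$chrom_sizes[[ch]]
      g <- if (length(grbs)) grbs[GenomicRanges::seqnames(grbs) == ch]
           else GenomicRanges::GRanges()
      segs <- setdiff_segments(g, L)
      for (j in seq_len(nrow(segs))) {
        len <- segs$end[j] - segs$start[j]
        n <- stats::rpois(1, config$cne_rate_out * len / 1e5)
        if (n == 0) next
        s <- sort(floor(segs$start[j] + stats::runif(n) * max(len - 600, 1)))
        w <- pmax(50, round(50 + stats::rexp(n, 1 / 100)))
        w <- pmin(w, pmax(segs$end[j] - s, 50))
        pieces[[length(pieces) + 1]] <- gr0(
          ch, s, s + w,
          query_chrom = paste0("chrQbg", sample(5, n, replace = TRUE)),
          query_start = floor(stats::runif(n, 0, 1e7)),
          query_end = floor(stats::runif(n, 0, 1e7)) + w,
          identity = stats::runif(n, 0.7, 1),
          grb_id = 0L)
      }
    }
    if (length(pieces) == 0) return(GenomicRanges::GRanges())
    sort(do.call(c, unname(pieces)))
  })
}

# place n ordered CNEs within [a, b) with Pareto(shape) gaps
lay_cnes <- function(a, b, n, shape) {
  w <- pmax(50, round(50 + stats::rexp(n, 1 / 100)))
  gaps <- (stats::runif(n + 1))^(-1 / shape) # Pareto(xm=1, shape)
  free <- max((b - a) - sum(w), n + 1)
  offs <- floor(cumsum(gaps[seq_len(n)]) / sum(gaps) * free)
  start <- a + offs + cumsum(c(0, w[-n]))
  list(start = start, end = start + w)
}

#' Generate a synthetic Hi-C contact matrix with planted domains
#'
#' Expected counts follow a power-law distance decay
#' \code{base * |i-j|^(-alpha)} multiplied by \code{within_tad_boost} when
#' bins i and j fall in the same planted domain; counts are sampled
#' negative-binomially with the configured dispersion (Poisson when
#' dispersion is 0) and symmetrised by construction.
#'
#' @param truth A \code{synthetic_truth} with planted TAD boundaries.
#' @param config The generating \code{\link{synthetic_config}}.
#' @param chrom Chromosome to simulate (default: first configured).
#' @return A \code{\link{contact_matrix}}.
#' @export
generate_contact_matrix <- function(truth, config = truth$config,
                                    chrom = names(config$chrom_sizes)[1]) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(derive_seed(config$seed, 3), {
    L <- config$chrom_sizes[[chrom]]
    b <- config$binsize
    n <- ceiling(L / b)
    bnd <- truth$tad_boundaries[[chrom]] %||% numeric(0)
    dom <- findInterval((seq_len(n) - 0.5) * b, bnd)
    i <- rep(seq_len(n), times = n)
    j <- rep(seq_len(n), each = n)
    up <- i <= j
    iu <- i[up]; ju <- j[up]
    d <- pmax(ju - iu, 1)
    mu <- config$contact_base * d^(-config$decay_alpha)
    mu <- mu * ifelse(dom[iu] == dom[ju], config$within_tad_boost, 1)
    cnt <- if (config$noise_dispersion <= 0) stats::rpois(length(mu), mu)
           else stats::rnbinom(length(mu), mu = mu,
                               size = 1 / config$noise_dispersion)
    M <- matrix(0, n, n)
    M[cbind(iu, ju)] <- cnt
    M[cbind(ju, iu)] <- cnt
    contact_matrix(M, chrom = chrom, binsize = b, chrom_len = L)
  })
}

#' Generate a multi-sample CTCF peak panel
#'
#' Sites are a mixture of constitutive (occupancy N-1 or N of N samples,
#' placed within 10 kb of planted domain edges), specific (occupancy 1-2,
#' uniform) and intermediate sites. Each carrying sample receives a 400 bp
#' peak jittered by less than 100 bp around the site summit.
#'
#' @param truth A \code{synthetic_truth}.
#' @param config The generating \code{\link{synthetic_config}}.
#' @return A list with \code{samples} (list of per-sample peak
#'   \code{GRanges}) and \code{sites} (site truth \code{GRanges} with
#'   \code{occupancy} and \code{category}).
#' @export
generate_ctcf_panel <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(derive_seed(config$seed, 4), {
    N <- config$n_ctcf_samples
    ns <- config$n_ctcf_sites
    cat <- sample(c("constitutive", "specific", "intermediate"), ns,
                  replace = TRUE,
                  prob = c(config$ctcf_constitutive_frac,
                           config$ctcf_specific_frac,
                           1 - config$ctcf_constitutive_frac -
                             config$ctcf_specific_frac))
    occ <- integer(ns)
    occ[cat == "constitutive"] <- sample(c(N - 1, N),
                                         sum(cat == "constitutive"),
                                         replace = TRUE)
    occ[cat == "specific"] <- sample(1:2, sum(cat == "specific"),
                                     replace = TRUE)
    occ[cat == "intermediate"] <- if (N > 4)
      sample(3:(N - 2), sum(cat == "intermediate"), replace = TRUE)
      else rep(1L, sum(cat == "intermediate"))
    occ <- pmin(pmax(occ, 1L), N)

    edges <- unlist(lapply(names(truth$tad_boundaries), function(ch)
      truth$tad_boundaries[[ch]]), use.names = FALSE)
    edge_chrom <- rep(names(truth$tad_boundaries),
                      lengths(truth$tad_boundaries))
    pos <- numeric(ns); chrom <- character(ns)
    chroms <- names(config$chrom_sizes)
    for (k in seq_len(ns)) {
      if (cat[k] == "constitutive" && length(edges) > 0) {
        e <- sample(length(edges), 1)
        chrom[k] <- edge_chrom[e]
        pos[k] <- edges[e] + round(stats::runif(1, -1e4, 1e4))
      } else {
        chrom[k] <- sample(chroms, 1, prob = config$chrom_sizes)
        pos[k] <- floor(stats::runif(1, 0, config$chrom_sizes[[chrom[k]]]))
      }
      pos[k] <- min(max(pos[k], 300), config$chrom_sizes[[chrom[k]]] - 300)
    }
    sites <- gr0(chrom, pos - 200, pos + 200, occupancy = occ,
                 category = cat)

    samples <- vector("list", N)
    carrier <- lapply(occ, function(o) sample(N, o))
    for (s in seq_len(N)) {
      idx <- which(vapply(carrier, function(cs) s %in% cs, logical(1)))
      if (length(idx) == 0) {
        samples[[s]] <- GenomicRanges::GRanges()
        next
      }
      ctr <- pos[idx] + round(stats::runif(length(idx), -99, 99))
      samples[[s]] <- sort(gr0(chrom[idx], ctr - 200, ctr + 200))
    }
    names(samples) <- paste0("sample", seq_len(N))
    list(samples = samples, sites = sites)
  })
}

#' Generate repeat annotations with SINE depletion inside planted GRBs
#'
#' SINE density inside planted GRBs equals \code{sine_depletion} times the
#' background density; LINE, LTR and DNA elements are uniform genome-wide.
#'
#' @param truth A \code{synthetic_truth}.
#' @param config The generating \code{\link{synthetic_config}}.
#' @return A \code{GRanges} with a \code{class} metadata column
#'   (\code{SINE}, \code{LINE}, \code{LTR}, \code{DNA}).
#' @export
generate_repeats <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed(derive_seed(config$seed, 5), {
    pieces <- list()
    widths <- c(SINE = 300, LINE = 1000, LTR = 500, DNA = 400)
    for (ch in names(config$chrom_sizes)) {
      L <- config$chrom_sizes[[ch]]
      g <- if (length(truth$grbs))
        truth$grbs[GenomicRanges::seqnames(truth$grbs) == ch]
        else GenomicRanges::GRanges()
      inside_bp <- if (length(g)) sum(GenomicRanges::width(g)) else 0
      # SINEs: depleted inside
      n_in <- stats::rpois(1, config$sine_rate_out * config$sine_depletion *
                                inside_bp / 1e5)
      n_out <- stats::rpois(1, config$sine_rate_out *
                                 (L - inside_bp) / 1e5)
      p <- c(sample_positions_in(g, n_in),
             sample_positions_out(g, L, n_out))
      if (length(p))
        pieces[[paste0(ch, "_SINE")]] <- gr0(ch, pmax(p - 150, 0),
                                             pmin(p + 150, L),
                                             class = "SINE")
      # other classes: uniform
      for (cl in c("LINE", "LTR", "DNA")) {
        n <- stats::rpois(1, 20 * L / 1e5)
        if (n == 0) next
        p <- floor(stats::runif(n, 0, L))
        hw <- widths[[cl]] / 2
        pieces[[paste0(ch, "_", cl)]] <- gr0(ch, pmax(p - hw, 0),
                                             pmin(p + hw, L), class = cl)
      }
    }
    if (length(pieces) == 0) return(GenomicRanges::GRanges())
    sort(do.call(c, unname(pieces)))
  })
}
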