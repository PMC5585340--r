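# Independent brute-force oracles used across the suite.

suppressPackageStartupMessages(library(GenomicRanges))

# exhaustive Viterbi: maximise over all k^T state paths
oracle_viterbi <- function(obs, means, vars, trans, init) {
  T_ <- length(obs); k <- length(means)
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), T_)))
  score <- apply(paths, 1, function(p) {
    s <- log(init[p[1]]) + dnorm(obs[1], means[p[1]], sqrt(vars[p[1]]),
                                 log = TRUE)
    for (t in seq_len(T_ - 1)) {
      s <- s + log(trans[p[t], p[t + 1]]) +
        dnorm(obs[t + 1], means[p[t + 1]], sqrt(vars[p[t + 1]]),
              log = TRUE)
    }
    s
  })
  unname(paths[which.max(score), ])
}

# brute-force qualifying-window scan of one alignment block: returns the
# merged column runs of all length-L windows with identity >= I
oracle_window_runs <- function(ref_aln, query_aln, I, L) {
  rc <- strsplit(toupper(ref_aln), "")[[1]]
  qc <- strsplit(toupper(query_aln), "")[[1]]
  m <- (rc == qc) & rc != "-" & qc != "-"
  n <- length(m)
  if (n < L) return(NULL)
  covered <- rep(FALSE, n)
  for (s in 1:(n - L + 1))
    if (sum(m[s:(s + L - 1)]) / L >= I - 1e-9)
      covered[s:(s + L - 1)] <- TRUE
  if (!any(covered)) return(NULL)
  r <- rle(covered)
  to <- cumsum(r$lengths); from <- to - r$lengths + 1
  cbind(from = from[r$values], to = to[r$values])
}

# per-window union coverage of CNEs, by direct interval intersection
oracle_density <- function(cnes, chrom, len, W, s) {
  nwin <- ceiling(len / s)
  ctr <- (seq_len(nwin) - 0.5) * s
  lo <- pmax(ctr - W / 2, 0); hi <- pmin(ctr + W / 2, len)
  r <- reduce(ranges(cnes[seqnames(cnes) == chrom]))
  vapply(seq_len(nwin), function(k) {
    win <- IRanges(lo[k] + 1, hi[k])
    100 * sum(width(intersect(r, win))) / (hi[k] - lo[k])
  }, numeric(1))
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
oracle_fisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  supp <- max(0, k - n):min(m, k)
  probs <- dhyper(supp, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided binomial p by enumeration (sum of outcomes no more likely
# than the observed one)
oracle_binom <- function(x, n, p0) {
  probs <- dbinom(0:n, n, p0)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# 0-based half-open GRanges shorthand for fixtures
g0 <- function(chrom, start0, end0, ...) {
  if (length(start0) == 0) return(GRanges())
  GRanges(chrom, IRanges(start0 + 1, end0), ...)
}

# small CNE set with query metadata for grb-module fixtures
toy_cnes <- function(starts, width = 100, chrom = "chr1",
                     query_chrom = "chrQ1") {
  if (length(starts) == 0) {
    gr <- GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      query_chrom = character(0), query_start = numeric(0),
      query_end = numeric(0), identity = numeric(0))
    return(gr)
  }
  g0(chrom, starts, starts + width,
     query_chrom = rep_len(query_chrom, length(starts)),
     query_start = starts, query_end = starts + width,
     identity = rep(0.9, length(starts)))
}
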