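# Internal helpers shared across modules.

# GRanges from 0-based half-open coordinates.
gr0 <- function(chrom, start0, end0, ...) {
  stopifnot(all(end0 >= start0))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L,
                                                 end = end0), ...)
}

# 0-based half-open start/end from a GRanges.
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)

# Midpoint (bp, 0-based) of a GRanges.
mid0 <- function(gr) floor((start0(gr) + end0(gr)) / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seeds derived from one master seed (kept < 2^31).
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 1024 * k) %% 2147483629
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483629))
  force(expr)
}

# Add-one empirical p-value from permutation/randomisation counts.
addone_p <- function(n_ge, n_draws) (1 + n_ge) / (1 + n_draws)
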