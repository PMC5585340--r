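test_that("segment decoding labels the higher-mean state as enriched", {
  sizes <- c(chr1 = 1e6)
  set.seed(12)
  cnes <- toy_cnes(sort(c(sample(100000:300000, 60),
                          sample(700000:900000, 60))), width = 500)
  track <- smooth_density(cnes, sizes, W = 5e4, s = 5e3)
  model <- fit_hmm(track, restarts = 5, seed = 4)
  seg <- decode_segments(model, track)
  expect_true(all(mcols(seg)$state %in% c("enriched", "background")))
  # tiles the chromosome without overlap
  expect_equal(sum(width(seg)), 1e6)
  expect_length(findOverlaps(seg, drop.self = TRUE), 0)

  # relabeling invariance: swapping the two states changes nothing
  swapped <- model
  swapped$means <- rev(model$means)
  swapped$vars <- rev(model$vars)
  swapped$trans <- model$trans[2:1, 2:1]
  swapped$init <- rev(model$init)
  expect_identical(decode_segments(swapped, track), seg)

  # degenerate flat track -> everything background
  flat <- smooth_density(GRanges(), sizes, W = 5e4, s = 5e3)
  mflat <- fit_hmm(flat, seed = 1)
  expect_true(mflat$degenerate)
  segflat <- decode_segments(mflat, flat)
  expect_true(all(mcols(segflat)$state == "background"))
  expect_length(filter_to_enriched(cnes, segflat), 0)
})

test_that("enriched-CNE filtering follows the midpoint rule", {
  seg <- c(g0("chr1", 0, 1000, state = "background"),
           g0("chr1", 1000, 2000, state = "enriched"),
           g0("chr1", 2000, 3000, state = "background"))
  # straddles the boundary, midpoint at 1050 -> inside enriched
  straddle <- toy_cnes(900, width = 300)
  expect_length(filter_to_enriched(straddle, seg), 1)
  # midpoint at 950 -> outside
  outside <- toy_cnes(900, width = 100)
  expect_length(filter_to_enriched(outside, seg), 0)

  set.seed(3)
  mixed <- toy_cnes(sample(0:2900, 50), width = 80)
  kept <- filter_to_enriched(mixed, seg)
  mids <- floor((start(mixed) - 1 + end(mixed)) / 2)
  expect_identical(kept, mixed[mids >= 1000 & mids < 2000])
})

test_that("gap-quantile splitting uses type-7 quantiles, strict splits", {
  # equal gaps: threshold equals the gaps, no strict exceedance
  cnes <- toy_cnes(c(0, 110, 220, 330, 440), width = 100)
  r <- split_by_gaps(cnes, q = 0.5)
  expect_equal(length(unique(r$region)), 1)

  # gaps 1,2,3,1000 at q=0.5: type-7 threshold 2.5 -> split at 3 and 1000
  starts <- c(0, 101, 203, 306, 1406)
  cnes <- toy_cnes(starts, width = 100)
  r <- split_by_gaps(cnes, q = 0.5)
  expect_equal(length(unique(r$region)), 3)
  expect_equal(as.integer(table(r$region)), c(3L, 1L, 1L))

  # q -> 1 limit: threshold is the maximum gap, strict splits -> one region
  r1 <- split_by_gaps(cnes, q = 1)
  expect_equal(length(unique(r1$region)), 1)
  # spans cover member CNEs
  sp <- region_spans(r1)
  expect_equal(start(sp) - 1, 0)
  expect_equal(end(sp), 1506)
})

test_that("synteny splitting uses maximal runs of query chromosomes", {
  cnes <- toy_cnes(c(0, 200, 400, 600), width = 100,
                   query_chrom = c("A", "A", "B", "B"))
  r <- split_by_query_chrom(split_by_gaps(cnes, q = 0.99))
  expect_equal(length(unique(r$region)), 2)

  cnes3 <- toy_cnes(c(0, 200, 400), width = 100,
                    query_chrom = c("A", "B", "A"))
  r3 <- split_by_query_chrom(split_by_gaps(cnes3, q = 0.99))
  expect_equal(length(unique(r3$region)), 3)

  one <- split_by_gaps(toy_cnes(c(0, 200), width = 100), q = 0.9)
  expect_equal(split_by_query_chrom(one)$region, one$region)
})

test_that("merge/filter follows the gene and CNE-count rules", {
  # 12 CNEs in a gene-bearing cluster, 3 CNEs in a gene-less cluster
  # 200 kb away: gene-less cluster merges in at D = 300 kb
  starts <- c(seq(0, 11000, by = 1000), 211100 + c(0, 500, 1000))
  cnes <- toy_cnes(starts, width = 100)
  regions <- split_by_gaps(cnes, q = 0.9)
  expect_equal(length(unique(regions$region)), 2)
  genes <- g0("chr1", 5000, 7000)
  merged <- merge_and_filter(regions, genes, D = 3e5, n_min = 10)
  expect_length(merged, 1)
  expect_equal(merged$cne_count, 15)
  expect_equal(end(merged), 211100 + 1100)
  # at D = 100 kb the gene-less cluster is out of reach and discarded
  strict <- merge_and_filter(regions, genes, D = 1e5, n_min = 10)
  expect_length(strict, 1)
  expect_equal(strict$cne_count, 12)

  # a region with 9 CNEs and a gene is discarded (< n_min)
  nine <- split_by_gaps(toy_cnes(seq(0, 8000, by = 1000)), q = 0.9)
  expect_length(merge_and_filter(nine, g0("chr1", 0, 2000), n_min = 10), 0)

  # two gene-bearing regions 200 kb apart are NOT merged
  two <- toy_cnes(c(seq(0, 10000, by = 1000), seq(210000, 220000, by = 1000)))
  regions2 <- split_by_gaps(two, q = 0.9)
  genes2 <- g0("chr1", c(2000, 212000), c(4000, 214000))
  out <- merge_and_filter(regions2, genes2, D = 3e5, n_min = 10)
  expect_length(out, 2)
})

test_that("call_grbs recovers planted GRBs and scales with coordinates", {
  expect_length(call_grbs(toy_cnes(numeric(0)), GRanges(),
                          c(chr1 = 1e6))$grbs, 0)

  cfg <- synthetic_config(chrom_sizes = c(chr1 = 20e6), n_grbs = 4,
                          seed = 7)
  gen <- generate_genome(cfg)
  cnes <- generate_cnes(gen$truth)
  call <- call_grbs(cnes, gen$genes, cfg$chrom_sizes, seed = 3)
  g <- call$grbs
  expect_true(all(g$cne_count >= 10))
  expect_true(all(g$contains_gene))
  expect_length(findOverlaps(g, drop.self = TRUE), 0)
  expect_false(is.unsorted(start(g)))
  # stage log is monotone over the filter stages
  expect_lte(call$log$cnes_in_enriched, call$log$input_cnes)
  # every planted GRB is hit by a call and edges are near truth
  truth <- gen$truth$grbs
  d <- vapply(seq_along(truth), function(i) {
    hits <- g[overlapsAny(g, truth[i])]
    if (length(hits) == 0) return(Inf)
    min(pmax(abs(start(hits) - start(truth[i])),
             abs(end(hits) - end(truth[i]))))
  }, numeric(1))
  expect_gte(mean(d <= 3e5), 0.75)

  # genome stretch: doubling coordinates with W, s, D doubled doubles spans
  sizes <- c(chr1 = 2e6)
  set.seed(44)
  base <- sort(c(sample(200000:500000, 40), sample(1200000:1500000, 40)))
  cnes1 <- toy_cnes(base, width = 200)
  cnes2 <- toy_cnes(base * 2, width = 400)
  genes1 <- g0("chr1", c(300000, 1300000), c(320000, 1320000))
  genes2 <- g0("chr1", 2 * c(300000, 1300000), 2 * c(320000, 1320000))
  c1 <- call_grbs(cnes1, genes1, sizes, W = 1e5, s = 1e4, q = 0.98,
                  D = 1e5, n_min = 10, seed = 6)
  c2 <- call_grbs(cnes2, genes2, sizes * 2, W = 2e5, s = 2e4, q = 0.98,
                  D = 2e5, n_min = 10, seed = 6)
  expect_equal(start(c2$grbs) - 1, 2 * (start(c1$grbs) - 1))
  expect_equal(end(c2$grbs), 2 * end(c1$grbs))
})
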