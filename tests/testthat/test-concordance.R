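test_that("TAD labels partition by the overlap thresholds", {
  grbs <- c(g0("chr1", 100e3, 185e3), g0("chr1", 300e3, 400e3),
            g0("chr1", 500e3, 515e3))
  tads <- c(g0("chr1", 100e3, 200e3),   # 85% covered by one GRB
            g0("chr1", 200e3, 300e3),   # 0% covered
            g0("chr1", 440e3, 540e3),   # 15% covered, below the 20% bar
            g0("chr1", 350e3, 530e3))   # overlaps two GRBs
  tads <- classify_tads_by_grb(tads, grbs, hi = 0.8, lo = 0.2)
  expect_equal(tads$grb_class[1], "GRB")
  expect_equal(tads$grb_class[2], "nonGRB")
  expect_equal(tads$grb_class[3], "nonGRB")
  expect_equal(tads$grb_class[4], "screened")
  expect_equal(tads$grb_overlap_frac[1], 0.85)
  expect_equal(sort(unique(tads$grb_class)),
               sort(unique(c("GRB", "nonGRB", "screened"))))
  expect_length(tads$grb_class, 4)
})

test_that("boundary distances match a brute-force scan", {
  grbs <- g0("chr1", 100e3, 900e3)
  tads <- g0("chr1", 80e3, 950e3)
  d <- boundary_distances(grbs, tads)
  expect_equal(d$start_dist, 20e3)
  expect_equal(d$end_dist, 50e3)

  expect_equal(boundary_distances(tads, tads)$start_dist, 0)

  set.seed(8)
  gs <- sort(sample(0:1e6, 20))
  ts <- sort(sample(0:1e6, 15))
  G <- g0("chr1", gs, gs + 5e4)
  T_ <- g0("chr1", ts, ts + 4e4)
  d <- boundary_distances(G, T_)
  brute_s <- vapply(start(G) - 1, function(p) min(abs(p - (start(T_) - 1))),
                    numeric(1))
  brute_e <- vapply(end(G), function(p) min(abs(p - end(T_))), numeric(1))
  expect_equal(d$start_dist, brute_s)
  expect_equal(d$end_dist, brute_e)

  be <- both_edges_within(G, T_, X = 2e4)
  expect_equal(be$count, sum(brute_s <= 2e4 & brute_e <= 2e4))
  expect_equal(both_edges_within(G, T_, X = 0)$count,
               sum(brute_s == 0 & brute_e == 0))
  expect_equal(both_edges_within(G, G, X = 0)$fraction, 1.0)
})

test_that("concordance p-value attains its add-one bounds", {
  sizes <- c(chr1 = 10e6)
  tads <- g0("chr1", seq(0, 9e6, by = 1e6), seq(0, 9e6, by = 1e6) + 8e5)
  # perfect concordance: GRBs identical to TADs
  res <- concordance_pvalue(tads, tads, X = 0, sizes, n_rand = 500,
                            seed = 3)
  expect_equal(res$p, 1 / 501)
  # impossible concordance: X smaller than any achievable distance gives
  # observed 0 and p near 1
  far <- g0("chr2", 0, 1e5)
  res0 <- concordance_pvalue(far, tads, X = 10,
                             c(sizes, chr2 = 1e6), n_rand = 99,
                             seed = 3)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p, 1)
})

test_that("permutation median test saturates and bounds correctly", {
  set.seed(2)
  a <- rnorm(200); b <- rnorm(200, 5) # 5 SD shift
  res <- permutation_test_median(a, b, n_perm = 1e4, seed = 7)
  expect_equal(res$p, 1 / (1e4 + 1))
  expect_equal(res$statistic, abs(median(a) - median(b)))

  same <- permutation_test_median(a, a, n_perm = 2000, seed = 7)
  expect_gte(same$p, 1 / 2001)
  expect_gt(same$p, 0.5) # identical groups: statistic 0 is never beaten
  # determinism
  expect_identical(permutation_test_median(a, b, 500, seed = 9),
                   permutation_test_median(a, b, 500, seed = 9))
})

test_that("Fisher test matches exhaustive hypergeometric enumeration", {
  tab <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  labels <- matrix("A", 20, 2)
  labels[1:10, 2] <- "B" # first 10 switch
  cls <- rep(c("GRB", "nonGRB"), each = 10)
  res <- compartment_switch_test(labels, cls)
  expect_equal(unname(as.vector(res$table)), c(10, 0, 0, 10))
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(res$p, oracle_fisher(tab), tolerance = 1e-12)

  # no switches anywhere -> degenerate table, p = 1
  none <- compartment_switch_test(matrix("A", 6, 3),
                                  rep(c("GRB", "nonGRB"), 3))
  expect_equal(none$p, 1)

  # random tables with margins <= 30 agree with enumeration
  set.seed(11)
  for (i in 1:20) {
    t2 <- matrix(rpois(4, 5), 2)
    if (sum(t2[, 1]) == 0 || sum(t2[, 2]) == 0) next
    expect_equal(fisher.test(t2)$p.value, oracle_fisher(t2),
                 tolerance = 1e-9)
  }
})

test_that("CTCF consensus merges staggered peaks and scores occupancy", {
  one <- ctcf_consensus(list(g0("chr1", 1000, 1400)), width = 400,
                        n_samples = 17)
  expect_equal(one$occupancy, 1)
  expect_equal(one$category, "specific")

  same <- ctcf_consensus(rep(list(g0("chr1", 1000, 1400)), 17),
                         width = 400)
  expect_length(same, 1)
  expect_equal(same$occupancy, 17)
  expect_equal(same$category, "constitutive")

  staggered <- lapply(0:4, function(k) g0("chr1", 1000 + 300 * k,
                                          1000 + 300 * k + 380))
  cons <- ctcf_consensus(staggered, width = 400, n_samples = 17)
  expect_length(cons, 1)
  expect_equal(cons$occupancy, 5)
  expect_equal(width(cons), 400 + 4 * 300)

  # category rule over the full occupancy range, N = 17
  occ <- 1:17
  expect_equal(ctcf_category(occ, 17),
               c("specific", "specific", rep("intermediate", 13),
                 "constitutive", "constitutive"))
})

test_that("boundary enrichment matches the closed-form binomial", {
  # 250 consensus peaks: 50 constitutive, 200 elsewhere-category
  cons <- g0("chr1", seq(0, 249) * 1e4, seq(0, 249) * 1e4 + 400)
  cons$occupancy <- c(rep(17, 50), rep(5, 200))
  cons$category <- ctcf_category(cons$occupancy, 17)
  # boundaries sit exactly at the 50 constitutive peaks
  bnd <- g0("chr1", seq(0, 49) * 1e4, seq(0, 49) * 1e4 + 1)
  res <- ctcf_boundary_enrichment(cons, bnd, d = 1000)
  cst <- res[res$category == "constitutive", ]
  expect_equal(cst$n_assigned, 50)
  expect_equal(cst$fold, (50 / 50) / (50 / 250)) # = 5
  expect_equal(cst$p, oracle_binom(50, 50, 0.2), tolerance = 1e-12)

  # no assigned peaks -> empty result
  none <- ctcf_boundary_enrichment(cons, g0("chr1", 5e6, 5e6 + 1),
                                   d = 100)
  expect_equal(nrow(none), 0)

  sweep <- ctcf_enrichment_sweep(cons, bnd, distances = c(1e3, 2e3))
  expect_equal(sort(unique(sweep$d)), c(1e3, 2e3))
})

test_that("feature profiles count windows on the anchor-relative scale", {
  anchor <- g0("chr1", 100e3, 200e3)
  # features only inside the anchor
  inside <- g0("chr1", seq(110e3, 190e3, by = 5e3),
               seq(110e3, 190e3, by = 5e3) + 100)
  pr <- feature_profile(inside, anchor, window = 4e3, nbins = 61)
  expect_true(all(pr$profile[, pr$rel > 0.1 & pr$rel < 0.9] > 0))
  expect_true(all(pr$profile[, pr$rel < -0.1 | pr$rel > 1.1] == 0))

  # hand-counted single window: features at 149.2-150.8 kb around centre
  feats <- g0("chr1", c(149200, 149900, 150700), c(149300, 150000, 150800))
  pr2 <- feature_profile(feats, anchor, window = 2e3, nbins = 7)
  # rel = 0.5 -> x = 150 kb, window [149e3, 151e3) catches all 3 midpoints
  expect_equal(pr2$profile[1, pr2$rel == 0.5], 3)
  expect_equal(sum(pr2$profile[1, pr2$rel %in% c(-1, 2)]), 0)
})

test_that("homologous spans and size scaling behave as specified", {
  # one CNE from an aberrant query chromosome is excluded from the span
  sp <- homologous_span(c("q1", "q1", "q2", "q1"),
                        c(100, 500, 90000, 900), c(200, 600, 91000, 1000))
  expect_equal(sp$chrom, "q1")
  expect_equal(sp$size, 1000 - 100)

  sizes <- cbind(human = c(1e6, 2e6, 3e6), other = c(1e6, 2e6, 3e6))
  sc <- grb_size_scaling(sizes)
  expect_equal(unname(sc$median_ratio["human", "other"]), 1.0)
  expect_equal(unname(sc$slope["other"]), 1.0)

  half <- cbind(a = c(1e6, 2e6, 4e6), b = c(5e5, 1e6, 2e6))
  sc2 <- grb_size_scaling(half)
  expect_equal(unname(sc2$median_ratio["a", "b"]), 0.5)
  expect_equal(unname(sc2$slope["b"]), 0.5)
})
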