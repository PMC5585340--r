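test_that("generators are deterministic under a fixed seed", {
  cfg <- synthetic_config(chrom_sizes = c(chr1 = 10e6), n_grbs = 3,
                          grb_size_min = 5e5, grb_size_max = 1e6,
                          n_ctcf_sites = 100, seed = 42)
  a <- generate_genome(cfg); b <- generate_genome(cfg)
  expect_identical(a$truth$grbs, b$truth$grbs)
  expect_identical(a$truth$tad_boundaries, b$truth$tad_boundaries)
  expect_identical(a$genes, b$genes)
  expect_identical(generate_cnes(a$truth), generate_cnes(b$truth))
  expect_identical(generate_contact_matrix(a$truth)$counts,
                   generate_contact_matrix(b$truth)$counts)
  expect_identical(generate_ctcf_panel(a$truth)$sites,
                   generate_ctcf_panel(b$truth)$sites)
  expect_identical(generate_repeats(a$truth), generate_repeats(b$truth))
})

test_that("planted GRBs respect bounds and the empty-plant case", {
  cfg0 <- synthetic_config(chrom_sizes = c(chr1 = 5e6), n_grbs = 0,
                           grb_size_min = 4e5, grb_size_max = 5e5,
                           seed = 1)
  gen0 <- generate_genome(cfg0)
  expect_length(gen0$truth$grbs, 0)
  expect_gt(length(gen0$genes), 0)

  cfg <- synthetic_config(chrom_sizes = c(chr1 = 3e6), n_grbs = 2,
                          grb_size_min = 5e5, grb_size_max = 5e5,
                          seed = 3)
  g <- generate_genome(cfg)$truth$grbs
  expect_length(g, 2)
  expect_true(all(start(g) >= 1 & end(g) <= 3e6))
  expect_length(findOverlaps(g, drop.self = TRUE), 0)
  expect_true(all(width(g) == 5e5))
  # every planted TAD boundary sits within jitter of a planted GRB edge
  bnd <- generate_genome(cfg)$truth$tad_boundaries$chr1
  edges <- sort(c(start(g) - 1, end(g)))
  expect_true(all(vapply(bnd, function(b) min(abs(b - edges)),
                         numeric(1)) <= cfg$tad_jitter))
  expect_error(synthetic_config(chrom_sizes = c(chr1 = 1e5), n_grbs = 1,
                                grb_size_min = 2e5, grb_size_max = 2e5),
               "too small")
})

test_that("CNE counts follow the planted Poisson rates and synteny", {
  cfg <- synthetic_config(chrom_sizes = c(chr1 = 6e6), n_grbs = 2,
                          grb_size_min = 1e6, grb_size_max = 1e6,
                          cne_rate_in = 20, cne_rate_out = 0,
                          seed = 9)
  gen <- generate_genome(cfg)
  cnes <- generate_cnes(gen$truth)
  expect_true(all(overlapsAny(cnes, gen$truth$grbs)))

  # distinct query chromosomes per GRB (synteny contract)
  hit <- findOverlaps(cnes, gen$truth$grbs)
  qc_by_grb <- split(cnes$query_chrom[queryHits(hit)], subjectHits(hit))
  expect_length(unique(vapply(qc_by_grb, function(x) unique(x)[1],
                              character(1))), 2)

  # Poisson moment check over replicates: mean inside count ~ rate * len
  rates <- vapply(1:40, function(r) {
    cfg_r <- synthetic_config(chrom_sizes = c(chr1 = 6e6), n_grbs = 2,
                              grb_size_min = 1e6, grb_size_max = 1e6,
                              cne_rate_in = 20, cne_rate_out = 0.5,
                              seed = 1000 + r)
    gen_r <- generate_genome(cfg_r)
    cc <- generate_cnes(gen_r$truth)
    sum(cc$grb_id > 0)
  }, numeric(1))
  lambda <- 20 * 2e6 / 1e5 # two 1 Mb GRBs
  se <- sqrt(lambda / 40)
  expect_lt(abs(mean(rates) - lambda), 3 * se)
})

test_that("contact matrices are symmetric with the planted boost", {
  cfg <- synthetic_config(chrom_sizes = c(chr1 = 5e6), n_grbs = 2,
                          grb_size_min = 1e6, grb_size_max = 1e6,
                          binsize = 2e4, tad_jitter = 0,
                          within_tad_boost = 3, noise_dispersion = 0.05,
                          seed = 5)
  gen <- generate_genome(cfg)
  M <- generate_contact_matrix(gen$truth)
  expect_identical(M$counts, t(M$counts))
  expect_true(all(is.finite(diag(M$counts))))

  # mean intra/inter contact ratio at fixed distance ~ boost, over seeds
  ratio_at <- function(seed) {
    cfg$seed <- seed
    gen <- generate_genome(cfg)
    M <- generate_contact_matrix(gen$truth)
    bnd <- gen$truth$tad_boundaries$chr1
    dom <- findInterval((seq_len(nrow(M$counts)) - 0.5) * cfg$binsize, bnd)
    d <- 5
    i <- seq_len(nrow(M$counts) - d)
    same <- dom[i] == dom[i + d]
    v <- M$counts[cbind(i, i + d)]
    mean(v[same]) / mean(v[!same])
  }
  ratios <- vapply(11:25, ratio_at, numeric(1))
  expect_lt(abs(mean(ratios) - 3), 0.45)

  # no-structure limit: boost 1, Poisson noise -> flat in expectation
  cfg1 <- synthetic_config(chrom_sizes = c(chr1 = 5e6), n_grbs = 2,
                           grb_size_min = 1e6, grb_size_max = 1e6,
                           binsize = 2e4, within_tad_boost = 1,
                           noise_dispersion = 0, seed = 5)
  gen1 <- generate_genome(cfg1)
  M1 <- generate_contact_matrix(gen1$truth)
  n <- nrow(M1$counts); d <- 3
  v <- M1$counts[cbind(seq_len(n - d), seq_len(n - d) + d)]
  expect_lt(abs(mean(v) - cfg1$contact_base / d), 3 * sd(v) / sqrt(length(v)))
})

test_that("CTCF panel honours the occupancy mixture and edge placement", {
  cfg1 <- synthetic_config(chrom_sizes = c(chr1 = 5e6), n_grbs = 1,
                           grb_size_min = 1e6, grb_size_max = 1e6,
                           n_ctcf_samples = 1, n_ctcf_sites = 50, seed = 2)
  p1 <- generate_ctcf_panel(generate_genome(cfg1)$truth)
  expect_true(all(p1$sites$occupancy == 1))

  cfg <- synthetic_config(chrom_sizes = c(chr1 = 20e6), n_grbs = 3,
                          grb_size_min = 1e6, grb_size_max = 2e6,
                          n_ctcf_sites = 1000,
                          ctcf_constitutive_frac = 0.2, seed = 8)
  gen <- generate_genome(cfg)
  panel <- generate_ctcf_panel(gen$truth)
  n_const <- sum(panel$sites$occupancy >= 16)
  se <- sqrt(1000 * 0.2 * 0.8)
  expect_lt(abs(n_const - 200), 3 * se)

  # constitutive sites concentrate at planted domain edges
  bnd <- gen$truth$tad_boundaries$chr1
  const <- panel$sites[panel$sites$category == "constitutive"]
  ctr <- (start(const) - 1 + end(const)) / 2
  d <- vapply(ctr, function(p) min(abs(p - bnd)), numeric(1))
  expect_true(all(d <= 1e4 + 300))
  # each sample's peak for a carried site stays within jitter of the site
  s1 <- panel$samples[[1]]
  hit <- distanceToNearest(s1, panel$sites)
  expect_true(all(S4Vectors::mcols(hit)$distance == 0))
})

test_that("SINE depletion inside planted GRBs matches the factor", {
  base_cfg <- function(depl, seed)
    synthetic_config(chrom_sizes = c(chr1 = 40e6), n_grbs = 8,
                     grb_size_min = 1e6, grb_size_max = 2e6,
                     sine_depletion = depl, seed = seed)
  gen0 <- generate_genome(base_cfg(0, 4))
  reps0 <- generate_repeats(gen0$truth)
  sines0 <- reps0[reps0$class == "SINE"]
  expect_length(findOverlaps(sines0, gen0$truth$grbs), 0)

  ratio_for <- function(depl, seed) {
    gen <- generate_genome(base_cfg(depl, seed))
    reps <- generate_repeats(gen$truth)
    s <- reps[reps$class == "SINE"]
    inside <- sum(overlapsAny(s, gen$truth$grbs))
    in_bp <- sum(width(gen$truth$grbs))
    out_bp <- 40e6 - in_bp
    (inside / in_bp) / ((length(s) - inside) / out_bp)
  }
  r <- ratio_for(0.3, 4)
  expect_gt(r, 0.2)
  expect_lt(r, 0.4)
  r1 <- ratio_for(1, 4)
  expect_gt(r1, 0.85)
  expect_lt(r1, 1.15)
})
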