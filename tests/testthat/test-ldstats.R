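test_that("haplotype r2 matches hand calculations and a brute-force oracle", {
  # perfectly co-inherited alleles
  x <- rep(c(1, 0), each = 8)
  expect_equal(haplotype_r2(x, x), 1)
  # AB=6, Ab=2, aB=2, ab=6 over 16 haplotypes: D = 0.125, r2 = 0.25
  a <- rep(c(1, 1, 0, 0), c(6, 2, 2, 6))
  b <- rep(c(1, 0, 1, 0), c(6, 2, 2, 6))
  expect_equal(haplotype_r2(a, b), 0.25)
  expect_error(haplotype_r2(rep(0, 8), x[1:8]), "biallelic")
  set.seed(1)
  for (k in 1:25) {
    u <- rbinom(20, 1, 0.5); v <- rbinom(20, 1, 0.5)
    if (length(unique(u)) < 2 || length(unique(v)) < 2) next
    expect_equal(haplotype_r2(u, v), brute_r2(u, v), tolerance = 1e-12)
    expect_equal(haplotype_r2(u, v), suppressWarnings(cor(u, v))^2,
                 tolerance = 1e-12)
  }
})

test_that("r2 between independent equifrequent sites shrinks as haplotype
           counts grow", {
  set.seed(2)
  mean_r2 <- function(n) {
    mean(replicate(300, {
      u <- rbinom(n, 1, 0.5); v <- rbinom(n, 1, 0.5)
      if (length(unique(u)) < 2 || length(unique(v)) < 2) return(NA)
      haplotype_r2(u, v)
    }), na.rm = TRUE)
  }
  expect_gt(mean_r2(8), mean_r2(64))
  expect_lt(mean_r2(64), 0.05)
})

test_that("genotype correlations square away the allele coding and match the
           direct Pearson formula", {
  d <- c(0, 0, 1, 1, 2, 2, 1, 1)
  e <- c(0, 1, 0, 1, 2, 1, 2, 1)
  expect_equal(genotype_corr2(d, d), 1)
  expect_equal(genotype_corr2(d, 2 - d), 1)
  expect_equal(genotype_corr2(d, e), cor(d, e)^2, tolerance = 1e-12)
  expect_equal(genotype_corr2(d, e), 0.25, tolerance = 1e-12)  # hand value
  expect_error(genotype_corr2(rep(1, 8), d), "constant")
})

test_that("homozygote pseudo-haplotypes keep only all-homozygous biallelic
           sites", {
  h1 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 1L))
  h2 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 0L), c(0L, 1L, 0L, 1L))
  x <- make_sample(h1, h2)
  hh <- homozygote_haplotypes(x)
  expect_identical(hh$pos, x$pos[c(1L, 3L)])
  expect_identical(unname(hh$haps), t(h1[c(1, 3), ]))
  y <- make_sample(matrix(0L, 2, 4), rbind(c(0L, 1L, 0L, 0L), c(1L, 0L, 0L, 0L)))
  expect_warning(homozygote_haplotypes(y), "no all-homozygous")
})

test_that("pseudo-haplotype LD from unphased homozygous sites tracks the
           truth-haplotype decay", {
  # few individuals so that all-homozygous biallelic sites are common
  s <- run_simulation(quick_sexual_config(sample_size = 4,
                                          genome_length = 3e4), seed = 51)
  hh <- homozygote_haplotypes(s)
  pt <- pair_r2_table(hh$haps, hh$contig, hh$pos, mac_min = 1, max_dist = 4000)
  w <- pt[pt$same_contig, ]
  expect_gt(nrow(w), 20)
  expect_lt(cor(w$value, w$distance), 0)
})

test_that("binning produces degenerate intervals for degenerate input", {
  pt <- structure(data.frame(contig = "ctg01", pos1 = 1:40, pos2 = (1:40) + 100,
                             distance = 100L, value = 0.4, same_contig = TRUE),
                  class = c("pair_table", "data.frame"))
  b <- bin_and_bootstrap(pt, width = 200, max_dist = 400, n_boot = 100)
  filled <- b[b$n > 0, ]
  expect_equal(filled$mean, 0.4)
  expect_equal(filled$ci_lo, 0.4)
  expect_equal(filled$ci_hi, 0.4)
  # one pair per bin: CI collapses onto the single value
  pt2 <- structure(data.frame(contig = "ctg01", pos1 = c(1L, 1L),
                              pos2 = c(101L, 301L), distance = c(100L, 300L),
                              value = c(0.2, 0.8), same_contig = TRUE),
                   class = c("pair_table", "data.frame"))
  b2 <- bin_and_bootstrap(pt2, width = 200, max_dist = 400, n_boot = 50)
  expect_equal(b2$ci_lo, b2$ci_hi)
  expect_equal(b2$mean, c(0.2, 0.8))
})

test_that("bin bootstrap intervals cover the true mean at roughly the nominal
           rate", {
  set.seed(4)
  true_mean <- 0.5
  cover <- replicate(60, {
    v <- rbinom(120, 1, true_mean)
    pt <- structure(data.frame(contig = "ctg01", pos1 = 1L, pos2 = 51L,
                               distance = 50L, value = v, same_contig = TRUE),
                    class = c("pair_table", "data.frame"))
    b <- bin_and_bootstrap(pt, width = 200, max_dist = 200, n_boot = 300)
    b$ci_lo[1] <= true_mean && true_mean <= b$ci_hi[1]
  })
  expect_gt(mean(cover), 0.85)
})

test_that("the r2-distance permutation test flags constructed decay and skips
           tiny segments", {
  # two tight clusters: within-cluster pairs in perfect LD at short distance,
  # cross-cluster pairs independent at long distance
  u <- rep(c(1L, 0L), each = 8)
  v <- rep(c(1L, 0L), 8)
  haps <- cbind(u, u, u, u, u, u, v, v, v, v, v, v)
  pos <- c(1:6 * 10L, 5000L + 1:6 * 10L)
  out <- segment_r2_distance_test(haps, pos, n_perm = 400)
  expect_false(out$skipped)
  expect_lt(out$correlation, 0)
  expect_lt(out$p_value, 0.02)
  expect_true(segment_r2_distance_test(haps[, 1:2], pos[1:2], 50)$skipped)
})

test_that("permutation p-values are calibrated on order-free segments", {
  set.seed(6)
  ps <- replicate(80, {
    haps <- matrix(rbinom(16 * 12, 1, 0.5), nrow = 16)
    ok <- apply(haps, 2, function(cc) length(unique(cc)) == 2)
    segment_r2_distance_test(haps[, ok, drop = FALSE],
                             sort(sample.int(2000, sum(ok))),
                             n_perm = 120)$p_value
  })
  expect_gt(mean(ps, na.rm = TRUE), 0.35)
  expect_lt(mean(ps, na.rm = TRUE), 0.65)
  expect_lt(mean(ps <= 0.05, na.rm = TRUE), 0.15)
})

test_that("sum-of-distances test: compatible segments give D4 = 0 and p = 1;
           a lone distant violation is flagged", {
  # perfect tree-like haplotypes: nested sets, no four-gamete pair
  haps <- cbind(rep(c(1, 0), c(8, 8)), rep(c(1, 0), c(4, 12)),
                rep(c(1, 0), c(2, 14)), rep(c(1, 0), c(6, 10)))
  out <- sum_of_distances_test(haps, c(10L, 500L, 900L, 1200L), n_perm = 100)
  expect_equal(out$D4, 0)
  expect_equal(out$p_value, 1)
  expect_equal(out$n_four_gamete, 0L)
  # single violating pair (columns 3 and 4) at the largest separation
  h2 <- cbind(haps[, 1], haps[, 2], haps[, 3],
              c(rep(0, 6), 1, 1, 1, 1, rep(0, 6)))
  pos2 <- c(10L, 20L, 30L, 2000L)
  o2 <- sum_of_distances_test(h2, pos2, n_perm = 2000)
  expect_equal(o2$n_four_gamete, 1L)  # only columns 1 and 4 show 4 gametes
  expect_equal(o2$D4, 2000 - 10)
  expect_lt(o2$p_value, 0.5)
})

test_that("PHI: compatible alignments give p = 1, recombinant block mosaics
           are detected, and duplicating sequences changes nothing", {
  compat <- cbind(rep(c(1, 0), c(8, 8)), rep(c(1, 0), c(4, 12)),
                  rep(c(1, 0), c(12, 4)))
  out <- phi_test(compat, n_perm = 100)
  expect_equal(out$phi, 0)
  expect_equal(out$p_value, 1)
  # two divergent parents and reciprocal block recombinants: pairs not
  # spanning a breakpoint stay compatible, distant pairs see all four gametes
  set.seed(7)
  m <- 40
  pa <- rep(0L, m); pb <- rep(1L, m)
  recomb <- t(sapply(1:12, function(k) {
    bp <- sample(5:35, 1)
    if (k %% 2 == 0) c(pa[1:bp], pb[(bp + 1):m]) else c(pb[1:bp], pa[(bp + 1):m])
  }))
  haps <- rbind(matrix(pa, 3, m, byrow = TRUE), matrix(pb, 3, m, byrow = TRUE),
                recomb)
  out2 <- phi_test(haps, window_w = 5, n_perm = 400)
  expect_false(out2$skipped)
  expect_lt(out2$p_value, 0.05)
  dup <- rbind(haps, haps)
  expect_equal(phi_test(dup, window_w = 5, n_perm = 50)$phi, out2$phi)
  norm <- phi_test(haps, window_w = 5, n_perm = 400, method = "normal")
  expect_lt(norm$p_value, 0.1)
})

test_that("decay curves are flat for constant r2 and report a baseline
           crossing", {
  pt <- structure(data.frame(contig = "ctg01", pos1 = 1L, pos2 = 1L,
                             distance = rep(seq(50, 2000, 50), each = 2),
                             value = 0.3, same_contig = TRUE),
                  class = c("pair_table", "data.frame"))
  dc <- decay_curve(pt, span = 0.75)
  expect_true(all(abs(dc$fit - 0.3) < 1e-6))
  expect_error(decay_curve(pt[1:4, ]), "too few")
})

test_that("LD decays with distance in sexual simulations but not in clonal
           ones, and the baseline crossing is reached", {
  s <- run_simulation(quick_sexual_config(), seed = 52)
  haps <- t(cbind(s$hap1, s$hap2))
  pt <- pair_r2_table(haps, s$contig, s$pos, mac_min = 4, max_dist = 2500)
  dc <- decay_curve(pt)
  expect_gt(dc$fit[1], dc$baseline_mean + dc$baseline_se)
  expect_false(is.na(dc$baseline_crossing))
  # genotype correlations from unphased data show the same trend
  gt <- genotype_pair_table(s, mac_min = 4, max_dist = 2500)
  w <- gt[gt$same_contig, ]
  expect_lt(cor(w$value, w$distance), 0)
  # strictly clonal: no decay (correlation indistinguishable from flat)
  sc <- run_simulation(quick_clonal_config(sample_size = 8), seed = 53)
  hc <- t(cbind(sc$hap1, sc$hap2))
  ptc <- pair_r2_table(hc, sc$contig, sc$pos, mac_min = 4, max_dist = 2500)
  wc <- ptc[ptc$same_contig, ]
  expect_gt(cor(wc$value, wc$distance), -0.05)
})
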