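test_that("DFE draws have the configured sign, mass and mean", {
  set.seed(1)
  cfg <- sim_config()
  s <- draw_dfe_effect(cfg, 2e5)
  expect_true(all(s <= 0))
  expect_equal(mean(s == 0), 1 - 0.4 / 1.4, tolerance = 0.02)
  del <- s[s < 0]
  expect_equal(mean(del), -0.01, tolerance = 0.03)  # gamma(shape .1) is heavy-tailed
  expect_true(all(draw_dfe_effect(sim_config(deleterious_fraction = 0), 1e4) == 0))
  expect_error(sim_config(dfe_shape = 0), "dfe_shape")
  expect_error(sim_config(deleterious_fraction = 1, dfe_mean = 0.01), "dfe_mean")
})

test_that("gene conversion is a no-op at alpha 0, resolves all hets at alpha 1,
           and picks the donor haplotype evenly", {
  set.seed(2)
  h <- rbind(sample(0:1, 50, TRUE), sample(0:1, 50, TRUE))
  expect_identical(apply_conversion(h, 0), h)
  conv <- apply_conversion(h, 1)
  expect_true(all(conv[1, ] == conv[2, ]))
  hom <- h[1, ] == h[2, ]
  expect_identical(conv[1, hom], h[1, hom])  # homozygous sites untouched
  # donor choice: at a 0/1 het site, outcome 1 means haplotype carrying 1 won
  won <- replicate(4e4, apply_conversion(rbind(0L, 1L), 1)[1, 1])
  expect_equal(mean(won), 0.5, tolerance = 0.02)
})

test_that("conversion conserves expected allele frequency", {
  set.seed(3)
  # 400 replicates of a 200-site haplotype pair with p = 0.3, alpha = 0.5
  dp <- replicate(400, {
    h <- matrix(rbinom(400, 1, 0.3), nrow = 2)
    mean(apply_conversion(h, 0.5)) - mean(h)
  })
  expect_lt(abs(mean(dp)), 3 * sd(dp) / sqrt(length(dp)))
})

test_that("run_simulation is deterministic given a seed", {
  cfg <- quick_sexual_config(n_generations = 200)
  a <- run_simulation(cfg, seed = 9)
  b <- run_simulation(cfg, seed = 9)
  expect_identical(a$hap1, b$hap1)
  expect_identical(a$hap2, b$hap2)
  expect_identical(a$pos, b$pos)
  c <- run_simulation(cfg, seed = 10)
  expect_false(identical(a$hap1, c$hap1) && identical(a$pos, c$pos))
})

test_that("strictly clonal reproduction without mutation resamples parental
           haplotype pairs", {
  set.seed(4)
  pop <- new_population(quick_sexual_config())
  pop <- advance_generation(pop, 400)
  parents <- pop$state
  frozen <- sim_config(pop_size = 60, genome_length = 1e4, mutation_rate = 0,
                       crossover_rate = 0, cloning_rate = 1,
                       n_generations = 1, sample_size = 8, n_contigs = 4)
  off <- advance_generation(pop, 1, config = frozen)$state
  # offspring columns are a subset of parental columns (no new alleles),
  # and every offspring haplotype pair equals some parental pair there
  idx <- match(off$pos, parents$pos)
  expect_false(anyNA(idx))
  pkey <- apply(cbind(parents$haps[seq(1, 119, 2), idx, drop = FALSE],
                      parents$haps[seq(2, 120, 2), idx, drop = FALSE]),
                1, paste, collapse = ",")
  okey <- apply(cbind(off$haps[seq(1, 119, 2), , drop = FALSE],
                      off$haps[seq(2, 120, 2), , drop = FALSE]),
                1, paste, collapse = ",")
  expect_true(all(okey %in% pkey))
})

test_that("offspring parent counts are consistent with uniform multinomial
           sampling when fitness is flat", {
  set.seed(5)
  ne <- 30L
  frozen <- sim_config(pop_size = ne, genome_length = 5000, mutation_rate = 0,
                       crossover_rate = 0, cloning_rate = 1, n_generations = 1,
                       sample_size = 4, n_contigs = 1, deleterious_fraction = 0)
  # synthetic parent state: parent i uniquely marked at site i on both haplotypes
  pop <- new_population(frozen)
  haps <- matrix(0L, 2L * ne, ne)
  for (i in seq_len(ne)) haps[c(2L * i - 1L, 2L * i), i] <- 1L
  pop$state <- list(haps = haps, pos = seq_len(ne), anc = integer(ne),
                    eff = numeric(ne), fixed_pos = integer(0),
                    fixed_allele = integer(0), generation = 0L)
  counts <- integer(ne)
  for (r in 1:30) {
    off <- advance_generation(pop, 1, config = frozen)$state
    for (i in seq_len(ne)) {
      parent <- off$pos[off$haps[2L * i - 1L, ] == 1L]
      counts[parent] <- counts[parent] + 1L
    }
  }
  gof <- chisq.test(counts, p = rep(1 / ne, ne))
  expect_gt(gof$p.value, 0.001)
})

test_that("neutral sexual diversity matches the 4*Ne*mu prediction", {
  # theta = 0.01 per site; average pairwise diversity over replicates
  pis <- sapply(1:4, function(k) {
    s <- run_simulation(quick_sexual_config(deleterious_fraction = 0), seed = 40 + k)
    n <- 2 * length(s$individuals)
    h <- cbind(s$hap1, s$hap2)
    tot <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) tot <- tot + sum(h[, i] != h[, j])
    tot / choose(n, 2) / s$config$genome_length
  })
  expect_gt(mean(pis), 0.006)
  expect_lt(mean(pis), 0.016)
})

test_that("long strictly clonal runs make old sites heterozygous in every
           individual (allele divergence under asexuality)", {
  s <- run_simulation(quick_clonal_config(n_generations = 1200, sample_size = 6),
                      seed = 11)
  het <- s$hap1 != s$hap2
  all_het <- rowMeans(het) == 1
  # sites heterozygous in everyone dominate among intermediate-frequency sites
  expect_gt(mean(all_het), 0.2)
  fb <- fis_by_site(s, mac_min = 4)
  expect_lt(mean(fb$fis), -0.8)
})

test_that("hybrid samples: no divergence means hybrids look like everyone else,
           long divergence doubles their heterozygosity", {
  cfg <- sim_config(pop_size = 80, genome_length = 2e4, mutation_rate = 2.5e-5,
                    crossover_rate = 2.5e-5, cloning_rate = 0,
                    n_generations = 1600, sample_size = 4, n_contigs = 10)
  h0 <- simulate_hybrid_scenario(cfg, cfg, split_generations = 0, n_hybrids = 4,
                                 n_sample_a = 4, seed = 21)
  het <- colMeans(h0$hap1 != h0$hap2)
  expect_lt(mean(het[h0$origin == "F1"]) / mean(het[h0$origin == "A"]), 1.6)
  h1 <- simulate_hybrid_scenario(cfg, cfg, split_generations = 800, n_hybrids = 4,
                                 n_sample_a = 4, seed = 22)
  het1 <- colMeans(h1$hap1 != h1$hap2)
  expect_gt(mean(het1[h1$origin == "F1"]) / mean(het1[h1$origin == "A"]), 1.5)
})

test_that("each hybrid haplotype's nearest neighbor sits in its source
           population", {
  cfg <- sim_config(pop_size = 80, genome_length = 2e4, mutation_rate = 2.5e-5,
                    crossover_rate = 2.5e-5, cloning_rate = 0,
                    n_generations = 1600, sample_size = 4, n_contigs = 10)
  h <- simulate_hybrid_scenario(cfg, cfg, split_generations = 800, n_hybrids = 3,
                                n_sample_a = 4, n_sample_b = 4, seed = 23)
  haps <- cbind(h$hap1, h$hap2)
  n <- length(h$individuals)
  orig <- c(h$hap_origin[, 1], h$hap_origin[, 2])
  f1 <- which(h$origin == "F1")
  for (i in f1) {
    for (k in 0:1) {
      col <- i + k * n
      dd <- colSums(haps != haps[, col])
      dd[col] <- NA
      dd[i + (1 - k) * n] <- NA  # exclude own other haplotype
      expect_identical(unname(orig[which.min(dd)]), unname(orig[col]))
    }
  }
})
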