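# Shared fixtures: tiny simulator configurations and hand-built samples.

# fast sexual configuration: theta = 4*Ne*mu = 0.01 per site
quick_sexual_config <- function(n_generations = 1200, sample_size = 8,
                                genome_length = 1e4, mutation_rate = 4e-5,
                                ...) {
  sim_config(pop_size = 60, genome_length = genome_length,
             mutation_rate = mutation_rate, crossover_rate = 4e-5,
             cloning_rate = 0, n_generations = n_generations,
             sample_size = sample_size, n_contigs = 4, ...)
}

# fast strictly clonal configuration
quick_clonal_config <- function(n_generations = 600, sample_size = 3, ...) {
  sim_config(pop_size = 60, genome_length = 1e4, mutation_rate = 2e-5,
             crossover_rate = 0, cloning_rate = 1,
             n_generations = n_generations, sample_size = sample_size,
             n_contigs = 4, ...)
}

# build a sample_set directly from haplotype matrices (sites x individuals)
make_sample <- function(h1, h2, pos = seq_len(nrow(h1)) * 10L,
                        genome_length = 1e4, n_contigs = 1) {
  cfg <- sim_config(pop_size = max(2L, ncol(h1)), genome_length = genome_length,
                    n_generations = 0, sample_size = max(2L, ncol(h1)),
                    n_contigs = n_contigs)
  clonescan:::.make_sample(h1, h2, as.integer(pos),
                           rep(0L, nrow(h1)), rep(0, nrow(h1)), cfg, 0L)
}

# sample_set in which every site has the given genotype counts (n_AA, n_AB, n_BB)
uniform_geno_sample <- function(counts, n_sites = 30) {
  n <- sum(counts)
  g1 <- c(rep(0L, counts[1]), rep(0L, counts[2]), rep(1L, counts[3]))
  g2 <- c(rep(0L, counts[1]), rep(1L, counts[2]), rep(1L, counts[3]))
  make_sample(matrix(rep(g1, each = n_sites), nrow = n_sites),
              matrix(rep(g2, each = n_sites), nrow = n_sites))
}

# segment_haplotypes from haplotype matrices (sites x individuals)
make_segment <- function(h1, h2, pos = seq_len(nrow(h1)) * 10L,
                         individuals = sprintf("IND%02d", seq_len(ncol(h1))),
                         contig = "ctg01") {
  colnames(h1) <- colnames(h2) <- individuals
  structure(list(contig = contig, start = min(pos), end = max(pos),
                 pos = as.integer(pos), hap1 = h1, hap2 = h2,
                 individuals = individuals),
            class = "segment_haplotypes")
}

# brute-force two-locus r2 from 0/1 haplotype vectors
brute_r2 <- function(x, y) {
  pa <- mean(x); pb <- mean(y)
  d <- mean(x * y) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# brute-force Hamming distance matrix over columns of a matrix
brute_hamming <- function(m) {
  k <- ncol(m)
  d <- matrix(0L, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) d[i, j] <- sum(m[, i] != m[, j])
  d
}
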