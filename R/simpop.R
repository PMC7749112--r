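#' Draw selection coefficients from the configured DFE
#'
#' With probability `1 - deleterious_fraction` a mutation is neutral (effect
#' exactly 0); otherwise its selection coefficient is minus a gamma deviate
#' with mean `|dfe_mean|` and shape `dfe_shape`, so every deleterious draw is
#' negative and the mean deleterious effect equals `dfe_mean`.
#'
#' @param config a [sim_config()].
#' @param n number of draws.
#' @return Numeric vector of `n` selection coefficients (<= 0).
#' @export
#' @examples
#' set.seed(1)
#' mean(draw_dfe_effect(sim_config(deleterious_fraction = 1), 1e4))
draw_dfe_effect <- function(config, n = 1) {
  validate_sim_config(config)
  .simcore_dfe(as.integer(n), config$deleterious_fraction,
               config$dfe_mean, config$dfe_shape)
}

#' Create a founder population
#'
#' Returns a monomorphic population of `config$pop_size` diploids (no
#' segregating sites) at generation 0, ready to be evolved with
#' [advance_generation()] or consumed by [run_simulation()].
#'
#' @param config a [sim_config()].
#' @return An object of class `population`.
#' @export
new_population <- function(config) {
  validate_sim_config(config)
  state <- list(haps = matrix(0L, nrow = 2L * config$pop_size, ncol = 0L),
                pos = integer(0), anc = integer(0), eff = numeric(0),
                fixed_pos = integer(0), fixed_allele = integer(0),
                generation = 0L)
  structure(list(state = state, config = config), class = "population")
}

#' Advance a population by one or more generations
#'
#' Each of the Ne offspring is, independently, clonal with the configuration's
#' effective cloning probability (a mitotic copy of one fitness-weighted
#' parent plus new mutations, no crossover) or sexual otherwise (two
#' fitness-weighted parents, each transmitting one gamete with
#' Poisson-distributed crossovers). Parents are sampled with replacement
#' proportional to multiplicative fitness; selfing is allowed. Gene conversion
#' is applied per segregating site at rate `conversion_rate` after
#' reproduction. Monomorphic sites are purged each generation.
#'
#' @param population a [new_population()] object.
#' @param n_gens number of generations to advance (default 1).
#' @param config optional replacement configuration (same `pop_size`).
#' @return The advanced `population`.
#' @export
advance_generation <- function(population, n_gens = 1, config = NULL) {
  stopifnot(inherits(population, "population"))
  cfg <- if (is.null(config)) population$config else validate_sim_config(config)
  population$state <- .simcore_run(
    population$state, cfg$pop_size, cfg$genome_length, cfg$mutation_rate,
    cfg$crossover_rate, effective_cloning_rate(cfg), cfg$conversion_rate,
    cfg$deleterious_fraction, cfg$dfe_mean, cfg$dfe_shape,
    as.integer(n_gens), cfg$sites_model == "finite4",
    ceiling(cfg$genome_length / cfg$n_contigs))
  population$config <- cfg
  population
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> Ne = %d, generation %d, %d segregating sites\n",
              x$config$pop_size, x$state$generation, length(x$state$pos)))
  invisible(x)
}

#' Apply within-locus gene conversion to one individual's haplotype pair
#'
#' Per site, with probability `alpha`, a heterozygous site is converted: the
#' allele of one haplotype (the donor, chosen with probability 1/2) overwrites
#' the other's. Homozygous sites are unaffected, so the expected population
#' allele frequency is unchanged.
#'
#' @param haplotype_pair a 2 x S integer matrix (rows = the two haplotypes).
#' @param alpha per-site conversion probability in \[0, 1\].
#' @return The converted 2 x S matrix.
#' @export
#' @examples
#' h <- rbind(c(0L, 1L, 0L), c(1L, 1L, 1L))
#' apply_conversion(h, 1)  # every heterozygous site made homozygous
apply_conversion <- function(haplotype_pair, alpha) {
  stopifnot(is.matrix(haplotype_pair), nrow(haplotype_pair) == 2L, alpha >= 0)
  s <- ncol(haplotype_pair)
  if (alpha == 0 || s == 0L) return(haplotype_pair)
  hit <- runif(s) < alpha
  het <- haplotype_pair[1L, ] != haplotype_pair[2L, ]
  conv <- which(hit & het)
  if (length(conv)) {
    donor_first <- runif(length(conv)) < 0.5
    haplotype_pair[2L, conv[donor_first]] <- haplotype_pair[1L, conv[donor_first]]
    haplotype_pair[1L, conv[!donor_first]] <- haplotype_pair[2L, conv[!donor_first]]
  }
  haplotype_pair
}

# contig striping: global 1-based positions -> (contig label, within-contig pos)
contig_of <- function(gpos, genome_length, n_contigs) {
  clen <- ceiling(genome_length / n_contigs)
  idx <- (gpos - 1L) %/% clen + 1L
  list(contig = sprintf("ctg%02d", idx),
       pos = as.integer(gpos - (idx - 1L) * clen),
       contig_length = as.integer(clen))
}

#' Sample individuals from a population into a `sample_set`
#'
#' Draws `n` diploid individuals without replacement and keeps the sites that
#' segregate within the sample. The truth haplotypes are retained (the sample
#' is perfectly phased), so genotypes are consistent with the haplotypes at
#' every site by construction.
#'
#' @param population a `population`.
#' @param n sample size; defaults to the configuration's `sample_size`.
#' @return An object of class `sample_set`: truth haplotype matrices `hap1`
#'   and `hap2` (sites x individuals, allele codes 0-3), site coordinates
#'   (`contig`, `pos`, global `gpos`), ancestral alleles `anc`, selection
#'   effects `eff`, individual labels and provenance. A sample with zero
#'   segregating sites is returned empty with a warning.
#' @export
sample_population <- function(population, n = NULL) {
  stopifnot(inherits(population, "population"))
  cfg <- population$config
  if (is.null(n)) n <- cfg$sample_size
  ids <- sort(sample.int(cfg$pop_size, n))
  st <- population$state
  if (length(st$pos) == 0L) {
    warning("no segregating sites in the population")
    return(.make_sample(matrix(0L, 0, n), matrix(0L, 0, n), integer(0),
                        integer(0), numeric(0), cfg, st$generation))
  }
  h1 <- t(st$haps[2L * ids - 1L, , drop = FALSE])
  h2 <- t(st$haps[2L * ids, , drop = FALSE])
  seg <- rowSums(h1 != h1[, 1L]) + rowSums(h2 != h1[, 1L]) > 0L
  .make_sample(h1[seg, , drop = FALSE], h2[seg, , drop = FALSE],
               st$pos[seg], st$anc[seg], st$eff[seg], cfg, st$generation)
}

.make_sample <- function(h1, h2, gpos, anc, eff, cfg, generation,
                         individuals = NULL, origin = NULL,
                         hap_origin = NULL) {
  n <- ncol(h1)
  if (is.null(individuals)) individuals <- sprintf("IND%02d", seq_len(n))
  cs <- contig_of(gpos, cfg$genome_length, cfg$n_contigs)
  colnames(h1) <- colnames(h2) <- individuals
  x <- list(hap1 = h1, hap2 = h2,
            contig = cs$contig, pos = cs$pos, gpos = as.integer(gpos),
            contig_length = cs$contig_length,
            anc = as.integer(anc), eff = eff,
            individuals = individuals, origin = origin,
            hap_origin = hap_origin,
            phased = TRUE, config = cfg, generation = generation)
  class(x) <- "sample_set"
  x
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d individuals, %d segregating sites on %d contigs (generation %d)\n",
              length(x$individuals), length(x$pos),
              length(unique(x$contig)), x$generation))
  invisible(x)
}

#' Number of sites in a sample
#' @param x a `sample_set`.
#' @return Integer site count.
#' @export
n_sites <- function(x) length(x$pos)

#' Run a forward simulation and sample it
#'
#' Evolves a monomorphic founder population for `config$n_generations`
#' generations and samples `config$sample_size` individuals without
#' replacement. Deterministic given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed passed to [set.seed()].
#' @return A `sample_set` (see [sample_population()]).
#' @export
#' @examples
#' s <- run_simulation(sim_config(pop_size = 20, genome_length = 2000,
#'                                mutation_rate = 1e-4, crossover_rate = 1e-4,
#'                                n_generations = 100, sample_size = 6),
#'                     seed = 1)
#' n_sites(s)
run_simulation <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  pop <- new_population(config)
  pop <- advance_generation(pop, config$n_generations)
  s <- sample_population(pop)
  s$seed <- seed
  s
}

# one meiotic gamete at the R level (used to form F1 hybrids); contigs
# assort independently, matching the compiled core
.meiosis_gamete <- function(h1, h2, gpos, genome_length, crossover_rate,
                            n_contigs = 1) {
  k <- rpois(1L, crossover_rate * genome_length)
  bp <- runif(k, 0, genome_length)
  clen <- ceiling(genome_length / n_contigs)
  bounds <- if (n_contigs > 1) seq_len(n_contigs - 1L) * clen else numeric(0)
  bounds <- bounds[bounds < genome_length]
  if (length(bounds))
    bp <- c(bp, bounds[runif(length(bounds)) < 0.5] + 0.5)
  use1 <- runif(1L) < 0.5
  if (length(bp) == 0L) return(if (use1) h1 else h2)
  side <- (findInterval(gpos, sort(bp)) %% 2L) == 0L
  if (!use1) side <- !side
  ifelse(side, h1, h2)
}

#' Simulate a two-population hybrid (F1) scenario
#'
#' Evolves a common ancestral population under `config_a` for its configured
#' burn-in, splits it into two isolated populations evolved independently for
#' `split_generations` under `config_a` and `config_b`, then forms
#' `n_hybrids` F1 individuals, each carrying one meiotic gamete from a random
#' individual of each population. The returned sample combines
#' `n_sample_a` individuals from population A, `n_sample_b` from population B
#' and the hybrids, labeled by origin (`"A"`, `"B"`, `"F1"`); for hybrids,
#' `hap1` carries the A-derived gamete and `hap2` the B-derived one (recorded
#' in `hap_origin`). Sampling only population A plus the hybrids
#' (`n_sample_b = 0`) emulates a cohort in which the second source population
#' was never collected.
#'
#' @param config_a,config_b configurations for the two populations; they must
#'   share `pop_size`, `genome_length` and `n_contigs`.
#' @param split_generations generations of isolated evolution after the split.
#' @param n_hybrids number of F1 individuals to create.
#' @param n_sample_a,n_sample_b individuals sampled from each source
#'   population (defaults: `config_a$sample_size` and 0).
#' @param seed optional seed.
#' @return A `sample_set` with `origin` and `hap_origin` fields.
#' @export
simulate_hybrid_scenario <- function(config_a, config_b = config_a,
                                     split_generations, n_hybrids,
                                     n_sample_a = config_a$sample_size,
                                     n_sample_b = 0, seed = NULL) {
  validate_sim_config(config_a)
  validate_sim_config(config_b)
  if (config_a$pop_size != config_b$pop_size ||
      config_a$genome_length != config_b$genome_length ||
      config_a$n_contigs != config_b$n_contigs)
    stop("the two configurations must share genome coordinates and pop_size")
  if (!is.null(seed)) set.seed(seed)

  anc_pop <- advance_generation(new_population(config_a),
                                config_a$n_generations)
  pop_a <- anc_pop
  pop_b <- anc_pop
  pop_b$config <- config_b
  if (split_generations > 0) {
    pop_a <- advance_generation(pop_a, split_generations)
    pop_b <- advance_generation(pop_b, split_generations)
  }

  sa <- pop_a$state
  sb <- pop_b$state
  gpos <- sort(union(sa$pos, sb$pos))
  expand <- function(st, cfg) {
    idx <- match(st$pos, gpos)
    h <- matrix(0L, nrow = nrow(st$haps), ncol = length(gpos))
    fixed <- setNames(st$fixed_allele, st$fixed_pos)
    miss <- setdiff(seq_along(gpos), idx)
    for (j in miss) {
      fa <- fixed[as.character(gpos[j])]
      if (!is.na(fa)) h[, j] <- as.integer(fa)
    }
    h[, idx] <- st$haps
    h
  }
  ha <- expand(sa, config_a)
  hb <- expand(sb, config_b)
  anc <- integer(length(gpos))
  anc[match(sa$pos, gpos)] <- sa$anc
  anc[match(setdiff(sb$pos, sa$pos), gpos)] <- sb$anc[!(sb$pos %in% sa$pos)]
  eff <- numeric(length(gpos))
  eff[match(sa$pos, gpos)] <- sa$eff
  eff[match(setdiff(sb$pos, sa$pos), gpos)] <- sb$eff[!(sb$pos %in% sa$pos)]

  ne <- config_a$pop_size
  ids_a <- sort(sample.int(ne, n_sample_a))
  ids_b <- if (n_sample_b > 0) sort(sample.int(ne, n_sample_b)) else integer(0)

  h1 <- h2 <- NULL
  origin <- character(0)
  add_ind <- function(a, b) {
    h1 <<- cbind(h1, a)
    h2 <<- cbind(h2, b)
  }
  for (i in ids_a) { add_ind(ha[2L * i - 1L, ], ha[2L * i, ]); origin <- c(origin, "A") }
  for (i in ids_b) { add_ind(hb[2L * i - 1L, ], hb[2L * i, ]); origin <- c(origin, "B") }
  for (k in seq_len(n_hybrids)) {
    pa <- sample.int(ne, 1L)
    pb <- sample.int(ne, 1L)
    ga <- .meiosis_gamete(ha[2L * pa - 1L, ], ha[2L * pa, ], gpos,
                          config_a$genome_length, config_a$crossover_rate,
                          config_a$n_contigs)
    gb <- .meiosis_gamete(hb[2L * pb - 1L, ], hb[2L * pb, ], gpos,
                          config_b$genome_length, config_b$crossover_rate,
                          config_b$n_contigs)
    add_ind(ga, gb)
    origin <- c(origin, "F1")
  }
  n <- length(origin)
  labs <- sprintf("%s%02d", ifelse(origin == "F1", "F1_", "IND"), seq_len(n))
  hap_origin <- cbind(h1 = ifelse(origin == "B", "B", "A"),
                      h2 = ifelse(origin == "A", "A", "B"))
  rownames(hap_origin) <- labs
  seg <- rowSums(h1 != h1[, 1L]) + rowSums(h2 != h1[, 1L]) > 0L
  out <- .make_sample(h1[seg, , drop = FALSE], h2[seg, , drop = FALSE],
                      gpos[seg], anc[seg], eff[seg], config_a,
                      pop_a$state$generation, individuals = labs,
                      origin = origin, hap_origin = hap_origin)
  out$seed <- seed
  out
}
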