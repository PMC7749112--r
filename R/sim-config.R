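#' Configuration for the forward population simulator
#'
#' Collects all parameters of the Wright-Fisher model of a facultatively
#' clonal diploid population: each offspring is produced clonally (a mitotic
#' copy of one fitness-weighted parent) with probability `cloning_rate`, and
#' sexually (two fitness-weighted parents, each transmitting one recombinant
#' gamete) otherwise. Mutations arise at `mutation_rate` per base pair per
#' genome copy per generation; a fraction `deleterious_fraction` of them draw
#' a negative selection coefficient from a gamma distribution with mean
#' `dfe_mean` and shape `dfe_shape` (fitness is multiplicative across sites,
#' heterozygote effect s/2). Within-locus gene conversion turns a heterozygous
#' site homozygous at rate `conversion_rate` per segregating site per
#' individual per generation, the donor haplotype chosen with probability 1/2.
#'
#' The default parameterisation is the full-scale study condition:
#' Ne = 2500, mu = 1e-6 per bp, crossover rate 1e-6 per bp per sexual
#' generation, genome length 1e6 bp, 200000 generations, giving a
#' population-scaled mutation rate 4*Ne*mu = 0.01. See [scaled_config()] for
#' a desk-scale rescaling that preserves the population-scaled parameters.
#'
#' @param pop_size number of diploid individuals (Ne >= 2).
#' @param genome_length genome length L in base pairs.
#' @param mutation_rate mutation rate per bp per genome copy per generation.
#' @param crossover_rate crossover rate per bp per sexual generation.
#' @param cloning_rate probability in \[0, 1\] that an offspring is clonal.
#' @param conversion_rate per-site gene-conversion rate alpha per generation.
#' @param deleterious_fraction fraction of mutations that are deleterious;
#'   default 0.4/1.4 (neutral:deleterious = 1:0.4).
#' @param dfe_mean mean selection coefficient of deleterious mutations
#'   (negative).
#' @param dfe_shape gamma shape parameter of the DFE.
#' @param n_generations number of generations to run.
#' @param sample_size number of diploid individuals sampled at the end.
#' @param sites_model `"infinite"` (biallelic 0/1 alleles, new mutations
#'   always hit fresh positions) or `"finite4"` (four-allele finite sites
#'   with equal exchange rates among the four nucleotides, producing
#'   recurrent mutation and triallelic sites).
#' @param n_contigs number of equal-length contig labels the genome
#'   coordinates are striped over.
#' @param time_scale rescaling factor recorded by [scaled_config()]; 1 for
#'   unscaled runs. Affects only how nominal cloning rates are mapped to the
#'   per-generation sexual rate (see [scaled_config()]).
#'
#' @return An object of class `sim_config` (a named list).
#' @seealso [run_simulation()], [scaled_config()]
#' @export
#' @examples
#' cfg <- sim_config()
#' cfg$pop_size
sim_config <- function(pop_size = 2500,
                       genome_length = 1e6,
                       mutation_rate = 1e-6,
                       crossover_rate = 1e-6,
                       cloning_rate = 0,
                       conversion_rate = 0,
                       deleterious_fraction = 0.4 / 1.4,
                       dfe_mean = -0.01,
                       dfe_shape = 0.1,
                       n_generations = 200000,
                       sample_size = 8,
                       sites_model = c("infinite", "finite4"),
                       n_contigs = 10,
                       time_scale = 1) {
  sites_model <- match.arg(sites_model)
  cfg <- list(pop_size = as.integer(pop_size),
              genome_length = genome_length,
              mutation_rate = mutation_rate,
              crossover_rate = crossover_rate,
              cloning_rate = cloning_rate,
              conversion_rate = conversion_rate,
              deleterious_fraction = deleterious_fraction,
              dfe_mean = dfe_mean,
              dfe_shape = dfe_shape,
              n_generations = as.integer(n_generations),
              sample_size = as.integer(sample_size),
              sites_model = sites_model,
              n_contigs = as.integer(n_contigs),
              time_scale = time_scale)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$pop_size < 2L) stop("pop_size must be >= 2", call. = FALSE)
  if (cfg$cloning_rate < 0 || cfg$cloning_rate > 1)
    stop("cloning_rate must be in [0, 1]", call. = FALSE)
  if (cfg$mutation_rate < 0 || cfg$crossover_rate < 0 || cfg$conversion_rate < 0)
    stop("mutation, crossover and conversion rates must be >= 0", call. = FALSE)
  if (cfg$dfe_shape <= 0) stop("dfe_shape must be > 0", call. = FALSE)
  if (cfg$deleterious_fraction > 0 && cfg$dfe_mean > 0)
    stop("dfe_mean must be <= 0 (deleterious effects)", call. = FALSE)
  if (cfg$deleterious_fraction < 0 || cfg$deleterious_fraction > 1)
    stop("deleterious_fraction must be in [0, 1]", call. = FALSE)
  if (cfg$sample_size > cfg$pop_size)
    stop("sample_size must be <= pop_size", call. = FALSE)
  if (cfg$genome_length < 1) stop("genome_length must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Desk-scale preset preserving the population-scaled parameters
#'
#' Standard population-genetic rescaling of the full-scale conditions by a
#' factor `scale`: the population is `scale` times smaller and one simulated
#' generation stands for `scale` generations of the full-scale population.
#' Per-generation rates are multiplied by `scale` (mutation and crossover
#' rates, and the per-offspring probability of sexual reproduction), so the
#' population-scaled quantities 4*Ne*mu, 4*Ne*r and Ne*(1 - cloning_rate)
#' match the full-scale values. Selection coefficients are *not* rescaled:
#' multiplying them by `scale` pushes individual coefficients out of the
#' diffusion regime (k*s approaching 1) and induces associative
#' overdominance around selected sites that the full-scale model does not
#' show; the statistics this package targets are neutral-site statistics, so
#' the DFE is kept at its per-generation values. The last of these controls how far a partially
#' clonal population deviates from Hardy-Weinberg equilibrium, so rescaling
#' the sexual rate is what keeps the cloning-rate sweep comparable across
#' scales. The conversion rate is *not* rescaled: it is interpreted in units
#' of the simulated population itself (the clonal-HWE equilibrium point is
#' alpha = 1/(2*Ne) of the population being simulated).
#'
#' `cloning_rate` is given on the nominal (full-scale) axis; the effective
#' per-generation clonal probability used by the simulator is
#' `1 - min(1, scale * (1 - cloning_rate))`.
#'
#' @param scale rescaling factor (default 10: Ne = 250, mu = 1e-5).
#' @param cloning_rate nominal cloning rate on the full-scale axis.
#' @param genome_length genome length in bp; default 3e4 (diversity per site
#'   is unaffected by length, which only sets the number of SNPs).
#' @param n_generations run length; default 20 * Ne.
#' @param ... further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
#' @examples
#' cfg <- scaled_config()
#' c(cfg$pop_size, cfg$mutation_rate, effective_cloning_rate(cfg))
scaled_config <- function(scale = 10, cloning_rate = 0, genome_length = 3e4,
                          n_generations = NULL, ...) {
  ne <- as.integer(round(2500 / scale))
  if (is.null(n_generations)) n_generations <- 20L * ne
  sim_config(pop_size = ne,
             genome_length = genome_length,
             mutation_rate = 1e-6 * scale,
             crossover_rate = 1e-6 * scale,
             cloning_rate = cloning_rate,
             n_generations = n_generations,
             time_scale = scale,
             ...)
}

#' Effective per-generation clonal probability of a configuration
#'
#' For unscaled configurations this is `cloning_rate` itself; for rescaled
#' ones the sexual rate is multiplied by the time-scale factor (capped at 1).
#'
#' @param config a [sim_config()].
#' @return A probability in \[0, 1\].
#' @export
effective_cloning_rate <- function(config) {
  validate_sim_config(config)
  1 - min(1, config$time_scale * (1 - config$cloning_rate))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  Ne = %d, L = %g bp over %d contigs, %d generations\n",
              x$pop_size, x$genome_length, x$n_contigs, x$n_generations))
  cat(sprintf("  mu = %g, crossover = %g, 4*Ne*mu = %g, 4*Ne*r = %g\n",
              x$mutation_rate, x$crossover_rate,
              4 * x$pop_size * x$mutation_rate,
              4 * x$pop_size * x$crossover_rate))
  cat(sprintf("  cloning rate = %g (effective %g), conversion alpha = %g\n",
              x$cloning_rate, effective_cloning_rate(x), x$conversion_rate))
  cat(sprintf("  DFE: fraction %.3g, gamma(mean %g, shape %g); sites: %s\n",
              x$deleterious_fraction, x$dfe_mean, x$dfe_shape, x$sites_model))
  invisible(x)
}
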