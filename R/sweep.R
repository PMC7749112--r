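# Cloning-rate sweep: simulate populations across a grid of cloning rates,
# apply the 8-individual / MAC >= 4 / 200-SNP subsampling scheme to each
# replicate, and locate the smallest rate of sexual reproduction whose mean
# F_IS distribution is indistinguishable from the fully sexual one.

#' Desk-scale preset used for cloning-rate and conversion-rate experiments
#'
#' A [scaled_config()] at rescaling factor 25 (Ne = 100) with 40 freely
#' assorting contigs of 1 kb. Many short contigs emulate scaffold-level data
#' and average the mean F_IS over many quasi-independent genealogies, which
#' keeps the spread of replicate means small enough for the sweep to resolve
#' the study's cloning-rate grid.
#'
#' @param cloning_rate nominal cloning rate.
#' @param ... further arguments passed to [scaled_config()].
#' @return A `sim_config`.
#' @export
sweep_config <- function(cloning_rate = 0, ...) {
  scaled_config(scale = 25, cloning_rate = cloning_rate,
                genome_length = 4e4, n_contigs = 40, ...)
}

#' Mean F_IS across a sweep of cloning rates
#'
#' For each cloning rate, runs `n_reps` independent forward simulations under
#' `config_fn(cloning_rate = rate)` and computes one subsampled mean F_IS per
#' replicate via [subsample_mean_fis()] (8 individuals, MAC >= 4, 200 SNPs by
#' default). Replicate seeds are derived deterministically from `seed`.
#'
#' @param rates cloning rates on the nominal axis (default the study grid
#'   `c(0, 0.5, 0.9, 0.99, 0.999, 1)`).
#' @param n_reps replicates per rate (default 20).
#' @param config_fn function of `cloning_rate` returning a [sim_config()];
#'   default [sweep_config()].
#' @param n_individuals,mac_min,n_snps subsampling scheme parameters.
#' @param seed integer seed.
#' @return A data.frame: `cloning_rate`, `replicate`, `mean_fis`.
#' @export
cloning_rate_sweep <- function(rates = c(0, 0.5, 0.9, 0.99, 0.999, 1),
                               n_reps = 20,
                               config_fn = sweep_config,
                               n_individuals = 8, mac_min = 4, n_snps = 200,
                               seed = 1) {
  rows <- list()
  for (ri in seq_along(rates)) {
    cfg <- config_fn(cloning_rate = rates[ri])
    for (rep in seq_len(n_reps)) {
      s <- run_simulation(cfg, seed = (seed * 997L + ri * 101L + rep) %% 2147483647L)
      m <- subsample_mean_fis(s, n_individuals = n_individuals,
                              mac_min = mac_min, n_snps = n_snps, n_sets = 1)
      rows[[length(rows) + 1L]] <-
        data.frame(cloning_rate = rates[ri], replicate = rep, mean_fis = m)
    }
  }
  do.call(rbind, rows)
}

#' Smallest indistinguishable sexual-reproduction rate in a sweep
#'
#' A cloning rate is *indistinguishable* from fully sexual reproduction when
#' at least half of its replicate mean-F_IS values fall inside the central
#' 95% interval of the cloning-rate-0 means; it is *below* that interval when
#' the mean of its replicate means is under the interval's lower edge.
#' Reports the smallest sexual-reproduction rate `100 * (1 - cloning_rate)`
#' (percent) that is indistinguishable while every higher cloning rate in the
#' grid falls below.
#'
#' @param sweep a data.frame from [cloning_rate_sweep()].
#' @return A list: `threshold_percent`, `table` (per-rate summary).
#' @export
sexual_rate_threshold <- function(sweep) {
  ref <- sweep$mean_fis[sweep$cloning_rate == 0]
  if (length(ref) == 0L) stop("sweep must include cloning rate 0")
  band <- quantile(ref, c(0.025, 0.975), names = FALSE)
  rates <- sort(unique(sweep$cloning_rate))
  tab <- do.call(rbind, lapply(rates, function(r) {
    m <- sweep$mean_fis[sweep$cloning_rate == r]
    data.frame(cloning_rate = r,
               sexual_percent = 100 * (1 - r),
               mean = mean(m),
               frac_in_band = mean(m >= band[1L] & m <= band[2L]),
               below = mean(m) < band[1L])
  }))
  tab$indistinguishable <- tab$frac_in_band >= 0.5
  threshold <- NA_real_
  for (k in order(tab$cloning_rate, decreasing = TRUE)) {
    higher <- tab$cloning_rate > tab$cloning_rate[k]
    if (tab$indistinguishable[k] && all(tab$below[higher])) {
      threshold <- tab$sexual_percent[k]
      break
    }
  }
  list(threshold_percent = threshold, table = tab, band = band)
}
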