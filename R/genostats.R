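# Per-site inbreeding coefficients and allelic-state statistics for small
# samples of diploid genotypes. F_IS follows the convention 1 - Ho/He with the
# Hardy-Weinberg expected heterozygote *count* rounded to the nearest integer
# before the ratio is taken; its value is 0 at Hardy-Weinberg proportions and
# -1 when every individual is heterozygous (the strict-clonality limit).

.round_he <- function(x, rounding) {
  if (rounding == "even") round(x) else floor(x + 0.5)
}

#' Per-site inbreeding coefficient F_IS from genotype counts
#'
#' For a biallelic site with genotype counts `(n_AA, n_AB, n_BB)`, computes
#' the allele frequency `p = (2 n_AA + n_AB) / (2n)`, the expected
#' heterozygote count `He = round(2 p (1 - p) n)`, and
#' `F_IS = 1 - Ho / He` with `Ho = n_AB`. Rounding of the fractional expected
#' count is half-to-even by default (`rounding = "up"` selects half-up). If
#' `He` rounds to 0 the coefficient is undefined and flagged.
#'
#' @param genotype_counts integer vector `c(n_AA, n_AB, n_BB)`.
#' @param rounding `"even"` (default) or `"up"` tie rule.
#' @return A list of class `fis_result`: `p`, `ho`, `he_raw`, `he`, `fis`,
#'   `undefined`.
#' @export
#' @examples
#' site_fis(c(0, 8, 0))$fis  # all heterozygous: -1
#' site_fis(c(2, 4, 2))$fis  # exact Hardy-Weinberg proportions: 0
site_fis <- function(genotype_counts, rounding = c("even", "up")) {
  rounding <- match.arg(rounding)
  stopifnot(length(genotype_counts) == 3L, all(genotype_counts >= 0))
  n <- sum(genotype_counts)
  if (n < 1L) stop("at least one genotype required")
  p <- (2 * genotype_counts[1L] + genotype_counts[2L]) / (2 * n)
  if (p == 0 || p == 1) stop("no minor allele: monomorphic site")
  he_raw <- 2 * p * (1 - p) * n
  he <- .round_he(he_raw, rounding)
  ho <- genotype_counts[2L]
  undefined <- he == 0
  structure(list(p = p, ho = ho, he_raw = he_raw, he = he,
                 fis = if (undefined) NA_real_ else 1 - ho / he,
                 undefined = undefined),
            class = "fis_result")
}

# allele counts per site over a (possibly subsampled) pair of haplotype
# matrices; returns S x 4 matrix of counts of codes 0..3
.allele_counts <- function(h1, h2) {
  s <- nrow(h1)
  cnt <- matrix(0, nrow = s, ncol = 4L)
  for (a in 0:3) cnt[, a + 1L] <- rowSums(h1 == a) + rowSums(h2 == a)
  cnt
}

# vectorised per-site F_IS machinery shared by fis_by_site and the
# subsampling scheme; returns a data.frame over all sites with allelic counts
.site_stats <- function(h1, h2, rounding = "even") {
  n <- ncol(h1)
  cnt <- .allele_counts(h1, h2)
  n_alleles <- rowSums(cnt > 0L)
  maxc <- do.call(pmax, as.data.frame(cnt))
  mac <- 2L * n - maxc          # minor allele count, valid for biallelic sites
  ho <- rowSums(h1 != h2)
  p <- maxc / (2 * n)
  he_raw <- 2 * p * (1 - p) * n
  he <- .round_he(he_raw, rounding)
  fis <- ifelse(he > 0, 1 - ho / he, NA_real_)
  data.frame(n_alleles = n_alleles, mac = mac, ho = ho, p = p,
             he_raw = he_raw, he = he, fis = fis,
             undefined = he == 0)
}

#' Per-site F_IS for the biallelic sites of a sample
#'
#' @param x a `sample_set`.
#' @param mac_min minimum minor allele count (default 0: no filter).
#' @param rounding tie rule for the expected heterozygote count.
#' @return A data.frame with one row per retained biallelic site: `contig`,
#'   `pos`, `mac`, `ho`, `he_raw`, `he`, `fis`, `undefined`.
#' @export
fis_by_site <- function(x, mac_min = 0, rounding = c("even", "up")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(x, "sample_set"))
  st <- .site_stats(x$hap1, x$hap2, rounding)
  keep <- st$n_alleles == 2L & st$mac >= mac_min
  cbind(data.frame(contig = x$contig[keep], pos = x$pos[keep]),
        st[keep, c("mac", "ho", "p", "he_raw", "he", "fis", "undefined")])
}

#' Minor allele count of each biallelic site
#'
#' Counts copies of the rarer allele among the `2n` sampled chromosomes.
#' Sites that are not biallelic get `NA`.
#'
#' @param x a `sample_set`.
#' @return Integer vector over sites.
#' @export
minor_allele_count <- function(x) {
  stopifnot(inherits(x, "sample_set"))
  st <- .site_stats(x$hap1, x$hap2)
  ifelse(st$n_alleles == 2L, as.integer(st$mac), NA_integer_)
}

#' Filter a sample to biallelic sites with minor allele count >= `mac_min`
#'
#' @param x a `sample_set`.
#' @param mac_min minimum minor allele count (default 4).
#' @return The filtered `sample_set`.
#' @export
filter_mac <- function(x, mac_min = 4) {
  mac <- minor_allele_count(x)
  keep <- which(!is.na(mac) & mac >= mac_min)
  subset_sites(x, keep)
}

#' Subset a sample to a set of sites
#' @param x a `sample_set`.
#' @param idx site indices to keep.
#' @return The subsetted `sample_set`.
#' @export
subset_sites <- function(x, idx) {
  stopifnot(inherits(x, "sample_set"))
  for (f in c("contig", "pos", "gpos", "anc", "eff"))
    x[[f]] <- x[[f]][idx]
  x$hap1 <- x$hap1[idx, , drop = FALSE]
  x$hap2 <- x$hap2[idx, , drop = FALSE]
  if (!is.null(x$ps)) x$ps <- x$ps[idx, , drop = FALSE]
  x
}

#' Mean F_IS over random sets of individuals and SNPs
#'
#' Repeats `n_sets` times: draw `n_individuals` individuals without
#' replacement, keep the sites that are biallelic with minor allele
#' count of at least `mac_min` *within the subsample*, draw `n_snps` of them without
#' replacement (all qualifying SNPs if fewer), and average the per-site
#' F_IS (sites whose rounded expected heterozygote count is 0 are excluded
#' from the mean). This is the subsampling scheme used to compare observed
#' data against simulated cloning-rate sweeps.
#'
#' @param x a `sample_set`.
#' @param n_individuals individuals per set (default 8).
#' @param mac_min minor-allele-count filter applied within the subsample.
#' @param n_snps SNPs per set (default 200).
#' @param n_sets number of random sets (default 100).
#' @param rounding tie rule for the expected heterozygote count.
#' @return Numeric vector of `n_sets` set means.
#' @export
subsample_mean_fis <- function(x, n_individuals = 8, mac_min = 4,
                               n_snps = 200, n_sets = 100,
                               rounding = c("even", "up")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(x, "sample_set"))
  n <- length(x$individuals)
  if (n < n_individuals) stop("fewer individuals than n_individuals")
  vapply(seq_len(n_sets), function(b) {
    ids <- sample.int(n, n_individuals)
    st <- .site_stats(x$hap1[, ids, drop = FALSE],
                      x$hap2[, ids, drop = FALSE], rounding)
    ok <- which(st$n_alleles == 2L & st$mac >= mac_min & !st$undefined)
    if (length(ok) == 0L) stop("no qualifying SNPs in subsample")
    if (length(ok) > n_snps) ok <- ok[sample.int(length(ok), n_snps)]
    mean(st$fis[ok])
  }, numeric(1))
}

#' One-sided clonality p-value from set means
#'
#' The fraction of simulated set means greater than or equal to the minimum
#' observed set mean. No multiple-comparison correction is applied.
#'
#' @param observed_set_means set means computed from the observed sample.
#' @param simulated_set_means set means computed from a simulated scenario.
#' @return A single p-value in \[0, 1\].
#' @export
#' @examples
#' clonality_pvalue(c(-0.09, 0.01), c(-0.9, -0.5, 0.0, 0.1))  # 0.5
clonality_pvalue <- function(observed_set_means, simulated_set_means) {
  stopifnot(length(observed_set_means) > 0, length(simulated_set_means) > 0)
  mean(simulated_set_means >= min(observed_set_means))
}

#' Allelic state of each site
#'
#' Classifies every site of a sample by its number of distinct alleles and
#' the unordered heterozygote classes present. For triallelic sites with
#' alleles A, B and C, three heterozygote classes (A/B, A/C, B/C) are
#' possible; a site carrying all three where the least frequent class occurs
#' in exactly one individual reports that individual as the private-het
#' carrier.
#'
#' @param x a `sample_set` (no missing genotypes).
#' @return A data.frame over sites: `contig`, `pos`, `n_alleles`,
#'   `n_het_classes`, `all_three_hets` (triallelic with all 3 classes),
#'   `private_het_carrier` (individual label or `NA`).
#' @export
classify_allelic_state <- function(x) {
  stopifnot(inherits(x, "sample_set"))
  s <- n_sites(x)
  cnt <- .allele_counts(x$hap1, x$hap2)
  n_alleles <- rowSums(cnt > 0L)
  lo <- pmin(x$hap1, x$hap2)
  hi <- pmax(x$hap1, x$hap2)
  het <- lo != hi
  n_het_classes <- integer(s)
  all_three <- logical(s)
  carrier <- rep(NA_character_, s)
  for (j in seq_len(s)) {
    hj <- which(het[j, ])
    if (length(hj) == 0L) next
    cls <- paste(lo[j, hj], hi[j, hj], sep = "/")
    tab <- table(cls)
    n_het_classes[j] <- length(tab)
    if (n_alleles[j] == 3L && length(tab) == 3L) {
      all_three[j] <- TRUE
      least <- which(tab == min(tab))
      if (length(least) == 1L && tab[least] == 1L)
        carrier[j] <- x$individuals[hj[cls == names(tab)[least]]]
    }
  }
  data.frame(contig = x$contig, pos = x$pos, n_alleles = n_alleles,
             n_het_classes = n_het_classes, all_three_hets = all_three,
             private_het_carrier = carrier, stringsAsFactors = FALSE)
}

#' Enrichment test for triallelic sites carrying all three heterozygotes
#'
#' A triallelic site requires at least one extra mutation on top of a
#' biallelic one; the per-site probability of such an event is estimated as
#' `P3 = N3 / (N2 + N3)`. Without genetic exchange, a triallelic site
#' displaying *all three* heterozygous genotypes requires yet another
#' mutation, so the expected number of such sites is `P3 * N3`. The observed
#' count is compared with a two-sided one-sample Z-test for proportions
#' (no continuity correction).
#'
#' @param N2,N3 numbers of biallelic and triallelic sites.
#' @param observed_threehet observed number of triallelic sites with all
#'   three heterozygote classes.
#' @return A list of class `triallelic_summary`: `N2`, `N3`, `P3`,
#'   `expected`, `observed`, `fold_enrichment`, `z`, `p_value`,
#'   `undefined` (TRUE when `N3 = 0`).
#' @export
#' @examples
#' triallelic_enrichment(9900, 100, 22)$fold_enrichment  # 22
triallelic_enrichment <- function(N2, N3, observed_threehet) {
  stopifnot(N2 + N3 > 0, observed_threehet <= N3)
  P3 <- N3 / (N2 + N3)
  expected <- P3 * N3
  if (N3 == 0) {
    return(structure(list(N2 = N2, N3 = N3, P3 = P3, expected = 0,
                          observed = observed_threehet,
                          fold_enrichment = NA_real_, z = NA_real_,
                          p_value = NA_real_, undefined = TRUE),
                     class = "triallelic_summary"))
  }
  phat <- observed_threehet / N3
  z <- (phat - P3) / sqrt(P3 * (1 - P3) / N3)
  structure(list(N2 = N2, N3 = N3, P3 = P3, expected = expected,
                 observed = observed_threehet,
                 fold_enrichment = observed_threehet / expected,
                 z = z, p_value = 2 * pnorm(-abs(z)), undefined = FALSE),
            class = "triallelic_summary")
}

#' Triallelic summary of a sample
#'
#' Tabulates biallelic (`N2`) and triallelic (`N3`) site counts, the observed
#' number of triallelic sites with all three heterozygote classes, runs
#' [triallelic_enrichment()], and collects private-heterozygote carriers.
#'
#' @param x a `sample_set`.
#' @return A `triallelic_summary` with an extra `private_het_carriers`
#'   character vector (one entry per qualifying site).
#' @export
triallelic_summary <- function(x) {
  cls <- classify_allelic_state(x)
  N2 <- sum(cls$n_alleles == 2L)
  N3 <- sum(cls$n_alleles == 3L)
  obs <- sum(cls$all_three_hets)
  out <- triallelic_enrichment(N2, N3, obs)
  out$private_het_carriers <- cls$private_het_carrier[!is.na(cls$private_het_carrier)]
  out
}

#' Uniformity of private heterozygotes across individuals
#'
#' Chi-square goodness-of-fit of the per-individual counts of private
#' heterozygous genotypes against a uniform expectation. Under clonality with
#' cross-sample contamination the private heterozygotes would concentrate in
#' the contaminated individuals; under genetic exchange they are spread
#' uniformly.
#'
#' @param carriers character vector, the carrier individual of each site.
#' @param individuals all individual labels (fixes zero counts).
#' @return A list: `counts` (named per-individual), `statistic`, `df`, `p_value`.
#' @export
private_het_uniformity <- function(carriers, individuals) {
  counts <- table(factor(carriers, levels = individuals))
  k <- length(individuals)
  expected <- length(carriers) / k
  statistic <- sum((counts - expected)^2 / expected)
  df <- k - 1L
  list(counts = counts, statistic = statistic, df = df,
       p_value = pchisq(statistic, df, lower.tail = FALSE))
}
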