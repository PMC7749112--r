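# Linkage-disequilibrium statistics: r2 between phased haplotypes, squared
# genotype correlations from unphased data, pseudo-haplotypes from
# all-homozygous sites, distance binning with percentile-bootstrap CIs, a
# LOESS decay curve with a cross-contig baseline readout, and three
# per-segment recombination tests (r2-distance correlation, sum of distances
# over four-gamete pairs, and the pairwise homoplasy index), each with a
# position-permutation null. Permutation p-values use the add-one convention
# (b + 1) / (m + 1) so they are never exactly zero.

#' Two-locus r-squared from phased haplotypes
#'
#' `r2 = D^2 / (pA (1 - pA) pB (1 - pB))` with `D = f(AB) - pA * pB`,
#' computed over the haplotypes in which both sites are observed. Both sites
#' must be biallelic and polymorphic.
#'
#' @param hap_i,hap_j allele vectors of the two sites across the same
#'   haplotypes.
#' @return r-squared in \[0, 1\].
#' @export
#' @examples
#' x <- rep(c(1, 1, 0, 0), c(6, 2, 2, 6))  # AB=6 Ab=2 aB=2 ab=6
#' y <- rep(c(1, 0, 1, 0), c(6, 2, 2, 6))
#' haplotype_r2(x, y)  # 0.25
haplotype_r2 <- function(hap_i, hap_j) {
  stopifnot(length(hap_i) == length(hap_j))
  ai <- unique(hap_i)
  aj <- unique(hap_j)
  if (length(ai) != 2L || length(aj) != 2L)
    stop("both sites must be biallelic and polymorphic")
  xi <- as.numeric(hap_i == ai[1L])
  xj <- as.numeric(hap_j == aj[1L])
  pa <- mean(xi)
  pb <- mean(xj)
  d <- mean(xi * xj) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Squared Pearson correlation between genotype dosages
#'
#' LD measured from unphased genotypes: the square of the Pearson correlation
#' between the dosage vectors (0, 1, 2 copies of an allele) of two sites
#' across individuals. Does not rely on phasing; squaring removes the
#' arbitrary sign of the allele coding.
#'
#' @param dosage_i,dosage_j dosage vectors across the same individuals.
#' @return Squared correlation in \[0, 1\].
#' @export
genotype_corr2 <- function(dosage_i, dosage_j) {
  stopifnot(length(dosage_i) == length(dosage_j))
  if (sd(dosage_i) == 0 || sd(dosage_j) == 0)
    stop("constant dosage vector")
  n <- length(dosage_i)
  sxy <- sum(dosage_i * dosage_j) - sum(dosage_i) * sum(dosage_j) / n
  sxx <- sum(dosage_i^2) - sum(dosage_i)^2 / n
  syy <- sum(dosage_j^2) - sum(dosage_j)^2 / n
  (sxy * sxy) / (sxx * syy)
}

#' Pseudo-haplotypes from sites homozygous in every individual
#'
#' Keeps the biallelic sites at which every individual is homozygous; each
#' individual then contributes a single unambiguous allele per site, yielding
#' one pseudo-haplotype per individual that can feed [pair_r2_table()]
#' without any phasing information.
#'
#' @param x a `sample_set`.
#' @return A list: `haps` (individuals x sites allele matrix), `contig`,
#'   `pos`. Empty (with a warning) if no site qualifies.
#' @export
homozygote_haplotypes <- function(x) {
  stopifnot(inherits(x, "sample_set"))
  st <- .site_stats(x$hap1, x$hap2)
  keep <- which(st$n_alleles == 2L & st$ho == 0L)
  if (length(keep) == 0L) {
    warning("no all-homozygous biallelic sites")
    return(list(haps = matrix(0L, length(x$individuals), 0L),
                contig = character(0), pos = integer(0)))
  }
  list(haps = t(x$hap1[keep, , drop = FALSE]),
       contig = x$contig[keep], pos = x$pos[keep])
}

# recode biallelic columns of a haplotype matrix (haplotypes x sites) to 0/1
.binarize <- function(haps) {
  apply(haps, 2L, function(col) as.numeric(col != col[1L]))
}

#' Pairwise LD table from phased haplotypes or pseudo-haplotypes
#'
#' Computes r-squared for every pair of biallelic sites with minor allele
#' count >= `mac_min` among the haplotypes. Within-contig pairs closer than
#' `max_dist` form the decay records; pairs on different contigs (distance
#' undefined) are sampled as the unlinked baseline.
#'
#' @param haps haplotype matrix (haplotypes in rows, sites in columns).
#' @param contig,pos site coordinates.
#' @param mac_min minor-allele-count filter (allele copies among haplotypes).
#' @param max_dist maximum within-contig distance retained (default 4000 bp).
#' @param n_baseline maximum number of cross-contig pairs sampled.
#' @param statistic label recorded in the result (`"r2"` or
#'   `"genotype-corr2"`).
#' @return A data.frame of class `pair_table` (`contig`, `pos1`, `pos2`,
#'   `distance`, `value`, `same_contig`); cross-contig rows have
#'   `distance = NA`.
#' @export
pair_r2_table <- function(haps, contig, pos, mac_min = 4, max_dist = 4000,
                          n_baseline = 20000, statistic = "r2") {
  nh <- nrow(haps)
  nall <- apply(haps, 2L, function(col) length(unique(col)))
  mac <- apply(haps, 2L, function(col) {
    tab <- tabulate(col + 1L, 4L)
    sum(tab) - max(tab)
  })
  keep <- which(nall == 2L & mac >= mac_min)
  if (length(keep) < 2L)
    return(structure(data.frame(contig = character(0), pos1 = integer(0),
                                pos2 = integer(0), distance = integer(0),
                                value = numeric(0), same_contig = logical(0)),
                     class = c("pair_table", "data.frame"),
                     statistic = statistic))
  x <- .binarize(haps[, keep, drop = FALSE])
  contig <- contig[keep]
  pos <- pos[keep]
  r2 <- suppressWarnings(cor(x))^2
  idx <- which(upper.tri(r2), arr.ind = TRUE)
  i <- idx[, 1L]
  j <- idx[, 2L]
  same <- contig[i] == contig[j]
  dist <- abs(pos[j] - pos[i])
  within <- same & dist <= max_dist
  cross <- which(!same)
  if (length(cross) > n_baseline)
    cross <- sample(cross, n_baseline)
  sel <- c(which(within), cross)
  out <- data.frame(contig = ifelse(same[sel], contig[i[sel]], NA_character_),
                    pos1 = pos[i[sel]], pos2 = pos[j[sel]],
                    distance = ifelse(same[sel], dist[sel], NA_integer_),
                    value = r2[cbind(i[sel], j[sel])],
                    same_contig = same[sel],
                    stringsAsFactors = FALSE)
  structure(out, class = c("pair_table", "data.frame"), statistic = statistic)
}

#' Pairwise LD table from unphased genotype correlations
#'
#' Same record structure as [pair_r2_table()] but the statistic is the
#' squared Pearson correlation between genotype dosages across individuals
#' ([genotype_corr2()]), so no phasing is needed.
#'
#' @param x a `sample_set`.
#' @inheritParams pair_r2_table
#' @return A `pair_table` with statistic tag `"genotype-corr2"`.
#' @export
genotype_pair_table <- function(x, mac_min = 4, max_dist = 4000,
                                n_baseline = 20000) {
  stopifnot(inherits(x, "sample_set"))
  st <- .site_stats(x$hap1, x$hap2)
  keep <- which(st$n_alleles == 2L & st$mac >= mac_min)
  minor <- apply(cbind(x$hap1[keep, , drop = FALSE],
                       x$hap2[keep, , drop = FALSE]), 1L, function(r) {
    tab <- tabulate(r + 1L, 4L)
    which(tab > 0 & tab < max(tab))[1L] - 1L
  })
  minor[is.na(minor)] <- vapply(which(is.na(minor)), function(q) {
    r <- c(x$hap1[keep[q], ], x$hap2[keep[q], ])
    sort(unique(r))[2L]
  }, numeric(1))
  dos <- (x$hap1[keep, , drop = FALSE] == minor) +
         (x$hap2[keep, , drop = FALSE] == minor)
  ok <- apply(dos, 1L, sd) > 0
  keep <- keep[ok]
  dos <- dos[ok, , drop = FALSE]
  contig <- x$contig[keep]
  pos <- x$pos[keep]
  r2 <- suppressWarnings(cor(t(dos)))^2
  idx <- which(upper.tri(r2), arr.ind = TRUE)
  i <- idx[, 1L]
  j <- idx[, 2L]
  same <- contig[i] == contig[j]
  dist <- abs(pos[j] - pos[i])
  within <- same & dist <= max_dist
  cross <- which(!same)
  if (length(cross) > n_baseline) cross <- sample(cross, n_baseline)
  sel <- c(which(within), cross)
  out <- data.frame(contig = ifelse(same[sel], contig[i[sel]], NA_character_),
                    pos1 = pos[i[sel]], pos2 = pos[j[sel]],
                    distance = ifelse(same[sel], dist[sel], NA_integer_),
                    value = r2[cbind(i[sel], j[sel])],
                    same_contig = same[sel],
                    stringsAsFactors = FALSE)
  structure(out, class = c("pair_table", "data.frame"),
            statistic = "genotype-corr2")
}

#' Bin pair statistics by distance with bootstrap confidence intervals
#'
#' Within-contig pairs are binned by distance, either into fixed-width bins
#' (left-closed, default 200 bp up to `max_dist`) or into `n_bins`
#' equal-count bins. Each bin's mean gets a percentile bootstrap CI
#' (`n_boot` replicates). Cross-contig pairs are summarised as the unlinked
#' baseline (mean, median, 10th-90th percentiles), attached as
#' `attr(, "baseline")`.
#'
#' @param pair_table a `pair_table`.
#' @param scheme `"width"` or `"equal_count"`.
#' @param width bin width in bp (width scheme).
#' @param max_dist maximum distance analysed (width scheme).
#' @param n_bins number of bins (equal-count scheme).
#' @param n_boot bootstrap replicates (default 1000).
#' @param conf confidence level (default 0.95).
#' @return A data.frame (`bin`, `lower`, `upper`, `n`, `mean`, `ci_lo`,
#'   `ci_hi`) with a `baseline` attribute.
#' @export
bin_and_bootstrap <- function(pair_table, scheme = c("width", "equal_count"),
                              width = 200, max_dist = 4000, n_bins = 4,
                              n_boot = 1000, conf = 0.95) {
  scheme <- match.arg(scheme)
  w <- pair_table[pair_table$same_contig & !is.na(pair_table$distance), ]
  if (scheme == "width") {
    edges <- seq(0, max_dist, by = width)
    if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
    w <- w[w$distance <= max_dist, ]
    binid <- findInterval(w$distance, edges, rightmost.closed = TRUE)
  } else {
    qs <- unique(quantile(w$distance, probs = seq(0, 1, length.out = n_bins + 1)))
    edges <- qs
    binid <- findInterval(w$distance, edges, rightmost.closed = TRUE)
  }
  nb <- length(edges) - 1L
  alpha <- (1 - conf) / 2
  rows <- lapply(seq_len(nb), function(b) {
    v <- w$value[binid == b]
    if (length(v) == 0L)
      return(data.frame(bin = b, lower = edges[b], upper = edges[b + 1L],
                        n = 0L, mean = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_))
    boots <- vapply(seq_len(n_boot), function(r)
      mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
    ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    data.frame(bin = b, lower = edges[b], upper = edges[b + 1L],
               n = length(v), mean = mean(v), ci_lo = ci[1L], ci_hi = ci[2L])
  })
  out <- do.call(rbind, rows)
  base <- pair_table$value[!pair_table$same_contig]
  attr(out, "baseline") <-
    if (length(base)) list(n = length(base), mean = mean(base),
                           se = sd(base) / sqrt(length(base)),
                           median = median(base),
                           q10 = quantile(base, 0.1, names = FALSE),
                           q90 = quantile(base, 0.9, names = FALSE))
    else NULL
  out
}

# r2 values and distances for all polymorphic pairs within one segment
.segment_pairs <- function(haps, pos) {
  nall <- apply(haps, 2L, function(col) length(unique(col)))
  keep <- which(nall == 2L)
  x <- .binarize(haps[, keep, drop = FALSE])
  pos <- pos[keep]
  s <- length(pos)
  if (s < 2L) return(list(n_snps = s))
  r2 <- suppressWarnings(cor(x))^2
  idx <- which(upper.tri(r2), arr.ind = TRUE)
  list(n_snps = s, pos = pos,
       i = idx[, 1L], j = idx[, 2L],
       r2 = r2[idx],
       dist = abs(pos[idx[, 2L]] - pos[idx[, 1L]]),
       x = x)
}

#' Per-segment test: correlation of r-squared with distance
#'
#' Pearson correlation of r2 with physical distance over all polymorphic
#' pairs of a phased segment. The null distribution permutes the SNP
#' positions among the observed positions (haplotype columns fixed);
#' recombination predicts a *negative* correlation, so the one-sided p-value
#' is the fraction of permutations with correlation <= the observed one
#' (add-one convention). Bonferroni correction across segments is the
#' caller's responsibility.
#'
#' @param haps haplotype matrix (haplotypes x sites) of the segment.
#' @param pos SNP positions (bp).
#' @param n_perm permutations (default 10000).
#' @return A list: `correlation`, `p_value`, `n_snps`, `skipped` (TRUE when
#'   fewer than 4 SNPs or fewer than 2 polymorphic pairs).
#' @export
segment_r2_distance_test <- function(haps, pos, n_perm = 10000) {
  sp <- .segment_pairs(haps, pos)
  if (sp$n_snps < 4L || length(sp$r2) < 2L || sd(sp$r2) == 0 || sd(sp$dist) == 0)
    return(list(correlation = NA_real_, p_value = NA_real_,
                n_snps = sp$n_snps, skipped = TRUE))
  obs <- cor(sp$r2, sp$dist)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pp <- sample(sp$pos)
    d <- abs(pp[sp$j] - pp[sp$i])
    if (sd(d) == 0) next
    if (cor(sp$r2, d) <= obs) hits <- hits + 1L
  }
  list(correlation = obs, p_value = (hits + 1) / (n_perm + 1),
       n_snps = sp$n_snps, skipped = FALSE)
}

#' Per-segment test: sum of distances between four-gamete pairs
#'
#' `D4` is the sum of physical distances over SNP pairs displaying all four
#' gametes among the segment's haplotypes. Recombination concentrates
#' four-gamete pairs at large distances, so the one-sided p-value is the
#' fraction of position permutations with `D4` at least as large as observed
#' (add-one convention). With no four-gamete pair, `D4 = 0` and `p = 1`.
#'
#' @inheritParams segment_r2_distance_test
#' @return A list: `D4`, `p_value`, `n_four_gamete`, `n_snps`, `skipped`.
#' @export
sum_of_distances_test <- function(haps, pos, n_perm = 10000) {
  sp <- .segment_pairs(haps, pos)
  if (sp$n_snps < 4L || length(sp$r2) < 2L)
    return(list(D4 = NA_real_, p_value = NA_real_, n_four_gamete = NA_integer_,
                n_snps = sp$n_snps, skipped = TRUE))
  x <- sp$x
  n11 <- crossprod(x)
  n10 <- crossprod(x, 1 - x)
  n01 <- t(n10)
  n00 <- crossprod(1 - x)
  four <- (n11 > 0 & n10 > 0 & n01 > 0 & n00 > 0)[cbind(sp$i, sp$j)]
  nf <- sum(four)
  if (nf == 0L)
    return(list(D4 = 0, p_value = 1, n_four_gamete = 0L,
                n_snps = sp$n_snps, skipped = FALSE))
  obs <- sum(sp$dist[four])
  fi <- sp$i[four]
  fj <- sp$j[four]
  hits <- 0L
  for (b in seq_len(n_perm)) {
    pp <- sample(sp$pos)
    if (sum(abs(pp[fj] - pp[fi])) >= obs) hits <- hits + 1L
  }
  list(D4 = obs, p_value = (hits + 1) / (n_perm + 1),
       n_four_gamete = nf, n_snps = sp$n_snps, skipped = FALSE)
}

#' Per-segment pairwise homoplasy index (PHI) test
#'
#' For binary sites the incompatibility score of a pair of
#' parsimony-informative sites is 1 when all four gametes are present and 0
#' otherwise; PHI is the mean score over nearby pairs: those separated by at
#' most `window_w` alignment columns (base pairs when `pos` is supplied,
#' informative-site columns otherwise). Without recombination, homoplasy
#' (incompatibility from recurrent mutation) is independent of site order, so
#' nearby pairs score like random ones; recombination lets nearby sites share
#' genealogies, making them *more compatible* than distant ones, so the test
#' rejects when the observed PHI is low relative to random orderings of the
#' sites. Significance comes from permuting the site order (default) or from
#' a normal approximation with moments estimated from the permuted values.
#'
#' @param haps haplotype matrix (haplotypes x sites).
#' @param window_w window width (default 100).
#' @param n_perm permutations (default 1000).
#' @param method `"permutation"` (default) or `"normal"`.
#' @param pos optional site positions in bp; when given, pair separation and
#'   the permutation reshuffling are on the positional scale, matching runs
#'   on full sequence alignments where non-SNP columns are monomorphic.
#' @return A list: `phi`, `p_value`, `n_informative`, `method`, `skipped`.
#' @export
phi_test <- function(haps, window_w = 100, n_perm = 1000,
                     method = c("permutation", "normal"), pos = NULL) {
  method <- match.arg(method)
  nall <- apply(haps, 2L, function(col) length(unique(col)))
  counts2 <- apply(haps, 2L, function(col) {
    tab <- table(col)
    length(tab) == 2L && min(tab) >= 2L
  })
  keep <- which(nall == 2L & counts2)
  if (length(keep) < 2L)
    return(list(phi = NA_real_, p_value = NA_real_,
                n_informative = length(keep), method = method, skipped = TRUE))
  x <- .binarize(haps[, keep, drop = FALSE])
  m <- ncol(x)
  n11 <- crossprod(x)
  n10 <- crossprod(x, 1 - x)
  incompat <- (n11 > 0 & n10 > 0 & t(n10) > 0 & crossprod(1 - x) > 0) * 1
  coords <- if (is.null(pos)) seq_len(m) else pos[keep]
  idx <- which(upper.tri(incompat), arr.ind = TRUE)
  inc <- incompat[idx]
  phi_of_coords <- function(cc) {
    sep <- abs(cc[idx[, 2L]] - cc[idx[, 1L]])
    inwin <- sep <= window_w
    if (!any(inwin)) return(NA_real_)
    mean(inc[inwin])
  }
  obs <- phi_of_coords(coords)
  if (is.na(obs))
    return(list(phi = NA_real_, p_value = NA_real_, n_informative = m,
                method = method, skipped = TRUE))
  perms <- vapply(seq_len(n_perm), function(b) phi_of_coords(sample(coords)),
                  numeric(1))
  perms <- perms[!is.na(perms)]
  p <- if (method == "permutation") {
    (sum(perms <= obs) + 1) / (length(perms) + 1)
  } else {
    mu <- mean(perms)
    sdev <- sd(perms)
    if (sdev == 0) { if (obs < mu) 0 else 1 } else pnorm(obs, mu, sdev)
  }
  list(phi = obs, p_value = p, n_informative = m, method = method,
       skipped = FALSE)
}

#' LOESS decay curve of LD versus distance
#'
#' Second-degree local regression (span 0.4 by default) of the pair statistic
#' on physical distance, evaluated on a distance grid, plus the smallest
#' distance at which the smoothed curve first enters the cross-contig
#' baseline band (baseline mean +/- 1 SE) — the distance at which LD has
#' decayed to its unlinked level.
#'
#' @param pair_table a `pair_table` with within-contig and (for the baseline)
#'   cross-contig rows.
#' @param span LOESS smoothing parameter (default 0.4).
#' @param degree LOESS degree (default 2).
#' @param grid_n grid resolution.
#' @return A list: `grid`, `fit`, `baseline_mean`, `baseline_se`,
#'   `baseline_crossing` (NA when the curve never enters the band).
#' @export
decay_curve <- function(pair_table, span = 0.4, degree = 2, grid_n = 200) {
  w <- pair_table[pair_table$same_contig & !is.na(pair_table$distance), ]
  if (nrow(w) < 10L) stop("too few pairs for a decay curve")
  fit <- loess(value ~ distance, data = w, span = span, degree = degree)
  grid <- seq(min(w$distance), max(w$distance), length.out = grid_n)
  pred <- predict(fit, newdata = data.frame(distance = grid))
  base <- pair_table$value[!pair_table$same_contig]
  bm <- if (length(base)) mean(base) else NA_real_
  bs <- if (length(base) > 1L) sd(base) / sqrt(length(base)) else NA_real_
  crossing <- NA_real_
  if (!is.na(bm)) {
    inside <- which(!is.na(pred) & pred <= bm + bs & pred >= bm - bs)
    below <- which(!is.na(pred) & pred <= bm + bs)
    hit <- if (length(inside)) inside[1L] else if (length(below)) below[1L] else NA
    if (!is.na(hit)) crossing <- grid[hit]
  }
  list(grid = grid, fit = pred, baseline_mean = bm, baseline_se = bs,
       baseline_crossing = crossing)
}
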