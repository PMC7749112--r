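# The modified four-gamete test. Within-locus gene conversion can only turn a
# heterozygous genotype homozygous, never the reverse, so it cannot produce a
# pair of individuals each heterozygous at two loci that jointly carry all
# four two-locus gametes. A SNP pair heterozygous in two individuals and
# displaying all four gametes ("recombinant" pair) therefore requires
# reciprocal recombination (or recurrent mutation, whose incidence does not
# grow with distance), making the fraction of recombinant pairs as a function
# of physical distance a conversion-proof recombination signal.

#' Two-locus gamete set of two doubly heterozygous individuals
#'
#' Both individuals must be heterozygous at both sites and phased; the four
#' phased haplotypes (two per individual) each define a two-locus gamete, and
#' the set of distinct gametes is returned. A set of size 4 is the
#' recombinant configuration unreachable by within-locus gene conversion.
#'
#' @param ind1,ind2 2 x 2 matrices: rows = the individual's two haplotypes,
#'   columns = the two sites; entries are allele codes.
#' @return Character vector of distinct gametes (`"a:b"`), length 2-4.
#' @export
#' @examples
#' g <- gamete_set(rbind(c(0, 0), c(1, 1)), rbind(c(0, 1), c(1, 0)))
#' length(g)  # 4: recombinant configuration
gamete_set <- function(ind1, ind2) {
  stopifnot(is.matrix(ind1), is.matrix(ind2),
            dim(ind1) == c(2L, 2L), dim(ind2) == c(2L, 2L))
  if (ind1[1L, 1L] == ind1[2L, 1L] || ind1[1L, 2L] == ind1[2L, 2L] ||
      ind2[1L, 1L] == ind2[2L, 1L] || ind2[1L, 2L] == ind2[2L, 2L])
    stop("both individuals must be heterozygous at both sites")
  g <- rbind(ind1, ind2)
  unique(paste(g[, 1L], g[, 2L], sep = ":"))
}

# records for one individual pair within one segment; h1/h2 are S x n site
# matrices of phased alleles
.pair_records <- function(h1, h2, pos, contig, a, b) {
  het_a <- h1[, a] != h2[, a]
  het_b <- h1[, b] != h2[, b]
  shared <- which(het_a & het_b)
  m <- length(shared)
  if (m < 2L) return(NULL)
  H <- cbind(h1[shared, a], h2[shared, a], h1[shared, b], h2[shared, b])
  multi <- apply(H, 1L, function(r) length(unique(r)) > 2L)
  idx <- which(upper.tri(diag(m)), arr.ind = TRUE)
  i <- idx[, 1L]
  j <- idx[, 2L]
  ng <- integer(length(i))
  simple <- !multi[i] & !multi[j]
  if (any(simple)) {
    # biallelic fast path: each individual's two gametes are complements, so
    # the union has size 4 iff the two individuals' phase parities differ
    q <- (H[, 1L] != H[, 3L])  # parity of ind a vs ind b hap1 alleles
    ng[simple] <- ifelse(q[i[simple]] != q[j[simple]], 4L, 2L)
  }
  for (k in which(!simple)) {
    s <- shared[i[k]]
    t <- shared[j[k]]
    g <- unique(c(paste(h1[s, a], h1[t, a]), paste(h2[s, a], h2[t, a]),
                  paste(h1[s, b], h1[t, b]), paste(h2[s, b], h2[t, b])))
    ng[k] <- length(g)
  }
  data.frame(ind1 = a, ind2 = b, contig = contig,
             pos1 = pos[shared[i]], pos2 = pos[shared[j]],
             distance = abs(pos[shared[j]] - pos[shared[i]]),
             n_gametes = ng, recombinant = ng == 4L,
             stringsAsFactors = FALSE)
}

#' Scan phased segments for recombinant SNP pairs
#'
#' For every unordered pair of individuals and every phased segment,
#' enumerates the SNP pairs at which both individuals are heterozygous,
#' classifies each by its gamete-set size, and records the physical distance.
#' A pair is recombinant when all four gametes are present. Classification is
#' symmetric in individual order and in site order.
#'
#' @param segments a `sample_set` (each contig is treated as one fully phased
#'   segment) or a list of `segment_haplotypes` from
#'   [common_phased_segments()].
#' @param individuals optional subset of individual labels.
#' @param dedupe drop duplicate site pairs that recur in several individual
#'   pairs, keeping each site pair once (default FALSE: pooled with
#'   duplicates).
#' @return A data.frame of `HetPairRecord`s: `ind1`, `ind2`, `contig`,
#'   `pos1`, `pos2`, `distance`, `n_gametes`, `recombinant`.
#' @export
scan_recombinant_pairs <- function(segments, individuals = NULL,
                                   dedupe = FALSE) {
  segs <- .as_segment_list(segments)
  out <- list()
  for (seg in segs) {
    inds <- seg$individuals
    use <- if (is.null(individuals)) seq_along(inds) else
      which(inds %in% individuals)
    if (length(use) < 2L) next
    for (ai in seq_along(use)) {
      for (bi in seq_len(ai - 1L)) {
        a <- use[ai]
        b <- use[bi]
        rec <- .pair_records(seg$hap1, seg$hap2, seg$pos, seg$contig, a, b)
        if (!is.null(rec)) {
          rec$ind1 <- inds[pmin(a, b)]
          rec$ind2 <- inds[pmax(a, b)]
          out[[length(out) + 1L]] <- rec
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(ind1 = character(0), ind2 = character(0),
                      contig = character(0), pos1 = integer(0),
                      pos2 = integer(0), distance = integer(0),
                      n_gametes = integer(0), recombinant = logical(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  if (dedupe)
    res <- res[!duplicated(res[, c("contig", "pos1", "pos2")]), ]
  rownames(res) <- NULL
  res
}

# coerce a sample_set (contig-wise) or a list of segments to a segment list
.as_segment_list <- function(segments) {
  if (inherits(segments, "sample_set")) {
    stopifnot(isTRUE(segments$phased))
    lapply(unique(segments$contig), function(ctg) {
      idx <- which(segments$contig == ctg)
      structure(list(contig = ctg,
                     start = min(segments$pos[idx]),
                     end = max(segments$pos[idx]),
                     pos = segments$pos[idx],
                     hap1 = segments$hap1[idx, , drop = FALSE],
                     hap2 = segments$hap2[idx, , drop = FALSE],
                     individuals = segments$individuals),
                class = "segment_haplotypes")
    })
  } else if (inherits(segments, "segment_haplotypes")) {
    list(segments)
  } else {
    stopifnot(all(vapply(segments, inherits, TRUE, "segment_haplotypes")))
    segments
  }
}

#' Recombinant fraction by distance bin
#'
#' Subdivides the records into `n_bins` distance bins with approximately
#' equal numbers of cases (boundary records fall in the lower bin), computes
#' the per-bin recombinant fraction with a percentile bootstrap CI, and tests
#' every pair of bins by permutation (records shuffled between the two bins),
#' two-sided with Bonferroni correction.
#'
#' @param records output of [scan_recombinant_pairs()].
#' @param n_bins number of equal-count bins (default 4).
#' @param n_boot bootstrap replicates for the CIs (default 1000).
#' @param n_perm permutations per bin comparison (default 10000).
#' @param bonferroni apply Bonferroni correction to the pairwise p-values.
#' @return A list: `bins` (data.frame with `bin`, `lower`, `upper`, `n`,
#'   `n_recombinant`, `fraction`, `ci_lo`, `ci_hi`) and `comparisons`
#'   (data.frame with `bin_a`, `bin_b`, `p_value`).
#' @export
recombinant_fraction_by_bin <- function(records, n_bins = 4, n_boot = 1000,
                                        n_perm = 10000, bonferroni = TRUE) {
  if (nrow(records) < n_bins) stop("fewer records than bins")
  qs <- quantile(records$distance, probs = seq(0, 1, length.out = n_bins + 1))
  edges <- unique(qs)
  binid <- cut(records$distance, breaks = edges, include.lowest = TRUE,
               labels = FALSE, right = TRUE)
  nb <- length(edges) - 1L
  bins <- do.call(rbind, lapply(seq_len(nb), function(b) {
    r <- records$recombinant[binid == b]
    boots <- vapply(seq_len(n_boot), function(k)
      mean(r[sample.int(length(r), replace = TRUE)]), numeric(1))
    data.frame(bin = b, lower = edges[b], upper = edges[b + 1L],
               n = length(r), n_recombinant = sum(r), fraction = mean(r),
               ci_lo = quantile(boots, 0.025, names = FALSE),
               ci_hi = quantile(boots, 0.975, names = FALSE))
  }))
  cmb <- combn(nb, 2L)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    a <- cmb[1L, k]
    b <- cmb[2L, k]
    ra <- records$recombinant[binid == a]
    rb <- records$recombinant[binid == b]
    pooled <- c(ra, rb)
    na <- length(ra)
    obs <- abs(mean(ra) - mean(rb))
    hits <- 0L
    for (q in seq_len(n_perm)) {
      sh <- sample(pooled)
      if (abs(mean(sh[seq_len(na)]) - mean(sh[-seq_len(na)])) >= obs - 1e-12)
        hits <- hits + 1L
    }
    data.frame(bin_a = a, bin_b = b,
               p_value = (hits + 1) / (n_perm + 1))
  }))
  if (bonferroni)
    comparisons$p_value <- pmin(1, comparisons$p_value * nrow(comparisons))
  list(bins = bins, comparisons = comparisons)
}

#' Permutation test for the distance shift of recombinant pairs
#'
#' Tests whether recombinant and non-recombinant SNP pairs differ in mean
#' physical distance by randomly relabeling records (`n_perm` times) and
#' comparing the absolute difference of class means; two-sided, add-one
#' convention.
#'
#' @param records output of [scan_recombinant_pairs()]; both classes must be
#'   non-empty.
#' @param n_perm permutations (default 10000).
#' @return A list: `mean_recombinant`, `mean_non_recombinant`,
#'   `difference`, `p_value`.
#' @export
distance_shift_test <- function(records, n_perm = 10000) {
  dr <- records$distance[records$recombinant]
  dn <- records$distance[!records$recombinant]
  if (length(dr) == 0L || length(dn) == 0L)
    stop("both recombinant and non-recombinant records are required")
  obs <- abs(mean(dr) - mean(dn))
  all_d <- c(dr, dn)
  nr <- length(dr)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    sh <- sample(all_d)
    if (abs(mean(sh[seq_len(nr)]) - mean(sh[-seq_len(nr)])) >= obs - 1e-12)
      hits <- hits + 1L
  }
  list(mean_recombinant = mean(dr), mean_non_recombinant = mean(dn),
       difference = obs, p_value = (hits + 1) / (n_perm + 1))
}
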