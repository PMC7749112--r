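# Quality control of read-based phasing output: per-individual phased blocks
# with switch/mismatch quality scores are filtered for conflicting read
# evidence, split or discarded at low-quality SNPs, complemented with
# embedded homozygous SNPs, and intersected across individuals into commonly
# phased segments. All filters are idempotent.

#' Construct a phased block
#'
#' A phased block is one individual's jointly phased set of heterozygous SNPs
#' on one contig: positions in strictly increasing order, the two haplotype
#' allele vectors, and optional per-SNP switch and mismatch quality scores
#' (phred-like; `Inf` when not available, e.g. truth haplotypes).
#'
#' @param individual individual label.
#' @param contig contig label.
#' @param pos strictly increasing SNP positions.
#' @param hap1,hap2 allele vectors (codes 0-3), heterozygous at every SNP
#'   unless `hom_ok = TRUE` (used internally after homozygote
#'   complementation).
#' @param switch_qual,mismatch_qual per-SNP quality scores.
#' @param hom_ok allow homozygous SNPs in the block.
#' @return An object of class `phased_block`.
#' @export
phased_block <- function(individual, contig, pos, hap1, hap2,
                         switch_qual = rep(Inf, length(pos)),
                         mismatch_qual = rep(Inf, length(pos)),
                         hom_ok = FALSE) {
  stopifnot(length(pos) == length(hap1), length(hap1) == length(hap2),
            length(switch_qual) == length(pos),
            length(mismatch_qual) == length(pos))
  if (length(pos) > 1L && any(diff(pos) <= 0))
    stop("positions must be strictly increasing")
  if (!hom_ok && any(hap1 == hap2))
    stop("block SNPs must be heterozygous")
  structure(list(individual = individual, contig = contig,
                 pos = as.integer(pos),
                 hap1 = as.integer(hap1), hap2 = as.integer(hap2),
                 switch_qual = switch_qual, mismatch_qual = mismatch_qual),
            class = "phased_block")
}

#' @export
print.phased_block <- function(x, ...) {
  cat(sprintf("<phased_block> %s %s: %d SNPs [%d-%d]\n", x$individual,
              x$contig, length(x$pos),
              if (length(x$pos)) min(x$pos) else NA,
              if (length(x$pos)) max(x$pos) else NA))
  invisible(x)
}

#' Truth haplotypes of a sample as phased blocks
#'
#' One block per individual per contig covering the heterozygous SNPs, with
#' infinite quality scores — the idealised phasing against which pipeline
#' round-trips are checked.
#'
#' @param x a phased `sample_set`.
#' @return A list of `phased_block`s.
#' @export
sample_to_blocks <- function(x) {
  stopifnot(inherits(x, "sample_set"), isTRUE(x$phased))
  out <- list()
  for (ctg in unique(x$contig)) {
    idx <- which(x$contig == ctg)
    for (i in seq_along(x$individuals)) {
      het <- idx[x$hap1[idx, i] != x$hap2[idx, i]]
      if (length(het) == 0L) next
      out[[length(out) + 1L]] <-
        phased_block(x$individuals[i], ctg, x$pos[het],
                     x$hap1[het, i], x$hap2[het, i])
    }
  }
  out
}

#' Filter a block on conflicting read evidence
#'
#' A diploid individual can carry at most two haplotypes for any pair of SNP
#' sites; read fragments supporting more than two distinct two-site allele
#' combinations indicate PCR template switching or paralogous alignment. The
#' block is dropped iff any within-block site pair has more than two distinct
#' combinations each supported by at least `min_reads` reads. Missing
#' evidence for a pair is treated as non-conflicting.
#'
#' @param block a `phased_block`.
#' @param evidence data.frame with columns `individual`, `contig`, `pos1`,
#'   `pos2`, `combo`, `count` (read-fragment support per two-site allele
#'   combination).
#' @param min_reads minimum read support for a combination to count
#'   (default 1).
#' @return TRUE (keep) or FALSE (drop).
#' @export
conflicting_evidence_filter <- function(block, evidence, min_reads = 1) {
  stopifnot(inherits(block, "phased_block"))
  ev <- evidence[evidence$individual == block$individual &
                 evidence$contig == block$contig &
                 evidence$pos1 %in% block$pos &
                 evidence$pos2 %in% block$pos &
                 evidence$count >= min_reads, , drop = FALSE]
  if (nrow(ev) == 0L) return(TRUE)
  combos <- tapply(ev$combo, paste(ev$pos1, ev$pos2),
                   function(v) length(unique(v)))
  all(combos <= 2L)
}

#' Split or drop a block at low-quality SNPs
#'
#' A SNP is low-quality when its switch *or* mismatch quality is below
#' `q_threshold`. Blocks with more than one low-quality SNP are discarded
#' (empty list); blocks with exactly one are split at that SNP, which is
#' excluded from both resulting sub-blocks; blocks with none pass unchanged.
#'
#' @param block a `phased_block`.
#' @param q_threshold quality threshold (default 100).
#' @return A list of 0, 1 or 2 `phased_block`s.
#' @export
quality_split <- function(block, q_threshold = 100) {
  stopifnot(inherits(block, "phased_block"))
  low <- which(block$switch_qual < q_threshold |
               block$mismatch_qual < q_threshold)
  if (length(low) > 1L) return(list())
  if (length(low) == 0L) return(list(block))
  take <- function(idx) {
    if (length(idx) == 0L) return(NULL)
    phased_block(block$individual, block$contig, block$pos[idx],
                 block$hap1[idx], block$hap2[idx],
                 block$switch_qual[idx], block$mismatch_qual[idx])
  }
  parts <- list(take(seq_len(low - 1L)),
                take(seq(low + 1L, length.out = length(block$pos) - low)))
  parts[!vapply(parts, is.null, TRUE)]
}

#' Add embedded homozygous SNPs to a phased block
#'
#' Homozygous SNPs located strictly between the block's first and last
#' heterozygous SNPs are assigned to both haplotypes (their phase is trivially
#' known). Heterozygous SNPs absent from the block (phasing failed there) are
#' never added.
#'
#' @param block a `phased_block`.
#' @param genotypes a `sample_set` providing the individual's genotypes on
#'   the block's contig.
#' @return The extended `phased_block`.
#' @export
complement_homozygous <- function(block, genotypes) {
  stopifnot(inherits(block, "phased_block"), inherits(genotypes, "sample_set"))
  i <- match(block$individual, genotypes$individuals)
  if (is.na(i)) stop("individual not found in genotypes")
  if (length(block$pos) == 0L) return(block)
  span <- range(block$pos)
  on_ctg <- which(genotypes$contig == block$contig &
                  genotypes$pos > span[1L] & genotypes$pos < span[2L])
  hom <- on_ctg[genotypes$hap1[on_ctg, i] == genotypes$hap2[on_ctg, i]]
  hom <- hom[!(genotypes$pos[hom] %in% block$pos)]
  if (length(hom) == 0L) return(block)
  pos <- c(block$pos, genotypes$pos[hom])
  o <- order(pos)
  phased_block(block$individual, block$contig, pos[o],
               c(block$hap1, genotypes$hap1[hom, i])[o],
               c(block$hap2, genotypes$hap2[hom, i])[o],
               c(block$switch_qual, rep(Inf, length(hom)))[o],
               c(block$mismatch_qual, rep(Inf, length(hom)))[o],
               hom_ok = TRUE)
}

#' Extract segments commonly phased in all requested individuals
#'
#' Finds, per contig, the maximal intervals over which every requested
#' individual has one covering phased block, takes the SNP positions present
#' in all covering blocks, and keeps segments containing at least
#' `min_nonsingleton` non-singleton SNPs (sites whose minor allele occurs in
#' at least two of the phased haplotypes).
#'
#' @param blocks list of `phased_block`s (all individuals mixed).
#' @param individuals individual labels that must be covered.
#' @param min_nonsingleton minimum number of non-singleton SNPs (default 15).
#' @return A list of `segment_haplotypes`: `contig`, `start`, `end`, `pos`,
#'   `hap1`, `hap2` (sites x individuals), `individuals`, plus a
#'   `nonsingleton` logical attribute over sites.
#' @export
common_phased_segments <- function(blocks, individuals,
                                   min_nonsingleton = 15) {
  blocks <- blocks[vapply(blocks, function(b) b$individual %in% individuals,
                          TRUE)]
  n <- length(individuals)
  out <- list()
  for (ctg in unique(vapply(blocks, `[[`, "", "contig"))) {
    cb <- blocks[vapply(blocks, function(b) b$contig == ctg, TRUE)]
    owners <- vapply(cb, `[[`, "", "individual")
    if (length(unique(owners)) < n) next
    spans <- t(vapply(cb, function(b) range(b$pos), integer(2)))
    # sweep the block boundaries for intervals covered once per individual
    pts <- sort(unique(c(spans)))
    for (k in seq_len(length(pts) - 1L)) {
      lo <- pts[k]
      hi <- pts[k + 1L]
      covering <- which(spans[, 1L] <= lo & spans[, 2L] >= hi)
      if (length(covering) < n) next
      if (length(unique(owners[covering])) < n) next
      # extend to the maximal interval covered by this same block set
      lo <- max(spans[covering, 1L])
      hi <- min(spans[covering, 2L])
      key <- paste(ctg, lo, hi)
      if (key %in% names(out)) next
      shared <- Reduce(intersect, lapply(cb[covering], function(b)
        b$pos[b$pos >= lo & b$pos <= hi]))
      if (length(shared) == 0L) next
      shared <- sort(shared)
      h1 <- h2 <- matrix(0L, nrow = length(shared), ncol = n,
                         dimnames = list(NULL, individuals))
      for (b in cb[covering]) {
        i <- match(b$individual, individuals)
        m <- match(shared, b$pos)
        h1[, i] <- b$hap1[m]
        h2[, i] <- b$hap2[m]
      }
      cnt <- .allele_counts(h1, h2)
      srt <- t(apply(cnt, 1L, sort, decreasing = TRUE))
      nonsing <- srt[, 2L] >= 2L
      if (sum(nonsing) < min_nonsingleton) next
      seg <- structure(list(contig = ctg, start = lo, end = hi,
                            pos = shared, hap1 = h1, hap2 = h2,
                            individuals = individuals),
                       class = "segment_haplotypes")
      attr(seg, "nonsingleton") <- nonsing
      out[[key]] <- seg
    }
  }
  unname(out)
}

#' @export
print.segment_haplotypes <- function(x, ...) {
  cat(sprintf("<segment_haplotypes> %s:%d-%d, %d SNPs x %d individuals\n",
              x$contig, x$start, x$end, length(x$pos), ncol(x$hap1)))
  invisible(x)
}

#' Switch inconsistency between two independent phasings
#'
#' Compares the relative phase orientation of consecutive shared heterozygous
#' SNPs between two phasings of the same individual. Within spans co-phased
#' in both (same block in both phasings), an adjacent SNP pair is
#' inconsistent iff the relative orientation flips between the phasings;
#' a global haplotype flip of either phasing leaves the result unchanged.
#'
#' @param phasing_a,phasing_b lists of `phased_block`s for one individual.
#' @return A list: `fraction` (inconsistent adjacent pairs / comparable
#'   pairs; `NA` when there are none), `n_pairs`, `n_inconsistent`,
#'   `contig_flags` (named logical: any inconsistency per contig).
#' @export
switch_inconsistency <- function(phasing_a, phasing_b) {
  inds <- unique(c(vapply(phasing_a, `[[`, "", "individual"),
                   vapply(phasing_b, `[[`, "", "individual")))
  if (length(inds) != 1L)
    stop("both phasings must belong to the same single individual")
  total <- 0L
  bad <- 0L
  flags <- logical(0)
  for (ba in phasing_a) {
    for (bb in phasing_b) {
      if (bb$contig != ba$contig) next
      shared <- intersect(ba$pos, bb$pos)
      ia <- match(shared, ba$pos)
      ib <- match(shared, bb$pos)
      het <- ba$hap1[ia] != ba$hap2[ia] & bb$hap1[ib] != bb$hap2[ib]
      same_pair <- (pmin(ba$hap1[ia], ba$hap2[ia]) ==
                      pmin(bb$hap1[ib], bb$hap2[ib])) &
                   (pmax(ba$hap1[ia], ba$hap2[ia]) ==
                      pmax(bb$hap1[ib], bb$hap2[ib]))
      use <- which(het & same_pair)
      if (length(use) < 2L) next
      orient <- ba$hap1[ia[use]] == bb$hap1[ib[use]]
      flips <- sum(diff(orient) != 0L)
      total <- total + length(use) - 1L
      bad <- bad + flips
      ctg <- ba$contig
      flags[ctg] <- isTRUE(flags[ctg]) || flips > 0L
    }
  }
  list(fraction = if (total > 0L) bad / total else NA_real_,
       n_pairs = total, n_inconsistent = bad, contig_flags = flags)
}
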