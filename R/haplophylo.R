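# Haplotype-incongruence detection. Within a phased segment each individual
# carries two haplotypes; under clonal propagation (or gene conversion) the
# two haplotypes of one individual find their closest relatives in a single
# other individual, whereas genetic exchange lets them pair with different
# individuals (incongruent grouping). Trees are neighbor-joining with SNP
# column bootstrap and midpoint rooting; externally inferred trees can be
# ingested as newick and scanned identically.

#' Pairwise haplotype distance matrix of a segment
#'
#' Hamming distances (SNP-difference counts) between all 2n haplotypes over
#' the segment's phased SNP columns; non-SNP positions are treated as
#' monomorphic and contribute nothing. Leaves are labeled
#' `"<individual>.1"` / `"<individual>.2"`.
#'
#' @param segment a `segment_haplotypes`.
#' @return A symmetric integer matrix with zero diagonal; the proportion of
#'   differences (counts / number of SNP columns) is attached as
#'   `attr(, "proportion")`.
#' @export
hap_distance_matrix <- function(segment) {
  stopifnot(inherits(segment, "segment_haplotypes"))
  n <- ncol(segment$hap1)
  labs <- c(paste0(segment$individuals, ".1"), paste0(segment$individuals, ".2"))
  h <- cbind(segment$hap1, segment$hap2)
  m <- ncol(h)
  d <- matrix(0L, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      d[i, j] <- d[j, i] <- sum(h[, i] != h[, j])
    }
  }
  attr(d, "proportion") <- d / max(1L, nrow(h))
  d
}

#' Closest haplotypic counterpart with an ambiguity margin
#'
#' The counterpart of a haplotype is the closest haplotype belonging to a
#' *different* individual (both haplotypes of the focal individual are
#' excluded from candidacy). The match is unambiguous when the runner-up is
#' at least `margin` SNPs farther than the best match (ties are ambiguous).
#'
#' @param d distance matrix from [hap_distance_matrix()].
#' @param focal focal haplotype label (e.g. `"IND01.1"`).
#' @param margin required gap `d2 - d1` in SNPs (default 3).
#' @return A list of class `counterpart_result`: `focal`, `best`, `d1`,
#'   `d2`, `unambiguous`.
#' @export
closest_counterpart <- function(d, focal, margin = 3) {
  labs <- rownames(d)
  stopifnot(focal %in% labs)
  own <- sub("\\.[12]$", "", focal)
  cand <- labs[sub("\\.[12]$", "", labs) != own]
  if (length(cand) < 2L) stop("need at least 2 candidate haplotypes")
  dd <- d[focal, cand]
  o <- order(dd)
  structure(list(focal = focal, best = cand[o[1L]],
                 d1 = dd[o[1L]], d2 = dd[o[2L]],
                 unambiguous = (dd[o[2L]] - dd[o[1L]]) >= margin),
            class = "counterpart_result")
}

# reverse best match: is `focal` the unique closest counterpart of `other`?
.is_reciprocal <- function(d, other, focal) {
  labs <- rownames(d)
  own <- sub("\\.[12]$", "", other)
  cand <- labs[sub("\\.[12]$", "", labs) != own]
  dd <- d[other, cand]
  best <- cand[dd == min(dd)]
  length(best) == 1L && best == focal
}

#' Classify the haplotype grouping of one individual in one segment
#'
#' Implements the counterpart procedure: (1) both of the individual's
#' haplotypes H1, H2 must have unambiguous closest counterparts H1', H2'
#' (margin in SNPs); (2) to exclude groupings that gene conversion could
#' cause, the counterpart distances d(H1, H1') and d(H2, H2') must both be
#' strictly smaller than the within-individual distance d(H1, H2); (3) both
#' matches must be reciprocal best matches. The grouping is then congruent if
#' H1' and H2' belong to a single individual and incongruent otherwise (the
#' pattern being the unordered pair of partner individuals); if any step
#' fails the segment is undetermined for this individual.
#'
#' @param segment a `segment_haplotypes` (or a precomputed distance matrix
#'   via `d`).
#' @param individual focal individual label.
#' @param margin ambiguity margin in SNPs (default 3).
#' @param d optional distance matrix (overrides `segment`).
#' @return A list: `status` (`"congruent"`, `"incongruent"` or
#'   `"undetermined"`), `pattern` (partner individuals; `NULL` when
#'   undetermined), `counterparts`, `reason` (for undetermined calls).
#' @export
classify_grouping <- function(segment, individual, margin = 3, d = NULL) {
  if (is.null(d)) d <- hap_distance_matrix(segment)
  h1 <- paste0(individual, ".1")
  h2 <- paste0(individual, ".2")
  stopifnot(h1 %in% rownames(d))
  und <- function(reason) list(status = "undetermined", pattern = NULL,
                               counterparts = NULL, reason = reason)
  c1 <- closest_counterpart(d, h1, margin)
  c2 <- closest_counterpart(d, h2, margin)
  if (!c1$unambiguous || !c2$unambiguous) return(und("ambiguous counterpart"))
  within <- d[h1, h2]
  if (!(c1$d1 < within && c2$d1 < within))
    return(und("counterpart not closer than within-individual distance"))
  if (!.is_reciprocal(d, c1$best, h1) || !.is_reciprocal(d, c2$best, h2))
    return(und("not a reciprocal best match"))
  p1 <- sub("\\.[12]$", "", c1$best)
  p2 <- sub("\\.[12]$", "", c2$best)
  list(status = if (p1 == p2) "congruent" else "incongruent",
       pattern = sort(unique(c(p1, p2))),
       counterparts = c(c1$best, c2$best), reason = NULL)
}

#' Classify all individuals of a segment
#'
#' @param segment a `segment_haplotypes`.
#' @param margin ambiguity margin in SNPs.
#' @return A data.frame: `individual`, `status`, `pattern` (partners joined
#'   with `"+"`; `NA` when undetermined).
#' @export
classify_segment <- function(segment, margin = 3) {
  d <- hap_distance_matrix(segment)
  rows <- lapply(segment$individuals, function(ind) {
    g <- classify_grouping(segment, ind, margin, d = d)
    data.frame(individual = ind, status = g$status,
               pattern = if (is.null(g$pattern)) NA_character_ else
                 paste(g$pattern, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Paralog screen from BLAST-style hit summaries
#'
#' A segment is excluded when any of its haplotypes has hits to more than
#' `max_contigs` distinct contigs (diverged repeat families) or more than
#' `max_high_identity` high-identity hits (identity >= `high_identity`;
#' more than two near-identical copies cannot be the two haplotypes of a
#' diploid locus). Haplotypes with no rows are treated as having 0 hits.
#'
#' @param hit_table data.frame with columns `haplotype`, `contig`,
#'   `identity` (0-1 scale), one row per hit.
#' @param haplotypes haplotype labels the segment comprises (defaults to
#'   those present in the table).
#' @param max_contigs maximum distinct hit contigs per haplotype (default 10).
#' @param max_high_identity maximum high-identity hits per haplotype
#'   (default 2).
#' @param high_identity identity threshold (default 0.90).
#' @return TRUE (keep) or FALSE (drop).
#' @export
paralog_screen <- function(hit_table, haplotypes = unique(hit_table$haplotype),
                           max_contigs = 10, max_high_identity = 2,
                           high_identity = 0.90) {
  for (h in haplotypes) {
    rows <- hit_table[hit_table$haplotype == h, , drop = FALSE]
    if (nrow(rows) == 0L) next
    if (length(unique(rows$contig)) > max_contigs) return(FALSE)
    if (sum(rows$identity >= high_identity) > max_high_identity) return(FALSE)
  }
  TRUE
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param d symmetric distance matrix with haplotype labels.
#' @return An unrooted `phylo` tree (class from \pkg{ape}).
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3L) stop("need at least 3 leaves")
  ape::nj(stats::as.dist(d))
}

#' Neighbor-joining tree with SNP-column bootstrap supports
#'
#' Resamples the segment's SNP columns with replacement `n` times, rebuilds
#' the NJ tree for each replicate, and annotates each internal edge of the
#' full-data tree with the percentage of replicates containing the same
#' bipartition.
#'
#' @param segment a `segment_haplotypes`.
#' @param n bootstrap replicates (default 1000).
#' @return A `phylo` tree whose `node.label` holds supports in percent.
#' @export
bootstrap_support <- function(segment, n = 1000) {
  d <- hap_distance_matrix(segment)
  tree <- nj_tree(d)
  h <- cbind(segment$hap1, segment$hap2)
  labs <- rownames(d)
  reps <- lapply(seq_len(n), function(b) {
    cols <- sample.int(nrow(h), replace = TRUE)
    hb <- h[cols, , drop = FALSE]
    m <- length(labs)
    db <- matrix(0L, m, m, dimnames = list(labs, labs))
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        db[i, j] <- db[j, i] <- sum(hb[, i] != hb[, j])
      }
    }
    ape::nj(stats::as.dist(db))
  })
  cl <- ape::prop.clades(tree, reps, rooted = FALSE)
  cl[is.na(cl)] <- 0L
  tree$node.label <- round(100 * cl / n)
  tree
}

#' Midpoint-root a tree
#'
#' Places the root halfway along the path between the two most distant
#' leaves. With all-zero branch lengths the rooting is arbitrary and flagged
#' with a warning.
#'
#' @param tree a `phylo` tree with branch lengths >= 0.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(tree$edge.length) && all(tree$edge.length == 0)) {
    warning("all branch lengths are zero; midpoint root is arbitrary")
    return(phangorn::midpoint(tree))
  }
  phangorn::midpoint(tree)
}

#' Scan a rooted tree for well-supported target-exclusive clades
#'
#' Enumerates the maximal clades composed exclusively of the target
#' haplotypes whose bipartition support meets `support_min`, reporting each
#' clade's size, whether it contains exactly one haplotype of every target
#' individual, and whether the root bipartition separates it from everything
#' else.
#'
#' @param tree a rooted `phylo` with `node.label` supports in percent
#'   (absent labels are treated as 100, so truth topologies can be scanned
#'   without bootstrapping).
#' @param targets target haplotype labels (e.g. every haplotype of the
#'   putative hybrid individuals).
#' @param support_min minimum bootstrap support in percent (default 70).
#' @return A list: `clades` (data.frame with `size`, `support`,
#'   `one_per_individual`, `root_separated`, `leaves`), and
#'   `any_qualifying`.
#' @export
monophyly_scan <- function(tree, targets, support_min = 70) {
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree))
  ntip <- length(tree$tip.label)
  target_ind <- unique(sub("\\.[12]$", "", targets))
  supports <- tree$node.label
  if (is.null(supports)) supports <- rep(100, tree$Nnode)
  supports <- suppressWarnings(as.numeric(supports))
  supports[is.na(supports)] <- 100
  root_node <- ntip + 1L
  root_children <- tree$edge[tree$edge[, 1L] == root_node, 2L]

  clade_tips <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  nodes <- seq_len(tree$Nnode) + ntip
  is_target_clade <- vapply(nodes, function(nd)
    all(clade_tips(nd) %in% targets), TRUE)
  qual <- nodes[is_target_clade &
                supports[nodes - ntip] >= support_min]
  # keep maximal qualifying clades only
  parent <- function(nd) tree$edge[tree$edge[, 2L] == nd, 1L]
  maximal <- qual[vapply(qual, function(nd) {
    p <- parent(nd)
    length(p) == 0L || !(p %in% qual)
  }, TRUE)]
  rows <- lapply(maximal, function(nd) {
    tips <- clade_tips(nd)
    inds <- sub("\\.[12]$", "", tips)
    data.frame(size = length(tips),
               support = supports[nd - ntip],
               one_per_individual = !anyDuplicated(inds) &&
                 setequal(inds, target_ind),
               root_separated = nd %in% root_children,
               leaves = paste(sort(tips), collapse = ","),
               stringsAsFactors = FALSE)
  })
  clades <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size = integer(0), support = numeric(0),
               one_per_individual = logical(0), root_separated = logical(0),
               leaves = character(0), stringsAsFactors = FALSE)
  list(clades = clades, any_qualifying = nrow(clades) > 0L)
}

#' Read and write trees in newick format
#'
#' Thin wrappers over \pkg{ape} so externally inferred trees (e.g. maximum
#' likelihood trees) can be scanned with [monophyly_scan()] exactly like the
#' internal NJ trees.
#'
#' @param path file path.
#' @param tree a `phylo`.
#' @return `read_newick` returns a `phylo`; `write_newick` returns the path
#'   invisibly.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
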