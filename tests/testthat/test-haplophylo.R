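test_that("haplotype distance matrices equal brute-force Hamming counts", {
  set.seed(1)
  h1 <- matrix(sample(0:1, 20 * 4, TRUE), 20, 4)
  h2 <- matrix(sample(0:1, 20 * 4, TRUE), 20, 4)
  g <- make_segment(h1, h2)
  d <- hap_distance_matrix(g)
  expect_equal(unname(d), brute_hamming(cbind(h1, h2)), ignore_attr = TRUE)
  expect_true(all(diag(d) == 0))
  expect_identical(d, t(d))
  expect_equal(attr(d, "proportion")[1, 5], d["IND01.1", "IND01.2"] / 20)
  # identical haplotypes at distance 0; 3 of 20 differences at 0.15
  g2 <- make_segment(cbind(rep(0L, 20), rep(0L, 20)),
                     cbind(c(rep(1L, 3), rep(0L, 17)), rep(0L, 20)))
  d2 <- hap_distance_matrix(g2)
  expect_equal(d2["IND01.1", "IND02.1"], 0)
  expect_equal(d2["IND01.1", "IND01.2"], 3)
  expect_equal(attr(d2, "proportion")["IND01.1", "IND01.2"], 0.15)
})

test_that("counterpart ambiguity margins behave at the stated boundaries", {
  labs <- c("A.1", "A.2", "B.1", "B.2", "C.1", "C.2")
  d <- matrix(10, 6, 6, dimnames = list(labs, labs))
  diag(d) <- 0
  d["A.1", "B.1"] <- d["B.1", "A.1"] <- 1
  d["A.1", "C.1"] <- d["C.1", "A.1"] <- 4
  cc <- closest_counterpart(d, "A.1")
  expect_identical(cc$best, "B.1")
  expect_true(cc$unambiguous)       # 4 - 1 >= 3
  d["A.1", "C.1"] <- d["C.1", "A.1"] <- 3
  expect_false(closest_counterpart(d, "A.1")$unambiguous)  # 3 - 1 < 3
  d["A.1", "C.1"] <- d["C.1", "A.1"] <- 1
  expect_false(closest_counterpart(d, "A.1")$unambiguous)  # tie
  # own-individual haplotypes are never candidates
  d["A.1", "A.2"] <- d["A.2", "A.1"] <- 0
  expect_identical(closest_counterpart(d, "A.1")$best, "B.1")
})

test_that("classify_grouping finds a constructed incongruent pattern and
           verifies every rule", {
  # 3 individuals, 40 SNPs; A.1 pairs with B.1, A.2 pairs with C.2
  base <- rep(0L, 40)
  alt <- rep(1L, 40)
  a1 <- base
  b1 <- base; b1[1] <- 1L                     # d(A.1, B.1) = 1
  a2 <- alt
  c2 <- alt; c2[40] <- 0L                     # d(A.2, C.2) = 1
  b2 <- c(rep(0L, 20), rep(1L, 20))           # far from everything
  c1 <- c(rep(1L, 20), rep(0L, 20))
  g <- make_segment(cbind(a1, b2, c1), cbind(a2, b1, c2),
                    individuals = c("A", "B", "C"))
  # built so that B's haplotypes are (b2, b1) and C's are (c1, c2)
  cl <- classify_grouping(g, "A")
  expect_identical(cl$status, "incongruent")
  expect_identical(cl$pattern, c("B", "C"))
  expect_setequal(cl$counterparts, c("B.2", "C.2"))
  # breaking reciprocity: make B.2 closer to B.1 than A.1 is
  d <- hap_distance_matrix(g)
  d["B.2", "B.1"] <- d["B.1", "B.2"] <- 0  # no effect: own individual excluded
  # breaking the within-individual distance rule: identical haplotypes in A
  g0 <- make_segment(cbind(a1, b2, c1), cbind(a1, b1, c2),
                     individuals = c("A", "B", "C"))
  expect_identical(classify_grouping(g0, "A")$status, "undetermined")
})

test_that("clonally duplicated individuals give congruent, never incongruent,
           groupings", {
  set.seed(2)
  for (k in 1:20) {
    h <- matrix(sample(0:1, 30 * 4, TRUE), 30, 4)
    # individual 2 is a mutated clone of individual 1 (1 diff per haplotype);
    # individuals 3 and 4 are distant noise
    h1 <- cbind(h[, 1], h[, 1], sample(0:1, 30, TRUE), sample(0:1, 30, TRUE))
    h1[1, 2] <- 1L - h1[1, 2]
    h2 <- cbind(h[, 2], h[, 2], sample(0:1, 30, TRUE), sample(0:1, 30, TRUE))
    h2[2, 2] <- 1L - h2[2, 2]
    g <- make_segment(h1, h2)
    cl <- classify_grouping(g, "IND01")
    expect_false(identical(cl$status, "incongruent"))
  }
})

test_that("paralog screens apply both hit-count rules at their boundaries", {
  hits <- function(n_ctg, n_high) {
    data.frame(haplotype = "H1",
               contig = sprintf("c%02d", seq_len(n_ctg)),
               identity = c(rep(0.95, n_high), rep(0.7, n_ctg - n_high)))
  }
  expect_true(paralog_screen(hits(10, 2)))
  expect_false(paralog_screen(hits(11, 2)))   # > 10 contigs
  expect_false(paralog_screen(hits(10, 3)))   # > 2 high-identity hits
  expect_true(paralog_screen(hits(10, 2), haplotypes = c("H1", "H2")))  # absent = keep
})

test_that("NJ recovers additive metrics and matches a four-point brute force", {
  # additive quartet: ((a:1,b:2):1.5,(c:3,d:4))
  labs <- c("a", "b", "c", "d")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["a", "b"] <- d["b", "a"] <- 3
  d["a", "c"] <- d["c", "a"] <- 5.5
  d["a", "d"] <- d["d", "a"] <- 6.5
  d["b", "c"] <- d["c", "b"] <- 6.5
  d["b", "d"] <- d["d", "b"] <- 7.5
  d["c", "d"] <- d["d", "c"] <- 7
  tr <- nj_tree(d)
  # brute-force four-point condition picks the ab|cd split
  s1 <- d["a", "b"] + d["c", "d"]
  s2 <- d["a", "c"] + d["b", "d"]
  s3 <- d["a", "d"] + d["b", "c"]
  expect_true(s1 < s2 && s1 < s3 && s2 == s3)
  true_tree <- ape::read.tree(text = "((a:1,b:2):1.5,(c:3,d:4));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(true_tree)), 0,
               ignore_attr = TRUE)
  # recovered patristic distances reproduce the additive input
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[labs, labs]),
               unname(d), tolerance = 1e-9)
  expect_error(nj_tree(d[1:2, 1:2]), "3 leaves")
  expect_equal(ape::Ntip(nj_tree(d[1:3, 1:3])), 3)
})

test_that("five-leaf additive matrices are recovered exactly", {
  newick <- "(((a:1,b:1):1,c:2.5):1,(d:2,e:1.5):0.5);"
  true_tree <- ape::read.tree(text = newick)
  d <- as.matrix(ape::cophenetic.phylo(true_tree))
  tr <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(true_tree)), 0,
               ignore_attr = TRUE)
  labs <- rownames(d)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[labs, labs]),
               unname(d), tolerance = 1e-9)
})

test_that("column bootstrap gives full support to a unanimous split", {
  set.seed(3)
  h1 <- cbind(matrix(0L, 30, 3), matrix(1L, 30, 3))
  h2 <- h1
  h1[1, 1] <- 1L; h1[2, 2] <- 1L; h1[3, 6] <- 0L  # sprinkle variation
  g <- make_segment(h1, h2)
  tr <- bootstrap_support(g, n = 200)
  d <- hap_distance_matrix(g)
  split_support <- max(tr$node.label, na.rm = TRUE)
  expect_gte(split_support, 99)
})

test_that("midpoint rooting places the root on the longest path", {
  # 3-leaf tree with branch lengths 1, 1, 5: the diameter path a-c has length
  # 6, so the root lies on the long branch, 3 from the far leaf
  tr <- ape::read.tree(text = "(a:1,b:1,c:5);")
  r <- midpoint_root(tr)
  expect_true(ape::is.rooted(r))
  depths <- ape::node.depth.edgelength(r)
  leafd <- depths[seq_len(3)]
  names(leafd) <- r$tip.label
  expect_equal(unname(leafd["c"]), 3)
  expect_equal(unname(leafd["a"]), 3)
  expect_equal(max(leafd), 3)
  # balanced ultrametric tree: root at the original center
  tb <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  rb <- midpoint_root(ape::unroot(tb))
  db <- ape::node.depth.edgelength(rb)[1:4]
  expect_true(all(abs(db - 2) < 1e-9))
  # unrooted bipartitions are preserved
  expect_equal(ape::dist.topo(ape::unroot(r), tr), 0, ignore_attr = TRUE)
})

test_that("monophyly scan reports maximal supported target clades, flags
           root separation, and applies the support threshold", {
  txt <- "((L1.1:1,(L2.1:1,L3.1:1)100:1)100:1,((L1.2:1,L4.1:1)90:1,(L4.2:1,(L2.2:1,L3.2:1)100:1)80:1):1);"
  tr <- ape::read.tree(text = txt)
  targets3 <- c("L1.1", "L2.1", "L3.1")
  ms <- monophyly_scan(tr, targets3)
  expect_true(ms$any_qualifying)
  expect_equal(ms$clades$size, 3)
  expect_true(ms$clades$one_per_individual)
  expect_true(ms$clades$root_separated)
  # all six haplotypes of L1-L3 never form a clade here
  ms6 <- monophyly_scan(tr, c(targets3, "L1.2", "L2.2", "L3.2"))
  expect_true(all(ms6$clades$size < 6))
  # scattered targets: no qualifying clade
  none <- monophyly_scan(tr, c("L1.1", "L4.2"))
  expect_false(none$any_qualifying)
  # support boundary: a 69-support clade is excluded at the default threshold
  txt69 <- sub("\\)80:", ")69:", sub("L4.2:1,\\(L2.2:1,L3.2:1\\)100",
                                     "L4.2:1,(L2.2:1,L3.2:1)69", txt))
  tr69 <- ape::read.tree(text = txt69)
  ms69 <- monophyly_scan(tr69, c("L2.2", "L3.2"))
  expect_false(ms69$any_qualifying)
  expect_true(monophyly_scan(tr69, c("L2.2", "L3.2"),
                             support_min = 69)$any_qualifying)
  # invariance to leaf order
  tr_rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  ms_rot <- monophyly_scan(tr_rot, targets3)
  expect_equal(ms_rot$clades$size, ms$clades$size)
  expect_equal(sort(strsplit(ms_rot$clades$leaves, ",")[[1]]),
               sort(strsplit(ms$clades$leaves, ",")[[1]]))
})

test_that("newick import/export round-trips trees for external scanning", {
  tr <- ape::read.tree(text = "((a:1,b:2)75:1,(c:1,d:1)90:2);")
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  tr2 <- read_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  expect_identical(tr2$node.label, tr$node.label)
})
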