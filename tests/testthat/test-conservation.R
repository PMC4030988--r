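aln_tbl <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = names(seqs), seq = unname(seqs))
}

test_that("three-taxon tree solves the pairwise distance equations", {
  # p-distances: ab 2/10, ac 3/10, bc 5/10
  aln <- aln_tbl(
    a = "AAAAAAAAAA",
    b = "CCAAAAAAAA",
    c = "AACCCAAAAA"
  )
  tree <- nj_tree(aln, model = "p")
  el <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(el[["a"]], (0.2 + 0.3 - 0.5) / 2)
  expect_equal(el[["b"]], (0.2 + 0.5 - 0.3) / 2)
  expect_equal(el[["c"]], (0.3 + 0.5 - 0.2) / 2)
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  # disjoint site sets flipped per branch make Hamming distances additive:
  # terminal branches a:2 b:1 c:3 d:1 sites, internal branch 2 sites
  n <- 40
  base <- rep("A", n)
  flip <- function(s, sites) { s[sites] <- "C"; s }
  right <- flip(base, 9:10)               # internal branch
  aln <- aln_tbl(
    a = paste(flip(base, 1:2), collapse = ""),
    b = paste(flip(base, 3), collapse = ""),
    c = paste(flip(right, 4:6), collapse = ""),
    d = paste(flip(right, 7), collapse = "")
  )
  tree <- nj_tree(aln, model = "p")
  # topology: ((a,b),(c,d))
  expect_true(ape::is.monophyletic(ape::unroot(tree), c("a", "b")))
  expect_equal(sum(tree$edge.length) * n, 2 + 1 + 3 + 1 + 2, tolerance = 1e-9)
  tips <- setNames(tree$edge.length, tree$tip.label[tree$edge[, 2]])
  expect_equal(tips[["c"]] * n, 3, tolerance = 1e-9)

  # row order does not change the unrooted tree
  perm <- aln[c(3, 1, 4, 2), ]
  tree2 <- nj_tree(perm, model = "p")
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(tree2))[1], 0)
  expect_equal(sum(tree2$edge.length), sum(tree$edge.length), tolerance = 1e-9)
})

test_that("identical sequences yield zero distances without error", {
  aln <- aln_tbl(a = "AAAA", b = "AAAA", c = "AAAA", d = "AACA")
  tree <- nj_tree(aln)
  expect_s3_class(tree, "phylo")
  expect_true(all(tree$edge.length >= 0))
})

test_that("Fitch counts match hand-worked columns and bounds", {
  tree <- ape::read.tree(text = "((a1:1,a2:1):1,(c1:1,c2:1):1);")
  aln <- aln_tbl(a1 = "AAAD", a2 = "ACAH", c1 = "CAAK", c2 = "CCAW")
  counts <- count_substitutions(aln, tree)
  expect_equal(counts[1], 1L)   # (A,A,C,C) splits with the tree: 1 change
  expect_equal(counts[2], 2L)   # (A,C,A,C) against the tree: 2 changes
  expect_equal(counts[3], 0L)   # invariant column
  expect_equal(counts[4], 3L)   # 4 distinct states: #states - 1

  # gaps are missing data: a gapped leaf adds no constraint
  aln_gap <- aln_tbl(a1 = "A", a2 = "-", c1 = "C", c2 = "C")
  expect_equal(count_substitutions(aln_gap, tree), 1L)
  aln_all_gap <- aln_tbl(a1 = "-", a2 = "-", c1 = "-", c2 = "-")
  expect_equal(count_substitutions(aln_all_gap, tree), 0L)
})

test_that("Fitch counts agree with phangorn's parsimony on random data", {
  skip_if_not_installed("phangorn")
  sim <- make_alignment(n_taxa = 12, n_cols = 120, tree_length = 4, seed = 23)
  tree <- nj_tree(sim$alignment)
  counts <- count_substitutions(sim$alignment, tree)
  m <- do.call(rbind, strsplit(sim$alignment$seq, ""))
  rownames(m) <- sim$alignment$id
  dat <- phangorn::phyDat(m, type = "AA")
  ps <- phangorn::parsimony(tree, dat, method = "fitch", site = "site")
  expect_equal(counts, unname(ps[attr(dat, "index")]))
})

test_that("counting is invariant under consistent leaf relabeling", {
  sim <- make_alignment(n_taxa = 8, n_cols = 60, tree_length = 3, seed = 29)
  tree <- nj_tree(sim$alignment)
  counts <- count_substitutions(sim$alignment, tree)
  perm <- withr::with_seed(1, sample(nrow(sim$alignment)))
  expect_equal(count_substitutions(sim$alignment[perm, ], tree), counts)
  expect_error(count_substitutions(sim$alignment, ape::rtree(8)), "match")
})

test_that("Poisson lower-tail threshold and degenerate lambdas", {
  prof <- call_conserved(c(0, 3, 4, 5, 12), lambda = 10)
  expect_equal(attr(prof, "q_star"), 4L)
  expect_equal(prof$conserved, c(TRUE, TRUE, TRUE, FALSE, FALSE))

  # lambda so small that even 0 is not improbable: nothing can be called
  prof0 <- call_conserved(c(0, 0, 1), lambda = 0.01)
  expect_equal(attr(prof0, "q_star"), -1L)
  expect_false(any(prof0$conserved))

  expect_error(call_conserved(1:3, lambda = 0), "positive")

  # q* non-decreasing in lambda; conserved set shrinks as alpha decreases
  qs <- vapply(c(4, 6, 10, 20, 40), function(l) {
    attr(call_conserved(0:5, l), "q_star")
  }, integer(1))
  expect_true(all(diff(qs) >= 0))
  counts <- rpois(100, 8)
  a1 <- call_conserved(counts, 8, alpha = 0.05)
  a2 <- call_conserved(counts, 8, alpha = 0.01)
  expect_true(all(which(a2$conserved) %in% which(a1$conserved)))
})

test_that("conserved hydrophobic positions map through reference gaps", {
  # reference has gaps at columns 2 and 4; column 7 is its 5th residue
  aln <- aln_tbl(
    ref = "A-L-SKLV",
    h1  = "AALTSKLV",
    h2  = "AALTSKIV",
    h3  = "AGLTSKMV"
  )
  counts <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L)
  prof <- call_conserved(counts, lambda = 10)
  hyd <- conserved_hydrophobic(prof, "ref", aln)
  # column 1 A -> position 1; column 3 L -> position 2; column 7 L -> 5;
  # column 8 V -> 6; serine and lysine columns excluded
  expect_equal(hyd$column, c(1L, 3L, 7L, 8L))
  expect_equal(hyd$position, c(1L, 2L, 5L, 6L))
  expect_equal(hyd$residue, c("A", "L", "L", "V"))
  expect_error(conserved_hydrophobic(prof, "nope", aln), "not found")
})

test_that("planted invariant columns are recovered end to end", {
  planted <- c(10, 40, 77, 120, 200)
  sim <- make_alignment(n_taxa = 24, n_cols = 250, tree_length = 6,
                        planted_conserved = planted, seed = 37)
  tree <- nj_tree(sim$alignment)
  counts <- count_substitutions(sim$alignment, tree)
  prof <- call_conserved(counts, sum(tree$edge.length))
  expect_true(all(prof$conserved[planted]))
})
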