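test_that("two- and three-taxon NJ match the closed-form oracles", {
  d2 <- matrix(c(0, 2, 2, 0), 2L, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$edge.length), c(1, 1))
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3L,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  # pendant lengths b_i = (d_ij + d_ik - d_jk)/2 = 1, 2, 3
  pd <- path_distance_oracle(t3)
  expect_equal(pd[rownames(d3), colnames(d3)], d3, tolerance = 1e-12)
  tip_edges <- t3$edge[, 2L] <= 3L
  lens <- t3$edge.length[tip_edges][order(t3$edge[tip_edges, 2L])]
  expect_equal(lens, c(1, 2, 3))
})

test_that("NJ recovers a planted additive tree exactly", {
  txt <- "((A:1,B:2):1,C:3,D:4);"
  planted <- read_newick(txt)
  d <- path_distance_oracle(planted)
  tr <- nj_tree(d)
  expect_equal(path_distance_oracle(tr)[rownames(d), colnames(d)], d, tolerance = 1e-10)
  # split AB|CD present: pruning A,B leaves C,D adjacent
  expect_true(ape::is.monophyletic(ape::root(tr, "D", resolve.root = TRUE), c("A", "B")))
})

test_that("NJ is exact on additive distances from random trees up to 8 tips", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(4:8, 1L)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.3, 2))
    tr0 <- ape::unroot(tr0)
    d <- path_distance_oracle(tr0)
    tr <- nj_tree(d)
    expect_equal(path_distance_oracle(tr)[rownames(d), colnames(d)], d, tolerance = 1e-8)
  }
})

test_that("negative NJ branch lengths are clamped with a warning", {
  d <- matrix(c(0, 1.5452, 4.9158, 2.7860, 2.4538,
                1.5452, 0, 4.0608, 1.8823, 1.4394,
                4.9158, 4.0608, 0, 2.1721, 3.5557,
                2.7860, 1.8823, 2.1721, 0, 1.2037,
                2.4538, 1.4394, 3.5557, 1.2037, 0), 5L)
  dimnames(d) <- list(letters[1:5], letters[1:5])
  expect_warning(tr <- nj_tree(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("UPGMA matches the hand agglomeration and fixes ultrametric input", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_tree(d)
  h <- attr(tr, "merge_heights")
  expect_equal(h, c(1, 2))
  cd <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(cd, d, tolerance = 1e-12)   # ultrametric fixed point
  # merge heights nondecreasing and output ultrametric for random input
  set.seed(12)
  for (i in 1:10) {
    dr <- random_distance(7L)
    trr <- upgma_tree(dr)
    hh <- attr(trr, "merge_heights")
    expect_true(all(diff(hh) >= -1e-12))
    cdr <- ape::cophenetic.phylo(trr)
    for (k in 1:20) {
      trio <- sample(7L, 3L)
      v <- sort(c(cdr[trio[1], trio[2]], cdr[trio[1], trio[3]], cdr[trio[2], trio[3]]))
      expect_lt(abs(v[2] - v[3]), 1e-9)    # two largest of any trio equal
    }
  }
})

test_that("UPGMA handles equal distances and identical rows", {
  d <- matrix(1, 4L, 4L) - diag(4L)
  dimnames(d) <- list(letters[1:4], letters[1:4])
  tr <- upgma_tree(d)
  expect_equal(max(attr(tr, "merge_heights")), 0.5, tolerance = 1e-12)
  two <- matrix(c(0, 0.8, 0.8, 0), 2L, dimnames = list(c("x", "y"), c("x", "y")))
  tr2 <- upgma_tree(two)
  expect_equal(attr(tr2, "merge_heights"), 0.4)
})

test_that("cophenetic correlation: perfect fit, degenerate error, Pearson oracle", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3L,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(cophenetic_correlation(upgma_tree(d), d), 1, tolerance = 1e-12)
  flat <- matrix(1, 3L, 3L) - diag(3L)
  dimnames(flat) <- dimnames(d)
  expect_error(cophenetic_correlation(upgma_tree(d), flat), "zero variance")
  set.seed(8)
  d1 <- random_distance(6L)
  d2 <- random_distance(6L)
  tr <- upgma_tree(d2)
  r <- cophenetic_correlation(tr, d1)
  cd <- ape::cophenetic.phylo(tr)[rownames(d1), colnames(d1)]
  r_direct <- cor(d1[upper.tri(d1)], cd[upper.tri(cd)])
  expect_equal(r, r_direct, tolerance = 1e-12)
  expect_lt(abs(r), 1)
})

test_that("Mantel test: self-concordance, affine invariance, vegan cross-check", {
  set.seed(31)
  d1 <- random_distance(6L)
  m <- mantel_test(d1, d1, n_perm = 99L, seed = 1L)
  expect_equal(m$statistic, 1)
  expect_equal(m$p.value, 1 / 100)
  d2 <- 3 * d1
  d2[upper.tri(d2) | lower.tri(d2)] <- d2[upper.tri(d2) | lower.tri(d2)] + 0.2
  expect_equal(mantel_test(d1, d2, n_perm = 9L, seed = 1L)$statistic, 1)
  # determinism under seed
  set.seed(31); dd1 <- random_distance(6L); dd2 <- random_distance(6L)
  expect_identical(mantel_test(dd1, dd2, n_perm = 199L, seed = 7L),
                   mantel_test(dd1, dd2, n_perm = 199L, seed = 7L))
  # r agrees with vegan's Mantel statistic
  vr <- suppressMessages(suppressWarnings(
    vegan::mantel(as.dist(dd1), as.dist(dd2), permutations = 99)))
  expect_equal(mantel_test(dd1, dd2, n_perm = 9L, seed = 1L)$statistic,
               unname(vr$statistic), tolerance = 1e-12)
})

test_that("Mantel p-value is invariant to joint relabeling and lies in (0, 1]", {
  set.seed(4)
  d1 <- random_distance(6L)
  d2 <- random_distance(6L)
  m <- mantel_test(d1, d2, n_perm = 199L, seed = 3L)
  perm <- sample(6L)
  m2 <- mantel_test(d1[perm, perm], d2[perm, perm], n_perm = 199L, seed = 3L)
  expect_equal(m$statistic, m2$statistic, tolerance = 1e-12)
  expect_gt(m$p.value, 0)
  expect_lte(m$p.value, 1)
})

test_that("Newick round trip preserves trees to 1e-12 and flags malformed input", {
  t1 <- read_newick("(A:1,B:1);")
  expect_equal(write_newick(t1), "(A:1,B:1);")
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3L,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d3)
  rt <- read_newick(write_newick(tr))
  expect_setequal(rt$tip.label, tr$tip.label)
  expect_equal(path_distance_oracle(rt)[tr$tip.label, tr$tip.label],
               path_distance_oracle(tr)[tr$tip.label, tr$tip.label], tolerance = 1e-12)
  set.seed(2)
  tr2 <- ape::rtree(7, br = function(k) runif(k, 1e-4, 3))
  rt2 <- read_newick(write_newick(tr2))
  expect_equal(path_distance_oracle(rt2)[tr2$tip.label, tr2$tip.label],
               path_distance_oracle(tr2)[tr2$tip.label, tr2$tip.label], tolerance = 1e-12)
  expect_error(read_newick("((A:1,B:1);"), "unclosed")
  expect_error(read_newick("(A:1,B:1));"), "position")
})

test_that("distance validation rejects asymmetric or negative input", {
  bad <- matrix(c(0, 1, 2, 0), 2L)
  expect_error(nj_tree(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2L)
  expect_error(upgma_tree(neg), "nonnegative")
  expect_error(nj_tree(matrix(0, 1L, 1L)), "at least 2")
})
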