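test_that("primer_summary counts match the hand-enumeration oracle", {
  # 6 genotypes x 5 loci with per-locus presence counts 6, 4, 1, 6, 2
  p <- matrix(0L, 6L, 5L, dimnames = list(paste0("g", 1:6), NULL))
  p[, 1L] <- 1L
  p[1:4, 2L] <- 1L
  p[3L, 3L] <- 1L
  p[, 4L] <- 1L
  p[5:6, 5L] <- 1L
  m <- band_matrix(p, primer = "P1", band_bp = c(300, 500, 800, 1200, 650))
  s <- primer_summary(m)
  pooled <- s[s$primer == "all", ]
  expect_equal(pooled$total_bands, 5L)
  expect_equal(pooled$monomorphic_bands, 2L)
  expect_equal(pooled$polymorphic_bands, 3L)
  expect_equal(pooled$polymorphism_percent, 60)
  expect_equal(pooled$unique_bands, 1L)
  expect_equal(pooled$size_min_bp, 300)
  expect_equal(pooled$size_max_bp, 1200)
})

test_that("all-monomorphic and unique-band definition cases", {
  m <- band_matrix(matrix(1L, 3L, 4L, dimnames = list(letters[1:3], NULL)), "P1")
  s <- primer_summary(m)
  expect_true(all(s$polymorphic_bands == 0L))
  expect_true(all(s$polymorphism_percent == 0))
  # a locus present in exactly one genotype is both polymorphic and unique;
  # absent in exactly one is negative_unique but not unique
  p <- rbind(a = c(1L, 0L), b = c(1L, 1L), c = c(0L, 1L))
  s2 <- primer_summary(band_matrix(p, "P1"))
  pooled <- s2[s2$primer == "all", ]
  expect_equal(pooled$polymorphic_bands, 2L)
  expect_equal(pooled$unique_bands, 0L)
  expect_equal(pooled$negative_unique, 2L)
})

test_that("per-primer counts sum to the pooled record and percent is consistent", {
  set.seed(10)
  for (i in 1:20) {
    m <- random_band_matrix()
    s <- primer_summary(m)
    per <- s[s$primer != "all", ]
    pooled <- s[s$primer == "all", ]
    expect_equal(sum(per$total_bands), pooled$total_bands)
    expect_equal(sum(per$monomorphic_bands), pooled$monomorphic_bands)
    expect_equal(sum(per$polymorphic_bands), pooled$polymorphic_bands)
    expect_equal(s$polymorphism_percent, 100 * s$polymorphic_bands / s$total_bands)
    expect_true(all(s$unique_bands <= s$polymorphic_bands))
  }
})

test_that("dominant PIC follows 2p(1-p)", {
  p <- rbind(g1 = c(1L, 1L, 1L), g2 = c(1L, 1L, 0L), g3 = c(1L, 0L, 0L),
             g4 = c(1L, 0L, 0L), g5 = c(1L, 1L, 0L), g6 = c(1L, 0L, 0L))
  pic <- pic_dominant(band_matrix(p, "P1"))$per_locus$pic
  expect_equal(pic[1L], 0)                # fixed band
  expect_equal(pic[2L], 0.5)              # p = 1/2: maximum
  expect_equal(pic[3L], 10 / 36)          # p = 1/6
  set.seed(3)
  m <- random_band_matrix()
  allpic <- pic_dominant(m)$per_locus
  expect_true(all(allpic$pic >= 0 & allpic$pic <= 0.5))
  expect_equal(allpic$pic == 0, allpic$band_freq == 1)
})

test_that("similarity coefficients match the 2x2-table oracle", {
  # third genotype keeps locus 3 scorable without touching the g1-g2 table
  p <- rbind(g1 = c(1L, 1L, 0L, 1L, 0L), g2 = c(1L, 0L, 0L, 1L, 1L),
             g3 = c(1L, 1L, 1L, 1L, 1L))
  m <- band_matrix(p, "P1")
  expect_equal(unname(band_similarity(m, "simple_matching")["g1", "g2"]), 0.6)
  expect_equal(unname(band_similarity(m, "dice")["g1", "g2"]), 2 / 3)
  expect_equal(unname(band_similarity(m, "jaccard")["g1", "g2"]), 0.5)
  # identical rows give 1 under all methods; disjoint rows give 0
  ident <- band_matrix(rbind(a = c(1L, 0L, 1L), b = c(1L, 0L, 1L), c = c(0L, 1L, 0L)), "P1")
  disj <- band_matrix(rbind(a = c(1L, 0L), b = c(0L, 1L)), "P1")
  for (meth in c("simple_matching", "dice", "jaccard")) {
    expect_equal(unname(band_similarity(ident, meth)["a", "b"]), 1)
    expect_equal(unname(band_similarity(disj, meth)["a", "b"]), 0)
  }
})

test_that("similarity matrices agree with the pairwise oracle on random data", {
  set.seed(7)
  for (i in 1:10) {
    m <- random_band_matrix(n_geno = 5L, n_loci = 30L)
    for (meth in c("simple_matching", "dice", "jaccard")) {
      sim <- band_similarity(m, meth)
      expect_true(isSymmetric(unname(sim)))
      expect_true(all(diag(sim) == 1))
      expect_true(all(sim >= 0 & sim <= 1))
      for (pair in list(c(1L, 2L), c(2L, 5L), c(3L, 4L))) {
        expect_equal(
          unname(sim[pair[1L], pair[2L]]),
          pair_similarity_oracle(m$presence[pair[1L], ], m$presence[pair[2L], ], meth)
        )
      }
    }
  }
})

test_that("Dice dominates Jaccard, with equality only at 0 and 1", {
  set.seed(42)
  for (i in 1:50) {
    m <- random_band_matrix(n_geno = 4L, n_loci = 25L)
    dice <- band_similarity(m, "dice")
    jac <- band_similarity(m, "jaccard")
    expect_true(all(dice - jac >= -1e-12))
    eq <- abs(dice - jac) < 1e-12
    expect_true(all(dice[eq] %in% c(0, 1)))
  }
})

test_that("similarity is invariant to locus order and equivariant to genotype order", {
  set.seed(5)
  m <- random_band_matrix()
  sim <- band_similarity(m, "dice")
  shuf <- sample(ncol(m$presence))
  m2 <- band_matrix(m$presence[, shuf], m$primer[shuf], m$band_bp[shuf])
  expect_equal(band_similarity(m2, "dice"), sim, ignore_attr = TRUE)
  perm <- sample(nrow(m$presence))
  m3 <- band_matrix(m$presence[perm, ], m$primer, m$band_bp)
  sim3 <- band_similarity(m3, "dice")
  expect_equal(unname(sim3[rownames(sim), colnames(sim)]), unname(sim),
               ignore_attr = TRUE)
})

test_that("degenerate Dice/Jaccard pairs return 1 with a warning", {
  # genotypes a and b show no bands at all; c carries them (keeps loci valid)
  z <- rbind(a = c(0L, 0L), b = c(0L, 0L), c = c(1L, 1L))
  mz <- band_matrix(z, "P1")
  expect_warning(dz <- band_similarity(mz, "dice"), "no bands")
  expect_equal(unname(dz["a", "b"]), 1)
  expect_warning(jz <- band_similarity(mz, "jaccard"), "no bands")
  expect_equal(unname(jz["a", "b"]), 1)
})

test_that("band matrix CSV round trip preserves the object", {
  set.seed(11)
  m <- random_band_matrix(n_geno = 4L, n_loci = 12L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_band_csv(m, f)
  m2 <- read_band_csv(f)
  expect_equal(m2$presence, m$presence, ignore_attr = TRUE)
  expect_equal(m2$primer, m$primer)
  # bundled demo fixture parses and satisfies the invariants
  demo <- read_band_csv(system.file("extdata", "demo_bands_issr.csv", package = "biosystax"))
  expect_true(all(colSums(demo$presence) > 0))
  expect_equal(nrow(demo$presence), 6L)
})

test_that("band_matrix rejects all-zero loci and malformed input", {
  expect_error(band_matrix(rbind(a = c(1L, 0L), b = c(1L, 0L)), "P1"), "all-zero")
  expect_error(band_matrix(rbind(a = c(1L, 2L), b = c(1L, 0L)), "P1"), "0/1")
  expect_error(band_similarity(band_matrix(rbind(a = 1L, b = 1L), "P1"), "hamming"))
})
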