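test_that("band simulator is deterministic and honors degenerate concordance", {
  spec <- cohort_spec(theta_w = 1, theta_b = 1, monomorphic_fraction = 0, seed = 11L)
  m1 <- simulate_band_matrix(spec)
  m2 <- simulate_band_matrix(spec)
  expect_identical(m1, m2)
  # theta_w = theta_b = 1: every genotype copies one shared reference
  expect_true(all(apply(m1$presence, 2L, function(col) length(unique(col)) == 1L)))
  dice <- band_similarity(m1, "dice")
  expect_true(all(abs(dice - 1) < 1e-12))
  # different seed gives different draws
  m3 <- simulate_band_matrix(cohort_spec(theta_w = 1, theta_b = 1,
                                         monomorphic_fraction = 0, seed = 12L))
  expect_false(identical(m1$presence, m3$presence))
})

test_that("band matrices have no all-zero locus and respect the monomorphic share", {
  spec <- cohort_spec(monomorphic_fraction = 0.25, loci_per_primer = 20L, seed = 4L)
  m <- simulate_band_matrix(spec)
  expect_true(all(colSums(m$presence) > 0L))
  n_loci <- ncol(m$presence)
  mono <- sum(colSums(m$presence) == nrow(m$presence))
  expect_gte(mono, round(0.25 * n_loci))  # planted monomorphic loci stay monomorphic
})

test_that("between-cluster simple matching matches the generative closed form", {
  # theta_w = 1, theta_b = 0.5, two clusters, many loci: expected
  # between-cluster similarity at polymorphic loci is theta_b, checked
  # against a direct Monte-Carlo simulation of the generative process
  theta_b <- 0.5
  spec <- cohort_spec(
    n_genotypes = 4L,
    cluster_assignment = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"),
    n_primers_per_system = 1L, loci_per_primer = 10000L,
    monomorphic_fraction = 0, theta_w = 1, theta_b = theta_b, seed = 21L
  )
  m <- simulate_band_matrix(spec)
  sm <- band_similarity(m, "simple_matching")
  between <- mean(sm[c("a1", "a2"), c("b1", "b2")])
  # independent Monte-Carlo oracle at 10x loci: draw reference pairs and
  # count agreement, conditioning on at-least-one-band support as the
  # generator does
  set.seed(99)
  n_mc <- 100000L
  r1 <- rbinom(n_mc, 1L, 0.5)
  r2 <- ifelse(rbinom(n_mc, 1L, theta_b) == 1L, r1, 1L - r1)
  keep <- !(r1 == 0L & r2 == 0L)  # theta_w = 1: all-zero locus iff both refs 0
  expected <- mean((r1 == r2)[keep])
  expect_lt(abs(between - expected), 0.02)
})

test_that("karyotype simulator yields the requested chromosome counts", {
  for (case in list(list(p = 2L, e = 0L, n = 24L), list(p = 2L, e = 3L, n = 27L),
                    list(p = 4L, e = 0L, n = 48L))) {
    k <- simulate_karyotype(karyotype_spec(base_x = 12L, ploidy = case$p,
                                           extra_chromosomes = case$e,
                                           n_cells = 3L, seed = 2L))
    expect_true(all(table(k$cell) == case$n))
  }
  k <- simulate_karyotype(karyotype_spec(seed = 8L))
  expect_true(all(k$short_arm_um <= k$long_arm_um))
  expect_true(all(k$short_arm_um > 0))
})

test_that("zero-noise karyotypes are identical chromosomes with A2 = 0", {
  k <- simulate_karyotype(karyotype_spec(length_sd = 0, arm_ratio_sd = 0,
                                         n_cells = 2L, seed = 1L))
  cell <- k[k$cell == 1L, ]
  expect_equal(length(unique(round(cell$short_arm_um, 12))), 1L)
  idx <- asymmetry_indices(cell)
  expect_equal(unname(idx["A2"]), 0)
  m <- chromosome_metrics(cell)
  expect_equal(length(unique(as.character(m$levan_class))), 1L)
})

test_that("metabolite simulator: zero noise hits cluster means, disjoint sets give Dice 0", {
  cl <- c(a1 = "A", a2 = "A", b1 = "B")
  prof <- simulate_metabolite_profiles(cl, n_compounds = 5L, presence_prob = 1,
                                       cluster_mean = 2, abundance_noise_sd = 0,
                                       seed = 1L)
  expect_true(all(prof == 2))
  pp <- rbind(A = c(1, 1, 0, 0), B = c(0, 0, 1, 1))
  prof2 <- simulate_metabolite_profiles(cl, n_compounds = 4L, presence_prob = pp,
                                        abundance_noise_sd = 0, seed = 1L)
  bm <- presence_absence(prof2)
  dice <- band_similarity(bm, "dice")
  expect_equal(unname(dice["a1", "b1"]), 0)
  expect_identical(prof2, simulate_metabolite_profiles(cl, n_compounds = 4L,
                                                       presence_prob = pp,
                                                       abundance_noise_sd = 0, seed = 1L))
})

test_that("UV spectra: rank-1 amplitude design puts 100% of variance on PC1", {
  amp <- cbind(band2 = c(0.2, 0.4, 0.6, 0.8), band1 = c(0.1, 0.2, 0.3, 0.4))
  sp <- simulate_uv_spectra(amp, noise_sd = 0, seed = 1L)
  expect_equal(dim(sp$absorbance), c(4L, 151L))
  fit <- pca_profiles(sp$absorbance, center = TRUE, scale. = FALSE)
  expect_gt(fit$variance_explained[1L], 100 - 1e-6)
  expect_error(simulate_uv_spectra(amp, band1_center_nm = 500), "inside the wavelength grid")
})

test_that("two amplitude groups separate on PC1 sign across seeds", {
  amp <- cbind(band2 = c(0.9, 0.85, 0.95, 0.3, 0.25, 0.35),
               band1 = c(0.3, 0.35, 0.25, 0.9, 0.95, 0.85))
  ok <- 0L
  for (s in 1:100) {
    sp <- simulate_uv_spectra(amp, noise_sd = 0.02, seed = s)
    fit <- pca_profiles(sp$absorbance, center = TRUE, scale. = FALSE)
    pc1 <- fit$scores[, 1L]
    if (length(unique(sign(pc1[1:3]))) == 1L && length(unique(sign(pc1[4:6]))) == 1L &&
        sign(pc1[1L]) != sign(pc1[4L])) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("Ct simulator inverts relative_expression exactly at zero noise", {
  folds <- rbind(PMT = c(1, 2, 4), TR1 = c(1, 0.5, 3))
  colnames(folds) <- c("cal", "g2", "g3")
  ct <- simulate_ct_table(folds, calibrator = "cal", ct_sd = 0, seed = 1L)
  rec <- relative_expression(ct, "actin", "cal")
  expect_equal(rec[rownames(folds), colnames(folds)], folds, tolerance = 1e-12)
})

test_that("generator parameter validation rejects invalid specs", {
  expect_error(cohort_spec(theta_w = 0.4, theta_b = 0.6), "theta_b")
  expect_error(cohort_spec(monomorphic_fraction = 1.2), "probability")
  expect_error(karyotype_spec(length_sd = -1), "standard deviations")
  expect_error(karyotype_spec(arm_ratio_mean = 0.8), "arm_ratio_mean")
  expect_error(simulate_metabolite_profiles(c(a = "A"), presence_prob = 2), "probability")
})
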