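# Synthetic-data generators. Every generator is a pure function of its
# spec, including the seed: the same spec always yields byte-identical
# output, and the caller's RNG stream is never disturbed.

#' Specification of a synthetic genotype cohort for dominant-marker data
#'
#' Describes a cohort with a planted cluster structure from which
#' [simulate_band_matrix()] draws band matrices. The generative model is a
#' cluster-profile model: each cluster carries a latent reference
#' presence/absence pattern, and genotypes copy their own cluster's pattern
#' with probability `theta_w` (within-cluster band concordance) or another
#' cluster's with probability `1 - theta_w`. Reference patterns of distinct
#' clusters agree at a locus with probability `theta_b`.
#'
#' Under this model the expected simple-matching similarity at a
#' polymorphic locus has a closed form. Writing \eqn{w = \theta_w^2 +
#' (1-\theta_w)^2}: between genotypes of the same cluster it is
#' \eqn{w + 2\theta_w(1-\theta_w)\,\theta_b}, and between genotypes of
#' clusters whose references agree with probability \eqn{\theta_b} it is
#' \eqn{w\,\theta_b + 2\theta_w(1-\theta_w)}. Averaged over all loci, a
#' `monomorphic_fraction` share contributes similarity 1. These closed
#' forms are what the parameter-recovery tests check against.
#'
#' @param n_genotypes number of genotypes (rows), at least 2.
#' @param cluster_assignment vector of cluster labels, one per genotype;
#'   names become the genotype labels.
#' @param n_primers_per_system number of primers.
#' @param loci_per_primer scored loci per primer.
#' @param monomorphic_fraction share of loci fixed present in all genotypes.
#' @param theta_w within-cluster band concordance, in `[theta_b, 1]`.
#' @param theta_b between-cluster band concordance, in `[0, theta_w]`.
#' @param seed integer seed; a field of the cohort specification, never
#'   global state.
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_band_matrix()]
#' @export
cohort_spec <- function(n_genotypes = 6L,
                        cluster_assignment = c(
                          stramonium = "A", tatula = "A", inermis = "A",
                          metel = "B", ferox = "C", innoxia = "C"
                        ),
                        n_primers_per_system = 6L,
                        loci_per_primer = 18L,
                        monomorphic_fraction = 0.2,
                        theta_w = 0.95,
                        theta_b = 0.55,
                        seed = 1L) {
  n_genotypes <- .assert_count(n_genotypes, "n_genotypes", min = 2L)
  if (length(cluster_assignment) != n_genotypes) {
    stop("`cluster_assignment` must have one label per genotype", call. = FALSE)
  }
  .assert_prob(monomorphic_fraction, "monomorphic_fraction")
  .assert_prob(theta_w, "theta_w")
  .assert_prob(theta_b, "theta_b")
  if (theta_b > theta_w) {
    stop("`theta_b` must not exceed `theta_w` (0 <= theta_b <= theta_w <= 1)", call. = FALSE)
  }
  if (is.null(names(cluster_assignment))) {
    names(cluster_assignment) <- paste0("g", seq_len(n_genotypes))
  }
  structure(
    list(
      n_genotypes = n_genotypes,
      cluster_assignment = cluster_assignment,
      n_primers_per_system = .assert_count(n_primers_per_system, "n_primers_per_system", 1L),
      loci_per_primer = .assert_count(loci_per_primer, "loci_per_primer", 1L),
      monomorphic_fraction = monomorphic_fraction,
      theta_w = theta_w,
      theta_b = theta_b,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Simulate a dominant-marker band matrix
#'
#' Draws a genotypes x loci presence/absence matrix from the cluster-profile
#' model described in [cohort_spec()]. A `monomorphic_fraction` share of loci
#' is present in every genotype; the remaining loci are polymorphic draws
#' from the latent cluster references. Loci that would come out absent in
#' every genotype are redrawn, so the result always satisfies the
#' [band_matrix()] contract. Band sizes are drawn uniformly on 100-3000 bp
#' as cosmetic metadata.
#'
#' @param spec a [cohort_spec()].
#' @param system_name primer-name prefix (e.g. `"ISSR"`).
#' @return A [band_matrix()].
#' @export
simulate_band_matrix <- function(spec, system_name = "ISSR") {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_genotypes
  n_loci <- spec$n_primers_per_system * spec$loci_per_primer
  clusters <- as.character(spec$cluster_assignment)
  levels <- unique(clusters)
  k <- length(levels)
  .with_seed(spec$seed, {
    n_mono <- round(spec$monomorphic_fraction * n_loci)
    presence <- matrix(0L, nrow = n, ncol = n_loci,
                       dimnames = list(names(spec$cluster_assignment), NULL))
    if (n_mono > 0L) presence[, seq_len(n_mono)] <- 1L
    draw_locus <- function() {
      # latent references: first cluster fair coin, others copy it w.p. theta_b
      ref <- integer(k)
      ref[1L] <- stats::rbinom(1L, 1L, 0.5)
      if (k > 1L) {
        agree <- stats::rbinom(k - 1L, 1L, spec$theta_b)
        ref[-1L] <- ifelse(agree == 1L, ref[1L], 1L - ref[1L])
      }
      own <- match(clusters, levels)
      use_own <- stats::rbinom(n, 1L, spec$theta_w) == 1L
      src <- own
      if (any(!use_own) && k > 1L) {
        src[!use_own] <- vapply(own[!use_own], function(c0) {
          others <- seq_len(k)[-c0]
          if (length(others) == 1L) others else sample(others, 1L)
        }, integer(1L))
      }
      ref[src]
    }
    for (j in seq(from = n_mono + 1L, length.out = n_loci - n_mono)) {
      locus <- draw_locus()
      while (sum(locus) == 0L) locus <- draw_locus()  # support: no all-zero locus
      presence[, j] <- locus
    }
    primer <- rep(sprintf("%s-%02d", system_name, seq_len(spec$n_primers_per_system)),
                  each = spec$loci_per_primer)
    sizes <- round(stats::runif(n_loci, 100, 3000))
    colnames(presence) <- make.unique(paste0(primer, "_", sizes, "bp"))
    band_matrix(presence, primer = primer, band_bp = sizes)
  })
}

#' Specification of a synthetic karyotype
#'
#' Parameters of the metaphase-cell generator [simulate_karyotype()]. The
#' chromosome number per cell is `base_x * ploidy + extra_chromosomes`,
#' covering euploid (2n = 2x, 4n = 4x), aneuploid (2x+1 ... 2x+3) and
#' tetraploid designs.
#'
#' @param base_x monoploid base chromosome number x (12 for *Datura*).
#' @param ploidy number of complete chromosome sets.
#' @param extra_chromosomes supernumerary chromosome copies (aneuploidy).
#' @param length_mean mean total chromosome length c, in micrometers.
#' @param length_sd standard deviation of c (micrometers).
#' @param arm_ratio_mean mean arm ratio l/s (>= 1).
#' @param arm_ratio_sd standard deviation of the arm ratio.
#' @param n_cells number of metaphase cells to generate.
#' @param seed integer seed.
#' @return An object of class `karyotype_spec`.
#' @export
karyotype_spec <- function(base_x = 12L, ploidy = 2L, extra_chromosomes = 0L,
                           length_mean = 4, length_sd = 0.4,
                           arm_ratio_mean = 1.5, arm_ratio_sd = 0.25,
                           n_cells = 8L, seed = 1L) {
  if (!is.numeric(length_mean) || length_mean <= 0) stop("`length_mean` must be positive", call. = FALSE)
  if (length_sd < 0 || arm_ratio_sd < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (arm_ratio_mean < 1) stop("`arm_ratio_mean` must be >= 1 (long arm is the longer arm)", call. = FALSE)
  structure(
    list(
      base_x = .assert_count(base_x, "base_x", 1L),
      ploidy = .assert_count(ploidy, "ploidy", 1L),
      extra_chromosomes = .assert_count(extra_chromosomes, "extra_chromosomes", 0L),
      length_mean = length_mean, length_sd = length_sd,
      arm_ratio_mean = arm_ratio_mean, arm_ratio_sd = arm_ratio_sd,
      n_cells = .assert_count(n_cells, "n_cells", 1L),
      seed = as.integer(seed)
    ),
    class = "karyotype_spec"
  )
}

#' Simulate metaphase chromosome measurements
#'
#' Generates `n_cells` metaphase cells, each with
#' `base_x * ploidy + extra_chromosomes` chromosomes. Total length is drawn
#' around `length_mean` (truncated positive) and the arm ratio r = l/s
#' around `arm_ratio_mean` (truncated at 1), then split as
#' s = c/(1+r), l = c r/(1+r), so `short_arm_um <= long_arm_um` always
#' holds and no chromosome has zero length. With both standard deviations
#' zero all chromosomes are identical, the downstream interchromosomal
#' asymmetry index is 0, and all centromere classes coincide.
#'
#' @param spec a [karyotype_spec()].
#' @param genotype label stamped on the output rows.
#' @return A data frame with columns
#'   `genotype, cell, chromosome, short_arm_um, long_arm_um`.
#' @export
simulate_karyotype <- function(spec, genotype = "g1") {
  stopifnot(inherits(spec, "karyotype_spec"))
  n_chr <- spec$base_x * spec$ploidy + spec$extra_chromosomes
  .with_seed(spec$seed, {
    out <- vector("list", spec$n_cells)
    for (cell in seq_len(spec$n_cells)) {
      c_tot <- stats::rnorm(n_chr, spec$length_mean, spec$length_sd)
      c_tot <- pmax(c_tot, 0.05 * spec$length_mean)  # no zero-length chromosome
      r <- pmax(stats::rnorm(n_chr, spec$arm_ratio_mean, spec$arm_ratio_sd), 1)
      out[[cell]] <- data.frame(
        genotype = genotype,
        cell = cell,
        chromosome = seq_len(n_chr),
        short_arm_um = c_tot / (1 + r),
        long_arm_um = c_tot * r / (1 + r)
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate genotype x compound metabolite profiles
#'
#' Concentrations follow a presence/abundance mixture: compound j is present
#' in a genotype of cluster c with probability `presence_prob[c, j]`; present
#' compounds get a log-normal abundance around the cluster mean
#' (`exp(rnorm(0, abundance_noise_sd))` multiplicative noise), mirroring the
#' positive, right-skewed scale of GC-MS peak areas. With
#' `abundance_noise_sd = 0` all present concentrations equal their cluster
#' means exactly.
#'
#' @param cluster_assignment named vector of cluster labels per genotype.
#' @param n_compounds number of compounds (columns).
#' @param presence_prob either a single probability, or a clusters x
#'   compounds matrix (row names = cluster labels) of presence
#'   probabilities.
#' @param cluster_mean either a single positive number or a clusters x
#'   compounds matrix of mean abundances for present compounds.
#' @param abundance_noise_sd log-scale noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return A numeric genotype x compound matrix (class `matrix`), with
#'   compounds named `cpd01 ...`.
#' @export
simulate_metabolite_profiles <- function(cluster_assignment,
                                         n_compounds = 31L,
                                         presence_prob = 1,
                                         cluster_mean = 1,
                                         abundance_noise_sd = 0.3,
                                         seed = 1L) {
  n_compounds <- .assert_count(n_compounds, "n_compounds", 1L)
  if (abundance_noise_sd < 0) stop("`abundance_noise_sd` must be >= 0", call. = FALSE)
  clusters <- as.character(cluster_assignment)
  levels <- unique(clusters)
  expand <- function(x, name) {
    if (length(x) == 1L) {
      x <- matrix(x, nrow = length(levels), ncol = n_compounds,
                  dimnames = list(levels, NULL))
    }
    if (!is.matrix(x) || ncol(x) != n_compounds) {
      stop(sprintf("`%s` must be scalar or a clusters x compounds matrix", name), call. = FALSE)
    }
    if (is.null(rownames(x))) rownames(x) <- levels
    x
  }
  presence_prob <- expand(presence_prob, "presence_prob")
  .assert_prob(as.vector(presence_prob), "presence_prob")
  cluster_mean <- expand(cluster_mean, "cluster_mean")
  if (any(cluster_mean <= 0)) stop("`cluster_mean` must be positive", call. = FALSE)
  n <- length(clusters)
  genos <- names(cluster_assignment)
  if (is.null(genos)) genos <- paste0("g", seq_len(n))
  .with_seed(seed, {
    prof <- matrix(0, nrow = n, ncol = n_compounds,
                   dimnames = list(genos, sprintf("cpd%02d", seq_len(n_compounds))))
    for (i in seq_len(n)) {
      cl <- clusters[i]
      present <- stats::rbinom(n_compounds, 1L, presence_prob[cl, ]) == 1L
      noise <- exp(stats::rnorm(n_compounds, 0, abundance_noise_sd))
      prof[i, present] <- cluster_mean[cl, present] * noise[present]
    }
    prof
  })
}

#' Simulate two-band UV absorption spectra
#'
#' Methanolic flavonoid extracts show two absorption bands in the 250-400 nm
#' window: Band II (240-280 nm) and Band I (300-380 nm). Each synthetic
#' spectrum is the sum of two Gaussian bands on a 1-nm grid plus white
#' noise.
#'
#' @param amplitudes numeric genotype x 2 matrix (or length-2 vector,
#'   recycled) of band amplitudes, columns = (Band II, Band I).
#' @param band2_center_nm,band1_center_nm band centers (nm), inside the grid.
#' @param widths length-2 positive Gaussian standard deviations (nm).
#' @param noise_sd absorbance noise standard deviation.
#' @param grid wavelength grid in nm (default 250:400).
#' @param seed integer seed.
#' @return A list of class `uv_spectra`: `wavelength_nm` and an
#'   `absorbance` genotype x wavelength matrix.
#' @export
simulate_uv_spectra <- function(amplitudes,
                                band2_center_nm = 265, band1_center_nm = 340,
                                widths = c(12, 18), noise_sd = 0.005,
                                grid = 250:400, seed = 1L) {
  if (is.vector(amplitudes)) amplitudes <- matrix(amplitudes, ncol = 2, byrow = TRUE)
  if (ncol(amplitudes) != 2L) stop("`amplitudes` must have two columns (Band II, Band I)", call. = FALSE)
  if (any(widths <= 0)) stop("band widths must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  centers <- c(band2_center_nm, band1_center_nm)
  if (any(centers < min(grid)) || any(centers > max(grid))) {
    stop("band centers must lie inside the wavelength grid", call. = FALSE)
  }
  genos <- rownames(amplitudes)
  if (is.null(genos)) genos <- paste0("g", seq_len(nrow(amplitudes)))
  .with_seed(seed, {
    shapes <- vapply(1:2, function(b) exp(-(grid - centers[b])^2 / (2 * widths[b]^2)),
                     numeric(length(grid)))
    absorbance <- amplitudes %*% t(shapes)
    absorbance <- absorbance +
      matrix(stats::rnorm(length(absorbance), 0, noise_sd), nrow = nrow(absorbance))
    dimnames(absorbance) <- list(genos, paste0("nm", grid))
    structure(list(wavelength_nm = as.numeric(grid), absorbance = absorbance),
              class = "uv_spectra")
  })
}

#' Simulate a qPCR Ct table from known fold changes
#'
#' Inverts the Livak model: given true fold changes per gene x genotype
#' (relative to a calibrator genotype), generates replicate Ct values with
#' Ct(target) = base Ct - log2(fold) and a flat reference-gene Ct, plus
#' normal replicate noise. Feeding the result to [relative_expression()]
#' with `ct_sd = 0` recovers the input folds exactly.
#'
#' @param fold_matrix numeric gene x genotype matrix of true fold changes
#'   (> 0); the calibrator column should be 1.
#' @param calibrator calibrator genotype name (a column of `fold_matrix`).
#' @param reference_gene reference gene name (default `"actin"`).
#' @param base_ct Ct of each target gene in the calibrator.
#' @param reference_ct Ct of the reference gene (all genotypes).
#' @param n_replicates technical replicates per gene x genotype.
#' @param ct_sd replicate Ct noise standard deviation (cycles).
#' @param seed integer seed.
#' @return A data frame `gene, genotype, replicate, ct`.
#' @export
simulate_ct_table <- function(fold_matrix, calibrator,
                              reference_gene = "actin",
                              base_ct = 26, reference_ct = 20,
                              n_replicates = 3L, ct_sd = 0.2, seed = 1L) {
  if (!is.matrix(fold_matrix) || any(fold_matrix <= 0)) {
    stop("`fold_matrix` must be a positive gene x genotype matrix", call. = FALSE)
  }
  if (!calibrator %in% colnames(fold_matrix)) {
    stop("`calibrator` must name a column of `fold_matrix`", call. = FALSE)
  }
  if (ct_sd < 0) stop("`ct_sd` must be >= 0", call. = FALSE)
  genes <- rownames(fold_matrix)
  genos <- colnames(fold_matrix)
  .with_seed(seed, {
    grid <- expand.grid(gene = c(genes, reference_gene), genotype = genos,
                        replicate = seq_len(n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- ifelse(grid$gene == reference_gene, reference_ct,
                 base_ct - log2(fold_matrix[cbind(
                   match(grid$gene, genes), match(grid$genotype, genos))]))
    grid$ct <- mu + stats::rnorm(nrow(grid), 0, ct_sd)
    grid[order(grid$gene, grid$genotype, grid$replicate), ]
  })
}
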