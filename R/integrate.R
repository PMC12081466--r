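# Multi-evidence consensus: fuses marker, metabolite, karyotype and
# expression distances on a shared genotype set into one consensus
# distance, a consensus dendrogram, pairwise similarity percentages, and
# a configurable taxonomic-rank suggestion.

#' Rescale a distance matrix to [0, 1]
#'
#' Divides off-diagonal entries by their maximum so that evidence streams
#' measured on incommensurable scales (band mismatch fractions, Euclidean
#' metabolite distances, expression distances) become comparable before
#' fusion. Uniform rescaling of the input leaves the result unchanged. A
#' constant off-diagonal carries no relational information and is an
#' error.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @return The standardized matrix, entries in `[0, 1]`, max off-diagonal
#'   entry exactly 1; the `evidence` attribute of `d` is preserved.
#' @export
standardize_distance <- function(d) {
  tag <- attr(d, "evidence")
  m <- .as_distance_matrix(d)
  off <- .upper_vec(m)
  if (max(off) == min(off)) {
    stop("constant off-diagonal: distance carries no relational information", call. = FALSE)
  }
  out <- m / max(off)
  attr(out, "evidence") <- tag
  out
}

#' Bundle evidence distance matrices for consensus
#'
#' Validates that all evidence matrices share one genotype label set,
#' reorders them consistently, and normalizes the fusion weights to sum
#' to 1 (equal weights by default).
#'
#' @param ... named distance matrices (or a single named list of them).
#' @param weights nonnegative weights, one per evidence; normalized
#'   internally.
#' @return An object of class `evidence_bundle`: list with `matrices`
#'   (standardized per [standardize_distance()]) and `weights`.
#' @export
evidence_bundle <- function(..., weights = NULL) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) && !is.matrix(mats[[1L]]) &&
      !inherits(mats[[1L]], "dist")) {
    mats <- mats[[1L]]
  }
  if (length(mats) < 1L) stop("at least one evidence matrix is required", call. = FALSE)
  if (is.null(names(mats)) || any(names(mats) == "")) {
    stop("every evidence matrix must be named", call. = FALSE)
  }
  mats <- lapply(mats, .as_distance_matrix)
  labs <- rownames(mats[[1L]])
  for (nm in names(mats)) {
    if (!setequal(rownames(mats[[nm]]), labs)) {
      stop(sprintf("evidence '%s' has a different genotype label set", nm), call. = FALSE)
    }
    mats[[nm]] <- mats[[nm]][labs, labs]
  }
  mats <- lapply(mats, standardize_distance)
  if (is.null(weights)) weights <- rep(1, length(mats))
  if (length(weights) != length(mats) || any(weights < 0) || sum(weights) == 0) {
    stop("`weights` must be nonnegative, one per evidence, not all zero", call. = FALSE)
  }
  weights <- weights / sum(weights)
  names(weights) <- names(mats)
  structure(list(matrices = mats, weights = weights), class = "evidence_bundle")
}

#' Consensus distance across evidence streams
#'
#' Weighted mean of the standardized evidence matrices — a simple,
#' auditable fusion in which each evidence contributes proportionally to
#' its weight and the result stays a distance matrix in `[0, 1]`.
#'
#' @param bundle an [evidence_bundle()].
#' @return A symmetric `[0, 1]` distance matrix with `evidence` attribute
#'   `"consensus"`.
#' @export
consensus_distance <- function(bundle) {
  stopifnot(inherits(bundle, "evidence_bundle"))
  out <- Reduce(`+`, Map(function(m, w) w * m, bundle$matrices, bundle$weights))
  attr(out, "evidence") <- "consensus"
  out
}

#' Pairwise similarity percentages from a consensus distance
#'
#' Converts a standardized consensus distance to similarity percentages
#' 100 (1 - d), the form in which overall between-taxon resemblance is
#' customarily quoted (e.g. "similarity of 45-79%").
#'
#' @param consensus a standardized (entries in `[0, 1]`) distance matrix.
#' @return A list of class `similarity_report`: `percent` (symmetric
#'   matrix, diagonal 100), `summary` (named vector min/mean/max over
#'   genotype pairs).
#' @export
similarity_report <- function(consensus) {
  m <- .as_distance_matrix(consensus, "consensus")
  if (max(m) > 1 + 1e-9) {
    stop("`consensus` must be standardized to [0, 1] (see standardize_distance)", call. = FALSE)
  }
  pct <- 100 * (1 - m)
  off <- .upper_vec(pct)
  structure(
    list(percent = pct,
         summary = c(min = min(off), mean = mean(off), max = max(off))),
    class = "similarity_report"
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("pairwise similarity: %.1f%% - %.1f%% (mean %.1f%%)\n",
              x$summary["min"], x$summary["max"], x$summary["mean"]))
  print(round(x$percent, 1))
  invisible(x)
}

#' Define a taxonomic-rank suggestion rule
#'
#' An ordered set of similarity thresholds mapping a consensus similarity
#' percentage to an infraspecific-rank suggestion. The shipped defaults
#' (>= 80% form, >= 55% subspecies, below that distinct species) are
#' heuristics for interpreting overall similarity bands, not nomenclatural
#' standards; every suggestion echoes the rule that produced it.
#'
#' @param thresholds named numeric vector of *strictly decreasing* lower
#'   bounds (percent), one per rank, ordered from the most similar rank
#'   down.
#' @param fallback rank assigned below the last threshold.
#' @return An object of class `rank_rule`.
#' @examples
#' rank_rule()  # form >= 80, subspecies >= 55, else distinct species
#' @export
rank_rule <- function(thresholds = c(form = 80, subspecies = 55),
                      fallback = "distinct species") {
  if (is.null(names(thresholds)) || any(names(thresholds) == "")) {
    stop("`thresholds` must be a named vector of rank lower bounds", call. = FALSE)
  }
  if (any(diff(thresholds) >= 0)) {
    stop("`thresholds` must be strictly decreasing", call. = FALSE)
  }
  if (any(thresholds < 0) || any(thresholds > 100)) {
    stop("`thresholds` are percentages in [0, 100]", call. = FALSE)
  }
  structure(list(thresholds = thresholds, fallback = fallback), class = "rank_rule")
}

#' Suggest a taxonomic rank from a similarity percentage
#'
#' Deterministic lookup of a similarity percentage against a
#' [rank_rule()]. The output carries the rule used: the suggestion is
#' configuration-dependent, never an absolute statement.
#'
#' @param similarity_percent similarity in `[0, 100]` (vectorized).
#' @param rule a [rank_rule()].
#' @return Data frame `similarity_percent, rank`, with the rule in
#'   attribute `rule`.
#' @examples
#' suggest_rank(c(79, 57, 60), rank_rule())
#' @export
suggest_rank <- function(similarity_percent, rule = rank_rule()) {
  stopifnot(inherits(rule, "rank_rule"))
  if (any(similarity_percent < 0) || any(similarity_percent > 100)) {
    stop("`similarity_percent` must lie in [0, 100]", call. = FALSE)
  }
  pick <- function(s) {
    hit <- which(s >= rule$thresholds)
    if (length(hit)) names(rule$thresholds)[hit[1L]] else rule$fallback
  }
  out <- data.frame(
    similarity_percent = similarity_percent,
    rank = vapply(similarity_percent, pick, character(1L))
  )
  attr(out, "rule") <- rule
  out
}

#' Simulate a full integrative cohort
#'
#' Generates every evidence stream for one planted-structure cohort: three
#' conspecific forms (cluster A), one intermediate taxon (cluster B) and
#' two outgroup-like taxa (cluster C) — the 3+1+2 design. Defaults: three
#' marker systems of 6 primers x 18 loci (108 bands per system) with 20%
#' monomorphic loci; a 31-compound metabolite profile with a shared core
#' and cluster-specific compound sets; diploid 2n = 2x = 24 karyotypes;
#' two-band UV spectra; and a 6-gene expression gradient.
#'
#' @param seed integer master seed; per-stream seeds are derived from it.
#' @param theta_w,theta_b band concordances of the marker model, see
#'   [cohort_spec()].
#' @return A list with elements `genotypes`, `clusters`, `bands` (list of
#'   three [band_matrix()] objects), `metabolites`, `spectra`, `karyotypes`
#'   (per-genotype measurement frames), `ct`, `calibrator`.
#' @export
simulate_cohort <- function(seed = 1L, theta_w = 0.95, theta_b = 0.55) {
  seed <- as.integer(seed)
  genotypes <- c("stramonium", "tatula", "inermis", "metel", "ferox", "innoxia")
  clusters <- c(stramonium = "A", tatula = "A", inermis = "A",
                metel = "B", ferox = "C", innoxia = "C")
  bands <- lapply(seq_along(c("ISSR", "SCoT", "CDDP")), function(i) {
    sys <- c("ISSR", "SCoT", "CDDP")[i]
    simulate_band_matrix(
      cohort_spec(cluster_assignment = clusters, theta_w = theta_w,
                  theta_b = theta_b, seed = seed + 101L * i),
      system_name = sys
    )
  })
  names(bands) <- c("ISSR", "SCoT", "CDDP")
  # 31 tropane-alkaloid-like compounds: 13 core + 6 per cluster
  pp <- matrix(0.05, nrow = 3, ncol = 31, dimnames = list(c("A", "B", "C"), NULL))
  pp[, 1:13] <- 1
  pp["A", 14:19] <- 0.9
  pp["B", 20:25] <- 0.9
  pp["C", 26:31] <- 0.9
  metabolites <- simulate_metabolite_profiles(
    clusters, n_compounds = 31L, presence_prob = pp,
    cluster_mean = 1, abundance_noise_sd = 0.3, seed = seed + 7L
  )
  amp <- cbind(band2 = c(0.9, 0.85, 0.95, 0.6, 0.35, 0.4),
               band1 = c(0.5, 0.55, 0.45, 0.75, 0.95, 0.9))
  rownames(amp) <- genotypes
  spectra <- simulate_uv_spectra(amp, noise_sd = 0.01, seed = seed + 11L)
  karyotypes <- lapply(genotypes, function(g) {
    simulate_karyotype(
      karyotype_spec(
        base_x = 12L, ploidy = 2L, extra_chromosomes = 0L,
        arm_ratio_mean = c(A = 1.4, B = 1.8, C = 2.4)[clusters[g]],
        seed = seed + 13L + match(g, genotypes)
      ),
      genotype = g
    )
  })
  names(karyotypes) <- genotypes
  folds <- rbind(
    PMT = c(1.2, 1.8, 1.0, 2.2, 2.5, 2.8),
    TR1 = c(2.9 / 2.5, 3.8 / 2.5, 1.0, 5.2 / 2.5, 5.5 / 2.5, 6.0 / 2.5),
    TR2 = c(5.8 / 3.4, 4.0 / 3.4, 5.4 / 3.4, 3.0 / 3.4, 3.8 / 3.4, 1.0),
    H6H = c(3.8 / 2.5, 1.8 / 2.5, 4.1 / 2.5, 2.7 / 2.5, 2.8 / 2.5, 1.0),
    HDH = c(0.66 / 1.4, 1.4 / 1.4, 0.44 / 1.4, 1.6 / 1.4, 1.2 / 1.4, 1.0),
    AT4 = c(0.37 / 0.32, 0.56 / 0.32, 1.0, 0.77 / 0.32, 0.9 / 0.32, 1.2 / 0.32)
  )
  colnames(folds) <- genotypes
  calibrator <- "inermis"
  folds <- sweep(folds, 1L, folds[, calibrator], "/")
  ct <- simulate_ct_table(folds, calibrator = calibrator, seed = seed + 29L)
  list(genotypes = genotypes, clusters = clusters, bands = bands,
       metabolites = metabolites, spectra = spectra, karyotypes = karyotypes,
       ct = ct, calibrator = calibrator)
}

#' Run the integrative consensus pipeline on a cohort
#'
#' From a cohort (as produced by [simulate_cohort()], or assembled from
#' read-in data of the same shape) computes: per-system marker similarity
#' (simple matching) and its pooled distance; metabolite presence/absence
#' Dice distance; karyotype distance (Euclidean on standardized 2n, A1,
#' A2); expression distance (Euclidean on log2 fold changes); fuses them
#' with [consensus_distance()]; and returns the consensus UPGMA
#' dendrogram, similarity report and rank suggestions for every genotype
#' pair.
#'
#' @param cohort list with elements `bands`, `metabolites`, `karyotypes`,
#'   `ct`, `calibrator` (see [simulate_cohort()]).
#' @param weights fusion weights for the four evidence streams (markers,
#'   metabolites, karyotype, expression); equal by default.
#' @param rule a [rank_rule()].
#' @return A list of class `consensus_result`: `evidence` (the bundle),
#'   `consensus` (distance), `tree` (`phylo`), `report`
#'   ([similarity_report()]), `ranks` (per-pair rank suggestions),
#'   `fold_changes`.
#' @export
consensus_pipeline <- function(cohort, weights = NULL, rule = rank_rule()) {
  marker_sims <- lapply(cohort$bands, band_similarity, method = "simple_matching")
  marker_d <- Reduce(`+`, lapply(marker_sims, similarity_to_distance)) / length(marker_sims)
  metab_d <- similarity_to_distance(
    band_similarity(presence_absence(cohort$metabolites), "dice")
  )
  karyo_feats <- t(vapply(cohort$karyotypes, function(k) {
    s <- karyotype_summary(k)
    c(count_2n = s$count_2n, A1 = s$A1, A2 = s$A2)
  }, numeric(3L)))
  karyo_scaled <- scale(karyo_feats)
  karyo_scaled[, apply(karyo_feats, 2L, stats::sd) == 0] <- 0
  karyo_d <- as.matrix(stats::dist(karyo_scaled))
  folds <- relative_expression(cohort$ct, reference_gene = "actin",
                               calibrator = cohort$calibrator)
  expr_d <- as.matrix(stats::dist(t(log2(folds))))
  bundle <- evidence_bundle(
    markers = marker_d, metabolites = metab_d,
    karyotype = karyo_d, expression = expr_d,
    weights = weights
  )
  consensus <- consensus_distance(bundle)
  tree <- upgma_tree(consensus)
  report <- similarity_report(consensus)
  pairs <- which(upper.tri(report$percent), arr.ind = TRUE)
  ranks <- suggest_rank(report$percent[pairs], rule)
  ranks <- data.frame(
    genotype_1 = rownames(report$percent)[pairs[, 1L]],
    genotype_2 = colnames(report$percent)[pairs[, 2L]],
    ranks
  )
  attr(ranks, "rule") <- rule
  structure(
    list(evidence = bundle, consensus = consensus, tree = tree,
         report = report, ranks = ranks, fold_changes = folds),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("integrative consensus over evidence:",
      paste(names(x$evidence$matrices), collapse = ", "), "\n")
  print(x$report)
  cat("\nrank suggestions (rule thresholds:",
      paste(sprintf("%s >= %g%%", names(attr(x$ranks, "rule")$thresholds),
                    attr(x$ranks, "rule")$thresholds), collapse = ", "), "):\n")
  print(x$ranks, digits = 3)
  invisible(x)
}
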