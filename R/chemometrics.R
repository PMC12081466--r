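# Calibration-based quantification (total phenolics, flavonoids,
# alkaloids all reduce to a linear standard curve and its inversion) and
# chemometric pattern analysis (PCA, HCA) of metabolite and UV-spectral
# profiles.

#' Fit a linear calibration curve
#'
#' Ordinary least squares of absorbance on concentration, as used for
#' colorimetric total-phenolic (gallic acid equivalents), total-flavonoid
#' (rutin equivalents) and total-alkaloid assays. The goodness of fit r is
#' the Pearson correlation of the standard points. Two-point curves are
#' accepted but flagged, since r = 1 by construction.
#'
#' @param concentration concentrations of the standards.
#' @param absorbance measured absorbances, same length.
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `r`, `range` (concentration range of the standards), `n`.
#' @examples
#' fit_calibration(c(0, 0.25, 0.5, 1), c(0.09, 2.1, 4.1, 8.1))
#' @export
fit_calibration <- function(concentration, absorbance) {
  if (length(concentration) != length(absorbance)) {
    stop("`concentration` and `absorbance` must have the same length", call. = FALSE)
  }
  if (length(concentration) < 2L || length(unique(concentration)) < 2L) {
    stop("calibration needs at least 2 distinct concentrations", call. = FALSE)
  }
  if (length(concentration) == 2L) {
    warning("calibration from only 2 standards: r = 1 by construction", call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration)
  co <- stats::coef(fit)
  if (abs(co[["concentration"]]) < .Machine$double.eps) {
    stop("calibration slope is zero: absorbance does not respond to concentration", call. = FALSE)
  }
  structure(
    list(
      slope = unname(co[["concentration"]]),
      intercept = unname(co[["(Intercept)"]]),
      r = stats::cor(concentration, absorbance),
      range = range(concentration),
      n = length(concentration)
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("A = %.4f C %+0.4f; r = %.4f (n = %d standards, C in [%g, %g])\n",
              x$slope, x$intercept, x$r, x$n, x$range[1L], x$range[2L]))
  invisible(x)
}

#' Invert a calibration curve to a concentration
#'
#' C = (A - intercept) / slope, multiplied by a dilution factor and divided
#' by the sample mass, giving equivalents per unit mass (e.g. mg gallic
#' acid equivalents per g). Absorbances below the intercept would yield
#' negative concentrations; these are clamped to 0 with a warning.
#' Absorbances outside the calibrated range are flagged.
#'
#' @param curve a [fit_calibration()] result.
#' @param absorbance measured absorbance(s).
#' @param dilution_factor multiplicative dilution correction.
#' @param sample_mass sample mass (> 0) normalising the result.
#' @return Concentration(s) in standard equivalents per unit mass.
#' @export
invert_calibration <- function(curve, absorbance, dilution_factor = 1, sample_mass = 1) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (any(!is.finite(absorbance))) stop("`absorbance` must be finite", call. = FALSE)
  if (sample_mass <= 0) stop("`sample_mass` must be positive", call. = FALSE)
  conc <- (absorbance - curve$intercept) / curve$slope
  if (any(conc < curve$range[1L] - 1e-9) || any(conc > curve$range[2L] + 1e-9)) {
    warning("absorbance outside the calibrated range: extrapolated estimate", call. = FALSE)
  }
  neg <- conc < 0
  if (any(neg)) {
    warning(sprintf("%d absorbance(s) below the calibration intercept: concentration clamped to 0",
                    sum(neg)), call. = FALSE)
    conc[neg] <- 0
  }
  conc * dilution_factor / sample_mass
}

#' Threshold a metabolite profile to presence/absence
#'
#' Scores each compound as present (1) where its concentration exceeds the
#' threshold, yielding a [band_matrix()] so that the whole dominant-marker
#' and tree machinery (Dice similarity, UPGMA dendrograms) applies
#' unchanged to chemotaxonomic data. Compounds absent in every genotype
#' after thresholding are dropped with a warning.
#'
#' @param profile genotype x compound concentration matrix (>= 0).
#' @param threshold detection threshold (>= 0); strictly-greater rule.
#' @return A [band_matrix()] with primer id `"metabolite"`; if no compound
#'   survives thresholding, an empty genotypes x 0 matrix with a warning.
#' @export
presence_absence <- function(profile, threshold = 0) {
  if (!is.matrix(profile) || any(profile < 0)) {
    stop("`profile` must be a nonnegative genotype x compound matrix", call. = FALSE)
  }
  if (threshold < 0) stop("`threshold` must be >= 0", call. = FALSE)
  bin <- (profile > threshold) * 1L
  keep <- colSums(bin) > 0L
  if (!any(keep)) {
    warning("no compound exceeds the threshold in any genotype: empty matrix returned",
            call. = FALSE)
    return(bin[, 0, drop = FALSE])
  }
  if (any(!keep)) {
    warning(sprintf("%d compound(s) below threshold everywhere dropped", sum(!keep)),
            call. = FALSE)
  }
  bin <- bin[, keep, drop = FALSE]
  band_matrix(bin, primer = "metabolite")
}

#' Principal component analysis of a profile matrix
#'
#' Singular-value decomposition of the column-preprocessed matrix.
#' The chemometric default is autoscaling: mean-centering plus
#' unit-variance scaling of every column; both steps are configurable.
#' Percent variance explained per component is 100 sigma_k^2 / sum
#' sigma^2 and sums to 100.
#'
#' @param x numeric matrix, observations (genotypes) x features; >= 2 rows.
#' @param center mean-center columns (default `TRUE`).
#' @param scale. scale columns to unit variance (default `TRUE`); constant
#'   columns are an error under scaling, reported by name.
#' @return An object of class `pca_result`: `scores` (observations x
#'   components), `loadings` (features x components, orthonormal),
#'   `variance_explained` (%), `sdev`.
#' @export
pca_profiles <- function(x, center = TRUE, scale. = TRUE) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 observations", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (scale. && any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant column(s) under unit-variance scaling: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (all(sds == 0)) stop("degenerate input: total variance is zero", call. = FALSE)
  fit <- stats::prcomp(x, center = center, scale. = scale.)
  ve <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(scores = fit$x, loadings = fit$rotation,
         variance_explained = ve, sdev = fit$sdev),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3L, length(x$variance_explained))
  cat(sprintf("PCA: %d components; variance explained: %s\n",
              length(x$variance_explained),
              paste(sprintf("PC%d %.1f%%", seq_len(k), x$variance_explained[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Hierarchical cluster analysis of a profile matrix
#'
#' Average-linkage (UPGMA) clustering of the rows. Quantitative profiles
#' use Euclidean row distances; binary (presence/absence) profiles use
#' 1 - Dice similarity, the convention for metabolite band patterns.
#' Routes through [upgma_tree()], so the result is a rooted ultrametric
#' `phylo` dendrogram.
#'
#' @param x numeric matrix (rows = genotypes), or a [band_matrix()] for the
#'   Dice route.
#' @param metric `"euclidean"` or `"dice"`; the default picks `"dice"` for
#'   a `band_matrix` input and `"euclidean"` otherwise.
#' @return A rooted ultrametric `phylo` tree.
#' @examples
#' hca(rbind(a = c(0, 0), b = c(0, 3), c = c(4, 0)))
#' @export
hca <- function(x, metric = NULL) {
  if (inherits(x, "band_matrix")) {
    if (is.null(metric)) metric <- "dice"
  } else {
    if (is.null(metric)) metric <- "euclidean"
    if (!is.matrix(x)) x <- as.matrix(x)
  }
  metric <- match.arg(metric, c("euclidean", "dice"))
  d <- switch(metric,
    euclidean = {
      m <- if (inherits(x, "band_matrix")) x$presence else x
      as.matrix(stats::dist(m, method = "euclidean"))
    },
    dice = {
      bm <- if (inherits(x, "band_matrix")) x else band_matrix((x > 0) * 1L, primer = "profile")
      similarity_to_distance(band_similarity(bm, "dice"))
    }
  )
  upgma_tree(d)
}
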