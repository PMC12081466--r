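# Dominant-marker band statistics: polymorphism counts, PIC, and binary
# similarity coefficients. Band frequencies are computed over genotypes
# (one consensus banding profile per genotype), not over population
# samples.

#' Per-primer band statistics
#'
#' Summarises a dominant band matrix per primer, plus a pooled `"all"`
#' record. A locus is *monomorphic* when the band is present in every
#' genotype, *polymorphic* otherwise, and *unique* when present in exactly
#' one genotype (a positive genotype-specific marker). Loci absent in
#' exactly one genotype are reported separately as `negative_unique`; they
#' count as polymorphic but not as unique.
#'
#' @param x a [band_matrix()].
#' @return A data frame with one row per primer and a final pooled row
#'   `"all"`; columns `primer, total_bands, monomorphic_bands,
#'   polymorphic_bands, polymorphism_percent, unique_bands,
#'   negative_unique, size_min_bp, size_max_bp, mean_pic`.
#' @examples
#' m <- band_matrix(rbind(g1 = c(1, 1, 0), g2 = c(1, 0, 1), g3 = c(1, 1, 1)),
#'                  primer = "P1")
#' primer_summary(m)
#' @export
primer_summary <- function(x) {
  stopifnot(inherits(x, "band_matrix"))
  n <- nrow(x$presence)
  counts <- colSums(x$presence)
  pic <- pic_dominant(x)$per_locus$pic
  one_group <- function(idx, label) {
    if (length(idx) == 0L) stop(sprintf("primer '%s' has no scored loci", label), call. = FALSE)
    cnt <- counts[idx]
    total <- length(idx)
    mono <- sum(cnt == n)
    poly <- total - mono
    sizes <- x$band_bp[idx]
    sizes <- sizes[!is.na(sizes)]
    data.frame(
      primer = label,
      total_bands = total,
      monomorphic_bands = mono,
      polymorphic_bands = poly,
      polymorphism_percent = 100 * poly / total,
      unique_bands = sum(cnt == 1L),
      negative_unique = sum(cnt == n - 1L),
      size_min_bp = if (length(sizes)) min(sizes) else NA_real_,
      size_max_bp = if (length(sizes)) max(sizes) else NA_real_,
      mean_pic = mean(pic[idx])
    )
  }
  primers <- unique(x$primer)
  per <- do.call(rbind, lapply(primers, function(p) one_group(which(x$primer == p), p)))
  pooled <- one_group(seq_along(x$primer), "all")
  out <- rbind(per, pooled)
  rownames(out) <- NULL
  out
}

#' Polymorphism information content for dominant markers
#'
#' For a dominant (presence/absence) locus with band frequency `p` — the
#' fraction of genotypes showing the band — the biallelic convention
#' \eqn{PIC = 1 - p^2 - (1-p)^2 = 2p(1-p)} is used. Values lie in
#' `[0, 0.5]`, maximal at `p = 0.5` and zero only for loci fixed present.
#'
#' @param x a [band_matrix()].
#' @return A list with `per_locus` (data frame `primer, locus, band_freq,
#'   pic`) and `per_primer` (data frame `primer, mean_pic`).
#' @export
pic_dominant <- function(x) {
  stopifnot(inherits(x, "band_matrix"))
  p <- colSums(x$presence) / nrow(x$presence)
  pic <- 2 * p * (1 - p)
  per_locus <- data.frame(primer = x$primer, locus = colnames(x$presence),
                          band_freq = p, pic = pic, row.names = NULL)
  per_primer <- stats::aggregate(pic ~ primer, data = per_locus, FUN = mean)
  names(per_primer)[2L] <- "mean_pic"
  list(per_locus = per_locus, per_primer = per_primer)
}

#' Pairwise binary similarity between genotypes
#'
#' For a genotype pair with 2x2 band counts a (1,1), b (1,0), c (0,1),
#' d (0,0):
#' * `simple_matching` = (a + d) / (a + b + c + d) — counts shared absences;
#' * `dice` = 2a / (2a + b + c);
#' * `jaccard` = a / (a + b + c).
#'
#' Dice and Jaccard are undefined when a pair shares no bands at all
#' (a + b + c = 0); such pairs are indistinguishable on the data and are
#' reported as 1 with a warning.
#'
#' @param x a [band_matrix()].
#' @param method one of `"simple_matching"`, `"dice"`, `"jaccard"`.
#' @return A symmetric genotype x genotype matrix with unit diagonal and a
#'   `method` attribute.
#' @examples
#' m <- band_matrix(rbind(g1 = c(1, 1, 0, 1, 0), g2 = c(1, 0, 0, 1, 1)), primer = "P1")
#' band_similarity(m, "simple_matching")["g1", "g2"]  # 0.6
#' @export
band_similarity <- function(x, method = c("simple_matching", "dice", "jaccard")) {
  stopifnot(inherits(x, "band_matrix"))
  method <- match.arg(method)
  p <- x$presence
  a <- p %*% t(p)
  b <- p %*% t(1L - p)
  cc <- t(b)
  d <- (1L - p) %*% t(1L - p)
  sim <- switch(method,
    simple_matching = (a + d) / (a + b + cc + d),
    dice = {
      denom <- 2 * a + b + cc
      degenerate <- denom == 0
      denom[degenerate] <- 1
      s <- 2 * a / denom
      s[degenerate] <- 1
      if (any(degenerate & upper.tri(degenerate))) {
        warning("pair(s) with no bands in either genotype: Dice reported as 1", call. = FALSE)
      }
      s
    },
    jaccard = {
      denom <- a + b + cc
      degenerate <- denom == 0
      denom[degenerate] <- 1
      s <- a / denom
      s[degenerate] <- 1
      if (any(degenerate & upper.tri(degenerate))) {
        warning("pair(s) with no bands in either genotype: Jaccard reported as 1", call. = FALSE)
      }
      s
    }
  )
  diag(sim) <- 1
  attr(sim, "method") <- method
  sim
}

#' Convert a similarity matrix to a distance matrix
#'
#' Complements similarities to distances d = 1 - s, the form consumed by
#' [nj_tree()] and [upgma_tree()].
#'
#' @param sim symmetric similarity matrix with entries in `[0, 1]`.
#' @param evidence provenance tag carried on the result.
#' @return A symmetric distance matrix with zero diagonal and an
#'   `evidence` attribute.
#' @export
similarity_to_distance <- function(sim, evidence = attr(sim, "method")) {
  if (!is.matrix(sim) || any(sim < -1e-9) || any(sim > 1 + 1e-9)) {
    stop("`sim` must be a similarity matrix with entries in [0, 1]", call. = FALSE)
  }
  d <- 1 - sim
  d[d < 0] <- 0
  diag(d) <- 0
  m <- attr(sim, "method")
  attr(d, "method") <- NULL
  attr(d, "evidence") <- if (is.null(evidence)) "similarity" else evidence
  d
}
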