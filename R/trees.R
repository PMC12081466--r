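# Distance-based tree inference and concordance statistics. Trees are
# ape "phylo" objects throughout, so the whole ape toolkit (plotting,
# rerooting, comparison) applies to every tree the package produces.

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: repeatedly join the pair minimising
#' Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k), with pendant branch
#' lengths from the standard two-point formulas. NJ is exact on additive
#' distances. Negative estimated branch lengths (possible on non-additive
#' input) are clamped to zero with a warning reporting the most negative
#' raw value. With two taxa the single edge is split equally.
#'
#' The input is typically `1 - similarity` from [band_similarity()] (via
#' [similarity_to_distance()]). Band data carry no substitution model; an
#' optional Jukes-Cantor transform for distances derived from sequence
#' p-distances is available as [jukes_cantor()] but is never applied
#' implicitly.
#'
#' @param d symmetric distance matrix (or `dist`), n >= 2, zero diagonal.
#' @return An unrooted `phylo` tree with tip labels taken from `d`.
#' @examples
#' d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' nj_tree(d)
#' @export
nj_tree <- function(d) {
  d <- .as_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("neighbor joining needs at least 2 taxa", call. = FALSE)
  if (n == 2L) {
    tree <- list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
      edge.length = rep(d[1L, 2L] / 2, 2L),
      tip.label = rownames(d),
      Nnode = 1L
    )
    class(tree) <- "phylo"
    attr(tree, "order") <- "cladewise"
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  if (any(neg)) {
    warning(sprintf(
      "%d negative NJ branch length(s) clamped to 0 (most negative raw value: %.6g)",
      sum(neg), min(tree$edge.length)
    ), call. = FALSE)
    tree$edge.length[neg] <- 0
  }
  tree
}

#' UPGMA (average-linkage) tree from a distance matrix
#'
#' Agglomerates by unweighted average linkage; each merge is placed at a
#' height of half the mean inter-cluster distance, so the cophenetic
#' distance between two tips equals the merge level of their joining
#' cluster. For an ultrametric input the cophenetic matrix of the result
#' reproduces the input exactly. Ties between candidate pairs are resolved
#' deterministically by the agglomeration order of [stats::hclust()].
#'
#' @param d symmetric distance matrix (or `dist`), n >= 2, zero diagonal.
#' @return A rooted ultrametric `phylo` tree; merge heights (half the
#'   average linkage heights, nondecreasing) in attribute `merge_heights`.
#' @export
upgma_tree <- function(d) {
  d <- .as_distance_matrix(d)
  if (nrow(d) < 2L) stop("UPGMA needs at least 2 taxa", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tree <- ape::as.phylo(hc)  # halves hclust heights -> ultrametric tree
  attr(tree, "merge_heights") <- hc$height / 2
  tree
}

#' Cophenetic correlation between a tree and a distance matrix
#'
#' Pearson correlation between the upper triangle of `d` and the tree's
#' cophenetic (patristic) distances, the standard goodness-of-fit measure
#' for a dendrogram as a summary of a distance matrix.
#'
#' @param tree a `phylo` tree whose tips match the labels of `d`.
#' @param d the distance matrix the tree was built from.
#' @return The correlation coefficient, in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree, d) {
  d <- .as_distance_matrix(d)
  if (!setequal(tree$tip.label, rownames(d))) {
    stop("tree tip labels must match the distance matrix labels", call. = FALSE)
  }
  cd <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  x <- .upper_vec(d)
  y <- .upper_vec(cd)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a distance triangle: cophenetic correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation r between the upper triangles, with a one-sided
#' (positive association) permutation p-value under simultaneous
#' row/column permutation of the second matrix, using the add-one
#' convention p = (1 + #\{r_perm >= r\}) / (n_perm + 1).
#'
#' @param d1,d2 distance matrices on the same labels.
#' @param n_perm number of permutations (>= 1).
#' @param seed optional integer seed making the permutation stream
#'   reproducible without touching the global RNG.
#' @return A list of class `mantel_test` with elements `statistic` (r),
#'   `p.value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999L, seed = NULL) {
  m1 <- .as_distance_matrix(d1, "d1")
  m2 <- .as_distance_matrix(d2, "d2")
  if (!identical(dim(m1), dim(m2))) stop("`d1` and `d2` must have the same size", call. = FALSE)
  if (!setequal(rownames(m1), rownames(m2))) {
    stop("`d1` and `d2` must share the same labels", call. = FALSE)
  }
  m2 <- m2[rownames(m1), colnames(m1)]
  n_perm <- .assert_count(n_perm, "n_perm", 1L)
  v1 <- .upper_vec(m1)
  if (stats::sd(v1) == 0 || stats::sd(.upper_vec(m2)) == 0) {
    stop("zero variance in a distance triangle: Mantel correlation undefined", call. = FALSE)
  }
  r_obs <- stats::cor(v1, .upper_vec(m2))
  n <- nrow(m1)
  r_perm <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stats::cor(v1, .upper_vec(m2[idx, idx]))
  }, numeric(1L)))
  p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  structure(list(statistic = r_obs, p.value = p, n_perm = n_perm),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, one-sided p = %.4g (%d permutations)\n",
              x$statistic, x$p.value, x$n_perm))
  invisible(x)
}

#' Jukes-Cantor distance transform
#'
#' Converts proportions of differing sites p into Jukes-Cantor distances
#' `-3/4 log(1 - 4p/3)`. Only meaningful for sequence p-distances; offered
#' as an optional transform and never applied to band-derived distances by
#' default.
#'
#' @param p matrix (or vector) of p-distances in `[0, 0.75)`.
#' @return Transformed distances of the same shape.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0) || any(p >= 0.75)) {
    stop("Jukes-Cantor transform requires p-distances in [0, 0.75)", call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Serialize a tree to Newick
#'
#' Writes branch lengths at 15 significant digits so that a write/parse
#' round trip reproduces the tree to within 1e-12.
#'
#' @param tree a `phylo` tree.
#' @param file optional output path; with `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  has_len <- !is.null(tree$edge.length)
  fmt <- function(node, edge_idx) {
    lab <- if (node <= length(tree$tip.label)) {
      tree$tip.label[node]
    } else {
      kid_edges <- children[[as.character(node)]]
      paste0("(", paste(vapply(kid_edges, function(e) fmt(tree$edge[e, 2L], e),
                               character(1L)), collapse = ","), ")")
    }
    if (has_len && !is.na(edge_idx)) {
      paste0(lab, ":", sprintf("%.15g", tree$edge.length[edge_idx]))
    } else {
      lab
    }
  }
  root <- length(tree$tip.label) + 1L
  s <- paste0(fmt(root, NA), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Parse a Newick string or file
#'
#' Validates parenthesis balance up front (reporting the character position
#' of the first imbalance) and then parses with [ape::read.tree()].
#'
#' @param text a Newick string, or `NULL` when `file` is given.
#' @param file optional path to a Newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply `text` or `file`", call. = FALSE)
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop(sprintf("malformed Newick: unmatched ')' at position %d", i), call. = FALSE)
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d unclosed '(' at end of string", depth), call. = FALSE)
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed Newick: parse failed", call. = FALSE)
  tree
}
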