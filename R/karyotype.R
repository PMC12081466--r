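# Karyotype morphometrics. Arm lengths are in micrometers; per-chromosome
# metrics follow the classical conventions: total length c = s + l,
# relative length RL = (c / sum c) x 100 within a metaphase cell, and
# centromeric index ci = (s / c) x 100, which drives the Levan centromere
# position classes.

#' Levan centromere classification from the centromeric index
#'
#' Maps ci = 100 s/c to the Levan position classes with the interval
#' convention: telocentric only at ci = 0, then left-open/right-closed
#' intervals (0, 12.5] acrocentric, (12.5, 25] subtelocentric, (25, 37.5]
#' submetacentric, (37.5, 50] metacentric — a strict partition of `[0, 50]`
#' whose class maxima are the classical boundary values.
#'
#' @param ci numeric vector of centromeric indices in `[0, 50]`.
#' @return An ordered factor with levels telocentric < acrocentric <
#'   subtelocentric < submetacentric < metacentric.
#' @examples
#' classify_centromere(c(0, 10, 20, 30, 45))
#' @export
classify_centromere <- function(ci) {
  if (!is.numeric(ci) || anyNA(ci)) stop("`ci` must be numeric without NA", call. = FALSE)
  if (any(ci < 0) || any(ci > 50 + 1e-9)) {
    stop("centromeric index must lie in [0, 50]", call. = FALSE)
  }
  # tolerate float rounding at the metacentric boundary (equal arms can
  # evaluate to 50 + eps)
  ci[ci > 50 & ci <= 50 + 1e-9] <- 50
  lv <- c("telocentric", "acrocentric", "subtelocentric", "submetacentric", "metacentric")
  cls <- ifelse(ci == 0, "telocentric",
         ifelse(ci <= 12.5, "acrocentric",
         ifelse(ci <= 25, "subtelocentric",
         ifelse(ci <= 37.5, "submetacentric", "metacentric"))))
  factor(cls, levels = lv, ordered = TRUE)
}

#' Per-chromosome metrics for one metaphase cell
#'
#' Derives, for every measured chromosome of a single cell: total length
#' c = s + l, relative length RL = (c / sum c) x 100 (summing to 100 over
#' the cell), centromeric index ci = (s / c) x 100, the arm ratio l/s, and
#' the Levan class. Measurements with short arm recorded longer than the
#' long arm are swapped with a warning.
#'
#' @param cell data frame with columns `short_arm_um` and `long_arm_um`
#'   (one row per chromosome of one cell); other columns are passed
#'   through.
#' @return The input data frame augmented with columns
#'   `total_um, rl_percent, ci, arm_ratio, levan_class`.
#' @export
chromosome_metrics <- function(cell) {
  need <- c("short_arm_um", "long_arm_um")
  if (!is.data.frame(cell) || !all(need %in% names(cell))) {
    stop("`cell` must be a data frame with columns short_arm_um and long_arm_um", call. = FALSE)
  }
  if (nrow(cell) < 1L) stop("a cell must contain at least one chromosome", call. = FALSE)
  s <- cell$short_arm_um
  l <- cell$long_arm_um
  if (anyNA(s) || anyNA(l) || any(s < 0) || any(l < 0)) {
    stop("arm lengths must be nonnegative and non-missing", call. = FALSE)
  }
  swap <- s > l
  if (any(swap)) {
    warning(sprintf("%d chromosome(s) had short arm > long arm; arms swapped", sum(swap)),
            call. = FALSE)
    tmp <- s[swap]; s[swap] <- l[swap]; l[swap] <- tmp
  }
  if (any(l == 0)) stop("long arm must be positive", call. = FALSE)
  ctot <- s + l
  if (sum(ctot) == 0) stop("zero total chromosome length in cell", call. = FALSE)
  cell$short_arm_um <- s
  cell$long_arm_um <- l
  cell$total_um <- ctot
  cell$rl_percent <- 100 * ctot / sum(ctot)
  cell$ci <- 100 * s / ctot
  cell$arm_ratio <- l / s
  cell$levan_class <- classify_centromere(cell$ci)
  cell
}

#' Romero Zarco asymmetry indices
#'
#' Intrachromosomal asymmetry A1 = 1 - mean(s_i / l_i) over the chromosome
#' records supplied (classically applied to homolog-pair mean arms; pass
#' the output of [pair_homologs()] for that reading). A1 is 0 for a
#' perfectly metacentric complement and 1 for an all-telocentric one.
#' Interchromosomal asymmetry A2 = sd(c) / mean(c), Pearson's coefficient
#' of variation of total chromosome lengths. Both indices are invariant to
#' uniform rescaling of all arm lengths.
#'
#' @param cell data frame with columns `short_arm_um`, `long_arm_um` (>= 2
#'   rows for A2).
#' @return Named numeric vector `c(A1 = ..., A2 = ...)`.
#' @examples
#' asymmetry_indices(data.frame(short_arm_um = c(2, 1), long_arm_um = c(3, 4)))
#' @export
asymmetry_indices <- function(cell) {
  need <- c("short_arm_um", "long_arm_um")
  if (!is.data.frame(cell) || !all(need %in% names(cell))) {
    stop("`cell` must be a data frame with columns short_arm_um and long_arm_um", call. = FALSE)
  }
  s <- cell$short_arm_um
  l <- cell$long_arm_um
  if (any(l <= 0)) stop("long arm must be positive for asymmetry indices", call. = FALSE)
  if (nrow(cell) < 2L) stop("at least 2 chromosomes are needed for A2", call. = FALSE)
  ctot <- s + l
  c(A1 = 1 - mean(s / l), A2 = stats::sd(ctot) / mean(ctot))
}

#' Ploidy/aneuploidy label from a chromosome count
#'
#' Expresses a somatic count as `k x + r` with the largest multiple k of
#' the base number such that the remainder r is below x, and prints the
#' conventional cytogenetic label: `2n=2x=24`, `2n=2x+3=27`, `2n=4x=48`.
#'
#' @param count somatic chromosome number (2n).
#' @param base_x monoploid base number x.
#' @return The label string.
#' @examples
#' ploidy_label(27, 12)
#' @export
ploidy_label <- function(count, base_x) {
  count <- .assert_count(count, "count", 1L)
  base_x <- .assert_count(base_x, "base_x", 1L)
  if (count < base_x) stop("`count` must be at least one base set (count >= base_x)", call. = FALSE)
  k <- count %/% base_x
  r <- count %% base_x
  if (r == 0L) sprintf("2n=%dx=%d", k, count) else sprintf("2n=%dx+%d=%d", k, r, count)
}

#' Pair homologous chromosomes by size
#'
#' Sorts the chromosomes of one cell by decreasing total length and pairs
#' consecutive entries (1-2, 3-4, ...), the implicit convention of
#' metaphase karyotyping software. With an odd count the smallest
#' chromosome is reported unpaired with a warning (as in aneuploid cells).
#'
#' @param cell data frame with columns `short_arm_um`, `long_arm_um`.
#' @return Data frame with one row per pair: `pair, short_arm_um,
#'   long_arm_um, total_um, ci` (per-pair means), plus attribute
#'   `unpaired` holding the leftover chromosome row (or `NULL`).
#' @export
pair_homologs <- function(cell) {
  m <- chromosome_metrics(cell)
  if (nrow(m) < 1L) stop("empty cell", call. = FALSE)
  m <- m[order(-m$total_um), , drop = FALSE]
  n <- nrow(m)
  n_pairs <- n %/% 2L
  unpaired <- NULL
  if (n %% 2L == 1L) {
    warning("odd chromosome count: smallest chromosome left unpaired", call. = FALSE)
    unpaired <- m[n, , drop = FALSE]
  }
  if (n_pairs == 0L) {
    out <- data.frame(pair = integer(0), short_arm_um = numeric(0),
                      long_arm_um = numeric(0), total_um = numeric(0), ci = numeric(0))
    attr(out, "unpaired") <- unpaired
    return(out)
  }
  idx1 <- seq(1L, by = 2L, length.out = n_pairs)
  idx2 <- idx1 + 1L
  out <- data.frame(
    pair = seq_len(n_pairs),
    short_arm_um = (m$short_arm_um[idx1] + m$short_arm_um[idx2]) / 2,
    long_arm_um = (m$long_arm_um[idx1] + m$long_arm_um[idx2]) / 2,
    total_um = (m$total_um[idx1] + m$total_um[idx2]) / 2
  )
  out$ci <- 100 * out$short_arm_um / (out$short_arm_um + out$long_arm_um)
  attr(out, "unpaired") <- unpaired
  out
}

#' Karyotype summary for one genotype
#'
#' Aggregates metaphase measurements across cells of one genotype: the
#' modal somatic chromosome number (ties broken toward the smaller count
#' with a warning), its ploidy label, per-pair mean arm lengths and Levan
#' classes from the modal cells, and the Romero Zarco asymmetry indices
#' averaged over modal cells (A1 on homolog-pair means).
#'
#' @param measurements data frame with columns `cell, chromosome,
#'   short_arm_um, long_arm_um` (a `genotype` column is allowed and
#'   ignored).
#' @param base_x monoploid base number used for the ploidy label.
#' @return A list of class `karyotype_summary`: `count_2n`, `ploidy_label`,
#'   `n_cells`, `pairs` (per-pair table averaged over modal cells), `A1`,
#'   `A2`.
#' @export
karyotype_summary <- function(measurements, base_x = 12L) {
  need <- c("cell", "short_arm_um", "long_arm_um")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements))) {
    stop("`measurements` must have columns cell, short_arm_um, long_arm_um", call. = FALSE)
  }
  counts <- table(measurements$cell)
  tab <- table(as.integer(counts))
  modal <- as.integer(names(tab)[tab == max(tab)])
  if (length(modal) > 1L) {
    warning(sprintf("modal chromosome count tie (%s); using the smaller",
                    paste(modal, collapse = ", ")), call. = FALSE)
  }
  modal <- min(modal)
  modal_cells <- names(counts)[as.integer(counts) == modal]
  per_cell <- lapply(modal_cells, function(cl) {
    cell <- measurements[measurements$cell == cl, , drop = FALSE]
    pairs <- pair_homologs(cell)
    # A1 over homolog-pair mean arms; A2 over all individual chromosomes
    a1 <- asymmetry_indices(if (nrow(pairs) > 1L) pairs else cell)["A1"]
    a2 <- asymmetry_indices(cell)["A2"]
    list(pairs = pairs, asym = c(A1 = unname(a1), A2 = unname(a2)))
  })
  pair_mats <- lapply(per_cell, function(x) as.matrix(x$pairs[, c("short_arm_um", "long_arm_um", "total_um", "ci")]))
  n_pairs <- min(vapply(pair_mats, nrow, integer(1L)))
  pair_mean <- Reduce(`+`, lapply(pair_mats, function(m) m[seq_len(n_pairs), , drop = FALSE])) /
    length(pair_mats)
  pairs <- data.frame(pair = seq_len(n_pairs), pair_mean)
  pairs$levan_class <- classify_centromere(pairs$ci)
  asym <- rowMeans(vapply(per_cell, function(x) x$asym, numeric(2L)))
  structure(
    list(
      count_2n = modal,
      ploidy_label = ploidy_label(modal, base_x),
      n_cells = length(counts),
      pairs = pairs,
      A1 = unname(asym["A1"]),
      A2 = unname(asym["A2"])
    ),
    class = "karyotype_summary"
  )
}

#' @export
print.karyotype_summary <- function(x, ...) {
  cat(sprintf("karyotype: %s over %d cell(s); A1 = %.3f, A2 = %.3f\n",
              x$ploidy_label, x$n_cells, x$A1, x$A2))
  print(x$pairs, digits = 4)
  invisible(x)
}

#' Read chromosome measurements from CSV
#'
#' Expects columns `genotype,cell,chromosome,short_arm_um,long_arm_um`.
#'
#' @param file path to a CSV file.
#' @return A data frame.
#' @export
read_karyotype_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("genotype", "cell", "chromosome", "short_arm_um", "long_arm_um")
  if (!all(need %in% names(df))) {
    stop(sprintf("karyotype CSV must contain columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df
}
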