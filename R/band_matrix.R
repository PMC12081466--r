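#' Construct a dominant-marker band matrix
#'
#' A `band_matrix` holds the presence/absence scores of dominant PCR
#' fingerprinting systems (ISSR, SCoT, CDDP, or any assay scored as band
#' present/absent, including thresholded metabolite profiles). Rows are
#' genotypes, columns are scored loci; each locus belongs to a primer (or
#' assay) and may carry a band size in base pairs.
#'
#' Loci absent in every genotype carry no information for dominant scoring
#' and violate the container's contract; they are rejected.
#'
#' @param presence integer/logical matrix (genotypes x loci) of 0/1 scores
#'   with genotype row names.
#' @param primer character vector, one primer id per locus. Recycled if
#'   length 1.
#' @param band_bp optional numeric vector of band sizes (bp) per locus;
#'   `NA` allowed where sizes were not recorded.
#' @return An object of class `band_matrix`: a list with elements
#'   `presence`, `primer`, `band_bp`.
#' @examples
#' m <- band_matrix(
#'   rbind(g1 = c(1, 1, 0), g2 = c(1, 0, 1)),
#'   primer = "UBC810", band_bp = c(540, 620, 780)
#' )
#' m
#' @export
band_matrix <- function(presence, primer, band_bp = NULL) {
  if (!is.matrix(presence)) stop("`presence` must be a matrix", call. = FALSE)
  storage.mode(presence) <- "integer"
  if (anyNA(presence) || !all(presence %in% c(0L, 1L))) {
    stop("`presence` must contain only 0/1 scores", call. = FALSE)
  }
  if (nrow(presence) < 2L) stop("a band matrix needs at least 2 genotypes", call. = FALSE)
  if (is.null(rownames(presence))) {
    rownames(presence) <- paste0("g", seq_len(nrow(presence)))
  }
  if (length(primer) == 1L) primer <- rep(primer, ncol(presence))
  if (length(primer) != ncol(presence)) {
    stop("`primer` must have one entry per locus", call. = FALSE)
  }
  if (is.null(band_bp)) band_bp <- rep(NA_real_, ncol(presence))
  if (length(band_bp) != ncol(presence)) {
    stop("`band_bp` must have one entry per locus", call. = FALSE)
  }
  if (any(!is.na(band_bp) & band_bp <= 0)) {
    stop("band sizes must be positive", call. = FALSE)
  }
  zero <- colSums(presence) == 0L
  if (any(zero)) {
    stop(sprintf("%d locus/loci absent in every genotype; a dominant band matrix may not contain all-zero loci", sum(zero)), call. = FALSE)
  }
  if (is.null(colnames(presence))) {
    colnames(presence) <- make.unique(paste(primer, seq_len(ncol(presence)), sep = "_"))
  }
  structure(
    list(presence = presence, primer = as.character(primer), band_bp = as.numeric(band_bp)),
    class = "band_matrix"
  )
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf(
    "band_matrix: %d genotypes x %d loci (%d primer%s)\n",
    nrow(x$presence), ncol(x$presence),
    length(unique(x$primer)), if (length(unique(x$primer)) == 1L) "" else "s"
  ))
  cat("genotypes:", paste(rownames(x$presence), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.band_matrix <- function(x) dim(x$presence)

#' Read a band matrix from CSV
#'
#' Expects columns `primer,band_bp,<genotype1>,...,<genotypeN>` with 0/1
#' cells; one row per scored locus. This is the interchange format written
#' by [write_band_csv()].
#'
#' @param file path to a CSV file.
#' @return A [band_matrix()].
#' @export
read_band_csv <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("primer", "band_bp")
  if (!all(need %in% names(df))) {
    stop("band CSV must contain columns 'primer' and 'band_bp'", call. = FALSE)
  }
  genos <- setdiff(names(df), need)
  if (length(genos) < 2L) stop("band CSV needs at least 2 genotype columns", call. = FALSE)
  presence <- t(as.matrix(df[, genos, drop = FALSE]))
  rownames(presence) <- genos
  band_matrix(presence, primer = df$primer, band_bp = df$band_bp)
}

#' Write a band matrix to CSV
#'
#' @param x a [band_matrix()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_band_csv <- function(x, file) {
  stopifnot(inherits(x, "band_matrix"))
  df <- data.frame(primer = x$primer, band_bp = x$band_bp, t(x$presence),
                   check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
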