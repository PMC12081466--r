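# Relative quantification of gene expression from qPCR Ct tables by the
# Livak 2^(-ddCt) method, and its association with metabolite
# accumulation across genotypes.

#' Relative expression by the 2^(-ddCt) method
#'
#' For each gene and genotype: dCt = mean Ct(gene) - mean Ct(reference);
#' ddCt = dCt - dCt(calibrator genotype); fold change =
#' efficiency^(-ddCt). With the default efficiency of 2 (100% amplification,
#' the convention when no standard-curve efficiencies are available) one
#' missing cycle doubles the estimate. The calibrator column is exactly 1
#' for every gene. Adding a constant to every Ct (target and reference
#' alike) leaves the result unchanged.
#'
#' @param ct data frame with columns `gene, genotype, replicate, ct`
#'   (replicates averaged per gene x genotype); Ct values must be
#'   positive.
#' @param reference_gene name of the internal control gene (e.g. actin);
#'   must be measured in every genotype.
#' @param calibrator genotype all fold changes are expressed against.
#' @param efficiency amplification efficiency base (default 2).
#' @return A numeric gene x genotype matrix of fold changes (> 0), the
#'   reference gene excluded.
#' @examples
#' ct <- data.frame(
#'   gene = rep(c("PMT", "actin"), each = 2),
#'   genotype = rep(c("cal", "s1"), 2),
#'   replicate = 1, ct = c(26, 24, 20, 20)
#' )
#' relative_expression(ct, "actin", "cal")  # PMT fold 4 in s1
#' @export
relative_expression <- function(ct, reference_gene = "actin", calibrator,
                                efficiency = 2) {
  need <- c("gene", "genotype", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct))) {
    stop("`ct` must be a data frame with columns gene, genotype, ct", call. = FALSE)
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("Ct values must be positive and finite", call. = FALSE)
  }
  if (efficiency <= 1) stop("`efficiency` must exceed 1", call. = FALSE)
  mean_ct <- tapply(ct$ct, list(ct$gene, ct$genotype), mean)
  if (!reference_gene %in% rownames(mean_ct)) {
    stop(sprintf("reference gene '%s' not found in the Ct table", reference_gene), call. = FALSE)
  }
  ref_row <- mean_ct[reference_gene, ]
  missing_ref <- colnames(mean_ct)[is.na(ref_row)]
  if (length(missing_ref)) {
    stop(sprintf("reference gene '%s' missing for genotype(s): %s",
                 reference_gene, paste(missing_ref, collapse = ", ")), call. = FALSE)
  }
  if (!calibrator %in% colnames(mean_ct)) {
    stop(sprintf("calibrator genotype '%s' not found in the Ct table", calibrator), call. = FALSE)
  }
  targets <- setdiff(rownames(mean_ct), reference_gene)
  if (anyNA(mean_ct[targets, , drop = FALSE])) {
    gap <- which(is.na(mean_ct[targets, , drop = FALSE]), arr.ind = TRUE)
    stop(sprintf("missing Ct for gene '%s' in genotype '%s'",
                 targets[gap[1L, 1L]], colnames(mean_ct)[gap[1L, 2L]]), call. = FALSE)
  }
  dct <- sweep(mean_ct[targets, , drop = FALSE], 2L, ref_row)
  ddct <- sweep(dct, 1L, dct[, calibrator])
  efficiency^(-ddct)
}

#' Exact-permutation Spearman correlation
#'
#' Spearman rank correlation with a permutation p-value. For n <= 8 the
#' p-value is exact: all n! permutations of one vector are enumerated and
#' p is the fraction with |rho| at least the observed |rho| (two-sided;
#' the identity permutation is included, so p > 0). For larger n a
#' Monte-Carlo approximation with 10^4 draws is used. Ties are handled by
#' midranks throughout, so the enumeration remains valid with tied data.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A list `rho`, `p.value`, `method` (`"exact"` or
#'   `"monte-carlo"`); with a constant input, `rho` and `p.value` are `NA`
#'   and the degeneracy is flagged in `method`.
#' @export
spearman_exact <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("`x` and `y` must share a length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p.value = NA_real_, method = "degenerate (constant input)"))
  }
  rho_obs <- stats::cor(x, y, method = "spearman")
  rx <- rank(x)
  ry <- rank(y)
  if (n <= 8L) {
    perms <- .permutations(n)
    rho_perm <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rho_perm) >= abs(rho_obs) - 1e-12)
    method <- "exact"
  } else {
    rho_perm <- vapply(seq_len(10000L), function(i) stats::cor(rx, sample(ry)), numeric(1L))
    p <- (1 + sum(abs(rho_perm) >= abs(rho_obs) - 1e-12)) / 10001
    method <- "monte-carlo"
  }
  list(rho = rho_obs, p.value = p, method = method)
}

#' Associate gene expression with metabolite accumulation
#'
#' For each gene, the Spearman rank correlation between its fold changes
#' and a metabolite level across genotypes (a totals vector, or a profile
#' matrix whose rows are summed to totals), with exact permutation
#' p-values at small n via [spearman_exact()]. Genes with constant fold
#' changes are flagged (`NA` correlation), not errors.
#'
#' @param fold_matrix gene x genotype fold-change matrix from
#'   [relative_expression()].
#' @param metabolite either a named vector of per-genotype metabolite
#'   levels or a genotype x compound matrix (row sums are used).
#' @return Data frame `gene, rho, p.value, method`, one row per gene.
#' @export
expression_metabolite_association <- function(fold_matrix, metabolite) {
  if (!is.matrix(fold_matrix)) stop("`fold_matrix` must be a gene x genotype matrix", call. = FALSE)
  if (is.matrix(metabolite)) metabolite <- rowSums(metabolite)
  if (is.null(names(metabolite))) {
    stop("`metabolite` must carry genotype names", call. = FALSE)
  }
  common <- intersect(colnames(fold_matrix), names(metabolite))
  if (length(common) < 3L) {
    stop("at least 3 shared genotypes are needed for a rank correlation", call. = FALSE)
  }
  res <- lapply(rownames(fold_matrix), function(g) {
    s <- spearman_exact(fold_matrix[g, common], metabolite[common])
    data.frame(gene = g, rho = s$rho, p.value = s$p.value, method = s$method)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Read a qPCR Ct table from CSV
#'
#' Expects columns `gene,genotype,replicate,ct`.
#'
#' @param file path to a CSV file.
#' @return A data frame.
#' @export
read_ct_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("gene", "genotype", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop(sprintf("Ct CSV must contain columns %s", paste(need, collapse = ", ")), call. = FALSE)
  }
  df
}
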