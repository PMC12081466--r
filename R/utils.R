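# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
.assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) < 1L || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
#' @noRd
.assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; with seed = NULL the expression uses the ambient stream.
#' @keywords internal
#' @noRd
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Coerce a square symmetric distance input (matrix or "dist") to a labelled
# numeric matrix with a zero diagonal, validating the DistanceMatrix contract.
#' @keywords internal
#' @noRd
.as_distance_matrix <- function(d, arg = "d") {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !is.numeric(d)) {
    stop(sprintf("`%s` must be a numeric matrix or a 'dist' object", arg), call. = FALSE)
  }
  if (nrow(d) != ncol(d)) stop(sprintf("`%s` must be square", arg), call. = FALSE)
  if (anyNA(d)) stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop(sprintf("`%s` must be symmetric", arg), call. = FALSE)
  }
  if (any(d < -1e-12)) stop(sprintf("`%s` must be nonnegative", arg), call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) {
    stop(sprintf("`%s` must have a zero diagonal", arg), call. = FALSE)
  }
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("g", seq_len(nrow(d)))
  }
  colnames(d) <- rownames(d)
  d
}

# Upper-triangle vector in a fixed (column-major) order shared by all
# matrix-correlation code in the package.
#' @keywords internal
#' @noRd
.upper_vec <- function(m) m[upper.tri(m)]

# All permutations of 1..n as a matrix with n! rows; used for exact
# permutation p-values at small n.
#' @keywords internal
#' @noRd
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    rest <- seq_len(n)[-k]
    out[r + seq_len(rows), 1L] <- k
    out[r + seq_len(rows), -1L] <- matrix(rest[sub], nrow = rows)
    r <- r + rows
  }
  out
}
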