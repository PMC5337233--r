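## Conversion matrices between fraction-vector interpretations.  All entries
## are exact 0/1 integers; only the data they act on are floating point.

## One-atom isotopomer-to-cumomer block: identity of size m + 1 stacked over a
## single all-ones row (the indeterminate-state row, which sorts last).
ic_base <- function(m) {
  rbind(diag(1L, m + 1L), matrix(1L, 1L, m + 1L))
}

kron_power <- function(B, n) {
  out <- matrix(1L, 1L, 1L)
  if (n > 0) for (i in seq_len(n)) out <- kronecker(out, B)
  storage.mode(out) <- "integer"
  out
}

#' Isotopomer-to-cumomer conversion matrix
#'
#' The rectangular matrix taking an isotopomer fraction vector (length
#' `(m + 1)^n`) to the full cumomer fraction vector.  For `m >= 1` it is the
#' n-fold Kronecker power of the one-atom block (identity of size `m + 1`
#' stacked over an all-ones row), with `(m + 2)^n` rows.  The degenerate
#' single-isotope case `m = 0` collapses to the trivial `[1]`, the
#' indeterminate state coinciding with the only determinate state.
#'
#' @param n Number of atoms.
#' @param m Greatest mass shift.
#' @return An integer 0/1 matrix.
#' @examples
#' ic_matrix(1, 1)
#' @export
ic_matrix <- function(n, m) {
  stopifnot(n >= 0, m >= 0)
  if (m == 0) return(matrix(1L, 1L, 1L))
  kron_power(ic_base(m), n)
}

## Un-collapsed variant used by convert(): keeps the full (m + 2)^n cumomer
## indexing even at m = 0 so that EMU block sums remain well defined.
ic_matrix_full <- function(n, m) kron_power(ic_base(m), n)

#' Punctured-cumomer (Reed-Muller) conversion matrix
#'
#' Removing the `(s + 1)`th row of the one-atom isotopomer-to-cumomer block
#' and taking the n-fold Kronecker power yields a square, invertible matrix:
#' the generalized Reed-Muller transform taking isotopomer fractions to the
#' cumomer fractions punctured at the determinate state `s`.  For `m = 1`,
#' `s = 0` this is the classical binary Reed-Muller pattern underlying
#' Wiechert-style cumomer vectors.
#'
#' @param n Number of atoms.
#' @param m Greatest mass shift.
#' @param s Determinate state in `[0, m]` excluded by the puncture.
#' @return An integer 0/1 matrix of dimension `(m + 1)^n`.
#' @examples
#' punctured_matrix(1, 1, 0)
#' @export
punctured_matrix <- function(n, m, s = 0) {
  stopifnot(n >= 0, m >= 0)
  s <- as.integer(s)
  if (length(s) != 1 || is.na(s) || s < 0 || s > m)
    abort(sprintf("s must be a determinate state in [0, %d]", m))
  B <- ic_base(m)[-(s + 1L), , drop = FALSE]
  kron_power(B, n)
}

#' Isotopomer-to-mass conversion matrix
#'
#' The rectangular matrix taking an isotopomer fraction vector to the mass
#' fraction vector (mass isotopomer distribution): entry `(j, a)` is 1 exactly
#' when the total mass shift of isotopomer `a` (its digit sum) equals
#' `j - 1`.  Each column holds exactly one 1, so mass vectors inherit the unit
#' sum of isotopomer vectors.
#'
#' @param n Number of atoms.
#' @param m Greatest mass shift.
#' @return An integer 0/1 matrix of dimension `(n * m + 1) x ((m + 1)^n)`.
#' @examples
#' im_matrix(2, 1)
#' @export
im_matrix <- function(n, m) {
  stopifnot(n >= 0, m >= 0)
  S <- mixed_radix_matrix(n, 0:m)
  shift <- if (n > 0) as.integer(rowSums(S)) else rep(0L, nrow(S))
  out <- matrix(0L, nrow = n * m + 1L, ncol = nrow(S))
  out[cbind(shift + 1L, seq_len(nrow(S)))] <- 1L
  out
}

#' Export a conversion matrix in Matrix Market format
#'
#' @param x An integer matrix (as returned by [ic_matrix()],
#'   [punctured_matrix()] or [im_matrix()]).
#' @param path Output file path (`.mtx`).
#' @return `path`, invisibly.
#' @export
write_matrix_mtx <- function(x, path) {
  Matrix::writeMM(methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"),
                  path)
  invisible(path)
}

#' @rdname write_matrix_mtx
#' @export
read_matrix_mtx <- function(path) {
  out <- as.matrix(Matrix::readMM(path))
  storage.mode(out) <- "integer"
  out
}
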