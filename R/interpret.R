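## The monoid layer: every valid interpretation of EMU labeling states combines
## disjoint EMUs with an associative, commutative product whose identity is the
## interpretation of the trivial (zero-atom) EMU.  Built-ins: mass
## distributions under convolution, Boolean-function fraction vectors under the
## Cartesian product with multiplication, and the atom count under addition.

#' Convolve two mass distributions
#'
#' The monoidal product of disjoint EMUs under the mass-distribution
#' interpretation: discrete convolution.  The identity is the length-1 vector
#' `c(1)`, the mass distribution of the trivial EMU.
#'
#' @param a,b Numeric mass fraction vectors (or mass [fraction_vector()]s).
#' @return Numeric vector of length `length(a) + length(b) - 1`; sums to 1
#'   when the inputs do.
#' @examples
#' convolve_mass(c(0.5, 0.5), c(0.5, 0.5))
#' @export
convolve_mass <- function(a, b) {
  a <- as_mass_values(a)
  b <- as_mass_values(b)
  if (length(a) == 0 || length(b) == 0) abort("mass vectors must be non-empty")
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

as_mass_values <- function(x) {
  if (inherits(x, "fraction_vector")) {
    if (fv_interp(x) != "mass") abort("expected a mass fraction vector")
    return(fv_values(x))
  }
  as.numeric(x)
}

#' Boolean-function product of disjoint EMU fraction vectors
#'
#' The monoidal product under the Boolean-function interpretation: the
#' Cartesian product of the two state spaces with multiplication of
#' fractions.  The two EMUs must have disjoint atom sets (conjunction is
#' undefined for conflicting determinate states); the output is indexed over
#' the sorted union of the atom positions.
#'
#' @param a,b Numeric isotopomer fraction vectors of the two EMUs (lengths
#'   `(m + 1)^|A|` and `(m + 1)^|B|`).
#' @param atoms_a,atoms_b Sorted atom positions of the two EMUs (1-based,
#'   within the parent moiety).
#' @param m Greatest mass shift shared by the enumeration.
#' @return Numeric vector over the isotopomers of the union EMU.
#' @examples
#' boolean_product(c(0.7, 0.3), c(0.6, 0.4), 1, 2, m = 1)
#' @export
boolean_product <- function(a, b, atoms_a, atoms_b, m = 1) {
  atoms_a <- sort(unique(as.integer(atoms_a)))
  atoms_b <- sort(unique(as.integer(atoms_b)))
  if (length(intersect(atoms_a, atoms_b)))
    abort("boolean_product() requires disjoint atom sets")
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != (m + 1)^length(atoms_a) || length(b) != (m + 1)^length(atoms_b))
    abort("fraction vector lengths do not match the atom sets")
  u <- sort(c(atoms_a, atoms_b))
  SU <- mixed_radix_matrix(length(u), 0:m)
  ia <- state_index(SU[, match(atoms_a, u), drop = FALSE], m + 1L)
  ib <- state_index(SU[, match(atoms_b, u), drop = FALSE], m + 1L)
  a[ia + 1L] * b[ib + 1L]
}

#' Atom count of an EMU
#'
#' The scalar interpretation: the number of atoms.  A homomorphism from
#' disjoint union to addition (`atom_count` of a disjoint union is the sum of
#' the counts); the identity is 0, the count of the trivial EMU.
#'
#' @param key An EMU key string (`"A{1,3}"`) or an integer vector of atom
#'   positions.
#' @return Non-negative integer.
#' @examples
#' atom_count("D{1,2}")
#' atom_count(integer(0))
#' @export
atom_count <- function(key) {
  if (is.character(key)) return(length(parse_emu_key(key)$atoms))
  length(unique(as.integer(key)))
}
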