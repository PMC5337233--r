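## Core state spaces: moiety specifications and the isotopomer / cumomer / EMU
## enumerations, with a fixed mixed-radix index encoding (atom 1 is the most
## significant digit; determinate states ascend 0 < 1 < ... < m and the
## indeterminate state (top) sorts last).

#' The indeterminate labeling state
#'
#' Labeling states are stored as integers: a determinate state is its mass
#' shift (0, 1, ..., m), the indeterminate state ("top", the disjunction of
#' every determinate state) is `NA`, and the contradictory state ("bottom",
#' produced only by logical conjunction) is `-1`.
#'
#' @return `st_top()` returns `NA_integer_`; `st_bottom()` returns `-1L`.
#' @examples
#' st_top()
#' st_bottom()
#' @export
st_top <- function() NA_integer_

#' @rdname st_top
#' @export
st_bottom <- function() -1L

is_top <- function(x) is.na(x)
is_bottom <- function(x) !is.na(x) & x < 0L
is_determinate <- function(x) !is.na(x) & x >= 0L

#' Tracer element configuration
#'
#' Maps each isotopic tracer element symbol to its greatest additional-neutron
#' number (mass shift), e.g. `tracer_config(C = 1, N = 1)` for a 13C/15N
#' experiment, or `tracer_config(H = 2)` when deuterium and tritium are both
#' in play.
#'
#' @param ... Named non-negative integers, one per element symbol.
#' @return A named integer vector of class `tracer_config`.
#' @examples
#' tracer_config(C = 1, N = 1)
#' @export
tracer_config <- function(...) {
  x <- c(...)
  if (length(x) == 0) abort("a tracer configuration needs at least one element")
  if (is.null(names(x)) || any(!nzchar(names(x))))
    abort("every tracer element must be named")
  if (anyDuplicated(names(x)))
    abort("duplicate element symbol in tracer configuration")
  x <- as.integer(x)
  if (any(is.na(x)) || any(x < 0))
    abort("element mass shifts must be non-negative integers")
  structure(setNames(x, names(c(...))), class = "tracer_config")
}

#' Moiety specification
#'
#' A moiety is any ordered set of isotopic atoms (not necessarily bonded, nor
#' from one metabolite).  The specification records the element of each atom,
#' the per-atom greatest mass shift (from the tracer configuration) and the
#' moiety-wide greatest shift `m` (the maximum over atoms; states above an
#' atom's own shift are representable but must carry probability zero).
#'
#' @param metabolite_id Metabolite (or fragment) identifier.
#' @param elements Character vector of element symbols, one per atom, or a
#'   single string of one-letter symbols (e.g. `"CCN"`).
#' @param tracer A [tracer_config()]; defaults to single-shift carbon.
#' @return A list of class `moiety_spec` with fields `metabolite_id`,
#'   `elements`, `shifts`, `n` (atom count) and `m` (greatest shift).
#' @examples
#' moiety_spec("CN", c("C", "N"), tracer_config(C = 1, N = 1))
#' @export
moiety_spec <- function(metabolite_id, elements, tracer = tracer_config(C = 1)) {
  if (length(elements) == 1 && !is.na(elements) && nchar(elements) > 1)
    elements <- strsplit(elements, "")[[1]]
  if (length(elements) == 1 && identical(elements, ""))
    elements <- character(0)
  elements <- as.character(elements)
  unknown <- setdiff(elements, names(tracer))
  if (length(unknown))
    abort(paste0("element(s) not in tracer configuration: ",
                 paste(unique(unknown), collapse = ", ")))
  shifts <- unname(tracer[elements])
  structure(
    list(metabolite_id = as.character(metabolite_id),
         elements = elements,
         shifts = as.integer(shifts),
         n = length(elements),
         m = if (length(shifts)) max(as.integer(shifts)) else 0L),
    class = "moiety_spec")
}

#' @export
print.moiety_spec <- function(x, ...) {
  cat(sprintf("<moiety_spec> %s: %s (n = %d, m = %d)\n",
              x$metabolite_id,
              if (x$n) paste(x$elements, collapse = "") else "(no atoms)",
              x$n, x$m))
  invisible(x)
}

## ---- mixed-radix machinery ------------------------------------------------

## All rows of the n-digit enumeration over `alphabet`, atom 1 most
## significant (the last atom cycles fastest).  `alphabet` may contain NA
## (top), which must come last.
mixed_radix_matrix <- function(n, alphabet) {
  if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  g <- expand.grid(rep(list(alphabet), n), KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(g)[, rev(seq_len(n)), drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

## Mixed-radix index (0-based) of rows of a determinate state matrix in base
## `base` (= m + 1), atom 1 most significant.
state_index <- function(states, base) {
  states <- rbind(states)
  n <- ncol(states)
  if (n == 0) return(rep(0L, nrow(states)))
  w <- base^((n - 1):0)
  as.integer(states %*% w)
}

## Inverse of state_index().
index_state <- function(index, n, base) {
  out <- matrix(0L, nrow = length(index), ncol = n)
  rem <- as.integer(index)
  if (n > 0) for (j in n:1) {
    out[, j] <- rem %% base
    rem <- rem %/% base
  }
  out
}

TOP_CHAR <- "\u22a4"

#' Format and parse state labels
#'
#' State tuples print as comma-separated digits with `"\u22a4"` (the down-tack glyph) for the
#' indeterminate state, e.g. `"0,1"` or `"\u22a4,1"`.  `parse_state_label()`
#' also accepts `"x"`, `"X"` or `"T"` for the indeterminate state.
#'
#' @param states Integer vector (or matrix with one row per state tuple);
#'   `NA` encodes the indeterminate state.
#' @param label A label string.
#' @return `state_label()` a character vector; `parse_state_label()` an
#'   integer vector with `NA` for indeterminate positions.
#' @examples
#' state_label(c(0L, NA))
#' parse_state_label("x,1")
#' @export
state_label <- function(states) {
  states <- rbind(states)
  if (ncol(states) == 0) return(rep("()", nrow(states)))
  chr <- matrix(as.character(states), nrow = nrow(states))
  chr[is.na(chr)] <- TOP_CHAR
  apply(chr, 1, paste, collapse = ",")
}

#' @rdname state_label
#' @export
parse_state_label <- function(label) {
  if (identical(label, "()")) return(integer(0))
  parts <- strsplit(label, ",", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  out <- suppressWarnings(as.integer(parts))
  out[parts %in% c(TOP_CHAR, "x", "X", "T")] <- NA_integer_
  if (any(is.na(out) & !(parts %in% c(TOP_CHAR, "x", "X", "T"))))
    abort(paste0("cannot parse state label: ", label))
  out
}

## ---- enumerations ---------------------------------------------------------

#' Enumerate the isotopomers of a moiety
#'
#' The `(m + 1)^n` fully determinate labeling states, in ascending mixed-radix
#' order (atom 1 most significant).
#'
#' @param spec A [moiety_spec()].
#' @return A tibble with columns `index` (0-based mixed-radix index), `states`
#'   (list of integer vectors) and `label`.
#' @examples
#' enumerate_isotopomers(moiety_spec("A", "CC"))
#' @export
enumerate_isotopomers <- function(spec) {
  stopifnot(inherits(spec, "moiety_spec"))
  S <- mixed_radix_matrix(spec$n, 0:spec$m)
  tibble(index = seq_len(nrow(S)) - 1L,
         states = lapply(seq_len(nrow(S)), function(i) S[i, ]),
         label = state_label(S))
}

## Fast path: the raw state matrix.
isotopomer_states <- function(spec) mixed_radix_matrix(spec$n, 0:spec$m)

#' Enumerate the cumomers of a moiety
#'
#' A cumomer assigns each atom either a determinate state or the indeterminate
#' state; atoms beyond the moiety (the countably infinite virtual tail) are
#' indeterminate by construction and are not stored.  Without puncturing there
#' are `(m + 2)^n` cumomers; puncturing at a determinate state `s` removes `s`
#' from the per-atom alphabet, leaving `(m + 1)^n` (the classical Wiechert
#' cumomers are the puncture at `s = 0`).
#'
#' @param spec A [moiety_spec()].
#' @param punctured_at Optional determinate state in `[0, m]` to exclude.
#' @return A tibble with columns `index`, `states` (integer vectors with `NA`
#'   for indeterminate) and `label`.
#' @examples
#' enumerate_cumomers(moiety_spec("A", "C"))
#' enumerate_cumomers(moiety_spec("A", "CC"), punctured_at = 0)
#' @export
enumerate_cumomers <- function(spec, punctured_at = NULL) {
  stopifnot(inherits(spec, "moiety_spec"))
  alphabet <- cumomer_alphabet(spec$m, punctured_at)
  S <- mixed_radix_matrix(spec$n, alphabet)
  tibble(index = seq_len(nrow(S)) - 1L,
         states = lapply(seq_len(nrow(S)), function(i) S[i, ]),
         label = state_label(S))
}

cumomer_alphabet <- function(m, punctured_at = NULL) {
  if (is.null(punctured_at)) return(c(0:m, NA_integer_))
  punctured_at <- as.integer(punctured_at)
  if (length(punctured_at) != 1 || is.na(punctured_at) ||
      punctured_at < 0 || punctured_at > m)
    abort(sprintf("punctured_at must be a determinate state in [0, %d]", m))
  c(setdiff(0:m, punctured_at), NA_integer_)
}

cumomer_states <- function(spec, punctured_at = NULL)
  mixed_radix_matrix(spec$n, cumomer_alphabet(spec$m, punctured_at))

#' Partition the cumomer set into EMU blocks
#'
#' The `(m + 2)^n` cumomers of a moiety partition into `2^n` mutually disjoint
#' blocks, one per subset `N` of atom positions: the block for `N` contains
#' exactly the `(m + 1)^|N|` cumomers determinate on `N` and indeterminate
#' elsewhere.  Each block is the state space of the EMU `(metabolite, N)`.
#'
#' @param spec A [moiety_spec()].
#' @return A tibble with one row per subset: `atom_set` (list of sorted
#'   integer positions), `key` (e.g. `"A{1,2}"`), `block_size`,
#'   `cumomer_index` (list of 0-based indices into [enumerate_cumomers()])
#'   and `labels` (list of state labels).
#' @examples
#' emu_partition(moiety_spec("A", "CC"))
#' @export
emu_partition <- function(spec) {
  stopifnot(inherits(spec, "moiety_spec"))
  n <- spec$n
  S <- cumomer_states(spec)
  det <- !is.na(S)
  ## subset bitmask of each cumomer row; atom i is bit i - 1
  if (n > 0) {
    mask <- as.integer(det %*% (2L^(0:(n - 1))))
  } else {
    mask <- rep(0L, nrow(S))
  }
  subsets <- 0:(2^n - 1)
  rows <- lapply(subsets, function(b) which(mask == b))
  atom_sets <- lapply(subsets, function(b) which(bitwAnd(b, 2L^(0:max(0, n - 1))) > 0))
  if (n == 0) atom_sets <- list(integer(0))
  tibble(
    atom_set = lapply(atom_sets, as.integer),
    key = vapply(atom_sets, function(a) emu_key(spec$metabolite_id, a), character(1)),
    block_size = lengths(rows),
    cumomer_index = lapply(rows, function(r) as.integer(r - 1L)),
    labels = lapply(rows, function(r) state_label(S[r, , drop = FALSE]))
  )
}

#' EMU keys
#'
#' An EMU (elementary metabolite unit) is a metabolite together with a sorted
#' set of its atom positions, written `"A{1,2}"`.  `parse_emu_key()` also
#' accepts square brackets (`"A[1,2]"`).
#'
#' @param metabolite_id Metabolite identifier.
#' @param atoms Integer vector of 1-based atom positions.
#' @param key A key string.
#' @return `emu_key()` a string; `parse_emu_key()` a list with fields
#'   `metabolite` and `atoms`.
#' @examples
#' emu_key("D", c(2, 1))
#' parse_emu_key("D[1,2]")
#' @export
emu_key <- function(metabolite_id, atoms) {
  atoms <- sort(unique(as.integer(atoms)))
  paste0(metabolite_id, "{", paste(atoms, collapse = ","), "}")
}

#' @rdname emu_key
#' @export
parse_emu_key <- function(key) {
  m <- regmatches(key, regexec("^([^{[]+)[{[]([0-9, ]*)[]}]$", key))[[1]]
  if (length(m) != 3) abort(paste0("cannot parse EMU key: ", key))
  atoms <- if (nzchar(trimws(m[3]))) {
    as.integer(trimws(strsplit(m[3], ",")[[1]]))
  } else integer(0)
  list(metabolite = m[2], atoms = sort(unique(atoms)))
}
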