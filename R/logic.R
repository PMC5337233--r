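## Multi-valued logic of labeling states: the determinate states 0..m are m + 1
## distinguished, mutually contradictory elements; top (indeterminate) is the
## conjunction identity and bottom (contradiction) the absorbing element.

#' Logical conjunction of labeling states
#'
#' Conjunction is defined for pairs that are equal, or where one side is the
#' indeterminate state (which then yields the other side).  Two distinct
#' determinate states are mutually contradictory and conjoin to bottom;
#' bottom absorbs everything.  Vectorized with the usual recycling.
#'
#' @param a,b Integer labeling states (`NA` = top, `-1` = bottom).
#' @return Integer vector of conjoined states.
#' @examples
#' conjoin_states(1L, st_top())   # 1
#' conjoin_states(0L, 1L)         # bottom
#' @export
conjoin_states <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  len <- max(length(a), length(b))
  a <- rep_len(a, len); b <- rep_len(b, len)
  out <- rep(st_bottom(), len)
  ta <- is_top(a); tb <- is_top(b)
  out[ta] <- b[ta]
  out[tb & !ta] <- a[tb & !ta]
  eq <- !ta & !tb & a == b & a >= 0L
  out[eq] <- a[eq]
  bot <- is_bottom(a) | is_bottom(b)
  out[bot] <- st_bottom()
  out
}

#' Logical conjunction of cumomers
#'
#' Pointwise conjunction of two cumomer state vectors over the same moiety.
#' Defined only when every position conjoins without contradiction; when the
#' two cumomers are determinate on disjoint atom sets, the fraction of the
#' conjunction is the product of the two fractions.
#'
#' @param a,b Integer state vectors of equal length (`NA` = indeterminate).
#' @return The conjoined state vector, or `NULL` if any position yields
#'   bottom (the conjunction is undefined).
#' @examples
#' conjoin_cumomers(c(NA, 1L), c(0L, NA))  # (0, 1)
#' conjoin_cumomers(c(1L, NA), c(0L, NA))  # NULL
#' @export
conjoin_cumomers <- function(a, b) {
  if (length(a) != length(b))
    abort("cumomers must be over the same moiety (equal length)")
  out <- conjoin_states(a, b)
  if (any(is_bottom(out))) return(NULL)
  out
}

#' Logical disjunction of fraction values
#'
#' Disjunction of mutually exclusive labeling states is addition of the
#' corresponding fractions; the disjunction of all isotopomer fractions of a
#' valid distribution is 1.
#'
#' @param fractions Numeric vector of probabilities in `[0, 1]`.
#' @return Their sum (0 for an empty vector).
#' @examples
#' disjoin_fractions(c(0.3, 0.2, 0.1))
#' @export
disjoin_fractions <- function(fractions) {
  fractions <- as.numeric(fractions)
  if (any(fractions < -1e-12 | fractions > 1 + 1e-12))
    abort("fractions must lie in [0, 1]")
  sum(fractions)
}

#' Cayley table of conjunction
#'
#' The full conjunction table over `{0..m, top, bottom}`, useful for
#' inspecting the closure properties of the multi-valued logic.
#'
#' @param m Greatest mass shift.
#' @return A tibble with columns `a`, `b`, `result` (state labels) over all
#'   `(m + 3)^2` pairs.
#' @examples
#' conjunction_table(1)
#' @export
conjunction_table <- function(m) {
  states <- c(0:m, st_top(), st_bottom())
  g <- expand.grid(a = states, b = states, KEEP.OUT.ATTRS = FALSE)
  lab <- function(x) {
    out <- as.character(x)
    out[is_top(x)] <- TOP_CHAR
    out[is_bottom(x)] <- "\u22a5"
    out
  }
  tibble(a = lab(g$a), b = lab(g$b),
         result = lab(conjoin_states(g$a, g$b)))
}
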