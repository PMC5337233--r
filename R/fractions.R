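## Fraction vectors: tibbles of (state label, probability) tagged with their
## interpretation and moiety specification.

FV_INTERPRETATIONS <- c("isotopomer", "cumomer", "punctured", "mass")

#' Fraction vectors
#'
#' A fraction vector is a probability vector over one interpretation of the
#' labeling state of a moiety: `"isotopomer"` (length `(m + 1)^n`, sums to 1),
#' `"cumomer"` (length `(m + 2)^n`, sums to `2^n`; every EMU block sums to 1),
#' `"punctured"` (length `(m + 1)^n`, the cumomer fractions punctured at a
#' determinate state `s`) or `"mass"` (length `n * m + 1`, sums to 1).  It is
#' represented as a tibble with columns `state` and `value`, carrying the
#' [moiety_spec()] and interpretation as attributes.
#'
#' @param values Numeric vector of probabilities, in the fixed enumeration
#'   order of the interpretation.
#' @param spec A [moiety_spec()].
#' @param interpretation One of `"isotopomer"`, `"cumomer"`, `"punctured"`,
#'   `"mass"`.
#' @param punctured_at Determinate state excluded by the puncture (only for
#'   `interpretation = "punctured"`).
#' @param validate Check lengths, non-negativity, sum rules and the
#'   surplus-state rule (states above an atom's own greatest shift must carry
#'   probability 0)?
#' @param tol Validation tolerance.
#' @return A tibble of class `fraction_vector`.
#' @examples
#' a <- moiety_spec("A", "CC")
#' fraction_vector(c(0.4, 0.3, 0.2, 0.1), a, "isotopomer")
#' @export
fraction_vector <- function(values, spec, interpretation = "isotopomer",
                            punctured_at = NULL, validate = TRUE,
                            tol = 1e-9) {
  stopifnot(inherits(spec, "moiety_spec"))
  interpretation <- match.arg(interpretation, FV_INTERPRETATIONS)
  values <- as.numeric(values)
  labels <- fv_labels(spec, interpretation, punctured_at)
  if (length(values) != length(labels))
    abort(sprintf("expected %d values for interpretation '%s' (n = %d, m = %d), got %d",
                  length(labels), interpretation, spec$n, spec$m, length(values)))
  out <- tibble(state = labels, value = values)
  class(out) <- c("fraction_vector", class(out))
  attr(out, "spec") <- spec
  attr(out, "interpretation") <- interpretation
  attr(out, "punctured_at") <-
    if (interpretation == "punctured") as.integer(punctured_at %||% 0L) else NULL
  if (validate) validate_fractions(out, tol = tol)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fv_labels <- function(spec, interpretation, punctured_at = NULL) {
  switch(interpretation,
    isotopomer = state_label(isotopomer_states(spec)),
    cumomer = state_label(cumomer_states(spec)),
    punctured = state_label(cumomer_states(spec, punctured_at %||% 0L)),
    mass = paste0("M+", 0:(spec$n * spec$m)))
}

fv_values <- function(x) x$value
fv_spec <- function(x) attr(x, "spec")
fv_interp <- function(x) attr(x, "interpretation")

#' Validate a fraction vector
#'
#' Checks non-negativity, the interpretation's sum rule (isotopomer and mass
#' vectors sum to 1; full cumomer vectors sum to `2^n` with every EMU block
#' summing to 1) and the surplus-state rule for heteronuclear moieties.
#'
#' @param x A [fraction_vector()].
#' @param tol Tolerance.
#' @return `x`, invisibly; aborts with a description of the violation.
#' @export
validate_fractions <- function(x, tol = 1e-9) {
  stopifnot(inherits(x, "fraction_vector"))
  spec <- fv_spec(x)
  v <- fv_values(x)
  interp <- fv_interp(x)
  if (any(v < -tol))
    abort("fraction vector has negative entries")
  if (interp %in% c("isotopomer", "mass") && abs(sum(v) - 1) > tol)
    abort(sprintf("%s fractions must sum to 1 (got %.12g)", interp, sum(v)))
  if (interp == "cumomer") {
    if (abs(sum(v) - 2^spec$n) > tol * 2^spec$n)
      abort(sprintf("cumomer fractions must sum to 2^n = %d (got %.12g)",
                    2^spec$n, sum(v)))
    part <- emu_partition(spec)
    for (i in seq_len(nrow(part))) {
      s <- sum(v[part$cumomer_index[[i]] + 1L])
      if (abs(s - 1) > tol)
        abort(sprintf("cumomer block %s must sum to 1 (got %.12g)",
                      part$key[i], s))
    }
  }
  ## surplus states: any position whose state exceeds that atom's own shift
  if (spec$n > 0 && any(spec$shifts < spec$m) &&
      interp %in% c("isotopomer", "cumomer", "punctured")) {
    S <- switch(interp,
      isotopomer = isotopomer_states(spec),
      cumomer = cumomer_states(spec),
      punctured = cumomer_states(spec, attr(x, "punctured_at")))
    surplus <- rep(FALSE, nrow(S))
    for (j in seq_len(spec$n)) {
      sj <- S[, j]
      surplus <- surplus | (!is.na(sj) & sj > spec$shifts[j])
    }
    if (any(v[surplus] > tol))
      abort("surplus labeling states (beyond an atom's greatest shift) must carry probability 0")
  }
  invisible(x)
}

#' Convert a fraction vector between interpretations
#'
#' Supported paths: isotopomer to cumomer, punctured or mass; and punctured
#' back to isotopomer (via the exact inverse of the Reed-Muller matrix).
#' Mass-to-isotopomer is not offered: the isotopomer-to-mass matrix is
#' rectangular and the conversion is not faithfully invertible (see
#' [pseudoinverse_demo()] for the minimum-norm preimage and why it is wrong).
#'
#' @param x A [fraction_vector()].
#' @param to Target interpretation.
#' @param punctured_at Puncture state for `to = "punctured"` (default 0, the
#'   classical Wiechert convention).
#' @param tol Validation tolerance for the result.
#' @return A [fraction_vector()] with the target interpretation.
#' @examples
#' a <- moiety_spec("A", "CC")
#' iso <- fraction_vector(c(0.4, 0.3, 0.2, 0.1), a, "isotopomer")
#' convert_fractions(iso, "mass")
#' @export
convert_fractions <- function(x, to, punctured_at = 0, tol = 1e-9) {
  stopifnot(inherits(x, "fraction_vector"))
  to <- match.arg(to, FV_INTERPRETATIONS)
  spec <- fv_spec(x)
  from <- fv_interp(x)
  v <- fv_values(x)
  if (from == "isotopomer" && to == "cumomer") {
    out <- as.numeric(ic_matrix_full(spec$n, spec$m) %*% v)
    return(fraction_vector(out, spec, "cumomer", validate = FALSE))
  }
  if (from == "isotopomer" && to == "punctured") {
    P <- punctured_matrix(spec$n, spec$m, punctured_at)
    return(fraction_vector(as.numeric(P %*% v), spec, "punctured",
                           punctured_at = punctured_at, validate = FALSE))
  }
  if (from == "punctured" && to == "isotopomer") {
    s <- attr(x, "punctured_at")
    P <- punctured_matrix(spec$n, spec$m, s)
    out <- as.numeric(solve(P, v))
    return(fraction_vector(out, spec, "isotopomer", tol = tol))
  }
  if (from == "isotopomer" && to == "mass") {
    out <- as.numeric(im_matrix(spec$n, spec$m) %*% v)
    return(fraction_vector(out, spec, "mass", tol = tol))
  }
  if (from == to) return(x)
  if (from == "mass")
    abort(paste0("non-invertible interpretation: mass fraction vectors cannot be ",
                 "faithfully converted back (the conversion matrix is rectangular); ",
                 "see pseudoinverse_demo() for the minimum-norm preimage"))
  abort(sprintf("no conversion path from '%s' to '%s'", from, to))
}

#' The Moore-Penrose pseudoinverse is not a conversion
#'
#' Applies the Moore-Penrose pseudoinverse of the isotopomer-to-mass matrix to
#' a mass fraction vector.  The result is the minimum-norm preimage, which
#' spreads each mass fraction uniformly over the isotopomers of that shift;
#' it is in general *not* the isotopomer vector the mass vector came from,
#' which is why mass-to-isotopomer is not offered as a conversion.  Exposed
#' for diagnostic and educational use.
#'
#' @param x A mass [fraction_vector()].
#' @return An isotopomer-interpretation [fraction_vector()] carrying attribute
#'   `pseudoinverse = TRUE`.
#' @examples
#' a <- moiety_spec("A", "CC")
#' m <- fraction_vector(c(0.4, 0.5, 0.1), a, "mass")
#' pseudoinverse_demo(m)  # (0.4, 0.25, 0.25, 0.1), not the true preimage
#' @export
pseudoinverse_demo <- function(x) {
  stopifnot(inherits(x, "fraction_vector"))
  if (fv_interp(x) != "mass") abort("pseudoinverse_demo() expects a mass fraction vector")
  spec <- fv_spec(x)
  IM <- im_matrix(spec$n, spec$m)
  out <- as.numeric(MASS::ginv(IM) %*% fv_values(x))
  fv <- fraction_vector(out, spec, "isotopomer", validate = FALSE)
  attr(fv, "pseudoinverse") <- TRUE
  fv
}

#' Marginalize an isotopomer vector onto a subset of atoms
#'
#' Sums the joint isotopomer distribution over the atoms outside `atoms`,
#' yielding the isotopomer fraction vector of the corresponding EMU.
#'
#' @param x An isotopomer [fraction_vector()].
#' @param atoms Integer vector of 1-based atom positions to keep.
#' @return An isotopomer [fraction_vector()] over the restricted moiety (its
#'   metabolite id gains the EMU suffix, e.g. `"A{1,2}"`).
#' @export
marginalize_fractions <- function(x, atoms) {
  stopifnot(inherits(x, "fraction_vector"))
  if (fv_interp(x) != "isotopomer")
    abort("marginalize_fractions() expects an isotopomer fraction vector")
  spec <- fv_spec(x)
  atoms <- sort(unique(as.integer(atoms)))
  if (length(atoms) && (min(atoms) < 1 || max(atoms) > spec$n))
    abort("atom positions out of range")
  sub <- moiety_spec(emu_key(spec$metabolite_id, atoms),
                     spec$elements[atoms],
                     tracer_from_spec(spec))
  v <- marginal_values(fv_values(x), spec, atoms, sub$m)
  fraction_vector(v, sub, "isotopomer", validate = FALSE)
}

## Reconstruct a tracer_config covering the spec's own elements.
tracer_from_spec <- function(spec) {
  if (spec$n == 0) return(tracer_config(C = 0))
  u <- !duplicated(spec$elements)
  do.call(tracer_config, as.list(setNames(spec$shifts[u], spec$elements[u])))
}

## Marginal of a raw isotopomer value vector (enumerated with spec's m) onto
## `atoms`, re-indexed in base sub_m + 1.  Rows carrying states beyond sub_m on
## the kept atoms are surplus and must have (numerically) zero probability.
marginal_values <- function(values, spec, atoms, sub_m, tol = 1e-9) {
  S <- isotopomer_states(spec)
  keep <- S[, atoms, drop = FALSE]
  ok <- if (length(atoms)) rowSums(keep > sub_m) == 0 else rep(TRUE, nrow(S))
  if (any(!ok) && any(values[!ok] > tol))
    abort("surplus labeling states carry nonzero probability; cannot marginalize")
  idx <- state_index(keep[ok, , drop = FALSE], sub_m + 1L)
  out <- numeric((sub_m + 1L)^length(atoms))
  agg <- rowsum(values[ok], idx)
  out[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  out
}

## Mass distribution (length sum(shifts) + 1) of a raw isotopomer value vector.
mass_values <- function(values, spec) {
  S <- isotopomer_states(spec)
  shift <- if (spec$n > 0) rowSums(S) else rep(0, nrow(S))
  out <- numeric(sum(spec$shifts) + 1L)
  keep <- shift <= sum(spec$shifts)  # surplus rows beyond total capacity
  agg <- rowsum(values[keep], shift[keep])
  out[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  if (any(!keep) && any(values[!keep] > 1e-9))
    abort("surplus labeling states carry nonzero probability")
  out
}

#' @export
print.fraction_vector <- function(x, ...) {
  spec <- fv_spec(x)
  cat(sprintf("# %s fraction vector for %s (n = %d, m = %d)\n",
              fv_interp(x), spec$metabolite_id, spec$n, spec$m))
  NextMethod()
}
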