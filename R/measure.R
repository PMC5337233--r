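## Measurement models: high-resolution MS tensors over per-element mass
## shifts, their collapse to the low-resolution mass distribution, GC-MS
## derivatization correction, and NMR splitting-pattern integrals.

#' High-resolution MS mass tensor
#'
#' A high-resolution MS measurement of a heteronuclear fragment resolves the
#' contribution of each tracer element separately: the result is a tensor
#' with one axis per distinct element, whose entry at per-element shift
#' combination `(k_C, k_N, ...)` is the total probability of isotopomers
#' whose element-wise shift totals match.
#'
#' @param x An isotopomer [fraction_vector()] over the fragment (EMU).
#' @return A numeric array of class `mass_tensor` with one named axis per
#'   distinct element (in order of first appearance); axis `e` runs from
#'   shift 0 to the summed greatest shift of that element's atoms.
#' @examples
#' cn <- moiety_spec("CN", "CN", tracer_config(C = 1, N = 1))
#' high_res_tensor(fraction_vector(c(0.4, 0.3, 0.2, 0.1), cn))
#' @export
high_res_tensor <- function(x) {
  stopifnot(inherits(x, "fraction_vector"))
  if (fv_interp(x) != "isotopomer")
    abort("high_res_tensor() expects an isotopomer fraction vector")
  spec <- fv_spec(x)
  v <- fv_values(x)
  elems <- unique(spec$elements)
  if (!length(elems)) elems <- character(0)
  S <- isotopomer_states(spec)
  dims <- unname(vapply(elems, function(e)
    sum(spec$shifts[spec$elements == e]) + 1L, integer(1)))
  if (!length(dims)) dims <- 1L
  out <- array(0, dim = dims,
               dimnames = if (length(elems))
                 lapply(setNames(dims, elems), function(d) paste0("M+", 0:(d - 1)))
               else NULL)
  per_elem <- vapply(elems, function(e) {
    cols <- which(spec$elements == e)
    as.integer(rowSums(S[, cols, drop = FALSE]))
  }, integer(nrow(S)))
  if (length(elems)) {
    idx <- matrix(per_elem + 1L, ncol = length(elems))
    ## surplus rows (per-element shift beyond the axis) must carry no mass
    inside <- rowSums(sweep(idx, 2, dims, `>`)) == 0
    if (any(!inside) && any(v[!inside] > 1e-9))
      abort("surplus labeling states carry nonzero probability")
    for (i in which(inside)) {
      pos <- idx[i, , drop = TRUE]
      out[matrix(pos, 1)] <- out[matrix(pos, 1)] + v[i]
    }
  } else {
    out[1] <- sum(v)
  }
  structure(out, class = c("mass_tensor", class(out)), elements = elems)
}

#' Collapse a mass tensor to the low-resolution mass distribution
#'
#' Sums the anti-diagonals: entries whose per-element shifts total the same
#' number of additional neutrons are indistinguishable at low resolution.
#'
#' @param x A `mass_tensor` (or plain numeric array).
#' @return Numeric mass fraction vector of length `sum(dim(x) - 1) + 1`.
#' @examples
#' collapse_tensor(matrix(c(0.4, 0.2, 0.3, 0.1), 2))
#' @export
collapse_tensor <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  total <- sum(d - 1L) + 1L
  out <- numeric(total)
  idx <- as.matrix(expand.grid(lapply(d, seq_len), KEEP.OUT.ATTRS = FALSE))
  shift <- rowSums(idx - 1L)
  vals <- as.numeric(x)[as.integer((idx - 1L) %*% cumprod(c(1L, head(d, -1)))) + 1L]
  agg <- rowsum(vals, shift)
  out[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  out
}

#' NMR splitting-pattern integral
#'
#' The proportional integral of a splitting pattern equals the conditional
#' probability of the detected labeling state given the observed nucleus'
#' state: the EMU fraction of the joint pattern divided by the observed
#' atom's fraction.  Detected atoms that are NMR-indistinguishable are passed
#' as an equivalence group, which relaxes the requirement to "at least one
#' atom of the group labeled"; ungrouped detected atoms must each be labeled.
#'
#' @param x An isotopomer [fraction_vector()] over the metabolite (e.g. from
#'   [brute_force_isotopomer_solve()]).
#' @param observed 1-based index of the observed atom.
#' @param observed_state Required determinate state of the observed atom
#'   (default 1, the singly labeled isotope).
#' @param detected Integer vector of detected atom indices (must not include
#'   the observed atom).
#' @param groups Optional list of integer vectors partitioning `detected`
#'   into equivalence groups; defaults to singletons.
#' @return A probability in `[0, 1]`.
#' @examples
#' leu <- moiety_spec("Leu", "CCCCCC")
#' p <- rep(1 / 64, 64)
#' nmr_splitting_integral(fraction_vector(p, leu), observed = 2,
#'                        detected = c(5, 6), groups = list(c(5, 6)))
#' @export
nmr_splitting_integral <- function(x, observed, observed_state = 1,
                                   detected, groups = NULL) {
  stopifnot(inherits(x, "fraction_vector"))
  if (fv_interp(x) != "isotopomer")
    abort("nmr_splitting_integral() expects an isotopomer fraction vector")
  spec <- fv_spec(x)
  observed <- as.integer(observed)
  detected <- sort(unique(as.integer(detected)))
  if (length(observed) != 1 || observed < 1 || observed > spec$n)
    abort("observed atom index out of range")
  if (any(detected < 1) || any(detected > spec$n))
    abort("detected atom index out of range")
  if (observed %in% detected)
    abort("the observed atom cannot also be a detected atom")
  if (is.null(groups)) groups <- as.list(detected)
  groups <- lapply(groups, function(g) sort(unique(as.integer(g))))
  if (!setequal(unlist(groups), detected) ||
      length(unlist(groups)) != length(detected))
    abort("groups must partition the detected atom set")
  v <- fv_values(x)
  S <- isotopomer_states(spec)
  denom_rows <- S[, observed] == observed_state
  denom <- sum(v[denom_rows])
  if (denom <= 0)
    abort(sprintf("undefined conditional: P(atom %d = %d) is zero",
                  observed, observed_state))
  keep <- denom_rows
  for (g in groups) {
    labeled <- rowSums(S[, g, drop = FALSE] > 0) > 0
    keep <- keep & labeled
  }
  sum(v[keep]) / denom
}

#' Correct a measured mass distribution for a derivatization agent
#'
#' A GC-MS measurement of a derivatized fragment is the convolution of the
#' fragment's mass distribution with that of the derivatization agent.  This
#' deconvolves the agent back out by solving the (banded) convolution system
#' in the least-squares sense.  Small negative entries caused by measurement
#' noise are clipped to zero and the result renormalized, with a warning.
#'
#' @param measured Numeric measured mass fraction vector.
#' @param agent Numeric mass fraction vector of the derivatization agent.
#' @param tol Negativity beyond this tolerance triggers the warning.
#' @return Numeric mass fraction vector of the underivatized fragment,
#'   length `length(measured) - length(agent) + 1`.
#' @examples
#' underiv <- c(0.7, 0.2, 0.1)
#' agent <- c(0.9, 0.1)
#' deconvolve_derivatization(convolve_mass(underiv, agent), agent)
#' @export
deconvolve_derivatization <- function(measured, agent, tol = 1e-9) {
  measured <- as_mass_values(measured)
  agent <- as_mass_values(agent)
  lt <- length(measured) - length(agent) + 1L
  if (lt < 1)
    abort("measured vector is shorter than the derivatization agent's")
  Tm <- matrix(0, length(measured), lt)
  for (j in seq_len(lt))
    Tm[j:(j + length(agent) - 1L), j] <- agent
  out <- as.numeric(qr.solve(Tm, measured))
  if (any(out < -tol)) {
    warn("deconvolution produced negative entries; clipping at 0 and renormalizing")
  }
  out[out < 0] <- 0
  s <- sum(out)
  if (s > 0) out <- out / s
  out
}
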