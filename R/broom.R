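## Tidiers for the package's result objects.

#' Tidy a labeling solution
#'
#' @param x A `labeling_solution` from [solve_steady_state()].
#' @param ... Unused.
#' @return A tibble with one row per EMU and mass shift: `emu`,
#'   `metabolite`, `size`, `role`, `shift` (`"M+0"`, ...), `fraction`.
#' @method tidy labeling_solution
#' @export
tidy.labeling_solution <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_len(nrow(x)), function(i) tibble(
    emu = x$emu[i], metabolite = x$metabolite[i], size = x$size[i],
    role = x$role[i],
    shift = paste0("M+", seq_along(x$mass[[i]]) - 1L),
    fraction = x$mass[[i]])))
}

#' Summarize a labeling solution
#'
#' @param x A `labeling_solution`.
#' @param ... Unused.
#' @return A one-row tibble: number of EMUs (total, solved, source), greatest
#'   EMU size, the worst deviation of any mass vector's sum from 1, and the
#'   most negative entry (0 when none).
#' @method glance labeling_solution
#' @export
glance.labeling_solution <- function(x, ...) {
  sums <- vapply(x$mass, sum, numeric(1))
  tibble(
    n_emus = nrow(x),
    n_solved = sum(x$role != "source"),
    n_sources = sum(x$role == "source"),
    max_size = max(x$size),
    max_sum_error = max(abs(sums - 1)),
    min_entry = min(vapply(x$mass, min, numeric(1))))
}

#' Tidy an identity system
#'
#' @param x An `identity_system` from [decompose_network()].
#' @param ... Unused.
#' @return A tibble with one row per identity: `lhs`, `size`, `flux_id`,
#'   `n_factors`, `rhs` (the factor keys joined with the monoidal product
#'   sign).
#' @method tidy identity_system
#' @export
tidy.identity_system <- function(x, ...) {
  tibble(lhs = x$lhs, size = x$size, flux_id = x$flux_id,
         n_factors = vapply(x$factors, nrow, integer(1)),
         rhs = vapply(x$factors, function(f)
           paste(f$key, collapse = " (*) "), character(1)))
}

#' Summarize an identity system
#'
#' @param x An `identity_system`.
#' @param ... Unused.
#' @return A one-row tibble: identity count, EMU count (closure), source-EMU
#'   count, greatest EMU size, number of convolution (multi-factor)
#'   identities.
#' @method glance identity_system
#' @export
glance.identity_system <- function(x, ...) {
  tibble(n_identities = nrow(x),
         n_emus = length(attr(x, "closure")),
         n_sources = length(attr(x, "sources")),
         max_size = max(x$size),
         n_convolutions = sum(vapply(x$factors, nrow, integer(1)) > 1))
}

#' Tidy a mass tensor
#'
#' @param x A `mass_tensor` from [high_res_tensor()].
#' @param ... Unused.
#' @return A tibble with one column of shifts per element axis plus
#'   `fraction`.
#' @method tidy mass_tensor
#' @export
tidy.mass_tensor <- function(x, ...) {
  elems <- attr(x, "elements")
  d <- dim(x) %||% length(x)
  g <- expand.grid(lapply(d, function(k) 0:(k - 1)), KEEP.OUT.ATTRS = FALSE)
  names(g) <- if (length(elems)) paste0("shift_", elems) else "shift"
  out <- as_tibble(g)
  out$fraction <- as.numeric(x)
  out
}
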