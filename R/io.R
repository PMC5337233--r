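## File formats: TSV fraction/flux/solution tables, YAML tracer and
## measurement configuration, JSON identity systems and solutions.  TSV uses
## '.' decimals and tab delimiters, locale-independent.

#' Read and write fraction vectors as TSV
#'
#' Two columns: `state` (a state-tuple label such as `"0,1"`, with the
#' indeterminate state written as the down-tack glyph or `x`; mass vectors
#' use `"M+0"`, `"M+1"`, ...) and `value`.
#'
#' @param x A [fraction_vector()].
#' @param path File path.
#' @param spec A [moiety_spec()] for reading.
#' @param interpretation Interpretation of the vector being read.
#' @param punctured_at Puncture state when reading a punctured vector.
#' @return `write_fractions_tsv()` returns `path` invisibly;
#'   `read_fractions_tsv()` a [fraction_vector()].
#' @export
write_fractions_tsv <- function(x, path) {
  stopifnot(inherits(x, "fraction_vector"))
  readr::write_tsv(tibble(state = x$state, value = x$value), path)
  invisible(path)
}

#' @rdname write_fractions_tsv
#' @export
read_fractions_tsv <- function(path, spec, interpretation = "isotopomer",
                               punctured_at = NULL) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    state = readr::col_character(), value = readr::col_double()))
  labels <- fv_labels(spec, interpretation, punctured_at)
  canon <- function(l) vapply(l, function(s) {
    if (grepl("^M\\+", s)) s else state_label(parse_state_label(s))
  }, character(1), USE.NAMES = FALSE)
  idx <- match(labels, canon(d$state))
  if (any(is.na(idx)))
    abort(paste0("fraction TSV is missing state(s): ",
                 paste(labels[is.na(idx)], collapse = ", ")))
  fraction_vector(d$value[idx], spec, interpretation, punctured_at = punctured_at)
}

#' Read and write flux assignments as TSV
#'
#' Two columns: `flux_id` and `value`.
#'
#' @param fluxes Named numeric vector or tibble.
#' @param path File path.
#' @return `read_fluxes_tsv()` returns a named numeric vector.
#' @export
write_fluxes_tsv <- function(fluxes, path) {
  fluxes <- resolve_fluxes(fluxes)
  readr::write_tsv(tibble(flux_id = names(fluxes), value = unname(fluxes)), path)
  invisible(path)
}

#' @rdname write_fluxes_tsv
#' @export
read_fluxes_tsv <- function(path) {
  d <- readr::read_tsv(path, col_types = readr::cols(
    flux_id = readr::col_character(), value = readr::col_double()))
  setNames(d$value, d$flux_id)
}

#' Read a tracer configuration from YAML
#'
#' Expects `elements: {C: 1, N: 1, ...}` mapping element symbols to greatest
#' mass shifts.
#'
#' @param path YAML file path.
#' @return A [tracer_config()].
#' @export
read_tracer_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$elements)) abort("tracer YAML must contain an 'elements' mapping")
  do.call(tracer_config, as.list(unlist(y$elements)))
}

#' Export an identity system as JSON
#'
#' One record per EMU in the closure: sources carry `factors = null`,
#' defined EMUs one record per identity with `flux` and `factors`.
#'
#' @param system An `identity_system`.
#' @param path Optional output path; omitted, the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_identities_json <- function(system, path = NULL) {
  stopifnot(inherits(system, "identity_system"))
  recs <- lapply(seq_len(nrow(system)), function(i) list(
    lhs = system$lhs[i], flux = system$flux_id[i],
    factors = system$factors[[i]]$key))
  src <- lapply(attr(system, "sources"), function(k)
    list(lhs = k, flux = NULL, factors = NULL))
  out <- jsonlite::toJSON(c(recs, src), auto_unbox = TRUE, null = "null",
                          pretty = TRUE)
  if (!is.null(path)) { writeLines(out, path); return(invisible(out)) }
  out
}

#' Write a labeling solution as TSV
#'
#' Long format: one row per EMU and mass shift, columns `emu`, `shift`
#' (`M+0`, ...), `fraction`.
#'
#' @param solution A `labeling_solution`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_solution_tsv <- function(solution, path) {
  readr::write_tsv(tidy(solution), path)
  invisible(path)
}

#' @rdname write_solution_tsv
#' @export
read_solution_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    emu = readr::col_character(), shift = readr::col_character(),
    fraction = readr::col_double()))
}
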