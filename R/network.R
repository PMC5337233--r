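## Atom-mapped reaction networks in a small text format, one reaction per
## line:
##
##   A[ab] + B[c] -> C[a] + D[bc] @ v
##
## Per-atom transition labels establish the left/right atom bijection.  Labels
## are single alphanumeric characters, or comma-separated multi-character
## labels (`A[a1,a2]`) for large moieties.  `#` starts a comment, blank lines
## are ignored, `<-` swaps the sides, and `<->` expands into two irreversible
## reactions with flux ids `v.fwd` / `v.rev`.  Metabolites with an empty label
## list (`E[]`, cofactors) are carried but ignored by decomposition.

#' Parse an atom-mapped reaction network
#'
#' @param text The network as a single string, a character vector of lines, or
#'   a file path (a single element naming an existing file is read).
#' @return A tibble of class `reaction_network` with one row per irreversible
#'   reaction: columns `line`, `flux_id`, `reagents` and `products`
#'   (list-columns of occurrence lists with fields `metabolite` and `labels`).
#'   The attribute `metabolite_atoms` maps metabolite ids to atom counts.
#' @examples
#' parse_network("A[ab] + B[c] -> C[a] + D[bc] @ v")
#' @export
parse_network <- function(text) {
  if (length(text) == 1 && !grepl("[\n@]", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[i])
    raw <- trimws(raw)
    if (!nzchar(raw)) next
    rows <- c(rows, parse_reaction_line(raw, i))
  }
  if (!length(rows)) abort("network contains no reactions")
  net <- dplyr::bind_rows(rows)
  ## consistent metabolite arity across the network
  occ <- c(unlist(net$reagents, recursive = FALSE),
           unlist(net$products, recursive = FALSE))
  arity <- tapply(vapply(occ, function(o) length(o$labels), integer(1)),
                  vapply(occ, function(o) o$metabolite, character(1)),
                  unique, simplify = FALSE)
  bad <- names(arity)[lengths(arity) > 1]
  if (length(bad))
    abort(paste0("inconsistent atom count for metabolite(s): ",
                 paste(bad, collapse = ", ")))
  class(net) <- c("reaction_network", class(net))
  attr(net, "metabolite_atoms") <-
    setNames(vapply(arity, `[[`, integer(1), 1), names(arity))
  net
}

parse_reaction_line <- function(raw, line) {
  perr <- function(msg) abort(sprintf("line %d: %s", line, msg))
  flux_split <- strsplit(raw, "@", fixed = TRUE)[[1]]
  if (length(flux_split) != 2) perr("expected exactly one '@ flux_id'")
  flux_id <- trimws(flux_split[2])
  if (!nzchar(flux_id)) perr("empty flux id")
  body <- flux_split[1]
  rev2 <- grepl("<->", body, fixed = TRUE)
  fwd <- grepl("->", body, fixed = TRUE)
  back <- grepl("<-", body, fixed = TRUE) && !rev2
  arrow <- if (rev2) "<->" else if (fwd) "->" else if (back) "<-" else
    perr("no reaction arrow found")
  sides <- strsplit(body, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2) perr("expected exactly one reaction arrow")
  lhs <- parse_side(sides[1], perr)
  rhs <- parse_side(sides[2], perr)
  if (back) { tmp <- lhs; lhs <- rhs; rhs <- tmp }
  check_balance <- function(rg, pr) {
    labs_l <- unlist(lapply(rg, `[[`, "labels"))
    labs_r <- unlist(lapply(pr, `[[`, "labels"))
    if (anyDuplicated(labs_l)) perr("duplicate atom label on the reagent side")
    if (anyDuplicated(labs_r)) perr("duplicate atom label on the product side")
    if (!setequal(labs_l, labs_r) || length(labs_l) != length(labs_r))
      perr(paste0("atom labels not conserved across the reaction (unmatched: ",
                  paste(union(setdiff(labs_l, labs_r), setdiff(labs_r, labs_l)),
                        collapse = ", "), ")"))
  }
  mk <- function(fid, rg, pr) {
    check_balance(rg, pr)
    tibble(line = line, flux_id = fid,
           reagents = list(rg), products = list(pr))
  }
  if (rev2) {
    list(mk(paste0(flux_id, ".fwd"), lhs, rhs),
         mk(paste0(flux_id, ".rev"), rhs, lhs))
  } else {
    list(mk(flux_id, lhs, rhs))
  }
}

parse_side <- function(side, perr) {
  terms <- strsplit(side, "+", fixed = TRUE)[[1]]
  lapply(terms, function(tm) {
    tm <- trimws(tm)
    m <- regmatches(tm, regexec("^([A-Za-z0-9_.-]+)\\[([^]]*)\\]$", tm))[[1]]
    if (length(m) != 3) perr(paste0("cannot parse term: '", tm, "'"))
    labels <- if (!nzchar(m[3])) character(0)
      else if (grepl(",", m[3], fixed = TRUE)) trimws(strsplit(m[3], ",")[[1]])
      else strsplit(m[3], "")[[1]]
    list(metabolite = m[2], labels = labels)
  })
}

#' Format a reaction network back to its text form
#'
#' @param net A `reaction_network` tibble.
#' @return A character vector, one reaction per line.
#' @export
format_network <- function(net) {
  side_text <- function(side) paste(vapply(side, function(o) {
    labs <- o$labels
    sep <- if (any(nchar(labs) > 1)) "," else ""
    paste0(o$metabolite, "[", paste(labs, collapse = sep), "]")
  }, character(1)), collapse = " + ")
  vapply(seq_len(nrow(net)), function(i) {
    paste0(side_text(net$reagents[[i]]), " -> ", side_text(net$products[[i]]),
           " @ ", net$flux_id[i])
  }, character(1))
}

#' @rdname format_network
#' @param path Output file path.
#' @return `write_network()` returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  writeLines(format_network(net), path)
  invisible(path)
}
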