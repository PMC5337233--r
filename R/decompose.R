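## Power-set decomposition of atom-mapped reactions into flux-weighted EMU
## identities: for every product and every non-empty subset of its atoms, the
## product EMU equals the flux times the monoidal product of the reagent EMUs
## that contribute those atoms.

#' Decompose one reaction into EMU identities
#'
#' For each product occurrence and each non-empty subset `S` of its atoms, one
#' identity is emitted whose left-hand side is the product EMU `(product, S)`
#' and whose right-hand-side factors are the reagent EMUs obtained by grouping
#' the pre-images of `S`'s atoms by origin reagent occurrence.  A reaction
#' therefore yields `sum over products of (2^n_p - 1)` identities; the empty
#' set is excluded on both sides (including it would force the contradiction
#' `f(empty) = v * f(empty)`).
#'
#' @param reaction One row of a [parse_network()] tibble (or a list with
#'   fields `flux_id`, `reagents`, `products`).
#' @return A tibble with columns `lhs` (EMU key), `lhs_metabolite`,
#'   `lhs_atoms` (list), `size`, `flux_id` and `factors` (list-column; each
#'   element a tibble with columns `metabolite`, `atoms`, `key`).
#' @examples
#' net <- parse_network("A[ab] + B[c] -> C[a] + D[bc] @ v")
#' decompose_reaction(net[1, ])
#' @export
decompose_reaction <- function(reaction) {
  if (inherits(reaction, "data.frame")) {
    stopifnot(nrow(reaction) == 1)
    reaction <- list(flux_id = reaction$flux_id[[1]],
                     reagents = reaction$reagents[[1]],
                     products = reaction$products[[1]])
  }
  reagents <- reaction$reagents
  products <- reaction$products
  ## label -> (reagent occurrence, position)
  lab_tab <- dplyr::bind_rows(lapply(seq_along(reagents), function(o) {
    labs <- reagents[[o]]$labels
    if (!length(labs)) return(NULL)
    tibble(label = labs, occurrence = o, position = seq_along(labs))
  }))
  out <- list()
  for (p in seq_along(products)) {
    prod <- products[[p]]
    np <- length(prod$labels)
    if (np == 0) next  # cofactor / untracked species
    origin <- lab_tab[match(prod$labels, lab_tab$label), ]
    for (bits in seq_len(2^np - 1)) {
      S <- which(bitwAnd(bits, 2L^(0:(np - 1))) > 0)
      org <- origin[S, ]
      groups <- split(org$position, org$occurrence)
      factors <- dplyr::bind_rows(lapply(names(groups), function(o) {
        oi <- as.integer(o)
        fa <- sort(groups[[o]])
        tibble(metabolite = reagents[[oi]]$metabolite,
               atoms = list(fa),
               key = emu_key(reagents[[oi]]$metabolite, fa))
      }))
      factors <- factors[order(factors$key), ]  # canonical factor order
      out[[length(out) + 1L]] <- tibble(
        lhs = emu_key(prod$metabolite, S),
        lhs_metabolite = prod$metabolite,
        lhs_atoms = list(as.integer(S)),
        size = length(S),
        flux_id = reaction$flux_id,
        factors = list(factors))
    }
  }
  dplyr::bind_rows(out)
}

#' Decompose a reaction network into an EMU identity system
#'
#' Takes the union of the per-reaction identity systems, canonically sorted
#' and deduplicated, and (optionally) restricts it to the backward-reachable
#' closure of a set of target EMUs: every EMU transitively needed to define
#' the targets.  Factors with no defining identity are source EMUs (substrate
#' labeling must be supplied to the solver).
#'
#' @param network A `reaction_network` from [parse_network()] (a character
#'   string is parsed first).
#' @param targets Optional character vector of EMU keys (`"D{1,2}"` or
#'   `"D[1,2]"`) to prune towards.
#' @return A tibble of class `identity_system` (columns as in
#'   [decompose_reaction()]), with attributes `closure` (all EMU keys in the
#'   pruned system, including sources), `sources` (keys with no defining
#'   identity), `metabolite_atoms` and `network`.
#' @examples
#' net <- parse_network("A[ab] + B[c] -> C[a] + D[bc] @ v")
#' decompose_network(net)
#' @export
decompose_network <- function(network, targets = NULL) {
  if (is.character(network)) network <- parse_network(network)
  ids <- dplyr::bind_rows(lapply(seq_len(nrow(network)), function(i)
    decompose_reaction(network[i, ])))
  if (!nrow(ids)) abort("network decomposes to no identities (no tracked atoms?)")
  ## canonical order and exact-duplicate removal
  ids$factor_sig <- vapply(ids$factors, function(f)
    paste(sort(f$key), collapse = "*"), character(1))
  ids <- dplyr::arrange(ids, .data$size, .data$lhs, .data$flux_id, .data$factor_sig)
  ids <- dplyr::distinct(ids, .data$lhs, .data$flux_id, .data$factor_sig,
                         .keep_all = TRUE)
  if (!is.null(targets)) {
    targets <- vapply(targets, function(k) {
      pk <- parse_emu_key(k); emu_key(pk$metabolite, pk$atoms)
    }, character(1), USE.NAMES = FALSE)
    missing_t <- setdiff(targets, ids$lhs)
    if (length(missing_t))
      abort(paste0("unresolvable EMU(s): no reaction produces ",
                   paste(missing_t, collapse = ", ")))
    needed <- character(0)
    queue <- targets
    while (length(queue)) {
      k <- queue[[1]]; queue <- queue[-1]
      if (k %in% needed) next
      needed <- c(needed, k)
      defs <- ids[ids$lhs == k, ]
      fac <- unique(unlist(lapply(defs$factors, `[[`, "key")))
      queue <- c(queue, setdiff(fac, needed))
    }
    ids <- ids[ids$lhs %in% needed, ]
    closure <- sort(needed)
  } else {
    closure <- sort(unique(c(ids$lhs, unlist(lapply(ids$factors, `[[`, "key")))))
  }
  sources <- setdiff(closure, unique(ids$lhs))
  ids$factor_sig <- NULL
  class(ids) <- c("identity_system", class(ids))
  attr(ids, "closure") <- closure
  attr(ids, "sources") <- sources
  attr(ids, "metabolite_atoms") <- attr(network, "metabolite_atoms")
  attr(ids, "network") <- network
  ids
}

#' @export
print.identity_system <- function(x, ...) {
  cat(sprintf("# EMU identity system: %d identities, %d EMUs (%d source)\n",
              nrow(x), length(attr(x, "closure")), length(attr(x, "sources"))))
  NextMethod()
}

#' Render identities in equation form
#'
#' @param x An `identity_system`.
#' @return Character vector like `"D{1,2} = v * (A{2} (*) B{1})"`.
#' @export
format_identities <- function(x) {
  vapply(seq_len(nrow(x)), function(i) {
    keys <- x$factors[[i]]$key
    rhs <- if (length(keys) > 1)
      paste0("(", paste(keys, collapse = " (*) "), ")") else keys
    paste0(x$lhs[i], " = ", x$flux_id[i], " * ", rhs)
  }, character(1))
}
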