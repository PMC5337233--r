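## Seeded generator of random, well-posed atom-mapped networks: atom-balanced
## by construction, every intermediate reachable from a substrate and drained
## towards a sink, and flux values that satisfy pool stationarity exactly
## (the network is grown from flux-carrying "active" metabolites whose supply
## is always fully consumed or explicitly drained).

#' Fixture generator configuration
#'
#' @param seed Integer seed; all randomness funnels through it.
#' @param n_metabolites Target number of metabolites (>= 2).
#' @param max_atoms Greatest atom count per metabolite (>= 1).
#' @param elements A [tracer_config()]; atoms are drawn from its elements.
#' @param cycle_probability Probability of appending a two-reaction futile
#'   cycle around an intermediate.
#' @param condensation_probability Probability of a bimolecular condensation
#'   when two equal-rate metabolites are available.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L, n_metabolites = 6, max_atoms = 3,
                           elements = tracer_config(C = 1),
                           cycle_probability = 0.25,
                           condensation_probability = 0.35) {
  if (n_metabolites < 2) abort("need at least 2 metabolites")
  if (max_atoms < 1) abort("max_atoms must be at least 1")
  structure(list(seed = as.integer(seed), n_metabolites = n_metabolites,
                 max_atoms = max_atoms, elements = elements,
                 cycle_probability = cycle_probability,
                 condensation_probability = condensation_probability),
            class = "fixture_config")
}

#' Generate a random well-posed network fixture
#'
#' Deterministic given the seed.  Substrate metabolites receive random
#' isotopomer labelings; every flux assignment satisfies per-pool
#' stationarity by construction.
#'
#' @param cfg A [fixture_config()].
#' @return A list with fields `network` (text lines), `fluxes` (named
#'   numeric), `inputs` (named list of isotopomer [fraction_vector()]s for
#'   the substrates), `elements` (metabolite element strings) and `config`.
#' @examples
#' fx <- generate_fixture(fixture_config(seed = 42))
#' fx$network
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  elems <- names(cfg$elements)
  label_pool <- c(letters, LETTERS, 0:9)
  met_counter <- 0L
  new_met <- function() { met_counter <<- met_counter + 1L; paste0("M", met_counter) }

  ## active metabolites: id, elements (per-atom vector), rate.  Atom
  ## transition labels are local to each emitted reaction line.
  actives <- list()
  met_elements <- character(0)
  n_src <- if (cfg$n_metabolites >= 4) sample(1:2, 1) else 1L
  for (s in seq_len(n_src)) {
    na <- sample(cfg$max_atoms, 1)
    id <- new_met()
    el <- sample(elems, na, replace = TRUE)
    met_elements[id] <- paste(el, collapse = "")
    actives[[length(actives) + 1L]] <- list(id = id, elements = el, rate = 1)
  }
  sources <- vapply(actives, `[[`, character(1), "id")
  reactions <- character(0)
  flux_counter <- 0L
  new_flux <- function() { flux_counter <<- flux_counter + 1L; paste0("v", flux_counter) }
  fluxes <- numeric(0)

  ## emit one line: reagent occurrences get fresh per-line labels covering
  ## atoms 1..total; each product is (id, origin), origin indexing into the
  ## concatenated reagent atom sequence (a bijection across the products)
  emit <- function(reagents, products, rate) {
    total <- sum(vapply(reagents, function(r) length(r$elements), integer(1)))
    if (total > length(label_pool)) abort("atom count exceeds the label pool")
    labs <- label_pool[seq_len(total)]
    off <- 0L
    lhs <- vapply(reagents, function(r) {
      k <- length(r$elements)
      out <- paste0(r$id, "[", paste(labs[off + seq_len(k)], collapse = ""), "]")
      off <<- off + k
      out
    }, character(1))
    rhs <- vapply(products, function(p)
      paste0(p$id, "[", paste(labs[p$origin], collapse = ""), "]"), character(1))
    fid <- new_flux()
    fluxes[fid] <<- rate
    reactions <<- c(reactions, paste0(paste(lhs, collapse = " + "), " -> ",
                                      paste(rhs, collapse = " + "), " @ ", fid))
    invisible(fid)
  }
  spawn <- function(elements, rate) {
    id <- new_met()
    met_elements[id] <<- paste(elements, collapse = "")
    list(id = id, elements = elements, rate = rate)
  }

  while (met_counter < cfg$n_metabolites && length(actives)) {
    rates <- vapply(actives, `[[`, numeric(1), "rate")
    sizes <- vapply(actives, function(a) length(a$elements), integer(1))
    pair <- NULL
    if (length(actives) >= 2) {
      ok <- outer(rates, rates, function(a, b) abs(a - b) < 1e-12) &
        outer(sizes, sizes, `+`) <= cfg$max_atoms &
        upper.tri(matrix(TRUE, length(rates), length(rates)))
      hits <- which(ok, arr.ind = TRUE)
      if (nrow(hits)) pair <- hits[sample(nrow(hits), 1), ]
    }
    if (!is.null(pair) && stats::runif(1) < cfg$condensation_probability) {
      a <- actives[[pair[1]]]; b <- actives[[pair[2]]]
      el <- c(a$elements, b$elements)
      perm <- sample(length(el))
      prod <- spawn(el[perm], a$rate)
      emit(list(a, b), list(list(id = prod$id, origin = perm)), a$rate)
      actives <- c(actives[-c(pair[1], pair[2])], list(prod))
      next
    }
    i <- sample(length(actives), 1)
    a <- actives[[i]]
    na <- length(a$elements)
    choice <- sample(c("permute", "split", "branch"), 1,
                     prob = c(0.45, if (na >= 2) 0.35 else 0, 0.2))
    if (choice == "split") {
      cut <- sample(na - 1, 1)
      perm <- sample(na)
      o1 <- perm[seq_len(cut)]; o2 <- perm[-seq_len(cut)]
      p1 <- spawn(a$elements[o1], a$rate); p2 <- spawn(a$elements[o2], a$rate)
      emit(list(a), list(list(id = p1$id, origin = o1),
                         list(id = p2$id, origin = o2)), a$rate)
      actives <- c(actives[-i], list(p1, p2))
    } else if (choice == "branch") {
      alpha <- sample(c(0.25, 0.5, 0.75), 1)
      perm1 <- sample(na); perm2 <- sample(na)
      p1 <- spawn(a$elements[perm1], a$rate * alpha)
      p2 <- spawn(a$elements[perm2], a$rate * (1 - alpha))
      emit(list(a), list(list(id = p1$id, origin = perm1)), a$rate * alpha)
      emit(list(a), list(list(id = p2$id, origin = perm2)), a$rate * (1 - alpha))
      actives <- c(actives[-i], list(p1), list(p2))
    } else {
      perm <- sample(na)
      p <- spawn(a$elements[perm], a$rate)
      emit(list(a), list(list(id = p$id, origin = perm)), a$rate)
      actives <- c(actives[-i], list(p))
    }
  }

  ## every substrate must feed the network: drain any untouched source
  for (a in actives) {
    if (!a$id %in% sources) next
    perm <- sample(length(a$elements))
    p <- spawn(a$elements[perm], a$rate)
    emit(list(a), list(list(id = p$id, origin = perm)), a$rate)
  }

  ## optional futile cycle around a consumed intermediate
  if (stats::runif(1) < cfg$cycle_probability) {
    net_so_far <- parse_network(reactions)
    consumed <- unique(unlist(lapply(net_so_far$reagents, function(rg)
      vapply(rg, `[[`, character(1), "metabolite"))))
    candidates <- setdiff(consumed, sources)
    if (length(candidates)) {
      met <- sample(candidates, 1)
      ael <- strsplit(met_elements[[met]], "")[[1]]
      na <- length(ael)
      x <- list(id = met, elements = ael, rate = 0.5)
      perm <- sample(na)
      y <- spawn(ael[perm], 0.5)
      emit(list(x), list(list(id = y$id, origin = perm)), 0.5)
      ## invert the forward permutation so y maps back onto met's own atoms
      emit(list(y), list(list(id = met, origin = order(perm))), 0.5)
    }
  }

  ## substrate labelings: random normalized isotopomer vectors obeying the
  ## surplus-state rule
  inputs <- list()
  for (id in sources) {
    spec <- moiety_spec(id, met_elements[[id]], cfg$elements)
    S <- isotopomer_states(spec)
    ok <- rep(TRUE, nrow(S))
    for (j in seq_len(spec$n)) ok <- ok & S[, j] <= spec$shifts[j]
    v <- numeric(nrow(S))
    v[ok] <- stats::runif(sum(ok))
    v <- v / sum(v)
    inputs[[id]] <- fraction_vector(v, spec, "isotopomer")
  }

  list(network = reactions, fluxes = fluxes, inputs = inputs,
       elements = met_elements, config = cfg)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
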