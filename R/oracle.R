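## Brute-force isotopomer-balance simulator: fixed-point iteration on the
## full joint isotopomer distribution of every metabolite.  Exponential in
## atom count, so only for small networks - it is the independent
## cross-check the EMU cascade is validated against.

#' Brute-force steady-state isotopomer solve
#'
#' Iterates the full isotopomer balance to a fixed point: each produced
#' metabolite's joint distribution is the flux-weighted mixture, over its
#' producing reactions, of the product distribution implied by the reagent
#' joints (reagent moieties entering a reaction are treated as independent,
#' and atoms are carried through the reaction's atom map).  Metabolites never
#' produced keep their input labeling (unlabeled by default).
#'
#' @param network A network text / file path / `reaction_network`.
#' @param fluxes Named flux values.
#' @param inputs Named list of isotopomer labelings for substrate metabolites
#'   (numeric vectors or [fraction_vector()]s).
#' @param tracer A [tracer_config()].
#' @param elements Optional metabolite element strings (see
#'   [build_cascade()]).
#' @param tol Fixed-point tolerance on the max-abs change per sweep.
#' @param max_iter Iteration cap; exceeding it aborts with the residual.
#' @return A named list of isotopomer [fraction_vector()]s, one per
#'   metabolite with tracked atoms.
#' @examples
#' brute_force_isotopomer_solve(
#'   "A[a] -> B[a] @ v", fluxes = c(v = 2),
#'   inputs = list(A = c(0.25, 0.75)))
#' @export
brute_force_isotopomer_solve <- function(network, fluxes, inputs = list(),
                                         tracer = tracer_config(C = 1),
                                         elements = NULL,
                                         tol = 1e-12, max_iter = 50000) {
  if (is.character(network)) network <- parse_network(network)
  fluxes <- resolve_fluxes(fluxes)
  specs <- metabolite_specs_from(attr(network, "metabolite_atoms"), tracer, elements)
  specs <- specs[vapply(specs, function(s) s$n > 0, logical(1))]
  inputs <- normalize_inputs(inputs, specs)

  produced <- unique(unlist(lapply(network$products, function(pr)
    vapply(pr, `[[`, character(1), "metabolite"))))
  produced <- intersect(produced, names(specs))
  unknowns <- setdiff(produced, names(inputs))

  ## current distributions
  dist <- lapply(specs, function(s) c(1, numeric((s$m + 1)^s$n - 1L)))
  for (met in names(inputs)) dist[[met]] <- fv_values(inputs[[met]])
  fixed <- setdiff(names(specs), unknowns)
  unl <- setdiff(fixed, names(inputs))
  unl <- unl[vapply(unl, function(met) {
    ## warn only for true sources that feed the network
    any(vapply(seq_len(nrow(network)), function(i)
      met %in% vapply(network$reagents[[i]], `[[`, character(1), "metabolite"),
      logical(1)))
  }, logical(1))]
  for (met in unl)
    warn(paste0("no input labeling for source metabolite ", met,
                "; assuming unlabeled"))

  ## precompute, per (reaction, product occurrence): for each reagent
  ## occurrence feeding it, the reagent positions (sorted) and the product
  ## positions carrying those atoms, plus the product enumeration
  plans <- list()
  for (i in seq_len(nrow(network))) {
    v <- fluxes[[network$flux_id[i]]]
    reagents <- network$reagents[[i]]
    lab_at <- lapply(reagents, `[[`, "labels")
    for (pr in network$products[[i]]) {
      met <- pr$metabolite
      if (!met %in% unknowns) next
      np <- length(pr$labels)
      pS <- isotopomer_states(specs[[met]])
      feeds <- list()
      for (o in seq_along(reagents)) {
        hit <- which(pr$labels %in% lab_at[[o]])
        if (!length(hit)) next
        rpos <- match(pr$labels[hit], lab_at[[o]])
        ord <- order(rpos)
        rpos <- rpos[ord]; ppos <- hit[ord]
        rspec <- specs[[reagents[[o]]$metabolite]]
        rS <- isotopomer_states(rspec)
        ## group index of each reagent isotopomer on the feeding positions
        group_idx <- state_index(rS[, rpos, drop = FALSE], rspec$m + 1L)
        ## lookup index of each product isotopomer into the marginal (NA for
        ## surplus states the reagent cannot carry)
        pstates <- pS[, ppos, drop = FALSE]
        ok <- rowSums(pstates > rspec$m) == 0
        lookup <- rep(NA_integer_, nrow(pS))
        lookup[ok] <- state_index(pstates[ok, , drop = FALSE], rspec$m + 1L) + 1L
        feeds[[length(feeds) + 1L]] <- list(
          metabolite = reagents[[o]]$metabolite,
          group_idx = group_idx,
          marg_len = (rspec$m + 1L)^length(rpos),
          lookup = lookup)
      }
      plans[[length(plans) + 1L]] <- list(
        metabolite = met, v = v, feeds = feeds, n_states = nrow(pS))
    }
  }
  if (!length(unknowns)) {
    return(lapply(setNames(names(specs), names(specs)), function(met)
      fraction_vector(dist[[met]], specs[[met]], "isotopomer", validate = FALSE)))
  }

  plan_mets <- vapply(plans, `[[`, character(1), "metabolite")
  weights <- vapply(plans, `[[`, numeric(1), "v")
  total_in <- tapply(weights, plan_mets, sum)
  if (any(total_in == 0))
    abort(paste0("zero total influx for metabolite(s): ",
                 paste(names(total_in)[total_in == 0], collapse = ", ")))

  for (iter in seq_len(max_iter)) {
    acc <- lapply(setNames(unknowns, unknowns), function(met)
      numeric(length(dist[[met]])))
    for (p in plans) {
      contrib <- rep(p$v, p$n_states)
      for (fd in p$feeds) {
        marg <- numeric(fd$marg_len)
        agg <- rowsum(dist[[fd$metabolite]], fd$group_idx)
        marg[as.integer(rownames(agg)) + 1L] <- agg[, 1]
        lk <- marg[fd$lookup]
        lk[is.na(lk)] <- 0
        contrib <- contrib * lk
      }
      acc[[p$metabolite]] <- acc[[p$metabolite]] + contrib
    }
    delta <- 0
    for (met in unknowns) {
      newd <- acc[[met]] / total_in[[met]]
      delta <- max(delta, max(abs(newd - dist[[met]])))
      dist[[met]] <- newd
    }
    if (delta < tol) break
    if (iter == max_iter)
      abort(sprintf("isotopomer fixed point did not converge in %d iterations (residual %g)",
                    max_iter, delta))
  }
  lapply(setNames(names(specs), names(specs)), function(met)
    fraction_vector(dist[[met]], specs[[met]], "isotopomer", validate = FALSE))
}

#' Project an oracle solution onto EMU mass distributions
#'
#' Marginalizes a brute-force isotopomer solution onto an EMU and applies the
#' isotopomer-to-mass conversion - the quantity the cascade solver computes
#' directly.
#'
#' @param oracle Result of [brute_force_isotopomer_solve()].
#' @param key An EMU key string.
#' @return Numeric mass fraction vector.
#' @export
oracle_emu_mass <- function(oracle, key) {
  pk <- parse_emu_key(key)
  if (!pk$metabolite %in% names(oracle))
    abort(paste0("oracle has no metabolite ", pk$metabolite))
  sub <- marginalize_fractions(oracle[[pk$metabolite]], pk$atoms)
  mass_values(fv_values(sub), fv_spec(sub))
}
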