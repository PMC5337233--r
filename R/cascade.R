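## Steady-state labeling cascade: per-EMU-size flux-balance systems solved in
## ascending size order.  At each size the consistent mass matrix is
## diag(total influx) minus the intra-size adjacency; multi-factor identities
## enter through virtual convolution vertices whose values are convolutions of
## strictly smaller, already-solved EMUs.

resolve_fluxes <- function(fluxes) {
  if (inherits(fluxes, "data.frame")) {
    stopifnot(all(c("flux_id", "value") %in% names(fluxes)))
    fluxes <- setNames(fluxes$value, fluxes$flux_id)
  }
  fluxes <- unlist(fluxes)
  if (is.null(names(fluxes)) || any(!nzchar(names(fluxes))))
    abort("fluxes must be named (flux_id -> value)")
  if (any(fluxes < 0)) abort("flux values must be non-negative")
  fluxes
}

metabolite_specs_from <- function(metabolite_atoms, tracer, elements = NULL) {
  mets <- names(metabolite_atoms)
  out <- lapply(mets, function(met) {
    n <- metabolite_atoms[[met]]
    el <- if (!is.null(elements) && met %in% names(elements)) elements[[met]]
      else paste(rep(names(tracer)[1], n), collapse = "")
    spec <- moiety_spec(met, el, tracer)
    if (spec$n != n)
      abort(sprintf("metabolite %s has %d atoms in the network but %d elements declared",
                    met, n, spec$n))
    spec
  })
  setNames(out, mets)
}

check_stationarity <- function(network, fluxes, input_mets, tol = 1e-8) {
  atoms <- attr(network, "metabolite_atoms")
  prod_f <- cons_f <- setNames(numeric(length(atoms)), names(atoms))
  for (i in seq_len(nrow(network))) {
    v <- fluxes[[network$flux_id[i]]]
    if (is.null(v) || is.na(v))
      abort(paste0("missing flux value for ", network$flux_id[i]))
    for (o in network$reagents[[i]]) cons_f[o$metabolite] <- cons_f[o$metabolite] + v
    for (o in network$products[[i]]) prod_f[o$metabolite] <- prod_f[o$metabolite] + v
  }
  for (met in names(atoms)) {
    if (atoms[[met]] == 0 || met %in% input_mets) next
    if (prod_f[met] == 0 || cons_f[met] == 0) next  # pure source / pure sink
    if (abs(prod_f[met] - cons_f[met]) > tol * max(prod_f[met], cons_f[met], 1))
      abort(sprintf("pool stationarity violated for metabolite %s (influx %g, efflux %g)",
                    met, prod_f[met], cons_f[met]))
  }
  invisible(TRUE)
}

normalize_inputs <- function(inputs, specs) {
  if (is.null(inputs)) inputs <- list()
  for (met in names(inputs)) {
    if (!met %in% names(specs))
      abort(paste0("input labeling supplied for unknown metabolite ", met))
    x <- inputs[[met]]
    spec <- specs[[met]]
    if (inherits(x, "fraction_vector")) {
      if (fv_interp(x) != "isotopomer")
        abort(paste0("input labeling for ", met, " must be an isotopomer fraction vector"))
      if (length(fv_values(x)) != (spec$m + 1)^spec$n)
        abort(paste0("input labeling for ", met, " has the wrong length"))
    } else {
      x <- fraction_vector(as.numeric(x), spec, "isotopomer")
      inputs[[met]] <- x
    }
    validate_fractions(inputs[[met]])
  }
  inputs
}

#' Assemble the per-size cascade system
#'
#' Classifies the EMUs of an identity system into source, intermediate and
#' sink vertices, and builds, for each EMU size, the adjacency blocks of the
#' flux-balance system.  Source vertices are EMUs of metabolites with declared
#' input labeling or with no defining identity (the latter default to
#' unlabeled, with a warning, when solved); sink EMUs are never consumed by
#' any identity; everything else is an intermediate.  Multi-factor identities
#' contribute virtual convolution vertices, classified with the sources of
#' their size.
#'
#' @param system An `identity_system` from [decompose_network()].
#' @param fluxes Named numeric vector (or tibble with columns `flux_id`,
#'   `value`) of non-negative flux values.
#' @param inputs Named list mapping substrate metabolite ids to isotopomer
#'   [fraction_vector()]s (plain numeric vectors are accepted and validated).
#' @param tracer A [tracer_config()].
#' @param elements Optional named character vector mapping metabolite ids to
#'   per-atom element strings (e.g. `c(CN = "CN")`); metabolites default to
#'   the first tracer element throughout.
#' @param tol Stationarity tolerance.
#' @return A list of class `cascade_system` with fields `sizes` (one entry
#'   per EMU size: vertex tibble, adjacency blocks `A21`, `A22`, `A31`,
#'   `A32`, identity bookkeeping), `specs`, `inputs`, `fluxes`.
#' @export
build_cascade <- function(system, fluxes, inputs = list(),
                          tracer = tracer_config(C = 1), elements = NULL,
                          tol = 1e-8) {
  stopifnot(inherits(system, "identity_system"))
  fluxes <- resolve_fluxes(fluxes)
  specs <- metabolite_specs_from(attr(system, "metabolite_atoms"), tracer, elements)
  inputs <- normalize_inputs(inputs, specs)
  net <- attr(system, "network")
  if (!is.null(net)) check_stationarity(net, as.list(fluxes), names(inputs), tol)
  missing_flux <- setdiff(unique(system$flux_id), names(fluxes))
  if (length(missing_flux))
    abort(paste0("missing flux value(s): ", paste(missing_flux, collapse = ", ")))

  input_mets <- names(inputs)
  lhs_mets <- vapply(system$lhs, function(k) parse_emu_key(k)$metabolite, character(1))
  unknown_lhs <- unique(system$lhs[!(lhs_mets %in% input_mets)])
  all_factor_keys <- unique(unlist(lapply(system$factors, `[[`, "key")))
  sink_keys <- setdiff(unknown_lhs, all_factor_keys)

  emu_len <- function(key) {
    pk <- parse_emu_key(key)
    sum(specs[[pk$metabolite]]$shifts[pk$atoms]) + 1L
  }
  key_size <- function(keys) vapply(keys, function(k)
    length(parse_emu_key(k)$atoms), integer(1))

  sizes <- sort(unique(key_size(unknown_lhs)))
  size_systems <- lapply(sizes, function(k) {
    unk <- unknown_lhs[key_size(unknown_lhs) == k]
    ## order: intermediates first, sinks last (the a2 / a3 partition)
    unk <- c(setdiff(unk, sink_keys), intersect(unk, sink_keys))
    idk <- system[system$lhs %in% unk, ]
    ## source-side vertices at this size: size-k source EMU factors and
    ## convolution vertices of multi-factor identities
    src_keys <- character(0)
    conv_keys <- character(0)
    terms <- vector("list", nrow(idk))
    for (i in seq_len(nrow(idk))) {
      f <- idk$factors[[i]]
      if (nrow(f) == 1 && f$key %in% unk) {
        terms[[i]] <- list(type = "intra", key = f$key)
      } else if (nrow(f) == 1) {
        src_keys <- union(src_keys, f$key)
        terms[[i]] <- list(type = "source", key = f$key)
      } else {
        ck <- paste(f$key, collapse = " (*) ")
        conv_keys <- union(conv_keys, ck)
        terms[[i]] <- list(type = "conv", key = ck, factors = f$key)
      }
    }
    a1 <- c(src_keys, conv_keys)
    n_int <- length(setdiff(unk, sink_keys))
    A <- matrix(0, length(unk), length(unk), dimnames = list(unk, unk))
    B <- matrix(0, length(unk), length(a1),
                dimnames = if (length(a1)) list(unk, a1) else list(unk, NULL))
    diag_efflux <- setNames(numeric(length(unk)), unk)
    for (i in seq_len(nrow(idk))) {
      v <- fluxes[[idk$flux_id[i]]]
      e <- idk$lhs[i]
      diag_efflux[e] <- diag_efflux[e] + v
      tm <- terms[[i]]
      if (tm$type == "intra") A[e, tm$key] <- A[e, tm$key] + v
      else B[e, tm$key] <- B[e, tm$key] + v
    }
    conv_factors <- setNames(lapply(terms[vapply(terms, function(t)
      t$type == "conv", logical(1))], `[[`, "factors"),
      vapply(terms[vapply(terms, function(t) t$type == "conv", logical(1))],
             `[[`, character(1), "key"))
    vertices <- tibble(
      key = c(a1, unk),
      role = c(rep("source", length(src_keys)), rep("convolution", length(conv_keys)),
               rep("intermediate", n_int), rep("sink", length(unk) - n_int)))
    list(size = k, vertices = vertices, unknowns = unk,
         a1 = a1, n_intermediate = n_int,
         A21 = B[seq_len(n_int), , drop = FALSE],
         A31 = B[seq_len(length(unk) - n_int) + n_int, , drop = FALSE],
         A22 = A[seq_len(n_int), seq_len(n_int), drop = FALSE],
         A32 = A[seq_len(length(unk) - n_int) + n_int, seq_len(n_int), drop = FALSE],
         intra = A, inflow = B, diag_efflux = diag_efflux,
         conv_factors = conv_factors)
  })
  structure(list(sizes = size_systems, specs = specs, inputs = inputs,
                 fluxes = fluxes, system = system,
                 emu_len = vapply(unique(c(unknown_lhs, all_factor_keys)),
                                  emu_len, integer(1))),
            class = "cascade_system")
}

#' @export
print.cascade_system <- function(x, ...) {
  cat(sprintf("<cascade_system> %d size level(s): %s\n",
              length(x$sizes),
              paste(vapply(x$sizes, function(s)
                sprintf("size %d (%d unknowns)", s$size, length(s$unknowns)),
                character(1)), collapse = ", ")))
  invisible(x)
}

## mass vector of a source EMU (input metabolite marginal, or unlabeled delta)
source_mass_value <- function(key, cascade, warned_env) {
  pk <- parse_emu_key(key)
  spec <- cascade$specs[[pk$metabolite]]
  len <- sum(spec$shifts[pk$atoms]) + 1L
  if (pk$metabolite %in% names(cascade$inputs)) {
    sub <- marginalize_fractions(cascade$inputs[[pk$metabolite]], pk$atoms)
    return(mass_values(fv_values(sub), fv_spec(sub)))
  }
  if (!isTRUE(warned_env$warned[[pk$metabolite]])) {
    warn(paste0("no input labeling for source metabolite ", pk$metabolite,
                "; assuming unlabeled (all mass at shift 0)"))
    warned_env$warned[[pk$metabolite]] <- TRUE
  }
  c(1, numeric(len - 1L))
}

## Strongly connected components of the intra-size dependency graph (tiny
## graphs; plain Kosaraju) - used only for solver failure diagnostics.
scc_components <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(list())
  visit <- function(g) {
    seen <- rep(FALSE, n); order <- integer(0)
    for (s in seq_len(n)) {
      if (seen[s]) next
      stack <- s
      while (length(stack)) {
        u <- stack[length(stack)]
        if (!seen[u]) {
          seen[u] <- TRUE
          nb <- which(g[u, ] != 0 & !seen)
          stack <- c(stack, nb)
        } else {
          stack <- stack[-length(stack)]
          if (!u %in% order) order <- c(order, u)
        }
      }
    }
    order
  }
  order <- visit(adj != 0)
  seen <- rep(FALSE, n); comps <- list()
  for (u in rev(order)) {
    if (seen[u]) next
    comp <- integer(0); stack <- u
    while (length(stack)) {
      w <- stack[[1]]; stack <- stack[-1]
      if (seen[w]) next
      seen[w] <- TRUE; comp <- c(comp, w)
      stack <- c(stack, which(adj[, w] != 0 & !seen))
    }
    comps[[length(comps) + 1L]] <- rownames(adj)[comp]
  }
  comps
}

#' Solve the steady-state labeling cascade
#'
#' Solves the flux-balance systems size by size: at each size the consistent
#' mass matrix (total-efflux diagonal minus intra-size adjacency) is applied
#' to the unknown mass distributions, with the right-hand side assembled from
#' source EMUs and convolutions of smaller, already-solved EMUs.
#'
#' @param cascade A [build_cascade()] result.
#' @param tol Relative residual tolerance of each linear solve.
#' @return A tibble of class `labeling_solution` with columns `emu`,
#'   `metabolite`, `atoms` (list), `size`, `role` and `mass` (list of mass
#'   fraction vectors, `M+0 ... M+max`).  Source EMU values are included with
#'   `role = "source"`.
#' @export
solve_steady_state <- function(cascade, tol = 1e-10) {
  stopifnot(inherits(cascade, "cascade_system"))
  solved <- list()
  warned_env <- new.env(); warned_env$warned <- list()
  source_vals <- list()
  value_of <- function(key) {
    if (!is.null(solved[[key]])) return(solved[[key]])
    if (is.null(source_vals[[key]]))
      source_vals[[key]] <<- source_mass_value(key, cascade, warned_env)
    source_vals[[key]]
  }
  for (sz in cascade$sizes) {
    unk <- sz$unknowns
    if (!length(unk)) next
    if (any(sz$diag_efflux <= 0)) {
      bad <- names(sz$diag_efflux)[sz$diag_efflux <= 0]
      abort(sprintf("zero-throughput EMU(s) at size %d: %s (consistent mass matrix singular)",
                    sz$size, paste(bad, collapse = ", ")))
    }
    lens <- vapply(unk, function(k) cascade$emu_len[[k]], integer(1))
    L <- max(lens)
    M <- diag(sz$diag_efflux, nrow = length(unk)) - sz$intra
    dimnames(M) <- dimnames(sz$intra)
    R <- matrix(0, length(unk), L, dimnames = list(unk, NULL))
    for (e in unk) {
      for (src in colnames(sz$inflow)) {
        v <- sz$inflow[e, src]
        if (v == 0) next
        val <- if (src %in% names(sz$conv_factors)) {
          Reduce(convolve_mass, lapply(sz$conv_factors[[src]], value_of))
        } else value_of(src)
        R[e, seq_along(val)] <- R[e, seq_along(val)] + v * val
      }
    }
    x <- tryCatch(solve(M, R), error = function(e) {
      comps <- scc_components(sz$intra)
      cyc <- comps[lengths(comps) > 1]
      abort(sprintf(paste0("singular or ill-conditioned consistent mass matrix at size %d",
                           if (length(cyc)) " (strongly connected component: %s)" else "",
                           "; the subnetwork is under-determined or has zero throughput"),
                    sz$size,
                    if (length(cyc)) paste(cyc[[1]], collapse = ", ") else ""))
    })
    res <- max(abs(M %*% x - R))
    if (res > tol * max(1, max(abs(R))))
      abort(sprintf("linear solve at size %d did not meet the residual tolerance (residual %g)",
                    sz$size, res))
    for (i in seq_along(unk))
      solved[[unk[i]]] <- as.numeric(x[i, seq_len(lens[i])])
  }
  all_sources <- names(source_vals)
  keys <- c(names(solved), all_sources)
  roles <- c(rep("solved", length(solved)), rep("source", length(all_sources)))
  pk <- lapply(keys, parse_emu_key)
  out <- tibble(
    emu = keys,
    metabolite = vapply(pk, `[[`, character(1), "metabolite"),
    atoms = lapply(pk, `[[`, "atoms"),
    size = vapply(pk, function(p) length(p$atoms), integer(1)),
    role = roles,
    mass = c(unname(solved), unname(source_vals)))
  ## annotate solved EMUs with the cascade's vertex classification
  vroles <- do.call(rbind, lapply(cascade$sizes, function(s)
    as.data.frame(s$vertices[s$vertices$role %in% c("intermediate", "sink"), ])))
  idx <- match(out$emu, vroles$key)
  out$role[!is.na(idx)] <- vroles$role[idx[!is.na(idx)]]
  out <- dplyr::arrange(out, .data$size, .data$emu)
  class(out) <- c("labeling_solution", class(out))
  attr(out, "specs") <- cascade$specs
  out
}

#' One-call forward simulation
#'
#' Parses, decomposes, assembles and solves in one step.
#'
#' @inheritParams build_cascade
#' @param network A network text / file path / `reaction_network`.
#' @param targets Optional EMU keys to prune the system towards.
#' @param tol Linear-solve residual tolerance.
#' @return A `labeling_solution` tibble (see [solve_steady_state()]).
#' @examples
#' sol <- simulate_labeling(
#'   "A[ab] + B[c] -> C[a] + D[bc] @ v",
#'   fluxes = c(v = 1),
#'   inputs = list(A = c(0, 1, 0, 0), B = c(1, 0)))
#' @export
simulate_labeling <- function(network, fluxes, inputs = list(),
                              tracer = tracer_config(C = 1), elements = NULL,
                              targets = NULL, tol = 1e-10) {
  system <- decompose_network(network, targets = targets)
  cascade <- build_cascade(system, fluxes, inputs, tracer, elements)
  solve_steady_state(cascade, tol = tol)
}

#' Highest-shift / all-labeled cumomer equivalence
#'
#' The mass fraction at the greatest shift of an EMU equals the cumomer
#' fraction of the all-maximally-labeled cumomer on those atoms.
#'
#' @param solution A `labeling_solution`.
#' @return A tibble with columns `emu`, `cumomer` (the all-max state label)
#'   and `fraction`.
#' @export
highest_shift_fractions <- function(solution) {
  stopifnot(inherits(solution, "labeling_solution"))
  specs <- attr(solution, "specs")
  tibble(
    emu = solution$emu,
    cumomer = vapply(seq_len(nrow(solution)), function(i) {
      spec <- specs[[solution$metabolite[i]]]
      at <- solution$atoms[[i]]
      st <- rep(NA_integer_, spec$n)
      st[at] <- spec$shifts[at]
      state_label(st)
    }, character(1)),
    fraction = vapply(solution$mass, function(v) v[length(v)], numeric(1)))
}
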