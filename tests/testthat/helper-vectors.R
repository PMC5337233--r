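# shared helpers: random normalized fraction vectors and small specs

carbon_spec <- function(n, m = 1, id = "X") {
  moiety_spec(id, paste(rep("C", n), collapse = ""), tracer_config(C = m))
}

rand_iso_values <- function(n, m) {
  v <- stats::runif((m + 1)^n)
  v / sum(v)
}

rand_iso_fv <- function(n, m, id = "X") {
  fraction_vector(rand_iso_values(n, m), carbon_spec(n, m, id), "isotopomer")
}

# maximum per-entry disagreement between a cascade solution and the
# brute-force oracle, over all solved EMUs
cascade_vs_oracle_err <- function(fx) {
  sol <- simulate_labeling(fx$network, fx$fluxes, fx$inputs,
                           elements = fx$elements)
  or <- brute_force_isotopomer_solve(fx$network, fx$fluxes, fx$inputs,
                                     elements = fx$elements)
  solved <- sol[sol$role != "source", ]
  max(vapply(seq_len(nrow(solved)), function(i)
    max(abs(solved$mass[[i]] - oracle_emu_mass(or, solved$emu[i]))),
    numeric(1)))
}
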