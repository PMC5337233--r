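test_that("a pass-through reaction transmits the input unchanged, at any flux", {
  set.seed(21)
  a <- rand_iso_values(2, 1)
  for (v in c(0.5, 3)) {
    sol <- simulate_labeling("A[ab] -> B[ab] @ v", c(v = v), list(A = a))
    b <- sol$mass[[which(sol$emu == "B{1,2}")]]
    expect_equal(b, as.numeric(im_matrix(2, 1) %*% a), tolerance = 1e-12)
  }
})

test_that("converging fluxes mix labelings in flux proportion", {
  a <- c(0.2, 0.8); b <- c(0.9, 0.1)
  v1 <- 2; v2 <- 3
  sol <- simulate_labeling(
    c("A[a] -> C[a] @ v1", "B[b] -> C[b] @ v2"),
    c(v1 = v1, v2 = v2), list(A = a, B = b))
  cc <- sol$mass[[which(sol$emu == "C{1}")]]
  expect_equal(cc, (v1 * a + v2 * b) / (v1 + v2), tolerance = 1e-12)
})

test_that("a condensation convolves the reagent EMUs", {
  sol <- simulate_labeling(
    "A[ab] + B[c] -> C[a] + D[bc] @ v", c(v = 1),
    inputs = list(A = c(0, 1, 0, 0),   # atom 2 of A fully labeled
                  B = c(1, 0)))        # B unlabeled
  expect_equal(sol$mass[[which(sol$emu == "D{1,2}")]], c(0, 1, 0))
  expect_equal(sol$mass[[which(sol$emu == "D{1}")]], c(0, 1))
  expect_equal(sol$mass[[which(sol$emu == "D{2}")]], c(1, 0))
  expect_equal(sol$mass[[which(sol$emu == "C{1}")]], c(1, 0))
})

test_that("the cascade agrees with the brute-force isotopomer oracle,
           including cycles and condensations", {
  for (s in c(3, 7, 13, 19, 23)) {
    fx <- generate_fixture(fixture_config(seed = s))
    expect_lt(cascade_vs_oracle_err(fx), 1e-8)
  }
  # explicit cycle with a condensation feeding it
  net <- c("S[ab] -> X[ab] @ v1",
           "X[ab] -> Y[ba] @ v2",
           "Y[ab] -> X[ba] @ v3",
           "X[ab] -> P[ab] @ v4")
  fl <- c(v1 = 1, v2 = 0.5, v3 = 0.5, v4 = 1)
  set.seed(31)
  inp <- list(S = rand_iso_values(2, 1))
  sol <- simulate_labeling(net, fl, inp)
  or <- brute_force_isotopomer_solve(net, fl, inp)
  for (k in c("X{1,2}", "Y{1}", "P{1,2}"))
    expect_equal(sol$mass[[which(sol$emu == k)]], oracle_emu_mass(or, k),
                 tolerance = 1e-8)
})

test_that("solutions are valid mass distributions and scale-invariant in flux", {
  fx <- generate_fixture(fixture_config(seed = 5))
  sol <- simulate_labeling(fx$network, fx$fluxes, fx$inputs,
                           elements = fx$elements)
  sums <- vapply(sol$mass, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(unlist(sol$mass) > -1e-12))
  sol2 <- simulate_labeling(fx$network, fx$fluxes * 11, fx$inputs,
                            elements = fx$elements)
  expect_equal(sol$mass, sol2$mass, tolerance = 1e-10)
})

test_that("cascade construction reports structural problems by name", {
  # pool stationarity violation
  expect_error(
    simulate_labeling(c("A[a] -> B[a] @ v1", "B[a] -> C[a] @ v2"),
                      c(v1 = 1, v2 = 2), list(A = c(1, 0))),
    "stationarity.*B")
  # missing flux value
  expect_error(
    simulate_labeling("A[a] -> B[a] @ v", c(w = 1), list(A = c(1, 0))),
    "flux")
  # undeclared substrate defaults to unlabeled, with a warning naming it
  expect_warning(
    sol <- simulate_labeling("A[a] -> B[a] @ v", c(v = 1), list()),
    "no input labeling.*A")
  expect_equal(sol$mass[[which(sol$emu == "B{1}")]], c(1, 0))
  # zero-throughput subnetwork -> structured error
  expect_error(
    simulate_labeling("A[a] -> B[a] @ v", c(v = 0), list(A = c(1, 0))),
    "zero-throughput")
})

test_that("the per-size blocks have the cascade's triangular structure", {
  sys <- decompose_network(parse_network("A[ab] + B[c] -> C[a] + D[bc] @ v"))
  casc <- build_cascade(sys, c(v = 1), list(A = c(0, 1, 0, 0), B = c(1, 0)))
  sizes <- vapply(casc$sizes, `[[`, numeric(1), "size")
  expect_equal(sizes, c(1, 2))
  s2 <- casc$sizes[[2]]
  # the size-2 system has a convolution vertex feeding D{1,2}
  expect_true(any(s2$vertices$role == "convolution"))
  expect_match(s2$vertices$key[s2$vertices$role == "convolution"],
               "A\\{2\\}.*B\\{1\\}")
  # no intra-size edges here, and every unknown has positive total efflux
  expect_true(all(s2$intra == 0))
  expect_true(all(s2$diag_efflux > 0))
  # sources have no in-edges by construction: inflow columns only
  expect_equal(ncol(s2$A21) + 0L, length(s2$a1))
})

test_that("the brute-force oracle reproduces joint independence in a
           condensation", {
  set.seed(17)
  a <- rand_iso_values(2, 1); b <- rand_iso_values(1, 1)
  or <- brute_force_isotopomer_solve(
    "A[ab] + B[c] -> C[a] + D[bc] @ v", c(v = 1), list(A = a, B = b))
  d <- or$D$value
  # D's joint = (A atom-2 marginal) x (B marginal), reordered by the atom map
  mA <- c(sum(a[c(1, 3)]), sum(a[c(2, 4)]))
  joint <- boolean_product(mA, b, 1, 2, m = 1)
  expect_equal(d, joint, tolerance = 1e-12)
})

test_that("highest-shift mass fractions equal all-labeled punctured-cumomer
           fractions from the oracle", {
  fx <- generate_fixture(fixture_config(seed = 29))
  sol <- simulate_labeling(fx$network, fx$fluxes, fx$inputs,
                           elements = fx$elements)
  or <- brute_force_isotopomer_solve(fx$network, fx$fluxes, fx$inputs,
                                     elements = fx$elements)
  hs <- highest_shift_fractions(sol)
  for (i in seq_len(nrow(sol))) {
    met <- sol$metabolite[i]
    if (!met %in% names(or)) next
    spec <- attr(sol, "specs")[[met]]
    cum <- convert_fractions(or[[met]], "cumomer")
    expect_equal(hs$fraction[i], cum$value[match(hs$cumomer[i], cum$state)],
                 tolerance = 1e-8)
  }
})
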