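test_that("the one-atom conversion block stacks the identity over a ones row", {
  expect_equal(ic_matrix(1, 1),
               matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(ic_matrix(0, 2), matrix(1L, 1, 1))
})

test_that("isotopomer-to-cumomer matrices are Kronecker powers of the one-atom
           block", {
  for (n in 0:3) for (m in 1:3) {
    expect_equal(ic_matrix(n, m),
                 isocascade:::kron_power(ic_matrix(1, m), n))
    expect_equal(dim(ic_matrix(n, m)), c((m + 2)^n, (m + 1)^n))
  }
})

test_that("isotopomer-to-mass matrices have one 1 per column at the digit sum", {
  for (n in 0:3) for (m in 0:2) {
    IM <- im_matrix(n, m)
    expect_equal(dim(IM), c(n * m + 1L, (m + 1L)^n))
    expect_true(all(colSums(IM) == 1))
    S <- isocascade:::mixed_radix_matrix(n, 0:m)
    shifts <- if (n > 0) rowSums(S) else 0
    expect_equal(apply(IM, 2, which.max) - 1L, as.integer(shifts),
                 ignore_attr = TRUE)
  }
})

test_that("punctured (Reed-Muller) matrices are square and invertible
           for all n <= 3, m <= 3, s <= m", {
  expect_equal(punctured_matrix(1, 1, 0),
               matrix(c(0, 1, 1, 1), 2, 2, byrow = TRUE), ignore_attr = TRUE)
  # deleting the second row of the one-atom m = 2 block
  expect_equal(punctured_matrix(1, 2, 1),
               matrix(c(1, 0, 0, 0, 0, 1, 1, 1, 1), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  for (n in 0:3) for (m in 0:3) for (s in 0:m) {
    P <- punctured_matrix(n, m, s)
    expect_equal(dim(P), c((m + 1)^n, (m + 1)^n))
    expect_true(abs(det(P)) > 0.5)  # 0/1 matrix with det +-1
    expect_equal(P %*% solve(P), diag(nrow(P)), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # product of two punctured matrices remains invertible
  P1 <- punctured_matrix(2, 1, 0); P2 <- punctured_matrix(2, 1, 1)
  expect_true(abs(det(P1 %*% P2)) > 0.5)
  expect_error(punctured_matrix(1, 1, 2), "determinate state")
})

test_that("conversion reproduces the worked two-atom example and round-trips", {
  spec <- carbon_spec(2, 1, "A")
  iso <- fraction_vector(c(0.4, 0.3, 0.2, 0.1), spec, "isotopomer")
  mass <- convert_fractions(iso, "mass")
  expect_equal(mass$value, c(0.4, 0.5, 0.1))
  expect_equal(mass$state, c("M+0", "M+1", "M+2"))
  # punctured round trip is exact
  for (s in 0:1) {
    p <- convert_fractions(iso, "punctured", punctured_at = s)
    back <- convert_fractions(p, "isotopomer")
    expect_equal(back$value, iso$value, tolerance = 1e-12)
  }
  # delta isotopomer (1,1) lights up exactly the four matching cumomers
  delta <- fraction_vector(c(0, 0, 0, 1), spec, "isotopomer")
  cum <- convert_fractions(delta, "cumomer")
  on <- cum$state[cum$value == 1]
  expect_setequal(on, c("1,1", state_label(c(1L, NA)),
                        state_label(c(NA, 1L)), state_label(c(NA, NA))))
  expect_equal(sum(cum$value), 4)
  expect_error(convert_fractions(mass, "isotopomer"), "non-invertible")
})

test_that("pseudoinverse of the mass conversion is the minimum-norm preimage,
           not the inverse", {
  spec <- carbon_spec(2, 1, "A")
  mass <- fraction_vector(c(0.4, 0.5, 0.1), spec, "mass")
  pin <- pseudoinverse_demo(mass)
  expect_equal(pin$value, c(0.4, 0.25, 0.25, 0.1), tolerance = 1e-9)
  expect_true(isTRUE(attr(pin, "pseudoinverse")))
  # the original (0.4, 0.3, 0.2, 0.1) is NOT recovered
  expect_false(isTRUE(all.equal(pin$value, c(0.4, 0.3, 0.2, 0.1))))
  # a symmetric isotopomer vector lies in the recoverable class
  sym <- fraction_vector(c(0.4, 0.25, 0.25, 0.1), spec, "isotopomer")
  mass_sym <- convert_fractions(sym, "mass")
  expect_equal(pseudoinverse_demo(mass_sym)$value, sym$value, tolerance = 1e-9)
  # one-atom mass matrices are identities, so the pinv is an exact inverse
  s1 <- carbon_spec(1, 2, "B")
  iso1 <- fraction_vector(c(0.5, 0.3, 0.2), s1, "isotopomer")
  expect_equal(pseudoinverse_demo(convert_fractions(iso1, "mass"))$value,
               iso1$value, tolerance = 1e-9)
})

test_that("highest mass fraction equals the all-max cumomer fraction", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(1:4, 1); m <- sample(1:2, 1)
    spec <- carbon_spec(n, m)
    iso <- fraction_vector(rand_iso_values(n, m), spec, "isotopomer")
    mass <- convert_fractions(iso, "mass")
    cum <- convert_fractions(iso, "cumomer")
    allmax <- state_label(rep(m, n))
    expect_equal(mass$value[n * m + 1], cum$value[match(allmax, cum$state)],
                 tolerance = 1e-12)
  }
})

test_that("surplus labeling states are rejected when they carry probability", {
  tr <- tracer_config(C = 1, N = 2)
  spec <- moiety_spec("CN", "CN", tr)   # atom 1 can shift at most 1, m = 2
  v <- numeric(9)
  v[isocascade:::state_index(c(2L, 0L), 3L) + 1] <- 1  # carbon at shift 2
  expect_error(fraction_vector(v, spec, "isotopomer"), "surplus")
  ok <- numeric(9)
  ok[isocascade:::state_index(c(1L, 2L), 3L) + 1] <- 1
  expect_silent(fraction_vector(ok, spec, "isotopomer"))
})

test_that("marginalization sums out the discarded atoms", {
  set.seed(5)
  spec <- carbon_spec(3, 1, "A")
  v <- rand_iso_values(3, 1)
  fv <- fraction_vector(v, spec, "isotopomer")
  sub <- marginalize_fractions(fv, c(1, 3))
  S <- isocascade:::isotopomer_states(spec)
  for (a in 0:1) for (b in 0:1) {
    expect_equal(
      sub$value[isocascade:::state_index(c(a, b), 2L) + 1],
      sum(v[S[, 1] == a & S[, 3] == b]))
  }
  expect_equal(sum(sub$value), 1, tolerance = 1e-12)
})

test_that("conversion matrices survive a Matrix Market round trip", {
  path <- withr::local_tempfile(fileext = ".mtx")
  M <- im_matrix(2, 1)
  write_matrix_mtx(M, path)
  expect_equal(read_matrix_mtx(path), M, ignore_attr = TRUE)
})
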