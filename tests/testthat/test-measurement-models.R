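cn_spec <- moiety_spec("CN", "CN", tracer_config(C = 1, N = 1))

test_that("the high-resolution tensor resolves per-element shifts", {
  v <- c(0.4, 0.3, 0.2, 0.1)  # (C,N) states (0,0),(0,1),(1,0),(1,1)
  t <- high_res_tensor(fraction_vector(v, cn_spec))
  expect_equal(dim(t), c(2, 2))
  expect_equal(attr(t, "elements"), c("C", "N"))
  expect_equal(t[1, 1], 0.4)  # P(C=0, N=0)
  expect_equal(t[1, 2], 0.3)  # P(C=0, N=1)
  expect_equal(t[2, 1], 0.2)  # P(C=1, N=0)
  expect_equal(t[2, 2], 0.1)
  expect_equal(sum(t), 1)
  # delta isotopomer -> delta tensor
  td <- high_res_tensor(fraction_vector(c(0, 0, 0, 1), cn_spec))
  expect_equal(as.numeric(td), c(0, 0, 0, 1))
})

test_that("a homonuclear tensor is one-axis and equals the mass conversion", {
  set.seed(8)
  v <- rand_iso_values(3, 1)
  t <- high_res_tensor(fraction_vector(v, carbon_spec(3, 1)))
  expect_equal(length(dim(t)), 1L)
  expect_equal(as.numeric(t), as.numeric(im_matrix(3, 1) %*% v),
               tolerance = 1e-12)
})

test_that("collapsing the tensor sums anti-diagonals to the low-res MID", {
  expect_equal(collapse_tensor(matrix(c(0.4, 0.2, 0.3, 0.1), 2)),
               c(0.4, 0.5, 0.1))
  expect_equal(collapse_tensor(matrix(1)), 1)
})

test_that("collapse after the tensor equals the direct mass conversion
           (commutation, random vectors, heteronuclear included)", {
  set.seed(12)
  tr <- tracer_config(C = 1, N = 1, H = 2)
  for (el in c("CC", "CN", "CNH", "CCNN")) {
    spec <- moiety_spec(el, el, tr)
    # random vector respecting the surplus rule
    S <- isocascade:::isotopomer_states(spec)
    ok <- rep(TRUE, nrow(S))
    for (j in seq_len(spec$n)) ok <- ok & S[, j] <= spec$shifts[j]
    v <- numeric(nrow(S)); v[ok] <- runif(sum(ok)); v <- v / sum(v)
    fv <- fraction_vector(v, spec)
    low <- collapse_tensor(high_res_tensor(fv))
    direct <- isocascade:::mass_values(v, spec)
    expect_equal(low, direct, tolerance = 1e-12)
    expect_equal(sum(low), 1, tolerance = 1e-9)
  }
})

test_that("NMR splitting integrals are conditional probabilities", {
  leu <- moiety_spec("Leu", "CCCCCC", tracer_config(C = 1))
  # fully labeled metabolite: every conditional is 1
  delta <- numeric(64); delta[64] <- 1
  expect_equal(nmr_splitting_integral(
    fraction_vector(delta, leu), observed = 2, detected = c(5, 6),
    groups = list(c(5, 6))), 1)
  # independent atoms: P(at least one delta labeled | alpha) = 1 - (1-q)^2
  p_alpha <- 0.37; q <- 0.22
  probs <- c(0.5, 0.6, p_alpha, 0.8, q, q)  # P(atom i = 1)
  S <- isocascade:::isotopomer_states(leu)
  v <- apply(S, 1, function(st) prod(ifelse(st == 1, probs, 1 - probs)))
  fv <- fraction_vector(v, leu)
  got <- nmr_splitting_integral(fv, observed = 3, detected = c(5, 6),
                                groups = list(c(5, 6)))
  expect_equal(got, 1 - (1 - q)^2, tolerance = 1e-12)
  # invariance under permutation within the equivalence group
  expect_equal(
    nmr_splitting_integral(fv, 3, 1, c(5, 6), list(c(6, 5))), got)
  # zero denominator
  none <- numeric(64); none[1] <- 1
  expect_error(nmr_splitting_integral(fraction_vector(none, leu), 2,
                                      detected = 5), "undefined conditional")
  expect_error(nmr_splitting_integral(fv, 5, detected = c(5, 6)),
               "observed atom cannot")
})

test_that("the leucine integral equals the cumomer-fraction quotient", {
  set.seed(14)
  leu <- moiety_spec("Leu", "CCCCCC", tracer_config(C = 1))
  v <- rand_iso_values(6, 1)
  fv <- fraction_vector(v, leu)
  got <- nmr_splitting_integral(fv, observed = 2, detected = c(5, 6),
                                groups = list(c(5, 6)))
  # the quotient of cumomer fractions: patterns (T,1,T,T,0,1), (T,1,T,T,1,0),
  # (T,1,T,T,1,1) over (T,1,T,T,T,T)
  cum <- convert_fractions(fv, "cumomer")
  cf <- function(st) cum$value[match(state_label(st), cum$state)]
  num <- cf(c(NA, 1L, NA, NA, 0L, 1L)) + cf(c(NA, 1L, NA, NA, 1L, 0L)) +
    cf(c(NA, 1L, NA, NA, 1L, 1L))
  den <- cf(c(NA, 1L, NA, NA, NA, NA))
  expect_equal(got, num / den, tolerance = 1e-12)
})

test_that("derivatization deconvolution inverts the convolution", {
  underiv <- c(0.7, 0.2, 0.1)
  agent <- c(0.9, 0.08, 0.02)
  measured <- convolve_mass(underiv, agent)
  expect_equal(deconvolve_derivatization(measured, agent), underiv,
               tolerance = 1e-9)
  # noisy measurement with a negative least-squares solution warns and clips
  noisy <- c(1, 0, 0)  # inconsistent with any convolution by the agent
  expect_warning(out <- deconvolve_derivatization(noisy, c(0.5, 0.5)),
                 "negative")
  expect_true(all(out >= 0))
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_error(deconvolve_derivatization(c(1), c(0.5, 0.5)), "shorter")
})
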