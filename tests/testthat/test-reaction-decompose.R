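ref_line <- "A[ab] + B[c] -> C[a] + D[bc] @ v"

test_that("the network grammar parses, validates and reports line numbers", {
  net <- parse_network(ref_line)
  expect_s3_class(net, "reaction_network")
  expect_equal(nrow(net), 1L)
  expect_length(net$reagents[[1]], 2)
  expect_length(net$products[[1]], 2)
  expect_equal(attr(net, "metabolite_atoms")[["D"]], 2L)
  # atom reordering is a valid bijection
  expect_silent(parse_network("A[ab] -> C[ba] @ v"))
  # unmatched label
  expect_error(parse_network("A[ab] -> C[a] @ v"), "line 1.*not conserved")
  # duplicate label on one side
  expect_error(parse_network("A[aa] -> C[aa] @ v"), "duplicate")
  # inconsistent arity across the network
  expect_error(parse_network(c("A[a] -> B[a] @ v1", "B[cd] -> A[dc] @ v2")),
               "inconsistent atom count")
  # comments, blank lines, reversed and reversible arrows
  net2 <- parse_network(c("# a comment", "",
                          "C[a] <- A[a] @ v1",
                          "A[b] <-> D[b] @ v2"))
  expect_equal(net2$flux_id, c("v1", "v2.fwd", "v2.rev"))
  expect_equal(net2$reagents[[1]][[1]]$metabolite, "A")
  # multi-character comma labels and cofactors
  net3 <- parse_network("Big[a1,a2] + ATP[] -> Out[a2,a1] + ADP[] @ v")
  expect_equal(net3$reagents[[1]][[1]]$labels, c("a1", "a2"))
  expect_equal(attr(net3, "metabolite_atoms")[["ATP"]], 0L)
  # round trip through the formatter
  expect_equal(format_network(parse_network(format_network(net))),
               format_network(net))
})

test_that("one reaction decomposes into the printed four-identity system", {
  ids <- decompose_reaction(parse_network(ref_line)[1, ])
  expect_equal(nrow(ids), 4L)   # (2^1 - 1) + (2^2 - 1)
  eqs <- sort(format_identities(structure(ids,
    class = c("identity_system", class(ids)))))
  expect_equal(eqs, sort(c(
    "C{1} = v * A{1}",
    "D{1} = v * A{2}",
    "D{2} = v * B{1}",
    "D{1,2} = v * (A{2} (*) B{1})")))
  # the convolution identity has two factors with disjoint origins
  conv <- ids[ids$lhs == "D{1,2}", ]
  expect_equal(sort(conv$factors[[1]]$key), c("A{2}", "B{1}"))
})

test_that("identity count equals the power-set count, against a brute-force
           enumeration oracle (random reactions, <= 6 atoms per side)", {
  set.seed(9)
  for (rep in 1:25) {
    n_atoms <- sample(2:6, 1)
    labs <- letters[seq_len(n_atoms)]
    # random partition of atoms into 1-2 reagents and 1-2 products
    cut_r <- if (n_atoms > 1) sample(n_atoms - 1, 1) else 1
    cut_p <- if (n_atoms > 1) sample(n_atoms - 1, 1) else 1
    sh <- sample(labs)
    rg <- if (runif(1) < 0.5) list(R1 = labs) else
      list(R1 = labs[seq_len(cut_r)], R2 = labs[-seq_len(cut_r)])
    pr <- if (runif(1) < 0.5) list(P1 = sh) else
      list(P1 = sh[seq_len(cut_p)], P2 = sh[-seq_len(cut_p)])
    line <- paste0(
      paste(vapply(names(rg), function(k)
        paste0(k, "[", paste(rg[[k]], collapse = ""), "]"), character(1)),
        collapse = " + "),
      " -> ",
      paste(vapply(names(pr), function(k)
        paste0(k, "[", paste(pr[[k]], collapse = ""), "]"), character(1)),
        collapse = " + "),
      " @ v")
    ids <- decompose_reaction(parse_network(line)[1, ])
    expected_n <- sum(vapply(pr, function(x) 2^length(x) - 1, numeric(1)))
    expect_equal(nrow(ids), expected_n)
    # no empty lhs or empty factor; factor sizes sum to the lhs size
    expect_true(all(ids$size >= 1))
    for (i in seq_len(nrow(ids))) {
      f <- ids$factors[[i]]
      expect_true(all(lengths(f$atoms) >= 1))
      expect_equal(sum(lengths(f$atoms)), ids$size[i])
    }
    # brute-force oracle: every non-empty subset of every product, grouped by
    # origin reagent, must appear exactly once
    for (k in names(pr)) {
      np <- length(pr[[k]])
      for (bits in seq_len(2^np - 1)) {
        S <- which(bitwAnd(bits, 2^(0:(np - 1))) > 0)
        want_lhs <- emu_key(k, S)
        hit <- ids[ids$lhs == want_lhs, ]
        expect_equal(nrow(hit), 1L)
        origin_labels <- pr[[k]][S]
        want_factors <- sort(vapply(names(rg), function(rk) {
          pos <- which(rg[[rk]] %in% origin_labels)
          if (!length(pos)) return(NA_character_)
          emu_key(rk, pos)
        }, character(1)))
        want_factors <- want_factors[!is.na(want_factors)]
        expect_equal(sort(hit$factors[[1]]$key), unname(want_factors))
      }
    }
  }
})

test_that("decomposition is invariant under reagent/product listing order", {
  a <- decompose_network(parse_network("A[ab] + B[c] -> C[a] + D[bc] @ v"))
  b <- decompose_network(parse_network("B[c] + A[ab] -> D[bc] + C[a] @ v"))
  expect_equal(format_identities(a), format_identities(b))
})

test_that("target pruning keeps the backward-reachable closure", {
  sys <- decompose_network(parse_network(ref_line), targets = "D{1,2}")
  expect_setequal(attr(sys, "closure"), c("D{1,2}", "A{2}", "B{1}"))
  expect_equal(nrow(sys), 1L)  # only the defining identity survives
  expect_setequal(attr(sys, "sources"), c("A{2}", "B{1}"))
  # square-bracket spelling of the target is accepted
  sys_b <- decompose_network(parse_network(ref_line), targets = "D[1,2]")
  expect_equal(attr(sys_b, "closure"), attr(sys, "closure"))
  # two-reaction chain: transitive closure
  chain <- parse_network(c("A[a] -> B[a] @ v1", "B[a] -> C[a] @ v2"))
  sys2 <- decompose_network(chain, targets = "C{1}")
  expect_setequal(attr(sys2, "closure"), c("C{1}", "B{1}", "A{1}"))
  expect_equal(nrow(sys2), 2L)
  # no targets: everything retained
  sys3 <- decompose_network(parse_network(ref_line))
  expect_equal(nrow(sys3), 4L)
  # unresolvable target
  expect_error(decompose_network(parse_network(ref_line), targets = "A{1}"),
               "unresolvable.*A\\{1\\}")
})
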