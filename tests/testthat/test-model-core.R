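test_that("conservation totals apply the stoichiometric weights", {
  expect_equal(conservation_totals(state_vector(E = 1)),
               c(enzyme = 1, adenine = 0, guanine = 0))
  expect_equal(conservation_totals(
    state_vector(EAA = 1, cdiA = 2, A = 3))[["adenine"]], 9)
  ct <- conservation_totals(state_vector(cAG = 5))
  expect_equal(ct[["adenine"]], 5)
  expect_equal(ct[["guanine"]], 5)
})

test_that("state construction enforces names and non-negativity", {
  expect_error(state_vector(Q = 1), "species")
  expect_error(state_vector(E = -1), "negative")
  expect_equal(sum(state_vector()), 0)
})

test_that("derivative matches direct mass-action substitution", {
  r <- rate_constants(coop(), kon = 1)
  d <- cyclase_derivative(state_vector(E = 1, G = 100), r)
  expect_equal(d[["EnG"]], 100)
  expect_equal(d[["EGn"]], 100)
  expect_equal(d[["G"]], -200)
  expect_equal(d[["E"]], -200)
  expect_true(all(d[c("EnA", "EAn", "EGG", "EGA", "EAG", "EAA",
                      "cdiA", "cdiG", "cAG", "A")] == 0))
})

test_that("empty state has zero derivative and negatives are rejected", {
  r <- rate_constants(coop())
  expect_equal(unname(cyclase_derivative(state_vector(), r)), rep(0, 14))
  s <- state_vector(E = 1)
  s["A"] <- -1
  expect_error(cyclase_derivative(s, r), "negative")
})

test_that("homeostasis clamps the substrate derivative components", {
  r <- rate_constants(coop())
  set.seed(11)
  for (i in 1:5) {
    d <- cyclase_derivative(random_state(), r, homeostasis = TRUE)
    expect_identical(unname(d[c("A", "G")]), c(0, 0))
  }
})

test_that("enzyme and base totals are conserved by the rate equations", {
  r <- rate_constants(coop())
  set.seed(42)
  for (i in 1:20) {
    s <- random_state()
    d <- cyclase_derivative(s, r)
    scale <- max(abs(d))
    # enzyme is neither created nor destroyed
    expect_lt(abs(sum(d[1:9])), 1e-12 * max(scale, 1))
    # d/dt of the adenine and guanine totals vanish in depletion mode
    dA_tot <- d[["A"]] + d[["EnA"]] + d[["EAn"]] + d[["EAG"]] +
      d[["EGA"]] + 2 * d[["EAA"]] + 2 * d[["cdiA"]] + d[["cAG"]]
    dG_tot <- d[["G"]] + d[["EnG"]] + d[["EGn"]] + d[["EAG"]] +
      d[["EGA"]] + 2 * d[["EGG"]] + 2 * d[["cdiG"]] + d[["cAG"]]
    expect_lt(abs(dA_tot), 1e-9 * max(scale, 1))
    expect_lt(abs(dG_tot), 1e-9 * max(scale, 1))
  }
})

test_that("derivative is linear in the enzyme block at fixed substrates", {
  r <- rate_constants(coop())
  set.seed(7)
  s <- random_state()
  s2 <- s
  s2[1:9] <- 2 * s[1:9]
  d1 <- cyclase_derivative(s, r)
  d2 <- cyclase_derivative(s2, r)
  expect_equal(unname(d2[1:9]), unname(2 * d1[1:9]), tolerance = 1e-12)
})

test_that("compiled and plain-R derivatives agree", {
  r <- rate_constants(coop(), kon = 3)
  set.seed(99)
  for (i in 1:10) {
    s <- random_state()
    expect_equal(cyclase_derivative(s, r),
                 gacakin:::cyclase_derivative_r(s, r), tolerance = 1e-14)
    expect_equal(cyclase_derivative(s, r, homeostasis = TRUE),
                 gacakin:::cyclase_derivative_r(s, r, homeostasis = TRUE),
                 tolerance = 1e-14)
  }
})
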