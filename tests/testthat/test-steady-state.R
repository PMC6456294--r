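# Independent oracle: rapid-equilibrium binding-polynomial flux weights.
# EGG ~ G^2/(K1G*K2G), (EAG+EGA) ~ A*G*(1/(K1G*KAG) + 1/(K1A*KGA)),
# EAA ~ A^2/(K1A*K2A); flux = kcat * weight, fractions normalized.  Exact
# only under detailed balance, so comparisons use a loose tolerance.
rapid_equilibrium_fractions <- function(p, A, G) {
  w <- c(G^2 / (p[["K1G"]] * p[["K2G"]]),
         A * G * (1 / (p[["K1G"]] * p[["KAG"]]) +
                    1 / (p[["K1A"]] * p[["KGA"]])),
         A^2 / (p[["K1A"]] * p[["K2A"]]))
  f <- c(p[["kcat_cdiG"]], p[["kcat_cGAMP"]], p[["kcat_cdiA"]]) * w
  f / sum(f)
}

test_that("symmetric parameters give 1:2:1 flux fractions at A = G", {
  ss <- steady_state_ratios(symmetric_params(), A = 100, G = 100)
  expect_equal(unname(unclass(ss$fractions)), c(0.25, 0.5, 0.25),
               tolerance = 1e-12)
})

test_that("long-horizon clamped integration converges to the exact solve", {
  p <- coop()
  ss <- steady_state_ratios(p, A = 100, G = 100)
  traj <- simulate_timecourse(
    p, reaction_conditions(A0 = 100, G0 = 100, duration = 3600,
                           homeostasis = TRUE), step = 3600)
  fr_int <- gacakin:::endpoint_flux_fractions(traj, p)
  expect_fractions_equal(ss$fractions, fr_int, 1e-3)
})

test_that("asymmetric activation at 4:1 ATP excess matches the binding-polynomial oracle", {
  p <- coop()
  p["kcat_cGAMP"] <- 0.27
  ss <- steady_state_ratios(p, A = 400, G = 100)
  oracle <- rapid_equilibrium_fractions(p, 400, 100)
  # oracle evaluates to ~0.916 cGAMP; small deviation expected because the
  # fitted constants break detailed balance (cycle flux)
  expect_equal(oracle[2], 0.9157, tolerance = 1e-3)
  expect_fractions_equal(ss$fractions, oracle, 0.01)
})

test_that("flux fractions depend mostly on the substrate ratio", {
  p <- coop()
  ps <- unclass(p)
  ps[c("kcat_cdiA", "kcat_cdiG", "kcat_cGAMP")] <-
    ps[c("kcat_cdiA", "kcat_cdiG", "kcat_cGAMP")] * 0.01
  ps <- structure(ps, class = "kinetic_params")
  base <- steady_state_ratios(ps, A = 300, G = 100)$fractions
  for (lam in c(0.5, 2, 10)) {
    sc <- steady_state_ratios(ps, A = 300 * lam, G = 100 * lam)$fractions
    # not exact: the detailed-balance-violating constants leave a
    # concentration-dependent cycle flux
    expect_fractions_equal(base, sc, 0.01)
  }
})

test_that("flux fractions are invariant to total enzyme", {
  p <- coop()
  f1 <- steady_state_ratios(p, 300, 100, E0 = 0.1)$fractions
  f2 <- steady_state_ratios(p, 300, 100, E0 = 10)$fractions
  expect_fractions_equal(f1, f2, 1e-12)
})

test_that("cGAMP is the dominant product across the physiological range", {
  p <- coop()
  for (r in c(2, 3, 4, 5, 8, 10)) {
    fr <- steady_state_ratios(p, A = 100 * r, G = 100)$fractions
    expect_gt(fr[["fraction_cGAMP"]],
              max(fr[["fraction_cdiG"]], fr[["fraction_cdiA"]]))
  }
  # strict majority where ATP excess is moderate
  for (r in c(3, 4, 5, 8))
    expect_gt(steady_state_ratios(p, 100 * r, 100)
              $fractions[["fraction_cGAMP"]], 0.5)
})

test_that("degenerate substrate input is rejected", {
  expect_error(steady_state_ratios(coop(), 0, 0), "substrate")
  expect_error(steady_state_ratios(coop(), -1, 100), ">= 0")
})
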