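test_that("A<->G exchange symmetry gives 1:2:1 product ratios", {
  traj <- simulate_timecourse(symmetric_params(),
                              reaction_conditions(A0 = 100, G0 = 100),
                              step = 3600)
  fr <- product_ratios(traj)
  expect_fractions_equal(fr, c(0.25, 0.50, 0.25), 1e-6)
})

test_that("without catalysis no product forms and binding equilibrates", {
  r <- rate_constants(coop())
  r[c("kcat_cdiA", "kcat_cdiG", "kcat_cGAMP")] <- 0
  traj <- simulate_timecourse(r, reaction_conditions(A0 = 100, G0 = 100,
                                                     duration = 100))
  fin <- gacakin:::final_state(traj)
  expect_equal(unname(fin[c("cdiA", "cdiG", "cAG")]), c(0, 0, 0))
  # occupancies have relaxed: derivative is negligible at the end
  d <- cyclase_derivative(fin, r)
  expect_lt(max(abs(d)), 1e-6)
  expect_error(product_ratios(traj), "no product")
})

test_that("trajectories respect conservation and positivity", {
  traj <- simulate_timecourse(coop(),
                              reaction_conditions(A0 = 150, G0 = 50),
                              step = 60)
  expect_true(all(traj$states >= 0))
  tot <- t(apply(traj$states, 1, conservation_totals))
  for (j in 1:3)
    expect_lt(max(abs(tot[, j] - tot[1, j])) / tot[1, j], 1e-6)
  expect_equal(traj$states[1, ],
               state_vector(E = 1, A = 150, G = 50))
})

test_that("homeostasis mode holds substrates exactly constant", {
  traj <- simulate_timecourse(
    coop(), reaction_conditions(A0 = 300, G0 = 100, duration = 600,
                                homeostasis = TRUE), step = 60)
  expect_true(all(traj$states[, "A"] == 300))
  expect_true(all(traj$states[, "G"] == 100))
})

test_that("sub-stepped explicit mode matches the stiff solver", {
  cond <- reaction_conditions(A0 = 100, G0 = 100)
  fr_euler <- product_ratios(
    simulate_timecourse(coop(), cond, mode = "euler", step = 1))
  fr_stiff <- product_ratios(
    simulate_timecourse(coop(), cond, mode = "stiff", step = 1))
  expect_fractions_equal(fr_euler, fr_stiff, 1e-4)
})

test_that("explicit mode refuses rather than clipping when over budget", {
  expect_error(
    simulate_timecourse(coop(), reaction_conditions(A0 = 100, G0 = 100),
                        mode = "euler", step = 3600, max_substeps = 1000),
    "sub-steps")
})

test_that("simulation is deterministic", {
  cond <- reaction_conditions(A0 = 120, G0 = 80, duration = 300)
  t1 <- simulate_timecourse(coop(), cond, step = 30)
  t2 <- simulate_timecourse(coop(), cond, step = 30)
  expect_identical(t1$states, t2$states)
})

test_that("reporting grid always includes the requested endpoint", {
  traj <- simulate_timecourse(coop(),
                              reaction_conditions(A0 = 100, G0 = 100,
                                                  duration = 100.5),
                              step = 40)
  expect_equal(max(traj$time), 100.5)
})

test_that("endpoint ratios are insensitive to the binding on-rate", {
  ef <- gacakin:::endpoint_fractions
  f1 <- ef(coop(), 100, 100, kon = 1)
  f10 <- ef(coop(), 100, 100, kon = 10)
  expect_fractions_equal(f1, f10, 1e-3)
})

test_that("product ratio normalization and error cases", {
  expect_equal(unname(unclass(product_ratios(c(1, 2, 1)))),
               c(0.25, 0.5, 0.25))
  expect_equal(unname(unclass(product_ratios(c(3, 0, 1)))),
               c(0.75, 0, 0.25))
  expect_error(product_ratios(c(0, 0, 0)), "no product")
  expect_error(product_ratios(c(-1, 1, 1)), "non-negative")
})

test_that("invalid conditions are rejected", {
  expect_error(reaction_conditions(E0 = 0), "E0")
  expect_error(reaction_conditions(A0 = 0, G0 = 0), "substrate")
  expect_error(reaction_conditions(duration = -1), "duration")
  expect_error(simulate_timecourse(coop(), reaction_conditions(),
                                   step = 0), "step")
})
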