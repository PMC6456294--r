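test_that("homeostasis scan rows are ratio-ordered steady states", {
  sc <- homeostasis_scan(symmetric_params(), ratios = c(3, 1),
                         G_ref = 100)
  expect_equal(sc$ratio, c(1, 3))
  expect_equal(sc[sc$ratio == 1, "fraction_cGAMP"], 0.5,
               tolerance = 1e-12)
  expect_true(sc$physiological_ref[sc$ratio == 3])
  expect_false(sc$physiological_ref[sc$ratio == 1])
})

test_that("cdiA rises monotonically with ATP excess", {
  sc <- homeostasis_scan(coop(), ratios = seq(1, 10, by = 1))
  expect_true(all(diff(sc$fraction_cdiA) >= 0))
})

test_that("scan fractions shift little with the reference concentration", {
  ps <- unclass(coop())
  ps[7:9] <- ps[7:9] * 0.01
  ps <- structure(ps, class = "kinetic_params")
  a <- homeostasis_scan(ps, ratios = c(1, 3, 10), G_ref = 100)
  b <- homeostasis_scan(ps, ratios = c(1, 3, 10), G_ref = 1000)
  # approximate only: cycle flux from the non-detailed-balance constants
  expect_lt(max(abs(a$fraction_cGAMP - b$fraction_cGAMP)), 0.01)
})

test_that("integration-based scan agrees with the exact solver", {
  a <- homeostasis_scan(coop(), ratios = c(1, 4), method = "steady")
  b <- homeostasis_scan(coop(), ratios = c(1, 4), method = "integrate")
  expect_fractions_equal(a$fraction_cGAMP, b$fraction_cGAMP, 1e-3)
})

test_that("fold = 1 reproduces the homeostasis scan bit for bit", {
  sc0 <- homeostasis_scan(coop(), ratios = c(1, 3, 9))
  sc1 <- asymmetric_scan(coop(), folds = 1, ratios = c(1, 3, 9))
  strip <- function(d, cols) {
    d <- as.data.frame(d)[, cols]
    rownames(d) <- NULL
    attr(d, "settings") <- NULL
    d
  }
  expect_identical(strip(sc0, names(as.data.frame(sc0))),
                   strip(sc1, names(as.data.frame(sc0))))
})

test_that("nine-fold heterodimeric activation is nearly fully selective", {
  sc <- asymmetric_scan(coop(), folds = 9, ratios = c(1, 2, 4, 6, 10))
  expect_gte(sc[sc$ratio == 4, "fraction_cGAMP"], 0.90)
  # maximum over the physiological range is interior, not at the edges
  best <- which.max(sc$fraction_cGAMP)
  expect_gt(sc$fraction_cGAMP[best], 0.90)
  expect_true(sc$ratio[best] > 1 && sc$ratio[best] < 10)
})

test_that("cGAMP selectivity grows with the activation fold", {
  sc <- asymmetric_scan(coop(), folds = c(1, 3, 9), ratios = 4)
  expect_true(all(diff(sc$fraction_cGAMP) > 0))
})

test_that("activation-energy conversion follows R*T*ln(fold)", {
  expect_equal(round(delta_delta_G(9, 301.15), 1), 1.3)
  expect_equal(delta_delta_G(1, 310), 0)
  # ln(e) = 1: ddG equals RT
  Te <- 0.600 / 1.987e-3
  expect_equal(delta_delta_G(exp(1), Te), 0.600, tolerance = 1e-12)
  # log additivity
  expect_equal(delta_delta_G(6, 300),
               delta_delta_G(2, 300) + delta_delta_G(3, 300),
               tolerance = 1e-12)
  expect_error(delta_delta_G(0), "fold")
  expect_error(delta_delta_G(2, -1), "temperature")
})

test_that("scan input validation", {
  expect_error(homeostasis_scan(coop(), ratios = c(-1, 2)), "positive")
  expect_error(homeostasis_scan(coop(), G_ref = 0), "G_ref")
  expect_error(asymmetric_scan(coop(), folds = 0.5), "folds")
})
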