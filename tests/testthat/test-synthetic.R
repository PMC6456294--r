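test_that("zero-noise product-ratio data equals the simulator output", {
  p <- coop()
  d <- sim_product_ratio_data(p, noise_sd = 0, replicates = 2,
                              atp_fraction = c(0.25, 0.75))
  for (i in seq_len(nrow(d))) {
    mod <- gacakin:::endpoint_fractions(p, d$A0[i], d$G0[i])
    expect_equal(c(d$fraction_cdiG[i], d$fraction_cGAMP[i],
                   d$fraction_cdiA[i]),
                 unname(unclass(mod)), tolerance = 1e-12)
  }
  expect_equal(attr(d, "truth")$seed, 1)
})

test_that("generators are seed-deterministic", {
  a <- sim_product_ratio_data(coop(), noise_sd = 2, seed = 5,
                              atp_fraction = c(0.25, 0.75))
  b <- sim_product_ratio_data(coop(), noise_sd = 2, seed = 5,
                              atp_fraction = c(0.25, 0.75))
  c <- sim_product_ratio_data(coop(), noise_sd = 2, seed = 6,
                              atp_fraction = c(0.25, 0.75))
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))

  s1 <- sim_alignment(n = 30, seed = 7)
  s2 <- sim_alignment(n = 30, seed = 7)
  expect_identical(s1$alignment, s2$alignment)

  r1 <- sim_initial_rate_data(39, 20, 0.03, noise_sd = 0.002, seed = 9)
  r2 <- sim_initial_rate_data(39, 20, 0.03, noise_sd = 0.002, seed = 9)
  expect_identical(r1$rate, r2$rate)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123)
  x1 <- stats::runif(1)
  set.seed(123)
  invisible(sim_alignment(n = 10, seed = 99))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("noisy fractions stay normalized and within [0, 1]", {
  d <- sim_product_ratio_data(coop(), noise_sd = 10, replicates = 5,
                              seed = 2, atp_fraction = c(0.1, 0.9))
  fr <- as.matrix(as.data.frame(d)[, 3:5])
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)), tolerance = 1e-12)
})

test_that("family counts follow largest-remainder allocation exactly", {
  syn <- sim_alignment(n = 100,
                       fractions = c(canonical = 0.6, hypr = 0.3,
                                     unclassifiable = 0.1), seed = 7)
  tab <- table(syn$truth$family)
  expect_equal(unname(tab[c("canonical", "hypr", "unclassifiable")]),
               structure(c(60L, 30L, 10L), class = "table"),
               ignore_attr = TRUE)
  # remainders: n = 7 at (0.6, 0.3, 0.1) -> floor (4, 2, 0) + 1 to 0.2
  syn7 <- sim_alignment(n = 7, seed = 1)
  expect_equal(sum(table(syn7$truth$family)), 7)
  expect_error(sim_alignment(fractions = c(canonical = 0.5, hypr = 0.3,
                                           unclassifiable = 0.1)),
               "sum to 1")
})

test_that("hypr-like synthetic sequences never carry a central Glu", {
  syn <- sim_alignment(n = 200, seed = 13)
  hypr_ids <- syn$truth$id[syn$truth$family == "hypr"]
  centre <- substr(syn$alignment[hypr_ids],
                   syn$positions$motif_start + 2,
                   syn$positions$motif_start + 2)
  expect_true(all(centre == "D"))
})

test_that("initial-rate generator saturates and floors negative draws", {
  d <- sim_initial_rate_data(343, 53, 0.03, noise_sd = 0)
  expect_gt(max(d$rate), 0.9 * 0.03)  # top of grid within 10% of kcat*E0
  dn <- sim_initial_rate_data(343, 53, 0.03, noise_sd = 0.05, seed = 4)
  expect_true(all(dn$rate >= 0))
  expect_true(any(dn$floored))
})
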