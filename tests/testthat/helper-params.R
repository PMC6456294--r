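# Shared fixtures built in code.

coop <- function() gaca_params("cooperative")
noncoop <- function() gaca_params("noncooperative")

# Fully A<->G symmetric parameter set: exchange symmetry forces product
# fractions 1/4 : 1/2 : 1/4 whenever A = G.
symmetric_params <- function(kcat = 0.03) {
  kinetic_params(K1A = 50, K2A = 30, K1G = 50, K2G = 30, KAG = 30,
                 KGA = 30, kcat_cdiA = kcat, kcat_cdiG = kcat,
                 kcat_cGAMP = kcat)
}

# Random non-negative model state (enzyme species modest, substrates large)
random_state <- function() {
  s <- state_vector()
  s[1:9] <- stats::runif(9, 0, 1)
  s[10:12] <- stats::runif(3, 0, 5)
  s[13:14] <- stats::runif(2, 0, 200)
  s
}

expect_fractions_equal <- function(a, b, tol) {
  expect_lt(max(abs(as.numeric(a) - as.numeric(b))), tol)
}
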