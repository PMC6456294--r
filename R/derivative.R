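#' Mass-action derivative of the 14-species cyclase network
#'
#' Evaluates the instantaneous rate of change (micromolar per second) of all
#' 14 model species under mass-action kinetics.  Binding steps are
#' bimolecular (enzyme species times free NTP), dissociation and catalysis
#' are unimolecular.  Catalysis converts a doubly-bound enzyme into free
#' enzyme plus the corresponding cyclic dinucleotide in one step: the model
#' assumes formation of the linear intermediate is rate-determining, so no
#' intermediate species appear.
#'
#' This is a plain-R reference implementation; simulation routines use an
#' identical compiled version (cross-checked by the test suite).
#'
#' @param state Model state (length 14, canonical order, non-negative).
#' @param rates A [rate_constants()] object (or [kinetic_params()], converted
#'   with `kon = 1`).
#' @param homeostasis If `TRUE`, the derivative components for free ATP and
#'   GTP are forced to zero (substrate clamping).
#' @return Named numeric vector of length 14: d\[species\]/dt in uM/s.
#' @examples
#' r <- rate_constants(gaca_params("cooperative"))
#' cyclase_derivative(state_vector(E = 1, G = 100), r)
#' @export
cyclase_derivative <- function(state, rates, homeostasis = FALSE) {
  validate_state(state)
  rates <- as_rate_constants(rates)
  d <- .Call(C_cyclase_derivative, as.numeric(state),
             as.numeric(rates_to_cvec(rates, homeostasis)))
  names(d) <- cyclase_species()
  d
}

# Pure-R transcription of the rate equations, kept as an independent check
# on the compiled version (not exported).
cyclase_derivative_r <- function(state, rates, homeostasis = FALSE) {
  validate_state(state)
  r <- as_rate_constants(rates)
  s <- as.list(structure(as.numeric(state), names = cyclase_species()))
  k <- as.list(unclass(r))
  with(c(s, k), {
    d <- c(
      E = kn1G * EnG - k1G * E * G + kn1G * EGn - k1G * E * G +
        kn1A * EAn - k1A * E * A + kn1A * EnA - k1A * E * A +
        kcat_cdiG * EGG + kcat_cGAMP * EGA + kcat_cdiA * EAA +
        kcat_cGAMP * EAG,
      EnG = k1G * E * G - kn1G * EnG - k2G * EnG * G + kn2G * EGG +
        knAG * EAG - kAG * EnG * A,
      EGn = k1G * E * G - kn1G * EGn + kn2G * EGG - k2G * EGn * G +
        knAG * EGA - kAG * EGn * A,
      EnA = k1A * E * A - kn1A * EnA + knGA * EGA - kGA * EnA * G +
        kn2A * EAA - k2A * EnA * A,
      EAn = k1A * E * A - kn1A * EAn + kn2A * EAA - k2A * EAn * A +
        knGA * EAG - kGA * EAn * G,
      EGG = k2G * EnG * G - kn2G * EGG + k2G * EGn * G - kn2G * EGG -
        kcat_cdiG * EGG,
      EGA = kAG * EGn * A - knAG * EGA + kGA * EnA * G - knGA * EGA -
        kcat_cGAMP * EGA,
      EAG = kAG * EnG * A - knAG * EAG + kGA * EAn * G - knGA * EAG -
        kcat_cGAMP * EAG,
      EAA = k2A * EnA * A - kn2A * EAA + k2A * EAn * A - kn2A * EAA -
        kcat_cdiA * EAA,
      cdiA = kcat_cdiA * EAA,
      cdiG = kcat_cdiG * EGG,
      cAG = kcat_cGAMP * EAG + kcat_cGAMP * EGA,
      A = -k1A * E * A + kn1A * EAn - k1A * E * A + kn1A * EnA -
        kAG * EGn * A + knAG * EGA - k2A * EnA * A + kn2A * EAA -
        k2A * EAn * A + kn2A * EAA - kAG * EnG * A + knAG * EAG,
      G = -k1G * E * G + kn1G * EnG - k1G * E * G + kn1G * EGn -
        k2G * EnG * G + kn2G * EGG - k2G * EGn * G + kn2G * EGG -
        kGA * EnA * G + knGA * EGA - kGA * EAn * G + knGA * EAG
    )
    if (homeostasis) d[c("A", "G")] <- 0
    d
  })
}
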