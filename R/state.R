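#' Canonical species order of the kinetic scheme
#'
#' All functions in the package exchange model states as vectors in this
#' fixed order.  `E` is the free active dimer; in the single-bound states
#' `n` marks the empty half-site (`EnG` = pocket 1 empty, GTP in pocket 2;
#' `EGn` = GTP in pocket 1, pocket 2 empty); in the double-bound states the
#' first letter is the occupant of pocket 1 (`EAG` = ATP in pocket 1, GTP in
#' pocket 2).  `cdiA`, `cdiG`, `cAG` are the released cyclic dinucleotides
#' and `A`, `G` the free nucleotide substrates.
#'
#' @return Character vector of the 14 species names.
#' @examples
#' cyclase_species()
#' @export
cyclase_species <- function() {
  c("E", "EnG", "EGn", "EnA", "EAn", "EGG", "EGA", "EAG", "EAA",
    "cdiA", "cdiG", "cAG", "A", "G")
}

ENZYME_SPECIES <- 1:9
IDX <- structure(1:14, names = c("E", "EnG", "EGn", "EnA", "EAn", "EGG",
                                 "EGA", "EAG", "EAA", "cdiA", "cdiG", "cAG",
                                 "A", "G"))

#' Build a model state vector
#'
#' Convenience constructor: any subset of species may be given by name, the
#' rest default to zero.  Concentrations are in micromolar.
#'
#' @param ... Named species concentrations, e.g. `E = 1, A = 100`.
#' @return Named numeric vector of length 14 in canonical order.
#' @examples
#' state_vector(E = 1, A = 100, G = 100)
#' @export
state_vector <- function(...) {
  given <- c(...)
  s <- structure(numeric(14), names = cyclase_species())
  if (length(given)) {
    if (is.null(names(given)) || !all(names(given) %in% names(s)))
      stop("species must be named and one of: ",
           paste(cyclase_species(), collapse = ", "), call. = FALSE)
    s[names(given)] <- given
  }
  validate_state(s)
  s
}

validate_state <- function(state) {
  if (length(state) != 14)
    stop("a model state must have 14 entries", call. = FALSE)
  if (any(!is.finite(state)))
    stop("state contains non-finite concentrations", call. = FALSE)
  if (any(state < 0))
    stop("state contains negative concentrations", call. = FALSE)
  invisible(state)
}

#' Conservation totals of a model state
#'
#' The reaction network conserves three quantities: total enzyme (the dimer
#' is neither created nor destroyed), total adenine base and total guanine
#' base (each NTP ends up free, enzyme-bound, or incorporated into a cyclic
#' dinucleotide; the homodimeric products carry two bases, the heterodimer
#' one of each).  Base totals are conserved only in depletion mode; under
#' substrate clamping they grow as product accumulates.
#'
#' @param state Model state vector (canonical order, see
#'   [cyclase_species()]).
#' @return Named numeric vector `c(enzyme, adenine, guanine)` in micromolar.
#' @examples
#' conservation_totals(state_vector(EAA = 1, cdiA = 2, A = 3))
#' @export
conservation_totals <- function(state) {
  validate_state(state)
  s <- unname(state)
  c(enzyme = sum(s[ENZYME_SPECIES]),
    adenine = s[IDX["A"]] + s[IDX["EnA"]] + s[IDX["EAn"]] + s[IDX["EAG"]] +
      s[IDX["EGA"]] + 2 * s[IDX["EAA"]] + 2 * s[IDX["cdiA"]] +
      s[IDX["cAG"]],
    guanine = s[IDX["G"]] + s[IDX["EnG"]] + s[IDX["EGn"]] + s[IDX["EAG"]] +
      s[IDX["EGA"]] + 2 * s[IDX["EGG"]] + 2 * s[IDX["cdiG"]] +
      s[IDX["cAG"]])
}

#' Reaction conditions for a simulated time course
#'
#' @param E0 Total active-dimer concentration (micromolar).
#' @param A0,G0 Initial (depletion mode) or clamped (homeostasis mode) ATP
#'   and GTP concentrations (micromolar).
#' @param duration Simulated time (seconds).
#' @param homeostasis If `TRUE`, substrates are clamped
#'   (d\[ATP\]/dt = d\[GTP\]/dt = 0), emulating cellular nucleotide
#'   homeostasis; if `FALSE` (default) the system is closed and substrates
#'   deplete, as in an in vitro assay.
#' @param temperature Kelvin; used only when reporting activation-energy
#'   differences (see [delta_delta_G()]).  Default 301.15 K (28 degrees C,
#'   the enzymatic assay temperature).
#' @return A list of class `"reaction_conditions"`.
#' @export
reaction_conditions <- function(E0 = 1, A0 = 100, G0 = 100, duration = 3600,
                                homeostasis = FALSE, temperature = 301.15) {
  if (!is.finite(E0) || E0 <= 0) stop("E0 must be > 0", call. = FALSE)
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  if (!is.finite(A0) || A0 < 0 || !is.finite(G0) || G0 < 0)
    stop("A0 and G0 must be >= 0", call. = FALSE)
  if (A0 == 0 && G0 == 0)
    stop("at least one substrate must be present (A0 or G0 > 0)",
         call. = FALSE)
  structure(list(E0 = E0, A0 = A0, G0 = G0, duration = duration,
                 homeostasis = isTRUE(homeostasis),
                 temperature = temperature),
            class = "reaction_conditions")
}

#' @export
print.reaction_conditions <- function(x, ...) {
  cat(sprintf(
    "Reaction conditions: E0 = %g uM, A0 = %g uM, G0 = %g uM, %g s, %s mode\n",
    x$E0, x$A0, x$G0, x$duration,
    if (x$homeostasis) "homeostasis (clamped)" else "depletion"))
  invisible(x)
}
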