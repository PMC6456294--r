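#' Kinetic parameter set for a dimeric dinucleotide cyclase
#'
#' Bundles the six dissociation constants and three catalytic rate constants
#' that define the two-site kinetic scheme of a homodimeric GGDEF cyclase.
#' The dimer binds one NTP per half-active site; the first binding event for
#' each substrate has its own constant (`K1A`, `K1G`), the second binding
#' event depends on which substrate is already bound: `K2A`/`K2G` for the
#' homodimeric paths and the conditional constants `KAG` (ATP given GTP
#' pre-bound, "K_A|G") and `KGA` (GTP given ATP pre-bound, "K_G|A") for the
#' heterodimeric path.  Differences between `K2G` and `KGA` (or `K2A` and
#' `KAG`) express *selective cooperativity*: the identity of the first
#' substrate bound tunes the affinity for the second.
#'
#' No detailed-balance (thermodynamic cycle closure) constraint is imposed on
#' the two heterodimeric constants: the fitted constants of the enzyme this
#' model describes violate cycle closure, and the model deliberately permits
#' that.
#'
#' @param K1A,K2A Dissociation constants for the first and second ATP binding
#'   events (micromolar).
#' @param K1G,K2G Same for GTP (micromolar).
#' @param KAG Dissociation constant for ATP binding when GTP is already bound
#'   (micromolar).
#' @param KGA Dissociation constant for GTP binding when ATP is already bound
#'   (micromolar).
#' @param kcat_cdiA,kcat_cdiG,kcat_cGAMP Catalytic rate constants (per
#'   second) for conversion of the doubly-bound enzyme into cyclic di-AMP,
#'   cyclic di-GMP and 3',3'-cGAMP respectively.
#'
#' @return A named numeric vector of class `"kinetic_params"`.
#' @seealso [gaca_params()] for the packaged presets,
#'   [rate_constants()] to convert to on/off rates.
#' @examples
#' p <- kinetic_params(K1A = 343, K2A = 53, K1G = 39, K2G = 20,
#'                     KAG = 71, KGA = 10,
#'                     kcat_cdiA = 0.03, kcat_cdiG = 0.03, kcat_cGAMP = 0.03)
#' p["K2G"] / p["KGA"]  # selective-cooperativity ratio
#' @export
kinetic_params <- function(K1A, K2A, K1G, K2G, KAG, KGA,
                           kcat_cdiA, kcat_cdiG, kcat_cGAMP) {
  p <- c(K1A = K1A, K2A = K2A, K1G = K1G, K2G = K2G, KAG = KAG, KGA = KGA,
         kcat_cdiA = kcat_cdiA, kcat_cdiG = kcat_cdiG,
         kcat_cGAMP = kcat_cGAMP)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  nm <- c("K1A", "K2A", "K1G", "K2G", "KAG", "KGA",
          "kcat_cdiA", "kcat_cdiG", "kcat_cGAMP")
  if (!is.numeric(p) || !all(nm %in% names(p)))
    stop("kinetic parameters must be numeric and named ",
         paste(nm, collapse = ", "), call. = FALSE)
  bad <- nm[!is.finite(p[nm]) | p[nm] <= 0]
  if (length(bad))
    stop("kinetic parameter(s) not strictly positive and finite: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(p)
}

#' Packaged kinetic parameter presets for WT GacA
#'
#' Returns one of the two published fitted parameter sets for the wild-type
#' GacA homodimer: the `"cooperative"` model (distinct first/second binding
#' constants, K1 > K2 for every path) or the `"noncooperative"` reference
#' model (first and second binding constants forced equal).  Values are read
#' from the versioned YAML shipped in `inst/extdata/presets/`.
#'
#' @param model `"cooperative"` or `"noncooperative"`.
#' @return A [kinetic_params()] object.
#' @examples
#' gaca_params("cooperative")
#' @export
gaca_params <- function(model = c("cooperative", "noncooperative")) {
  model <- match.arg(model)
  path <- system.file("extdata", "presets", "gaca_params.yaml",
                      package = "gacakin", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  v <- cfg$presets[[model]]
  do.call(kinetic_params, v)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Dimeric cyclase kinetic parameters\n")
  cat("  Dissociation constants (uM):\n")
  cat(sprintf("    K1A = %-8g K2A = %-8g (ATP path)\n", x["K1A"], x["K2A"]))
  cat(sprintf("    K1G = %-8g K2G = %-8g (GTP path)\n", x["K1G"], x["K2G"]))
  cat(sprintf("    K_A|G = %-6g K_G|A = %-6g (mixed path)\n",
              x["KAG"], x["KGA"]))
  cat("  Catalytic constants (1/s):\n")
  cat(sprintf("    kcat cdiA = %g, cdiG = %g, cGAMP = %g\n",
              x["kcat_cdiA"], x["kcat_cdiG"], x["kcat_cGAMP"]))
  invisible(x)
}

#' Convert dissociation constants to mass-action on/off rate constants
#'
#' Every binding step is assigned the same on-rate `kon` (binding is fast and
#' never rate-limiting: all kcat values are far below 1/s), and each off-rate
#' is `kon * K` for the corresponding dissociation constant, so that
#' `koff / kon` reproduces K exactly.  Catalytic constants are copied
#' through.
#'
#' @param params A [kinetic_params()] object.
#' @param kon Common on-rate for the six binding transitions
#'   (per micromolar per second).  Default 1.
#' @return A named numeric vector of class `"rate_constants"` with elements
#'   `k1A, k2A, k1G, k2G, kAG, kGA` (on-rates), `kn1A, kn2A, kn1G, kn2G,
#'   knAG, knGA` (off-rates) and the three `kcat_*` entries.
#' @examples
#' rate_constants(gaca_params("cooperative"))["kn1G"]  # 39 / s
#' @export
rate_constants <- function(params, kon = 1) {
  validate_kinetic_params(params)
  if (!is.numeric(kon) || length(kon) != 1 || !is.finite(kon) || kon <= 0)
    stop("kon must be a single strictly positive number", call. = FALSE)
  r <- c(k1A = kon, k2A = kon, k1G = kon, k2G = kon, kAG = kon, kGA = kon,
         kn1A = kon * unname(params["K1A"]),
         kn2A = kon * unname(params["K2A"]),
         kn1G = kon * unname(params["K1G"]),
         kn2G = kon * unname(params["K2G"]),
         knAG = kon * unname(params["KAG"]),
         knGA = kon * unname(params["KGA"]),
         kcat_cdiA = unname(params["kcat_cdiA"]),
         kcat_cdiG = unname(params["kcat_cdiG"]),
         kcat_cGAMP = unname(params["kcat_cGAMP"]))
  structure(r, class = "rate_constants")
}

# Internal: rate constants -> the length-16 parameter vector consumed by the
# compiled right-hand side (order fixed in src/cyclase.c).
rates_to_cvec <- function(rates, homeostasis = FALSE) {
  c(rates[c("k1A", "k2A", "k1G", "k2G", "kAG", "kGA",
            "kn1A", "kn2A", "kn1G", "kn2G", "knAG", "knGA",
            "kcat_cdiA", "kcat_cdiG", "kcat_cGAMP")],
    as.numeric(homeostasis))
}

as_rate_constants <- function(x, kon = 1) {
  if (inherits(x, "rate_constants")) return(x)
  if (inherits(x, "kinetic_params")) return(rate_constants(x, kon = kon))
  stop("expected a 'kinetic_params' or 'rate_constants' object",
       call. = FALSE)
}
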