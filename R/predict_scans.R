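#' Product-ratio scan under substrate homeostasis
#'
#' Computes clamped-substrate product fractions across a range of ATP:GTP
#' ratios, emulating cellular conditions where nucleotide pools are held at
#' homeostatic levels.  For each ratio `r` the exact steady-state solver is
#' evaluated at `A = r * G_ref`, `G = G_ref` (the flux fractions depend only
#' on the ratio in the fast-binding regime, which a test asserts).  Rows are
#' annotated with the physiological reference point `r = 3`: cellular ATP
#' typically exceeds GTP three-fold or more.
#'
#' @param params A [kinetic_params()] object.
#' @param ratios ATP:GTP ratios to scan (positive, ascending recommended).
#' @param G_ref Clamped GTP concentration (micromolar).
#' @param kon Common binding on-rate (per uM per s).
#' @param E0 Active-dimer concentration (uM); scales fluxes, not fractions.
#' @param method `"steady"` (exact linear solve, default) or `"integrate"`
#'   (long-horizon clamped integration, endpoint instantaneous flux
#'   fractions; for cross-checking).
#' @param duration Horizon for `method = "integrate"` (s).
#' @return Data frame of class `"cyclase_scan"`: one row per ratio with
#'   `ratio`, `A`, `G`, the three `fraction_*` columns, the three `flux_*`
#'   columns (uM/s) and `physiological_ref` (`TRUE` at r = 3).
#' @examples
#' homeostasis_scan(gaca_params("cooperative"), ratios = c(1, 3, 10))
#' @export
homeostasis_scan <- function(params, ratios = seq(1, 10, by = 0.5),
                             G_ref = 100, kon = 1, E0 = 1,
                             method = c("steady", "integrate"),
                             duration = 3600) {
  method <- match.arg(method)
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("ratios must be strictly positive", call. = FALSE)
  if (!is.finite(G_ref) || G_ref <= 0)
    stop("G_ref must be > 0", call. = FALSE)
  ratios <- sort(ratios)

  rows <- lapply(ratios, function(r) {
    A <- r * G_ref
    if (method == "steady") {
      ss <- steady_state_ratios(params, A = A, G = G_ref, kon = kon,
                                E0 = E0)
      fr <- ss$fractions
      fl <- ss$fluxes
    } else {
      traj <- simulate_timecourse(
        params,
        reaction_conditions(E0 = E0, A0 = A, G0 = G_ref,
                            duration = duration, homeostasis = TRUE),
        mode = "stiff", step = duration, kon = kon)
      fin <- final_state(traj)
      fl <- c(cdiG = unname(params["kcat_cdiG"] * fin["EGG"]),
              cGAMP = unname(params["kcat_cGAMP"] *
                               (fin["EAG"] + fin["EGA"])),
              cdiA = unname(params["kcat_cdiA"] * fin["EAA"]))
      fr <- product_ratios(unname(fl))
    }
    data.frame(ratio = r, A = A, G = G_ref,
               fraction_cdiG = fr[["fraction_cdiG"]],
               fraction_cGAMP = fr[["fraction_cGAMP"]],
               fraction_cdiA = fr[["fraction_cdiA"]],
               flux_cdiG = fl[["cdiG"]], flux_cGAMP = fl[["cGAMP"]],
               flux_cdiA = fl[["cdiA"]])
  })
  out <- do.call(rbind, rows)
  out$physiological_ref <- out$ratio == 3
  structure(out,
            settings = list(G_ref = G_ref, kon = kon, E0 = E0,
                            method = method, fold = 1),
            class = c("cyclase_scan", "data.frame"))
}

#' Asymmetric-activation scan
#'
#' Repeats [homeostasis_scan()] with the heterodimeric catalytic constant
#' multiplied by each value in `folds`, modeling a regulatory (receiver-
#' domain) activation that accelerates cGAMP synthesis more than the
#' homodimeric reactions.  `fold = 1` reproduces [homeostasis_scan()]
#' exactly.
#'
#' @inheritParams homeostasis_scan
#' @param folds Multipliers (>= 1) applied to `kcat_cGAMP`.
#' @return `"cyclase_scan"` data frame with an extra `fold` column.
#' @examples
#' sc <- asymmetric_scan(gaca_params("cooperative"), folds = c(1, 9),
#'                       ratios = c(1, 3, 4, 10))
#' subset(sc, fold == 9 & ratio == 4)$fraction_cGAMP
#' @export
asymmetric_scan <- function(params, folds = c(1, 9),
                            ratios = seq(1, 10, by = 0.5), G_ref = 100,
                            kon = 1, E0 = 1,
                            method = c("steady", "integrate"),
                            duration = 3600) {
  if (any(!is.finite(folds)) || any(folds < 1))
    stop("folds must be >= 1", call. = FALSE)
  validate_kinetic_params(params)
  out <- lapply(folds, function(f) {
    p <- params
    p["kcat_cGAMP"] <- params[["kcat_cGAMP"]] * f
    sc <- homeostasis_scan(p, ratios = ratios, G_ref = G_ref, kon = kon,
                           E0 = E0, method = method, duration = duration)
    cbind(fold = f, as.data.frame(sc))
  })
  out <- do.call(rbind, out)
  structure(out,
            settings = list(G_ref = G_ref, kon = kon, E0 = E0,
                            method = match.arg(method), folds = folds),
            class = c("cyclase_scan", "data.frame"))
}

#' @export
plot.cyclase_scan <- function(x, ...) {
  d <- as.data.frame(x)
  if (!"fold" %in% names(d)) d$fold <- 1
  graphics::plot(range(d$ratio), c(0, 1), type = "n",
                 xlab = "ATP:GTP ratio", ylab = "product fraction", ...)
  k <- 0
  for (f in unique(d$fold)) {
    sub <- d[d$fold == f, ]
    graphics::lines(sub$ratio, sub$fraction_cdiG, col = "darkgreen",
                    lty = k + 1)
    graphics::lines(sub$ratio, sub$fraction_cGAMP, col = "purple",
                    lty = k + 1)
    graphics::lines(sub$ratio, sub$fraction_cdiA, col = "orange",
                    lty = k + 1)
    k <- k + 1
  }
  graphics::abline(v = 3, col = "grey", lty = 3)
  graphics::legend("topright", c("cdiG", "cGAMP", "cdiA"),
                   col = c("darkgreen", "purple", "orange"), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Activation-energy difference implied by a rate-constant ratio
#'
#' Transition-state relation between a fold change in a catalytic rate
#' constant and the corresponding difference in activation free energy:
#' `ddG = R * T * ln(fold)` with R = 1.987e-3 kcal/(mol K).  A nine-fold
#' rate asymmetry corresponds to only about 1.3 kcal/mol at 28 degrees C --
#' well within reach of a modest conformational change.
#'
#' @param fold Rate-constant ratio (> 0).
#' @param temperature Kelvin (> 0).  Default 301.15 K (28 C, the enzymatic
#'   assay temperature).
#' @return Activation-energy difference in kcal/mol.
#' @examples
#' delta_delta_G(9)  # ~1.3 kcal/mol
#' @export
delta_delta_G <- function(fold, temperature = 301.15) {
  if (any(!is.finite(fold)) || any(fold <= 0))
    stop("fold must be > 0", call. = FALSE)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0 (kelvin)", call. = FALSE)
  R <- 1.987e-3  # kcal / (mol K)
  R * temperature * log(fold)
}
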