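#' Simulate a reaction time course
#'
#' Integrates the 14-species mass-action network from `E = E0`,
#' `A = A0`, `G = G0` (all other species zero) over `[0, duration]`.
#'
#' Two integration modes are offered.  `"stiff"` (default) uses `lsoda` from
#' \pkg{deSolve} with a compiled right-hand side; the network is stiff
#' (binding/unbinding rates of order 10--400 per second against catalytic
#' rates of 0.03 per second), and an implicit/adaptive method is the safe
#' default.  `"euler"` reproduces the classic fixed-step linear update
#' `x(t+dt) = x(t) + dt * dx/dt` on the reporting grid, but automatically
#' sub-steps whenever the requested step would overshoot: the effective step
#' is bounded so that no species can lose more than a `safety` fraction of
#' itself in one update, which keeps the explicit scheme stable and all
#' concentrations non-negative.  A literal 1-second explicit step would be
#' unstable at realistic substrate concentrations; the reporting grid is
#' just the output resolution.  If the required sub-stepping exceeds
#' `max_substeps` per reporting interval the integrator stops with an error
#' rather than clipping.
#'
#' @param params A [kinetic_params()] or [rate_constants()] object.
#' @param conditions A [reaction_conditions()] object.
#' @param mode `"stiff"` or `"euler"`.
#' @param step Reporting interval in seconds (default 1).
#' @param kon Common binding on-rate (per uM per s) used when `params` is a
#'   `kinetic_params` object.  Default 1.
#' @param safety Stability fraction for `"euler"` sub-stepping (default 0.1).
#' @param rtol,atol Relative/absolute tolerances for `"stiff"` mode.
#' @param max_substeps Cap on sub-steps per reporting interval in `"euler"`
#'   mode.
#' @return An object of class `"cyclase_trajectory"`: list with elements
#'   `time` (seconds), `states` (matrix, one row per time point, 14 columns
#'   in canonical order), `conditions`, `mode`, `kon`.
#' @seealso [product_ratios()], [steady_state_ratios()]
#' @examples
#' traj <- simulate_timecourse(gaca_params("cooperative"),
#'                             reaction_conditions(A0 = 100, G0 = 100,
#'                                                 duration = 60))
#' product_ratios(traj)
#' @export
simulate_timecourse <- function(params,
                                conditions = reaction_conditions(),
                                mode = c("stiff", "euler"),
                                step = 1, kon = 1, safety = 0.1,
                                rtol = 1e-8, atol = 1e-10,
                                max_substeps = 1e7) {
  mode <- match.arg(mode)
  if (!inherits(conditions, "reaction_conditions"))
    stop("conditions must be a reaction_conditions() object", call. = FALSE)
  if (!is.finite(step) || step <= 0) stop("step must be > 0", call. = FALSE)
  rates <- as_rate_constants(params, kon = kon)
  p <- as.numeric(rates_to_cvec(rates, conditions$homeostasis))
  y0 <- state_vector(E = conditions$E0, A = conditions$A0,
                     G = conditions$G0)
  times <- seq(0, conditions$duration, by = step)
  if (times[length(times)] < conditions$duration)
    times <- c(times, conditions$duration)

  if (mode == "stiff") {
    sol <- deSolve::ode(y = as.numeric(y0), times = times,
                        func = "cyclase_derivs", parms = p,
                        dllname = "gacakin",
                        initfunc = "cyclase_initparms",
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 50000)
    istate <- attr(sol, "istate")[1]
    if (!is.null(istate) && istate < 0)
      stop("stiff integration failed (lsoda istate = ", istate, ")",
           call. = FALSE)
    states <- unname(sol[, -1, drop = FALSE])
  } else {
    states <- .Call(C_euler_timecourse, as.numeric(y0), p,
                    as.numeric(times), as.numeric(safety),
                    as.numeric(max_substeps))
  }

  # The solvers can leave harmless rounding-level negatives; anything larger
  # is a real failure and is reported, never clipped.
  floor_neg <- -100 * atol - 1e-12 * max(abs(states))
  if (min(states) < floor_neg)
    stop("integration produced a negative concentration (",
         format(min(states)), " uM); reduce the tolerances or step",
         call. = FALSE)
  states[states < 0] <- 0
  colnames(states) <- cyclase_species()

  structure(list(time = times, states = states, conditions = conditions,
                 mode = mode, kon = kon),
            class = "cyclase_trajectory")
}

#' @export
print.cyclase_trajectory <- function(x, ...) {
  cat(sprintf("Cyclase trajectory: %d time points over %g s (%s mode, %s)\n",
              length(x$time), max(x$time), x$mode,
              if (x$conditions$homeostasis) "clamped substrates"
              else "substrate depletion"))
  fin <- final_state(x)
  cat(sprintf("  endpoint products (uM): cdiG = %.4g, cGAMP = %.4g, cdiA = %.4g\n",
              fin["cdiG"], fin["cAG"], fin["cdiA"]))
  invisible(x)
}

#' @export
as.data.frame.cyclase_trajectory <- function(x, ...) {
  data.frame(time = x$time, x$states, check.names = FALSE)
}

#' @export
plot.cyclase_trajectory <- function(x, which = c("products", "enzyme"),
                                    ...) {
  which <- match.arg(which)
  cols <- if (which == "products") c("cdiG", "cAG", "cdiA")
          else cyclase_species()[1:9]
  graphics::matplot(x$time, x$states[, cols, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (s)",
                    ylab = "concentration (uM)", ...)
  graphics::legend("topleft", legend = cols, lty = 1,
                   col = seq_along(cols), bty = "n")
  invisible(x)
}

final_state <- function(traj) {
  traj$states[nrow(traj$states), ]
}

#' Endpoint product ratios of a trajectory
#'
#' Normalized fractions of the three cyclic dinucleotides at the final time
#' point: each product concentration divided by the summed product
#' concentration.
#'
#' @param x A `"cyclase_trajectory"` from [simulate_timecourse()], or a
#'   numeric vector of the three product concentrations
#'   `(cdiG, cGAMP, cdiA)`.
#' @return Named numeric vector of class `"product_ratios"` with elements
#'   `fraction_cdiG`, `fraction_cGAMP`, `fraction_cdiA` (sum 1).
#' @examples
#' product_ratios(c(cdiG = 1, cGAMP = 2, cdiA = 1))
#' @export
product_ratios <- function(x) {
  if (inherits(x, "cyclase_trajectory")) {
    fin <- final_state(x)
    prod <- unname(c(fin["cdiG"], fin["cAG"], fin["cdiA"]))
  } else if (is.numeric(x) && length(x) == 3) {
    prod <- as.numeric(x)
  } else {
    stop("x must be a cyclase trajectory or a length-3 numeric vector",
         call. = FALSE)
  }
  if (any(!is.finite(prod)) || any(prod < 0))
    stop("product concentrations must be finite and non-negative",
         call. = FALSE)
  tot <- sum(prod)
  if (tot <= 0) stop("no product formed: cannot compute ratios",
                     call. = FALSE)
  structure(c(fraction_cdiG = prod[1] / tot,
              fraction_cGAMP = prod[2] / tot,
              fraction_cdiA = prod[3] / tot),
            class = "product_ratios")
}

#' @export
print.product_ratios <- function(x, digits = 4, ...) {
  cat(sprintf("Product ratios: cdiG %.*f | cGAMP %.*f | cdiA %.*f\n",
              digits, x[["fraction_cdiG"]], digits, x[["fraction_cGAMP"]],
              digits, x[["fraction_cdiA"]]))
  invisible(x)
}
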