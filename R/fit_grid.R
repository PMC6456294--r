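#' Product-ratio dataset
#'
#' Observed endpoint fractions of the three cyclic dinucleotides at a set of
#' initial ATP/GTP mixes (depletion-mode in vitro reactions).
#'
#' @param A0,G0 Initial ATP and GTP concentrations (micromolar).
#' @param fraction_cdiG,fraction_cGAMP,fraction_cdiA Observed product
#'   fractions, each in \[0, 1\]; per record they must sum to 1 within 0.02
#'   (measurement rounding is tolerated).
#' @param replicate Optional replicate index.
#' @return Data frame of class `"product_ratio_data"`.
#' @export
product_ratio_data <- function(A0, G0, fraction_cdiG, fraction_cGAMP,
                               fraction_cdiA, replicate = NULL) {
  d <- data.frame(A0 = A0, G0 = G0,
                  fraction_cdiG = fraction_cdiG,
                  fraction_cGAMP = fraction_cGAMP,
                  fraction_cdiA = fraction_cdiA)
  if (!is.null(replicate)) d$replicate <- replicate
  fr <- as.matrix(d[, c("fraction_cdiG", "fraction_cGAMP",
                        "fraction_cdiA")])
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("fractions must lie in [0, 1]", call. = FALSE)
  if (any(abs(rowSums(fr) - 1) > 0.02))
    stop("each record's fractions must sum to 1 within 0.02", call. = FALSE)
  if (any(!is.finite(d$A0)) || any(d$A0 < 0) ||
      any(!is.finite(d$G0)) || any(d$G0 < 0) || any(d$A0 + d$G0 <= 0))
    stop("A0 and G0 must be >= 0 with A0 + G0 > 0", call. = FALSE)
  structure(d, class = c("product_ratio_data", "data.frame"))
}

# Endpoint depletion-mode product fractions for one (A0, G0) condition.
endpoint_fractions <- function(params, A0, G0, E0 = 1, duration = 3600,
                               kon = 1, rtol = 1e-6, atol = 1e-9) {
  traj <- simulate_timecourse(
    params,
    reaction_conditions(E0 = E0, A0 = A0, G0 = G0, duration = duration),
    mode = "stiff", step = duration, kon = kon, rtol = rtol, atol = atol)
  product_ratios(traj)
}

# Squared-difference score between observed and modeled fractions, in
# percentage points (fractions x 100), summed over the three products.
ratio_sq_error <- function(observed, modeled) {
  sum((100 * (as.numeric(observed) - as.numeric(modeled)))^2)
}

#' Least-squares error of a parameter set against product-ratio data
#'
#' For each record, simulates the depletion-mode endpoint product fractions
#' at that record's `(A0, G0)` (one-hour horizon by default) and accumulates
#' the squared differences to the observed fractions over all records and
#' all three products.  Fractions are scored in percentage points (x100),
#' so a total mismatch of one product pair contributes 100^2 = 10,000.
#'
#' @param params A [kinetic_params()] object.
#' @param data A [product_ratio_data()] object.
#' @param E0 Simulated enzyme concentration (uM).
#' @param duration Simulated reaction time (s).
#' @param kon Common binding on-rate (per uM per s).
#' @param rtol,atol Integration tolerances.
#' @return Single non-negative number (percentage-points squared).
#' @export
heterodimer_error <- function(params, data, E0 = 1, duration = 3600,
                              kon = 1, rtol = 1e-6, atol = 1e-9) {
  if (!inherits(data, "product_ratio_data"))
    stop("data must be a product_ratio_data() object", call. = FALSE)
  validate_kinetic_params(params)
  key <- paste(data$A0, data$G0)
  err <- 0
  for (k in unique(key)) {
    rows <- which(key == k)
    mod <- tryCatch(
      endpoint_fractions(params, data$A0[rows[1]], data$G0[rows[1]],
                         E0 = E0, duration = duration, kon = kon,
                         rtol = rtol, atol = atol),
      error = function(e)
        stop("simulation failed at record with A0 = ", data$A0[rows[1]],
             ", G0 = ", data$G0[rows[1]], ": ", conditionMessage(e),
             call. = FALSE))
    for (i in rows)
      err <- err + ratio_sq_error(
        c(data$fraction_cdiG[i], data$fraction_cGAMP[i],
          data$fraction_cdiA[i]),
        mod)
  }
  err
}

# Lexicographic argmin of an error surface: smallest (KAG, KGA) pair among
# the cells attaining the minimum; flags ties.
surface_argmin <- function(err, KAG_axis, KGA_axis) {
  m <- min(err)
  hits <- which(err == m, arr.ind = TRUE)  # rows = KAG index, cols = KGA
  ord <- order(KAG_axis[hits[, 1]], KGA_axis[hits[, 2]])
  first <- hits[ord[1], ]
  list(KAG = KAG_axis[first[1]], KGA = KGA_axis[first[2]],
       minimum = m, tie = nrow(hits) > 1)
}

#' Grid-search fit of the heterodimeric dissociation constants
#'
#' Estimates `K_A|G` and `K_G|A` -- the dissociation constants for binding
#' the second, different substrate -- by exhaustive grid search: every
#' combination on the two axes (default 1--100 uM in 1 uM steps, 10,000
#' combinations) is scored with [heterodimer_error()] against the supplied
#' product-ratio data, holding the single-substrate constants and all kcat
#' values of `base` fixed.  The heterodimeric kcat is conventionally fixed
#' equal to the homodimeric ones before this fit.  The argmin is reported;
#' exact ties are broken toward the lexicographically smallest
#' `(K_A|G, K_G|A)` pair and flagged.
#'
#' @param data A [product_ratio_data()] object.
#' @param base A [kinetic_params()] object supplying the fixed constants
#'   (its `KAG`/`KGA` entries are overwritten cell by cell).
#' @param KAG_grid,KGA_grid Grid axes (micromolar, strictly positive).
#' @param E0,duration,kon,rtol,atol Passed to [heterodimer_error()].
#' @param verbose Print progress every 10 grid rows.
#' @return Object of class `"heterodimer_fit"`: `error` (matrix, rows =
#'   `KAG_grid`, cols = `KGA_grid`), the axes, `KAG`/`KGA` (argmin),
#'   `minimum`, `tie`, `n_eval`, `best_params`, `metric`, `settings`.
#'   Methods: `print`, `summary`, `coef`, `plot`, `predict`.
#' @examples
#' \donttest{
#' d <- sim_product_ratio_data(noise_sd = 0)
#' fit <- fit_heterodimer(d, gaca_params("cooperative"),
#'                        KAG_grid = 69:73, KGA_grid = 8:12)
#' coef(fit)
#' }
#' @export
fit_heterodimer <- function(data, base,
                            KAG_grid = 1:100, KGA_grid = 1:100,
                            E0 = 1, duration = 3600, kon = 1,
                            rtol = 1e-6, atol = 1e-9, verbose = FALSE) {
  if (!inherits(data, "product_ratio_data") || nrow(data) == 0)
    stop("data must be a non-empty product_ratio_data() object",
         call. = FALSE)
  validate_kinetic_params(base)
  if (!length(KAG_grid) || !length(KGA_grid) ||
      any(KAG_grid <= 0) || any(KGA_grid <= 0))
    stop("grid axes must be non-empty and strictly positive", call. = FALSE)

  err <- matrix(NA_real_, length(KAG_grid), length(KGA_grid),
                dimnames = list(KAG = KAG_grid, KGA = KGA_grid))
  p <- base
  for (i in seq_along(KAG_grid)) {
    p["KAG"] <- KAG_grid[i]
    for (j in seq_along(KGA_grid)) {
      p["KGA"] <- KGA_grid[j]
      err[i, j] <- heterodimer_error(p, data, E0 = E0, duration = duration,
                                     kon = kon, rtol = rtol, atol = atol)
    }
    if (verbose && i %% 10 == 0)
      message(sprintf("grid row %d / %d (K_A|G = %g uM)",
                      i, length(KAG_grid), KAG_grid[i]))
  }

  am <- surface_argmin(err, KAG_grid, KGA_grid)
  best <- base
  best["KAG"] <- am$KAG
  best["KGA"] <- am$KGA

  structure(list(error = err, KAG_grid = KAG_grid, KGA_grid = KGA_grid,
                 KAG = am$KAG, KGA = am$KGA, minimum = am$minimum,
                 tie = am$tie, n_eval = length(err),
                 best_params = best,
                 metric = "sum of squared residuals (percentage points^2)",
                 settings = list(E0 = E0, duration = duration, kon = kon,
                                 rtol = rtol, atol = atol),
                 data = data),
            class = "heterodimer_fit")
}

#' @export
coef.heterodimer_fit <- function(object, ...) {
  c(KAG = object$KAG, KGA = object$KGA)
}

#' @export
print.heterodimer_fit <- function(x, ...) {
  cat(sprintf(
    "Heterodimeric-constant grid search: %d error evaluations\n", x$n_eval))
  cat(sprintf("  argmin: K_A|G = %g uM, K_G|A = %g uM (error %.4g)%s\n",
              x$KAG, x$KGA, x$minimum,
              if (x$tie) "  [tie: smallest pair reported]" else ""))
  cat("  metric:", x$metric, "\n")
  invisible(x)
}

#' @export
summary.heterodimer_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  grid: K_A|G in [%g, %g] (%d), K_G|A in [%g, %g] (%d)\n",
              min(object$KAG_grid), max(object$KAG_grid),
              length(object$KAG_grid),
              min(object$KGA_grid), max(object$KGA_grid),
              length(object$KGA_grid)))
  cat(sprintf("  error range: [%.4g, %.4g]\n",
              min(object$error), max(object$error)))
  invisible(object)
}

#' @export
plot.heterodimer_fit <- function(x, log_scale = TRUE, ...) {
  z <- if (log_scale) log10(x$error + 1e-12) else x$error
  graphics::image(x$KAG_grid, x$KGA_grid, z,
                  xlab = "K_A|G (uM)", ylab = "K_G|A (uM)",
                  main = if (log_scale) "log10 least-squares error"
                  else "least-squares error", ...)
  graphics::points(x$KAG, x$KGA, pch = 4, cex = 2)
  invisible(x)
}

#' @export
predict.heterodimer_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    newdata <- unique(object$data[, c("A0", "G0")])
  s <- object$settings
  out <- newdata
  fr <- t(vapply(seq_len(nrow(newdata)), function(i)
    as.numeric(endpoint_fractions(object$best_params, newdata$A0[i],
                                  newdata$G0[i], E0 = s$E0,
                                  duration = s$duration, kon = s$kon,
                                  rtol = s$rtol, atol = s$atol)),
    numeric(3)))
  out$fraction_cdiG <- fr[, 1]
  out$fraction_cGAMP <- fr[, 2]
  out$fraction_cdiA <- fr[, 3]
  out
}
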