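# Seeded synthetic-data generators.  These emulate, at the level of derived
# numeric tables, the three kinds of measurements the fitting and motif
# modules consume: endpoint product-ratio tables, single-substrate
# initial-rate tables, and labeled GGDEF alignments.  Every generator is
# deterministic under a fixed seed and records its seed and generating
# truth in attributes (and JSON sidecars when written to disk).

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic product-ratio dataset
#'
#' Simulates depletion-mode one-hour endpoint product fractions at a set of
#' ATP/GTP mixes (fractions of a fixed total NTP pool), then adds
#' independent Gaussian replicate noise in percentage points, clamps to
#' \[0, 1\] and renormalizes each replicate to sum to 1.  With
#' `noise_sd = 0` the rows equal the simulator output exactly.
#'
#' @param params Generating [kinetic_params()] (ground truth).
#' @param atp_fraction ATP share of the total pool at each design point.
#' @param total_ntp Total NTP pool (micromolar) split by `atp_fraction`.
#' @param replicates Technical replicates per design point.
#' @param noise_sd Additive Gaussian noise, standard deviation in
#'   percentage points (0 allowed).
#' @param seed RNG seed (recorded in the output).
#' @param E0,duration,kon Simulation settings (see
#'   [simulate_timecourse()]).
#' @return A [product_ratio_data()] object with a `replicate` column and a
#'   `truth` attribute (generating parameters, design, seed, noise_sd,
#'   generator version).
#' @examples
#' d <- sim_product_ratio_data(noise_sd = 0, atp_fraction = c(0.25, 0.75))
#' @export
sim_product_ratio_data <- function(params = gaca_params("cooperative"),
                                   atp_fraction = c(0.10, 0.25, 0.50,
                                                    0.75, 0.90),
                                   total_ntp = 200, replicates = 3,
                                   noise_sd = 2, seed = 1, E0 = 1,
                                   duration = 3600, kon = 1) {
  validate_kinetic_params(params)
  if (any(atp_fraction <= 0) || any(atp_fraction >= 1))
    stop("atp_fraction values must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)

  design <- data.frame(A0 = atp_fraction * total_ntp,
                       G0 = (1 - atp_fraction) * total_ntp)
  model <- t(vapply(seq_len(nrow(design)), function(i)
    as.numeric(endpoint_fractions(params, design$A0[i], design$G0[i],
                                  E0 = E0, duration = duration,
                                  kon = kon)),
    numeric(3)))

  rows <- with_seed(seed, {
    out <- vector("list", nrow(design) * replicates)
    k <- 1
    for (i in seq_len(nrow(design))) {
      for (rep in seq_len(replicates)) {
        fr <- model[i, ]
        if (noise_sd > 0) {
          fr <- fr + stats::rnorm(3, 0, noise_sd / 100)
          fr <- pmin(pmax(fr, 0), 1)
          if (sum(fr) == 0) fr <- model[i, ]  # pathological draw
          fr <- fr / sum(fr)
        }
        out[[k]] <- data.frame(A0 = design$A0[i], G0 = design$G0[i],
                               fraction_cdiG = fr[1],
                               fraction_cGAMP = fr[2],
                               fraction_cdiA = fr[3], replicate = rep)
        k <- k + 1
      }
    }
    do.call(rbind, out)
  })

  d <- product_ratio_data(rows$A0, rows$G0, rows$fraction_cdiG,
                          rows$fraction_cGAMP, rows$fraction_cdiA,
                          replicate = rows$replicate)
  attr(d, "truth") <- list(params = unclass(params), seed = seed,
                           noise_sd = noise_sd, replicates = replicates,
                           atp_fraction = atp_fraction,
                           total_ntp = total_ntp, E0 = E0,
                           duration = duration, kon = kon,
                           generator = "gacakin::sim_product_ratio_data",
                           version = 1)
  d
}

#' Generate a synthetic single-substrate initial-rate dataset
#'
#' Evaluates the cooperative rate law on a concentration design (default:
#' zero plus a log-spaced grid from 1 uM to 10 mM, matching a typical
#' enzyme-coupled assay design) and adds Gaussian noise in rate units.
#' Negative noisy rates are floored at zero and flagged.
#'
#' @param K1,K2,kcat Generating truth (see [single_substrate_rate()]).
#' @param substrate `"ATP"` or `"GTP"`.
#' @param conc Concentration design (micromolar).
#' @param E0 Enzyme concentration (micromolar).
#' @param noise_sd Gaussian noise sd in uM/s (0 allowed).
#' @param seed RNG seed.
#' @return An [initial_rate_data()] object with a logical `floored` column
#'   and a `truth` attribute.
#' @export
sim_initial_rate_data <- function(K1, K2, kcat,
                                  substrate = c("ATP", "GTP"),
                                  conc = c(0, 10^seq(0, 4,
                                                     length.out = 11)),
                                  E0 = 1, noise_sd = 0, seed = 1) {
  substrate <- match.arg(substrate)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  v <- single_substrate_rate(conc, K1, K2, kcat, E0)
  floored <- rep(FALSE, length(v))
  if (noise_sd > 0) {
    v <- with_seed(seed, v + stats::rnorm(length(v), 0, noise_sd))
    floored <- v < 0
    v[floored] <- 0
  }
  d <- initial_rate_data(conc, v, substrate = substrate, E0 = E0)
  d$floored <- floored
  attr(d, "truth") <- list(K1 = K1, K2 = K2, kcat = kcat, E0 = E0,
                           seed = seed, noise_sd = noise_sd,
                           generator = "gacakin::sim_initial_rate_data",
                           version = 1)
  d
}

# Largest-remainder allocation of n items to fractional shares: counts are
# exact (floor plus one for the largest remainders), so test expectations
# are deterministic.
largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  counts
}

ALN_WIDTH <- 60
ALN_POS304 <- 10
ALN_POS348 <- 25
ALN_MOTIF_START <- 40
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a labeled synthetic GGDEF alignment
#'
#' Emits a gap-free reference sequence (`GacA_ref`, a Hypr-type template)
#' plus `n` sequences with prescribed residues at the signature columns,
#' sampled per family template:
#'
#' * `canonical`: Asp at the selectivity position, Arg at the cross-dimer
#'   position, motif `GG[D/E]EF` (central residue drawn D or E);
#' * `hypr`: Ser or Thr at the selectivity position, Tyr at the cross-dimer
#'   position, motif `GGDE[F/Y]` (central residue always D -- the Ser-Thr
#'   class never tolerates a central E);
#' * `unclassifiable`: a gap placed at one signature column.
#'
#' All other columns hold random residues.  Family counts follow
#' largest-remainder allocation (exact), or multinomial sampling when
#' `mode = "multinomial"`.
#'
#' @param n Number of sequences (excluding the reference).
#' @param fractions Named shares for `canonical`, `hypr`, `unclassifiable`
#'   (must sum to 1).
#' @param seed RNG seed.
#' @param mode `"exact"` (largest remainder, default) or `"multinomial"`.
#' @return List of class `"synthetic_alignment"`: `alignment` (named
#'   character vector, reference first), `truth` (data frame `id`,
#'   `family`), `reference_id`, `positions` (list with `motif_start`,
#'   `pos348`, `pos304` ungapped reference positions), `seed`.
#' @export
sim_alignment <- function(n = 100,
                          fractions = c(canonical = 0.6, hypr = 0.3,
                                        unclassifiable = 0.1),
                          seed = 1, mode = c("exact", "multinomial")) {
  mode <- match.arg(mode)
  need <- c("canonical", "hypr", "unclassifiable")
  if (!all(need %in% names(fractions)) ||
      abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0))
    stop("fractions must be named ", paste(need, collapse = "/"),
         " and sum to 1", call. = FALSE)

  sig_cols <- c(ALN_POS304, ALN_POS348, ALN_MOTIF_START + 0:4)

  with_seed(seed, {
    counts <- if (mode == "exact") largest_remainder(n, fractions[need])
              else as.numeric(stats::rmultinom(1, n, fractions[need]))
    names(counts) <- need
    family <- rep(need, counts)

    ref <- sample(AA20, ALN_WIDTH, replace = TRUE)
    ref[ALN_POS304] <- "Y"
    ref[ALN_POS348] <- "S"
    ref[ALN_MOTIF_START + 0:4] <- c("G", "G", "D", "E", "F")

    make_seq <- function(fam) {
      s <- sample(AA20, ALN_WIDTH, replace = TRUE)
      if (fam == "canonical") {
        s[ALN_POS304] <- "R"
        s[ALN_POS348] <- "D"
        s[ALN_MOTIF_START + 0:4] <- c("G", "G", sample(c("D", "E"), 1),
                                      "E", "F")
      } else if (fam == "hypr") {
        s[ALN_POS304] <- "Y"
        s[ALN_POS348] <- sample(c("S", "T"), 1)
        s[ALN_MOTIF_START + 0:4] <- c("G", "G", "D", "E",
                                      sample(c("F", "Y"), 1))
      } else {
        s[sample(sig_cols, 1)] <- "-"
      }
      paste(s, collapse = "")
    }

    seqs <- vapply(family, make_seq, character(1))
    ids <- sprintf("seq%04d", seq_along(seqs))
    names(seqs) <- ids
    alignment <- c(GacA_ref = paste(ref, collapse = ""), seqs)

    structure(list(alignment = alignment,
                   truth = data.frame(id = ids, family = family,
                                      row.names = NULL),
                   reference_id = "GacA_ref",
                   positions = list(motif_start = ALN_MOTIF_START,
                                    pos348 = ALN_POS348,
                                    pos304 = ALN_POS304),
                   seed = seed, mode = mode,
                   generator = "gacakin::sim_alignment", version = 1),
              class = "synthetic_alignment")
  })
}

#' @export
print.synthetic_alignment <- function(x, ...) {
  cat(sprintf(
    "Synthetic GGDEF alignment: %d sequences + reference '%s' (seed %d)\n",
    nrow(x$truth), x$reference_id, x$seed))
  print(table(x$truth$family))
  invisible(x)
}
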