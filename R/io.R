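# Plain-text I/O.  All tables are TSV with a leading '#' comment block that
# declares units and generator metadata; alignments are written as aligned
# FASTA via Biostrings; sidecars are JSON.

write_tsv_commented <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a trajectory as tidy TSV
#'
#' One row per time point: `time` plus the 14 species columns, with a
#' header comment declaring units.
#'
#' @param traj A `"cyclase_trajectory"`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write_tsv_commented(
    as.data.frame(traj), path,
    c("cyclase reaction trajectory",
      "time in seconds; concentrations in micromolar",
      sprintf("mode: %s; homeostasis: %s", traj$mode,
              traj$conditions$homeostasis)))
}

#' Write / read a product-ratio dataset as TSV
#'
#' @param data A [product_ratio_data()] object.
#' @param path File path.
#' @return `write_product_ratio_data()` the path invisibly;
#'   `read_product_ratio_data()` a [product_ratio_data()] object.
#' @export
write_product_ratio_data <- function(data, path) {
  truth <- attr(data, "truth")
  com <- c("product-ratio dataset",
           "A0, G0 in micromolar; fraction_* dimensionless (sum 1)")
  if (!is.null(truth))
    com <- c(com, sprintf("generator: %s (version %s, seed %s, noise_sd %s)",
                          truth$generator, truth$version, truth$seed,
                          truth$noise_sd))
  write_tsv_commented(as.data.frame(data), path, com)
}

#' @rdname write_product_ratio_data
#' @export
read_product_ratio_data <- function(path) {
  d <- read_tsv_commented(path)
  product_ratio_data(d$A0, d$G0, d$fraction_cdiG, d$fraction_cGAMP,
                     d$fraction_cdiA,
                     replicate = if ("replicate" %in% names(d)) d$replicate)
}

#' Write / read an initial-rate dataset as TSV
#'
#' @param data An [initial_rate_data()] object.
#' @param path File path.
#' @return `write_initial_rate_data()` the path invisibly;
#'   `read_initial_rate_data()` an [initial_rate_data()] object.
#' @export
write_initial_rate_data <- function(data, path) {
  write_tsv_commented(
    as.data.frame(data), path,
    c("single-substrate initial-rate dataset",
      "conc in micromolar; rate in micromolar per second",
      sprintf("substrate: %s; E0_uM: %g", attr(data, "substrate"),
              attr(data, "E0"))))
}

#' @rdname write_initial_rate_data
#' @export
read_initial_rate_data <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- grep("^# substrate:", hdr, value = TRUE)
  substrate <- sub("^# substrate: (\\w+);.*$", "\\1", meta)
  E0 <- as.numeric(sub("^.*E0_uM: ([0-9.eE+-]+).*$", "\\1", meta))
  d <- read_tsv_commented(path)
  out <- initial_rate_data(d$conc, d$rate, substrate = substrate, E0 = E0)
  if ("floored" %in% names(d)) out$floored <- d$floored
  out
}

#' Export a grid-search error surface
#'
#' Writes the error matrix as TSV (rows = `K_A|G` axis, columns = `K_G|A`
#' axis) plus a JSON sidecar carrying the axes, argmin, metric label,
#' settings and an MD5 hash of the settings.
#'
#' @param fit A `"heterodimer_fit"` object.
#' @param path Output TSV path; the sidecar gets `.json` appended.
#' @return The TSV path, invisibly.
#' @export
write_error_surface <- function(fit, path) {
  m <- as.data.frame(fit$error)
  names(m) <- paste0("KGA_", fit$KGA_grid)
  m <- cbind(KAG = fit$KAG_grid, m)
  write_tsv_commented(
    m, path,
    c("grid-search error surface",
      "rows: K_A|G axis (uM); columns: K_G|A axis (uM)",
      paste("metric:", fit$metric)))
  side <- list(KAG_grid = fit$KAG_grid, KGA_grid = fit$KGA_grid,
               argmin = list(KAG = fit$KAG, KGA = fit$KGA),
               minimum = fit$minimum, tie = fit$tie,
               n_eval = fit$n_eval, metric = fit$metric,
               settings = fit$settings,
               settings_hash = settings_hash(fit$settings))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a prediction scan as TSV
#'
#' @param scan A `"cyclase_scan"` data frame.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_scan <- function(scan, path) {
  s <- attr(scan, "settings")
  write_tsv_commented(
    as.data.frame(scan), path,
    c("clamped-substrate product-ratio scan",
      "A, G in micromolar; fraction_* dimensionless; flux_* in uM/s",
      sprintf("G_ref_uM: %g; E0_uM: %g; method: %s", s$G_ref, s$E0,
              s$method)))
}

#' Write a synthetic alignment as aligned FASTA plus truth sidecar
#'
#' @param syn A `"synthetic_alignment"` from [sim_alignment()].
#' @param path Output FASTA path; the JSON truth sidecar gets `.json`
#'   appended.
#' @return The FASTA path, invisibly.
#' @export
write_alignment <- function(syn, path) {
  aa <- Biostrings::AAStringSet(syn$alignment)
  Biostrings::writeXStringSet(aa, path, width = 80)
  side <- list(truth = syn$truth, reference_id = syn$reference_id,
               positions = syn$positions, seed = syn$seed,
               generator = syn$generator, version = syn$version)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Stable MD5 of a settings list (hash of its canonical JSON serialization).
settings_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
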