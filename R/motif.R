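#' Read a protein multiple alignment
#'
#' Thin wrapper over \pkg{Biostrings} that returns the alignment as a named
#' character vector of gapped sequences (equal widths).
#'
#' @param path Aligned FASTA or Stockholm file.
#' @param format `"fasta"` or `"stockholm"`.
#' @return Named character vector of aligned (gapped) sequences.
#' @export
read_alignment <- function(path, format = c("fasta", "stockholm")) {
  format <- match.arg(format)
  msa <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(msa)
  if (length(unique(nchar(seqs))) != 1)
    stop("alignment rows have unequal widths", call. = FALSE)
  seqs
}

GAP_CHARS <- c("-", ".")

#' Map ungapped reference positions to alignment columns
#'
#' Given a reference sequence inside the alignment, finds the alignment
#' columns holding the reference's residues at the requested ungapped
#' positions (1-based on both sides).  This is how structure-derived residue
#' numbers (e.g. the selectivity positions of a reference enzyme) are
#' located in an arbitrary alignment.
#'
#' @param alignment Named character vector of gapped sequences (equal
#'   widths), e.g. from [read_alignment()].
#' @param reference_id Name of the reference sequence.
#' @param positions Ungapped residue indices on the reference.
#' @return Integer vector of alignment columns, one per position.
#' @examples
#' map_columns(c(ref = "G-GDEF"), "ref", 2)  # column 3
#' @export
map_columns <- function(alignment, reference_id, positions) {
  if (!reference_id %in% names(alignment))
    stop("reference sequence '", reference_id, "' not in alignment",
         call. = FALSE)
  chars <- strsplit(alignment[[reference_id]], "")[[1]]
  notgap <- !(chars %in% GAP_CHARS)
  ungapped <- cumsum(notgap)
  nres <- sum(notgap)
  if (any(positions < 1) || any(positions > nres))
    stop("position(s) beyond the reference's ungapped length (", nres, ")",
         call. = FALSE)
  vapply(positions,
         function(p) which(notgap & ungapped == p)[1],
         integer(1))
}

#' Locate the GGDEF signature and selectivity columns
#'
#' Maps the three features of the GGDEF-domain classification onto alignment
#' columns via a named reference sequence: the 5-column signature motif
#' (starting at `motif_start`), the Watson--Crick-face selectivity position
#' (`pos348`; Ser/Thr there marks the promiscuous Hypr subclass, Asp the
#' canonical GTP-specific one) and the cross-dimer stacking position
#' (`pos304`; Arg in canonical diguanylate cyclases, Tyr in Hypr enzymes).
#' Position numbers are in the reference's own (GmGacA-style) numbering;
#' `offset` accommodates homologs whose numbering is shifted (e.g. -1 for
#' the one-residue-shorter GsGacA numbering).
#'
#' @param alignment Named character vector of gapped sequences.
#' @param reference_id Name of the reference sequence.
#' @param motif_start Ungapped position of the motif's first residue on the
#'   reference.
#' @param pos348,pos304 Ungapped selectivity positions on the reference.
#' @param offset Added to all three positions before mapping.
#' @return List with `motif` (5 columns), `pos348`, `pos304`.
#' @export
signature_columns <- function(alignment, reference_id, motif_start,
                              pos348, pos304, offset = 0) {
  cols <- map_columns(alignment, reference_id,
                      c(motif_start + offset + 0:4, pos348 + offset,
                        pos304 + offset))
  list(motif = cols[1:5], pos348 = cols[6], pos304 = cols[7])
}

#' Classify aligned GGDEF-domain sequences
#'
#' Reads, for every sequence, the 5-residue signature motif and the two
#' selectivity positions at the given alignment columns, then classifies:
#'
#' * `active`: the motif matches `[GAS]G[DE]E[FY]` -- the permissive
#'   signature pattern with the obligatory general-base glutamate at the
#'   fourth position -- with one structural override: a central Glu
#'   combined with Ser/Thr at the selectivity position (the "Ser/GGEEF"
#'   combination) is called inactive, because with the short Ser side chain
#'   the Glu-coordinated magnesium and the nucleobase contacts can no
#'   longer both be satisfied ("Goldilocks" spacing); the flexible Asp at
#'   the selectivity position tolerates either central residue.
#' * `family_hint`: `"hypr-like"` when the selectivity position holds Ser or
#'   Thr (promiscuous ATP+GTP enzymes), `"canonical-like"` for Asp
#'   (GTP-specific), otherwise `"other"`.
#'
#' Sequences with an alignment gap at any signature column are marked
#' unclassifiable and never imputed.  The `pattern_discrepancy` column
#' flags sequences whose call would differ under the shorter 4-position
#' pattern `[GAS]G[DE][FY]` that ignores the general-base position.
#'
#' @param alignment Named character vector of gapped sequences.
#' @param columns Column map from [signature_columns()].
#' @return Data frame of class `"motif_records"`: `id`, `motif`, `pos348`,
#'   `pos304`, `classifiable`, `active`, `family_hint`,
#'   `pattern_discrepancy`.
#' @export
classify_sequences <- function(alignment, columns) {
  widths <- unique(nchar(alignment))
  if (length(widths) != 1)
    stop("alignment rows have unequal widths", call. = FALSE)
  need <- c(columns$motif, columns$pos348, columns$pos304)
  if (any(need < 1) || any(need > widths))
    stop("signature columns fall outside the alignment width", call. = FALSE)

  rows <- lapply(names(alignment), function(id) {
    ch <- strsplit(alignment[[id]], "")[[1]]
    motif_ch <- ch[columns$motif]
    p348 <- ch[columns$pos348]
    p304 <- ch[columns$pos304]
    gapped <- any(c(motif_ch, p348, p304) %in% GAP_CHARS)
    motif <- paste(motif_ch, collapse = "")
    if (gapped) {
      return(data.frame(id = id, motif = motif, pos348 = p348,
                        pos304 = p304, classifiable = FALSE, active = NA,
                        family_hint = "unclassifiable",
                        pattern_discrepancy = FALSE))
    }
    goldilocks_block <- p348 %in% c("S", "T") && substr(motif, 3, 3) == "E"
    active5 <- grepl("^[GAS]G[DE]E[FY]$", motif) && !goldilocks_block
    active4 <- grepl("^[GAS]G[DE].[FY]$", motif) && !goldilocks_block
    family <- if (p348 %in% c("S", "T")) "hypr-like"
              else if (p348 == "D") "canonical-like" else "other"
    data.frame(id = id, motif = motif, pos348 = p348, pos304 = p304,
               classifiable = TRUE, active = active5, family_hint = family,
               pattern_discrepancy = active4 != active5)
  })
  structure(do.call(rbind, rows),
            class = c("motif_records", "data.frame"))
}

#' Summarize classified GGDEF sequences
#'
#' Cross-tabulates the selectivity-position class (Asp / Ser-Thr / other)
#' against the central motif residue (D / E / other) over the classifiable
#' records, reports per-class fractions, the count of Arg at the cross-dimer
#' stacking position, and the number of gapped (unclassifiable) records.
#'
#' @param records A `"motif_records"` data frame from
#'   [classify_sequences()].
#' @return List of class `"motif_summary"`: `n_total`, `n_classified`,
#'   `n_unclassifiable`, `cross_tab` (matrix), `fractions` (matrix; `NA`
#'   when nothing classified, with `fractions_defined = FALSE`),
#'   `central_by_family` (per-family fractions of central D vs E),
#'   `n_arg_pos304`, `n_active`.
#' @export
motif_summary <- function(records) {
  if (!inherits(records, "motif_records") || nrow(records) == 0)
    stop("records must be a non-empty motif_records data frame",
         call. = FALSE)
  cls <- records[records$classifiable, , drop = FALSE]
  p348_class <- factor(
    ifelse(cls$pos348 == "D", "Asp",
           ifelse(cls$pos348 %in% c("S", "T"), "Ser-Thr", "other")),
    levels = c("Asp", "Ser-Thr", "other"))
  centre <- substr(cls$motif, 3, 3)
  centre_class <- factor(
    ifelse(centre == "D", "D", ifelse(centre == "E", "E", "other")),
    levels = c("D", "E", "other"))
  tab <- table(p348_class, centre_class)
  defined <- nrow(cls) > 0
  fractions <- if (defined) tab / nrow(cls) else tab * NA_real_
  central_by_family <- t(apply(tab, 1, function(r)
    if (sum(r) > 0) r / sum(r) else r * NA_real_))

  structure(list(n_total = nrow(records), n_classified = nrow(cls),
                 n_unclassifiable = sum(!records$classifiable),
                 cross_tab = unclass(tab),
                 fractions = unclass(fractions),
                 fractions_defined = defined,
                 central_by_family = central_by_family,
                 n_arg_pos304 = sum(cls$pos304 == "R"),
                 n_active = sum(cls$active)),
            class = "motif_summary")
}

#' @export
print.motif_summary <- function(x, ...) {
  cat(sprintf("GGDEF motif summary: %d sequences (%d classified, %d gapped)\n",
              x$n_total, x$n_classified, x$n_unclassifiable))
  cat("  selectivity position x central motif residue:\n")
  print(x$cross_tab)
  if (x$fractions_defined && x$n_classified > 0) {
    cat(sprintf("  active (5-position signature): %d / %d\n",
                x$n_active, x$n_classified))
    cat(sprintf("  Arg at cross-dimer position: %d / %d\n",
                x$n_arg_pos304, x$n_classified))
  } else {
    cat("  no classifiable sequences: fractions undefined\n")
  }
  invisible(x)
}
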