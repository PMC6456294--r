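test_that("reference positions map through gaps to alignment columns", {
  aln <- c(ref = "G-GDEF", other = "GAGDEF")
  expect_equal(map_columns(aln, "ref", 2), 3)
  expect_equal(map_columns(aln, "ref", 1), 1)
  expect_equal(map_columns(aln, "ref", c(1, 5)), c(1, 6))
  expect_error(map_columns(aln, "ref", 7), "beyond")
  expect_error(map_columns(aln, "missing", 1), "not in alignment")
})

# Minimal hand-built alignment: col 1 = cross-dimer position, col 2 =
# selectivity position, cols 4-8 = signature motif.
toy_columns <- list(motif = 4:8, pos348 = 2, pos304 = 1)
toy_aln <- c(
  hypr_ok    = "YSxGGDEFx",  # Ser + GGDEF: active Hypr
  hypr_dead  = "YSxGGEEFx",  # Ser + central E: Goldilocks-inactive
  canon_ddef = "RDxGGDEFx",  # Asp tolerates either central residue
  canon_geef = "RDxGGEEFx",
  broken     = "RDxKGDEFx",  # first motif position outside [GAS]
  no_base    = "RDxGGDAFx",  # general-base Glu missing
  gappy      = "Y-xGGDEFx")  # gap at a signature column

test_that("signature classification follows the motif and Goldilocks rules", {
  rec <- classify_sequences(toy_aln, toy_columns)
  expect_s3_class(rec, "motif_records")
  get <- function(id, col) rec[rec$id == id, col]
  expect_true(get("hypr_ok", "active"))
  expect_equal(get("hypr_ok", "family_hint"), "hypr-like")
  expect_false(get("hypr_dead", "active"))
  expect_true(get("canon_ddef", "active"))
  expect_true(get("canon_geef", "active"))
  expect_equal(get("canon_geef", "family_hint"), "canonical-like")
  expect_false(get("broken", "active"))
  expect_false(get("no_base", "active"))
  expect_true(get("no_base", "pattern_discrepancy"))
  expect_false(get("gappy", "classifiable"))
  expect_equal(get("gappy", "family_hint"), "unclassifiable")
})

test_that("summaries count every record exactly once", {
  rec <- classify_sequences(toy_aln, toy_columns)
  s <- motif_summary(rec)
  expect_equal(s$n_total, length(toy_aln))
  expect_equal(s$n_classified + s$n_unclassifiable, s$n_total)
  expect_equal(sum(s$cross_tab), s$n_classified)
  expect_equal(sum(s$fractions), 1, tolerance = 1e-9)
})

test_that("central-residue split is tabulated per selectivity class", {
  # 6 Asp-class sequences with central D, 4 with central E
  aln <- c(
    stats::setNames(rep("RDxGGDEFx", 6), paste0("d", 1:6)),
    stats::setNames(rep("RDxGGEEFx", 4), paste0("e", 1:4)))
  s <- motif_summary(classify_sequences(aln, toy_columns))
  expect_equal(unname(s$central_by_family["Asp", c("D", "E")]),
               c(0.6, 0.4))
  expect_equal(s$n_arg_pos304, 10)
})

test_that("an all-gapped alignment yields a flagged, empty summary", {
  aln <- c(a = "Y-xGGDEFx", b = "YSx-GDEFx")
  s <- motif_summary(classify_sequences(aln, toy_columns))
  expect_equal(s$n_classified, 0)
  expect_false(s$fractions_defined && s$n_classified > 0)
})

test_that("summaries are invariant to sequence order", {
  syn <- sim_alignment(n = 40, seed = 3)
  cols <- signature_columns(syn$alignment, syn$reference_id,
                            syn$positions$motif_start,
                            syn$positions$pos348, syn$positions$pos304)
  s1 <- motif_summary(classify_sequences(syn$alignment, cols))
  perm <- sample(length(syn$alignment))
  s2 <- motif_summary(classify_sequences(syn$alignment[perm], cols))
  expect_equal(s1$cross_tab, s2$cross_tab)
  expect_equal(s1$n_arg_pos304, s2$n_arg_pos304)
})

test_that("classification round-trips the generator's ground truth", {
  syn <- sim_alignment(n = 120, seed = 11)
  cols <- signature_columns(syn$alignment, syn$reference_id,
                            syn$positions$motif_start,
                            syn$positions$pos348, syn$positions$pos304)
  rec <- classify_sequences(syn$alignment, cols)
  rec <- rec[rec$id != syn$reference_id, ]
  merged <- merge(rec, syn$truth, by = "id")
  expected <- c(canonical = "canonical-like", hypr = "hypr-like",
                unclassifiable = "unclassifiable")
  expect_identical(merged$family_hint,
                   unname(expected[merged$family]))
  # all non-gapped synthetic sequences carry an active signature
  expect_true(all(merged$active[merged$classifiable]))
})

test_that("numbering offsets shift the mapped columns", {
  syn <- sim_alignment(n = 5, seed = 2)
  c0 <- signature_columns(syn$alignment, syn$reference_id,
                          syn$positions$motif_start,
                          syn$positions$pos348, syn$positions$pos304)
  c1 <- signature_columns(syn$alignment, syn$reference_id,
                          syn$positions$motif_start + 1,
                          syn$positions$pos348 + 1,
                          syn$positions$pos304 + 1, offset = -1)
  expect_identical(c0, c1)
})
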