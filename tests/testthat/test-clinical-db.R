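rawRow <- function(fviii = "20", sev = "mild", type = "Point",
                   effect = "Missense", pos = 100, ...) {
  data.frame(mutation_type = type, variant_effect = effect,
             position_legacy = pos, fviii_c_raw = fviii,
             severity_reported = sev, stringsAsFactors = FALSE, ...)
}

test_that("activity strings sanitize by the published substitution rules", {
  raw <- rbind(
    rawRow("10 to 24"),            # range -> midpoint 17
    rawRow("< 1", sev = "severe"), # bound -> 0
    rawRow("\u00a0<\u00a01", sev = "severe"),  # non-breaking spaces tolerated
    rawRow("> 5", sev = "moderate"),           # bound -> 5
    rawRow("< 10"),                # bound -> 10
    rawRow("< 11"),                # bound -> 11
    rawRow("36.5")                 # plain numeric untouched
  )
  san <- sanitizeRecords(raw)
  expect_equal(nrow(san$exclusions), 0)
  expect_equal(san$records$fviii_c_value, c(17, 0, 0, 5, 10, 11, 36.5))
  # the two kinds of rewrites are logged as transformations
  expect_true(all(c("range_mean", "bound:<1") %in% san$transformations$rule))
})

test_that("ambiguous, inconsistent and out-of-schema records are dropped with rules", {
  raw <- rbind(
    rawRow(),                                      # kept
    rawRow(sev = "mild/moderate"),                 # ambiguous severity
    rawRow("0 to 2", sev = "severe"),              # range spans severity bands
    rawRow("< 2", sev = "moderate"),               # unlisted bound marker
    rawRow("NR"),                                  # non-numeric
    rawRow(""),                                    # missing activity
    rawRow("150"),                                 # above 100
    rawRow(type = "Deletion"),                     # wrong mutation type
    rawRow(effect = "Nonsense"),                   # wrong variant effect
    rawRow(pos = -5),                              # signal peptide
    rawRow(pos = 9999)                             # outside mature protein
  )
  san <- sanitizeRecords(raw)
  expect_equal(nrow(san$records), 1)
  expect_equal(nrow(san$exclusions), 10)
  expect_setequal(
    san$exclusions$rule,
    c("ambiguous_severity", "ambiguous_range", "non_numeric", "non_numeric",
      "missing_activity", "activity_above_100", "type_effect", "type_effect",
      "position_out_of_mature", "position_out_of_mature"))
  # every input row is accounted for exactly once
  expect_equal(nrow(raw), nrow(san$records) + nrow(san$exclusions))
  expect_false(anyDuplicated(san$exclusions$row_id) > 0)
})

test_that("stop codons and assay disagreements are removed", {
  raw <- rbind(
    cbind(rawRow(), protein_change = "Arg15*", fviii_c_1st = "20", fviii_c_2st = "20"),
    cbind(rawRow(), protein_change = "Ala10Val", fviii_c_1st = "20", fviii_c_2st = "55"),
    cbind(rawRow(), protein_change = "Ala10Val", fviii_c_1st = "20", fviii_c_2st = "20")
  )
  san <- sanitizeRecords(raw)
  expect_equal(nrow(san$records), 1)
  expect_setequal(san$exclusions$rule, c("stop_codon", "assay_disagreement"))
})

test_that("sanitation is idempotent and validates its schema", {
  raw <- rbind(rawRow("10 to 24"), rawRow("< 1", sev = "severe"), rawRow("77", sev = "zzz"))
  s1 <- sanitizeRecords(raw)
  s2 <- sanitizeRecords(s1$records)
  expect_equal(s2$records$fviii_c_value, s1$records$fviii_c_value)
  expect_equal(nrow(s2$exclusions), 0)
  expect_equal(nrow(s2$transformations), 0)
  expect_error(sanitizeRecords(raw[, -4]), "fviii_c_raw")
})

test_that("fisher association matches exact hypergeometric enumeration", {
  # table [[5,0],[0,5]]: p = 2 / C(10,5)
  res <- fisherAssociation(1:5, 6:10, 1:5)
  expect_equal(res$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$odds_ratio, Inf)
  # identical composition: OR 1, p 1
  res2 <- fisherAssociation(1:10, 11:20, c(1:5, 11:15))
  expect_equal(res2$odds_ratio, 1)
  expect_equal(res2$p_value, 1)
  # symmetry under swapping the groups
  set.seed(11)
  rep_pos <- sample(1:60, 25)
  pa <- fisherAssociation(1:30, 31:60, rep_pos)
  pb <- fisherAssociation(31:60, 1:30, rep_pos)
  expect_equal(pa$p_value, pb$p_value)
  # degenerate margin
  expect_warning(res3 <- fisherAssociation(1:3, 4:6, integer(0)), "margin")
  expect_equal(res3$p_value, 1)
  expect_error(fisherAssociation(1:3, 3:5, 1), "disjoint")
})

test_that("legacy numbering converts to HGVS by the signal-peptide offset", {
  expect_equal(legacyToHgvs(1942), 1961)
  expect_equal(legacyToHgvs(1751), 1770)
  expect_equal(legacyToHgvs(1), 20)
  expect_error(legacyToHgvs(0), "positive")
})
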