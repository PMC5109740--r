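test_that("cardinality regions cover the positive integers exactly once per axis", {
  for (axis in c("REGIONAL_LN", "DISTANT_ORGANS")) {
    regions <- cardinality_regions(axis)
    for (k in 1:50) {
      inside <- regions$lower <= k & (is.na(regions$upper) | k <= regions$upper)
      expect_equal(sum(inside), 1)
      expect_equal(region_for(axis, k), regions$label[inside])
    }
  }
})

test_that("region_for maps boundary counts to the published intervals", {
  expect_equal(region_for("REGIONAL_LN", 2), "C2OR3")
  expect_equal(region_for("REGIONAL_LN", 7), "C7PLUS")
  expect_equal(region_for("DISTANT_ORGANS", 1), "C1")
  expect_equal(region_for("REGIONAL_LN", c(4, 6)), c("C4TO6", "C4TO6"))
  expect_error(region_for("REGIONAL_LN", 0), "NoEvidence")
})

test_that("invasion depth rank is a strict total order over the eight sites", {
  ranks <- invasion_rank(invasion_depths)
  expect_equal(sort(ranks), 0:7)
  expect_equal(length(unique(ranks)), 8)
  # consistent with anatomy: submucosa shallower than subserosa, etc.
  expect_lt(invasion_rank("SUBMUCOSA"), invasion_rank("MUSCULARIS_PROPRIA"))
  expect_lt(invasion_rank("SUBSEROSA"), invasion_rank("VISCERAL_PERITONEUM"))
  expect_equal(which.max(invasion_rank(invasion_depths)),
               which(invasion_depths == "OTHER_ORGANS"))
})

test_that("validate_records accepts consistent records and localises breaches", {
  ok <- rec(invasion = "SUBSEROSA", rln_examined = 31, rln_positive = 0)
  expect_equal(nrow(validate_records(ok)), 0)

  v <- validate_records(rec(invasion = "SUBSEROSA", rln_examined = 3, rln_positive = 5))
  expect_equal(v$field, "rln_positive")
  expect_equal(v$severity, "error")

  v <- validate_records(rec(invasion = "SUBSEROSA", rln_examined = 5,
                            peritoneal_mets = TRUE, distant_organ_count = 0))
  expect_equal(v$field, "peritoneal_mets")

  # deep invasion cannot be confined
  v <- validate_records(rec(invasion = "SUBSEROSA", growth = "CONFINED",
                            rln_examined = 5))
  expect_true(any(v$field == "growth" & v$severity == "error"))

  # invasion details are only allowed on an assessed T axis
  v <- validate_records(rec(t_epistemic = "NO_EVIDENCE", invasion = "SUBMUCOSA",
                            growth = "INFILTRATIVE", rln_examined = 5))
  expect_true(any(v$field == "invasion"))

  # zero nodes examined with an assessed N axis is suspicious, not fatal
  v <- validate_records(rec(invasion = "SUBMUCOSA", rln_examined = 0))
  expect_equal(v$severity, "warning")
  expect_equal(nrow(tnm_classify(rec(invasion = "SUBMUCOSA", rln_examined = 0))), 1)
})

test_that("tnm_rank orders codes within an axis and leaves X/T0 unranked", {
  expect_true(all(diff(tnm_rank("T", c("is", "1", "2", "3", "4a", "4b"))) > 0))
  expect_true(all(diff(tnm_rank("N", c("0", "1a", "1b", "1c", "2a", "2b"))) > 0))
  expect_true(is.na(tnm_rank("T", "X")) && is.na(tnm_rank("T", "0")))
  expect_true(is.na(tnm_rank("N", "X")))
  expect_error(tnm_rank("M", "2"), "Unknown")
})
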