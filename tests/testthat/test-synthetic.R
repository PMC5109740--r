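test_that("the canonical space has 550 distinct states that all materialize validly", {
  states <- enumerate_canonical_states()
  expect_equal(nrow(states), 10 * 11 * 5)
  records <- canonical_records(states)
  expect_equal(nrow(dplyr::distinct(records[, -1])), nrow(states))
  v <- validate_records(records)
  expect_equal(sum(v$severity == "error"), 0)

  # contains the deposits-without-metastasis example state
  expect_true(any(states$t_state == "SUBSEROSA" & states$n_state == "ASSESSED" &
                    states$n_region == "NONE" & states$deposits &
                    states$m_region == "NONE" & !states$peritoneal))
})

test_that("classification over the canonical space covers every code", {
  s <- canonical_setup()
  expect_setequal(code_value(s$classified$t), c("X", "0", "is", "1", "2", "3", "4a", "4b"))
  expect_setequal(code_value(s$classified$n), c("X", "0", "1a", "1b", "1c", "2a", "2b"))
  expect_setequal(code_value(s$classified$m), c("0", "1a", "1b"))
})

test_that("sample_records is seeded, valid and exhaustive over N categories", {
  expect_equal(nrow(sample_records(0, seed = 7)), 0)
  a <- sample_records(200, seed = 42)
  b <- sample_records(200, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, sample_records(200, seed = 43)))
  expect_equal(sum(validate_records(a)$severity == "error"), 0)

  big <- sample_records(1000, seed = 1)
  expect_setequal(code_value(tnm_classify(big)$n),
                  c("X", "0", "1a", "1b", "1c", "2a", "2b"))
})

test_that("the packaged fixture matches the published expert codes table", {
  fx <- table5_fixture()
  expect_equal(nrow(fx$records), 15)
  expect_equal(unname(unlist(fx$gold[7, c("t", "n", "m")])), c("pT3", "pN1c", "M0"))
  expect_equal(unname(unlist(fx$gold[15, c("t", "n", "m")])), c("pT4a", "pN2b", "M1a"))
})
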