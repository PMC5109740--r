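test_that("T assignment follows the invasion-depth criteria", {
  cases <- tibble::tribble(
    ~invasion,             ~expected,
    "EPITHELIUM",          "pTis",
    "LAMINA_PROPRIA",      "pTis",
    "SUBMUCOSA",           "pT1",
    "MUSCULARIS_PROPRIA",  "pT2",
    "SUBSEROSA",           "pT3",
    "ADVENTITIA",          "pT3",
    "VISCERAL_PERITONEUM", "pT4a",
    "OTHER_ORGANS",        "pT4b"
  )
  got <- assign_t(rec(invasion = cases$invasion, rln_examined = 10))
  expect_equal(got$code, cases$expected)

  expect_equal(assign_t(rec(t_epistemic = "NO_ASSESSMENT", rln_examined = 5))$code, "pTX")
  noev <- rec(t_epistemic = "NO_EVIDENCE", rln_examined = 5,
              assessment_mode = "CLINICAL")
  expect_equal(assign_t(noev)$code, "cT0")
})

test_that("N assignment follows node counts and the deposit rule", {
  cases <- tibble::tribble(
    ~rln_positive, ~deposits, ~expected,
    0L,  FALSE, "pN0",
    0L,  TRUE,  "pN1c",
    1L,  FALSE, "pN1a",
    2L,  FALSE, "pN1b",
    3L,  FALSE, "pN1b",
    4L,  FALSE, "pN2a",
    6L,  FALSE, "pN2a",
    7L,  FALSE, "pN2b",
    29L, FALSE, "pN2b",
    2L,  TRUE,  "pN1b"   # deposits are ignored once nodes are positive
  )
  got <- assign_n(rec(invasion = "SUBSEROSA", rln_examined = 40,
                      rln_positive = cases$rln_positive,
                      tumour_deposits = cases$deposits))
  expect_equal(got$code, cases$expected)
  expect_equal(assign_n(rec(invasion = "SUBSEROSA", n_epistemic = "NO_ASSESSMENT",
                            rln_examined = 0))$code, "pNX")
})

test_that("M assignment distinguishes one organ from several or the peritoneum", {
  cases <- tibble::tribble(
    ~organs, ~peritoneal, ~expected,
    0L, FALSE, "M0",
    1L, FALSE, "M1a",
    2L, FALSE, "M1b",
    1L, TRUE,  "M1b"
  )
  got <- assign_m(rec(invasion = "SUBSEROSA", rln_examined = 10,
                      distant_organ_count = cases$organs,
                      peritoneal_mets = cases$peritoneal))
  expect_equal(got$code, cases$expected)
  # the code object still records pathological confirmation of metastases
  expect_equal(got$modifier, c("none", "p", "p", "p"))
})

test_that("published example rows render the expert strings", {
  expect_equal(
    tnm_classify(rec(invasion = "SUBSEROSA", rln_examined = 31, rln_positive = 0))$tnm,
    "pT3pN0M0")
  expect_equal(
    tnm_classify(rec(invasion = "VISCERAL_PERITONEUM", rln_examined = 40,
                     rln_positive = 29))$tnm,
    "pT4apN2bM0")
  expect_equal(
    tnm_classify(rec(invasion = "SUBSEROSA", rln_examined = 20,
                     tumour_deposits = TRUE))$tnm,
    "pT3pN1cM0")
})

test_that("classification is pure: same input, same output", {
  r <- rec(invasion = c("SUBMUCOSA", "OTHER_ORGANS"), rln_examined = 12,
           rln_positive = c(0, 6))
  expect_identical(tnm_classify(r), tnm_classify(r))
})

test_that("classification rejects inconsistent records, naming the violation", {
  bad <- rec(invasion = "SUBSEROSA", rln_examined = 3, rln_positive = 5)
  expect_error(tnm_classify(bad), "rln_positive")
})

test_that("N rank is non-decreasing in the positive-node count", {
  counts <- 0:30
  got <- assign_n(rec(invasion = "SUBSEROSA", rln_examined = 40,
                      rln_positive = counts))
  expect_true(all(diff(got$rank) >= 0))
})

test_that("T rank is non-decreasing in invasion depth", {
  got <- assign_t(rec(invasion = invasion_depths, rln_examined = 10))
  expect_true(all(diff(got$rank) >= 0))
})

test_that("every canonical state gets exactly one code per axis", {
  s <- canonical_setup()
  res <- s$classified
  expect_equal(nrow(res), 550)
  expect_true(all(!is.na(res$t) & !is.na(res$n) & !is.na(res$m)))
  expect_true(all(code_value(res$t) %in% c("X", "0", "is", "1", "2", "3", "4a", "4b")))
  expect_true(all(code_value(res$n) %in% c("X", "0", "1a", "1b", "1c", "2a", "2b")))
  expect_true(all(code_value(res$m) %in% c("0", "1a", "1b")))
})
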