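test_that("the axiom set is deterministic and structurally sound", {
  a <- build_axiom_set()
  b <- build_axiom_set()
  expect_identical(owl_axiom_strings(a), owl_axiom_strings(b))

  # 35 representational units: 8 T values x {c,p}, 7 N values x {c,p},
  # M0/M1a/M1b plus pM1a/pM1b
  expect_equal(sum(a$concepts$category == "unit"), 35)
  expect_equal(nrow(a$relations), 7)
  expect_equal(a$relations$inverse[a$relations$name == "represents"],
               "isRepresentedBy")

  # exactly one equivalence axiom per defined concept
  equiv_lhs <- vapply(Filter(function(x) x$kind == "equivalentTo", a$axioms),
                      function(x) x$lhs$name, "")
  defined <- a$concepts$name[a$concepts$category == "defined"]
  expect_equal(sort(equiv_lhs), sort(defined))
  expect_equal(anyDuplicated(equiv_lhs), 0)

  # every concept referenced in an axiom is declared
  referenced <- unique(unlist(lapply(a$axioms, function(ax) {
    ops <- c(list(ax$lhs, ax$rhs), ax$operands)
    unlist(lapply(Filter(Negate(is.null), ops), tnmstage:::expr_named_concepts))
  })))
  expect_true(all(referenced %in% a$concepts$name))

  expect_error(build_axiom_set(version = "6"), "version")
})

test_that("unit-bearing concepts carry existential and closure representation axioms", {
  a <- build_axiom_set()
  strings <- owl_axiom_strings(a)
  # the submucosa concept conjoins an invasive-confinement quality with a
  # submucosa inclusion, and closes its units with the non-unit escape
  expect_true(any(grepl(
    "EquivalentTo\\(InvasiveTumourOfSubmucosaOfColonAndRectum And\\(.*Confinement.*SubmucosaOfLargeIntestine",
    strings)))
  expect_true(any(grepl(
    "SubClassOf\\(InvasiveTumourOfSubmucosaOfColonAndRectum Only\\(isRepresentedBy Or\\(.*Not\\(RepresentationalUnitInTNMClassification\\)",
    strings)))
  # distant metastases are defined by negated inclusion in regional nodes
  expect_true(any(grepl(
    "EquivalentTo\\(DistantMetastasisOfColonAndRectumTumour And\\(.*Not\\(Some\\(isIncludedIn ColonAndRectumRegionalLymphNode\\)\\)",
    strings)))
  # each unit-bearing concept has one Some- and one Only-representation axiom
  for (concept in a$units$concept) {
    some_n <- sum(grepl(paste0("^SubClassOf\\(", concept, " Some\\(isRepresentedBy"),
                        strings))
    only_n <- sum(grepl(paste0("^SubClassOf\\(", concept, " Only\\(isRepresentedBy"),
                        strings))
    expect_equal(c(some_n, only_n), c(1, 1))
  }
})

test_that("model checking realizes the published example states correctly", {
  a <- build_axiom_set()
  states <- enumerate_canonical_states()

  # tumour deposits without nodal metastases -> the N1c aggregate concept
  st <- states[states$t_state == "SUBSEROSA" & states$n_state == "ASSESSED" &
                 states$n_region == "NONE" & states$deposits &
                 states$m_region == "NONE", ]
  r <- realize_instance(st, a)
  expect_true(
    "TumourOfColonAndRectumWithTumourDepositsWithoutRegionalLymphNodeMetastasis" %in%
      r$matched)
  expect_equal(r$codes$value[r$codes$axis == "N"], "1c")

  # seven or more positive nodes -> the 7-or-more aggregate concept
  st <- states[states$t_state == "VISCERAL_PERITONEUM" & states$n_region == "C7PLUS" &
                 !states$deposits & states$m_region == "NONE", ]
  r <- realize_instance(st, a)
  expect_true("TumourOfColonAndRectumWith7OrMoreMetastaticRegionalLymphNodes" %in%
                r$matched)
  expect_equal(r$codes$value[r$codes$axis == "N"], "2b")

  # a state outside the canonical space is rejected
  bogus <- st
  bogus$t_state <- "LIVER"
  expect_error(realize_instance(bogus, a), "canonical")
})

test_that("ruleset and model-checking oracle agree on every canonical state", {
  s <- canonical_setup()
  realized <- oracle_realizations()
  for (i in seq_len(nrow(s$states))) {
    oracle <- realized[[i]]$codes
    expect_identical(
      stats::setNames(oracle$value, oracle$axis),
      c(T = code_value(s$classified$t[i]),
        N = code_value(s$classified$n[i]),
        M = code_value(s$classified$m[i]))
    )
  }
})

test_that("no defined concept is unsatisfiable over the canonical space", {
  s <- canonical_setup()
  realized <- oracle_realizations()
  defined <- s$axioms$concepts$name[s$axioms$concepts$category == "defined"]
  nonempty <- unique(unlist(lapply(realized, function(r) {
    names(Filter(length, r$extensions[defined]))
  })))
  expect_setequal(nonempty, defined)
})

test_that("no canonical state matches two unit-bearing concepts on one axis", {
  s <- canonical_setup()
  realized <- oracle_realizations()
  for (r in realized) {
    matched <- s$axioms$units[s$axioms$units$concept %in% r$matched, ]
    expect_equal(unname(table(factor(matched$axis, levels = c("T", "N", "M")))),
                 c(1L, 1L, 1L), ignore_attr = TRUE)
  }
})
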