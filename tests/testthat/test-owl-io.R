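test_that("OWL export re-parses to the same axiom multiset in all three syntaxes", {
  a <- build_axiom_set()
  reference <- owl_axiom_strings(a)
  parsed <- list()
  for (syntax in c("turtle", "rdfxml", "functional")) {
    doc <- export_owl(a, syntax = syntax)
    p <- parse_owl(text = doc, syntax = syntax, base_iri = a$base_iri)
    expect_identical(owl_axiom_strings(p), reference)
    expect_setequal(p$concepts, a$concepts$name)
    parsed[[syntax]] <- p
  }
  # syntax independence: same axiom multiset whichever serialization is read
  expect_identical(owl_axiom_strings(parsed$turtle),
                   owl_axiom_strings(parsed$rdfxml))
  expect_identical(owl_axiom_strings(parsed$turtle),
                   owl_axiom_strings(parsed$functional))
  expect_error(export_owl(a, syntax = "manchester"), "arg")
})

test_that("the export declares the seven relations as object properties", {
  a <- build_axiom_set()
  p <- parse_owl(text = export_owl(a, syntax = "turtle"), syntax = "turtle",
                 base_iri = a$base_iri)
  expect_setequal(p$relations,
                  c("represents", "isRepresentedBy", "locatedIn", "isIncludedIn",
                    "hasPart", "isBearerOf", "projectsOnto"))
  expect_true(nrow(p$inverses) >= 1)
  expect_true(any(p$inverses$a == "isRepresentedBy" & p$inverses$b == "represents" |
                    p$inverses$a == "represents" & p$inverses$b == "isRepresentedBy"))
})

test_that("export -> re-parse -> re-export is idempotent at the triple level", {
  a <- build_axiom_set()
  g1 <- read_graph(text = export_owl(a, syntax = "turtle"), format = "turtle")
  g2 <- read_graph(text = write_graph(g1, format = "turtle"), format = "turtle")
  expect_true(tnmstage:::same_graph(g1, g2))
  g3 <- read_graph(text = write_graph(g1, format = "rdfxml"), format = "rdfxml")
  expect_true(tnmstage:::same_graph(g1, g3))
})

test_that("an independent RDF parser accepts the exported serializations", {
  a <- build_axiom_set()
  ttl <- tempfile(fileext = ".ttl")
  xml <- tempfile(fileext = ".rdf")
  export_owl(a, path = ttl, syntax = "turtle")
  export_owl(a, path = xml, syntax = "rdfxml")
  script <- paste(
    "import sys, rdflib",
    "g1 = rdflib.Graph(); g1.parse(sys.argv[1], format='turtle')",
    "g2 = rdflib.Graph(); g2.parse(sys.argv[2], format='xml')",
    "assert len(g1) == len(g2) and len(g1) > 0",
    "print(len(g1))",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), ttl, xml), stdout = TRUE,
            stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  n_triples <- suppressWarnings(as.integer(out[length(out)]))
  expect_equal(n_triples, nrow(read_graph(ttl, format = "turtle")))
})
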