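Package: tnmstage
Title: Rule-Based and Ontology-Based TNM Staging of Colorectal Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns TNM (version 7) T, N and M codes to colorectal pathology
    records with a deterministic rule engine, builds the matching
    description-logic axiom set (representational units, defined tumour and
    tumour-aggregate concepts, closure axioms) and exports it as an OWL 2
    ontology in Turtle, RDF/XML and functional syntax. A brute-force finite
    model checker realizes instances against the axiom set and serves as the
    semantic oracle for the rule engine. Includes readers and writers for
    tabular pathology records and RDF instance graphs, a classification report
    with expert-agreement summaries, an exhaustive enumeration of the canonical
    record space, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    xml2,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
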