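# Shared, lazily computed fixtures: the canonical state space, its
# materialized records and rule-based classification, and the model-checking
# realization of every state. Computed once per test run.

.shared <- new.env(parent = emptyenv())

canonical_setup <- function() {
  if (is.null(.shared$states)) {
    .shared$axioms <- build_axiom_set()
    .shared$states <- enumerate_canonical_states()
    .shared$records <- canonical_records(.shared$states)
    .shared$classified <- tnm_classify(.shared$records)
  }
  .shared
}

# realize every canonical state once; list of realize_instance() results
oracle_realizations <- function() {
  s <- canonical_setup()
  if (is.null(.shared$realized)) {
    .shared$realized <- lapply(seq_len(nrow(s$states)), function(i) {
      realize_instance(s$states[i, ], s$axioms)
    })
  }
  .shared$realized
}

# strip the c/p prefix and axis letter, leaving the bare value ("pT4a" -> "4a")
code_value <- function(code) sub("^[cp]?[TNM]", "", code)

# one-record tibble shorthand for rule tests
rec <- function(...) tnm_records(...)
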