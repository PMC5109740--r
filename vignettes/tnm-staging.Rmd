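---
title: "Colorectal TNM staging: the rule engine, the axiom set and the model-checking oracle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorectal TNM staging: the rule engine, the axiom set and the model-checking oracle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnmstage)
library(dplyr)
```

## The staging problem

TNM describes the anatomical extent of a malignant tumour along three
independent axes: T for the primary tumour, N for metastases in *regional*
lymph nodes, and M for distant metastases. For colorectal carcinoma under
TNM version 7, the axes depend on a small set of findings a pathologist
records for every resected specimen:

* **T** — the deepest layer of the gut wall the tumour invades. Tumour
  confined to the epithelium or lamina propria is carcinoma in situ (Tis);
  invasion of the submucosa is T1, of the muscularis propria T2, of the
  subserosa or the non-peritonealized pericolic surface (adventitia) T3, of
  the visceral peritoneum T4a, and of adjacent organs T4b. TX marks an
  unassessable primary and T0 an assessed specimen with no evidence of a
  primary tumour.
* **N** — the count of tumour-positive regional lymph nodes: one node N1a,
  2–3 nodes N1b, 4–6 nodes N2a, 7 or more N2b. Pericolorectal tumour
  deposits (satellites) *without* any nodal metastasis ground N1c; once any
  node is positive, the count alone governs. NX marks nodes that could not
  be assessed.
* **M** — the number of distantly involved organs or sites: none M0, exactly
  one M1a, several — or any peritoneal involvement — M1b.

The prefix `p` (pathological) or `c` (clinical) records the evidence level
of the assessment; reports conventionally print the M axis unprefixed.

`tnmstage` implements this classification three times over, on purpose:

1. as a **compiled rule engine** (`assign_t()`, `assign_n()`, `assign_m()`,
   `tnm_classify()`) operating on tibbles of pathology records;
2. as a **description-logic axiom set** (`build_axiom_set()`) in which every
   staging criterion is a defined concept with necessary-and-sufficient
   conditions, exportable as an OWL 2 ontology;
3. as a **brute-force model checker** (`realize_instance()`) that renders a
   record as a finite instance model and evaluates the axioms over it.

The third is the package's internal oracle: the rule engine and the
axiom set are written independently, and the test suite proves them
extensionally equal over the entire canonical input space.

## Records and validation

A pathology record is one row of a tibble: invasion depth and growth
pattern, examined and positive regional-node counts, the tumour-deposit
flag, the distant-organ count and the intraperitoneal flag, plus epistemic
status per axis and the assessment mode.

```{r}
records <- tnm_records(
  invasion = c("SUBSEROSA", "VISCERAL_PERITONEUM"),
  rln_examined = c(20, 24), rln_positive = c(0, 15),
  tumour_deposits = c(TRUE, FALSE),
  distant_organ_count = c(0, 1)
)
tnm_classify(records)
```

`validate_records()` returns violations as data rather than raising: a
record with more positive than examined nodes, peritoneal metastases
without a distant organ, invasion details on an unassessed T axis, or a
confined growth pattern beyond the lamina propria is inconsistent input
and refused by the classifier. One situation is flagged as a warning but
still classified: an assessed N axis with zero nodes examined. No
minimum-node rule enters N assignment — the examined count is carried for
provenance only, and NX arises solely from an explicit no-assessment.

Two modelling choices deserve note. The depth vocabulary includes the
muscularis propria (T2) and invasion of adjacent organs (T4b) alongside
the mucosal and serosal layers, so that every published code is reachable.
The adventitia — the non-peritonealized surface — maps to T3, consistent
with its position between the subserosa and the visceral peritoneum; we
know of no printed criterion making it a T4 ground, and keep it at T3.

## The axiom set

`build_axiom_set()` constructs the ontology programmatically: seven object
properties (`represents`/`isRepresentedBy` as an inverse pair, `locatedIn`,
`isIncludedIn`, `hasPart`, `isBearerOf`, `projectsOnto`), upper-type stubs
(`MaterialObject`, `Quality`, `InformationObject`), anatomical concepts as
opaque names, and one *representational unit* concept per TNM code value
and modifier — 16 T units, 14 N units and 5 M units (M0, M1a, M1b, pM1a,
pM1b), 35 in total. Counts never appear as integers: they are abstracted
into disjoint *cardinality value regions* (1, 2-or-3, 4-to-6, 7-or-more
for nodes; 1, 2-or-more for distant organs), and a quality individual
borne by the tumour aggregate `projectsOnto` its region.

Each staging criterion is a defined concept with exactly one equivalence
axiom, e.g. the T1 criterion conjoins an invasive-confinement quality with
inclusion in the submucosa, and the N1c criterion demands a tumour-deposit
part with no metastatic regional node. Unit-bearing concepts then carry an
existential `isRepresentedBy` axiom naming their units and the universal
closure axiom with the `or not RepresentationalUnitInTNMClassification`
escape, which admits non-TNM information objects while pinning down the
TNM units.

```{r}
ax <- build_axiom_set()
glance(ax)
```

Two choices were genuinely open:

* The epistemic grounds (no assessment / no evidence) are modelled as
  qualities projecting onto `NoAssessment`/`NoEvidence` values, one quality
  class per axis. A record with zero positive nodes materializes a
  regional-node `NoEvidence` quality; this lets N0 and N1c be defined
  positively instead of through closed-world negation over defined
  concepts.
* The node-count and organ-count qualities are both cardinalities borne by
  the same aggregate individual, so they are split into two subclasses of
  `Cardinality` (`MetastaticRegionalLymphNodeCardinality`,
  `DistantMetastasisOrganCardinality`). With a single shared quality class,
  an M-axis count of 1 would satisfy the N1a definition's quality
  restriction and break per-axis disjointness.

`export_owl()` serializes the set to Turtle, RDF/XML or OWL functional
syntax under a configurable base IRI; `parse_owl()` reads any of the three
back, and re-parsing reproduces the axiom multiset exactly. The axiom
counts of this reconstruction are a property of its own modelling choices;
they are validated structurally (one equivalence per defined concept,
per-axis unit disjointness, 35 units), not against any external figure.

## The canonical state space and the oracle

The staging criteria cannot distinguish two records that agree on: the T
state (2 epistemic states + 8 depths = 10), the N state (no assessment, or
{zero positive, four count regions} × deposits yes/no = 11), and the M
state (nothing, or {one, several organs} × peritoneum, of which
"one organ + peritoneum" collapses the organ to the peritoneum itself = 5).
`enumerate_canonical_states()` lists all 10 × 11 × 5 = 550 cells;
`canonical_records()` materializes each with the smallest count in every
region (1, 2, 4, 7; 2 distant organs) and examined nodes = positive + 10.

`realize_instance()` renders a state as a finite ABox — aggregate, tumour,
lymph-node, metastasis, deposit and quality individuals with their
relation edges — and evaluates every equivalence axiom set-theoretically
(conjunction as intersection, existential restriction through the edge
relation, universal restriction as its dual, negation as complement over
the model's individuals, which is sound here because each instance model
is complete for its record). Definitions are evaluated in declaration
order, which topologically orders their dependencies; a second pass
asserts the fixpoint. The units reachable from matched unit-bearing
concepts are the ontology's own answer.

```{r}
states <- enumerate_canonical_states()
st <- states |> filter(t_state == "SUBSEROSA", n_region == "NONE",
                       deposits, m_region == "NONE")
realize_instance(st, ax)$codes
```

The test suite checks, over all 550 states: totality and uniqueness (each
state matches exactly one unit-bearing concept per axis), agreement with
the rule engine on all three axes, satisfiability of every defined
concept, and monotonicity of the T and N ranks in depth and node count.
550 states is the whole input space at criterion resolution, so these are
exhaustive proofs, not samples.

## Synthetic data and what it does not show

`sample_records()` draws canonical states uniformly and fills in counts
uniformly within regions (7-or-more is truncated at 15 nodes, several
organs at 4), with a uniform 1–30 tumour-free examined-node offset. This
exercises every criterion cell but does not emulate a clinical cohort:
real colorectal series are dominated by T3 N0 M0, counts are heavily
skewed, and the axes are correlated. Passing tests therefore demonstrate
logical correctness of the classification, not calibration against any
hospital distribution — the packaged 15-record example table, with its
expert codes, is the only empirical anchor, and the agreement the
acceptance script reports is computed on it.

The packaged fixture ships as a plain CSV in the example table's dialect
("Invasion of", "rLN", "tp rLN", "TD/ Sat.", "dMT", "ip dMT", expert code
columns `T_P`/`N_P`/`M_P`). The `dMT` column is read as the number of
distantly involved organs/sites, which is the quantity the M1a/M1b split
needs; a deliberately small interval: one row with `dMT = 1` carries the
expert code M1a, consistent with that reading.

```{r}
fx <- table5_fixture()
report <- write_report(tnm_classify(fx$records), gold = fx$gold)
glance(report)
```

## RDF instance graphs

`write_rdf_instances()` renders records as an RDF ABox in the same pattern
the model checker uses — per specimen one tumour-aggregate individual with
`hasPart` links to the primary tumour, a metastatic regional lymph node
when present, deposits and distant metastases, qualities projecting onto
value regions, and `isRepresentedBy` links to individuals of the assigned
unit classes. Counts are encoded as region membership, with the raw
integer kept in a `rawCount` annotation so `read_rdf_instances()` is an
exact inverse. Graphs serialize to Turtle (emitted as the line-based
N-Triples subset, which any Turtle parser accepts) and RDF/XML.

Multi-site invasion is out of the record model's scope: a record stores
only the deepest invasion site, and callers must pre-reduce multi-site
findings before classification.

## Scope and limitations

* Only the colorectal module of TNM version 7 is implemented; the site and
  version are explicit arguments so other modules can be added without
  changing the interface. Version 6 criteria, stage grouping I–IV and the
  additional modifiers (y/r/a prefixes, mi/sn/i+/mol+ suffixes, G, L, V,
  Pn, C, R) are out of scope.
* Clinical records are staged with the same criteria table as pathological
  ones and differ only in the `c` prefix; clinical and pathological
  assessments differ in meaning and evidence level, and downstream use
  should treat the prefix as load-bearing. There is no MX: an
  unassessable M axis is not representable and is rejected at input.
* The model checker is a finite-model evaluator, not a tableau reasoner:
  it decides concept membership over the single-specimen instance models
  this package constructs, which is exactly what the equivalence tests
  need, and nothing more general.
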