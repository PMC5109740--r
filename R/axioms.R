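# Concept expressions: a small description-logic expression language over
# named concepts, used both to state the axioms and to evaluate them against
# finite instance models (see realize_instance()).

c_named <- function(name) list(type = "named", name = name)
c_and   <- function(...) list(type = "and", args = list(...))
c_or    <- function(...) list(type = "or", args = list(...))
c_not   <- function(arg) list(type = "not", arg = arg)
c_some  <- function(rel, filler) list(type = "some", rel = rel, filler = filler)
c_only  <- function(rel, filler) list(type = "only", rel = rel, filler = filler)

as_expr <- function(x) if (is.character(x)) c_named(x) else x

# Canonical rendering of an expression; conjunction/disjunction operands are
# sorted so that structurally equal expressions render identically.
expr_string <- function(e) {
  e <- as_expr(e)
  switch(e$type,
    named = e$name,
    and = paste0("And(", paste(sort(vapply(e$args, expr_string, "")), collapse = " "), ")"),
    or  = paste0("Or(",  paste(sort(vapply(e$args, expr_string, "")), collapse = " "), ")"),
    not = paste0("Not(", expr_string(e$arg), ")"),
    some = paste0("Some(", e$rel, " ", expr_string(e$filler), ")"),
    only = paste0("Only(", e$rel, " ", expr_string(e$filler), ")"),
    rlang::abort(paste0("Unknown expression type: ", e$type))
  )
}

expr_named_concepts <- function(e) {
  e <- as_expr(e)
  switch(e$type,
    named = e$name,
    and = unlist(lapply(e$args, expr_named_concepts)),
    or  = unlist(lapply(e$args, expr_named_concepts)),
    not = expr_named_concepts(e$arg),
    some = expr_named_concepts(e$filler),
    only = expr_named_concepts(e$filler)
  )
}

axiom_string <- function(ax) {
  switch(ax$kind,
    subClassOf   = paste0("SubClassOf(", expr_string(ax$lhs), " ", expr_string(ax$rhs), ")"),
    equivalentTo = paste0("EquivalentTo(", expr_string(ax$lhs), " ", expr_string(ax$rhs), ")"),
    disjointClasses = paste0("DisjointClasses(",
                             paste(sort(vapply(ax$operands, expr_string, "")), collapse = " "), ")")
  )
}

# local concept-name shorthands used only while building the axiom set
.cn <- list(
  unit_root = "RepresentationalUnitInTNMClassification",
  agg = "TumourOfColonAndRectumAggregate",
  tum = "ColonAndRectumTumour"
)

depth_concepts <- c(
  EPITHELIUM          = "EpitheliumOfLargeIntestine",
  LAMINA_PROPRIA      = "LaminaPropriaOfLargeIntestine",
  SUBMUCOSA           = "SubmucosaOfLargeIntestine",
  MUSCULARIS_PROPRIA  = "MuscularisPropriaOfLargeIntestine",
  SUBSEROSA           = "SubserosaOfLargeIntestine",
  ADVENTITIA          = "AdventitiaOfLargeIntestine",
  VISCERAL_PERITONEUM = "VisceralPeritoneum",
  OTHER_ORGANS        = "AdjacentOrganStructure"
)

region_concepts <- c(
  C1 = "Cardinality1", C2OR3 = "Cardinality2or3", C4TO6 = "Cardinality4to6",
  C7PLUS = "Cardinality7orMore", C2PLUS = "Cardinality2orMore"
)

unit_name <- function(axis, value, modifier) {
  paste0("ColonRectumTNM_", ifelse(modifier == "p", "p", ""), axis, value)
}

# quality pattern: isBearerOf some (QualityClass and projectsOnto some Value)
quality_some <- function(quality, value_expr) {
  c_some("isBearerOf", c_and(c_named(quality), c_some("projectsOnto", value_expr)))
}

#' Build the colorectal TNM v7 axiom set
#'
#' Constructs, in memory, the description-logic axiom set the staging rules
#' compile: the seven object-property relations with their represents /
#' isRepresentedBy inverse pair, upper-type stubs (MaterialObject, Quality,
#' InformationObject), the anatomical and value-region vocabulary, one
#' representational-unit concept per TNM code value and modifier (35 in
#' total), and one defined tumour or tumour-aggregate concept per staging
#' criterion. Every defined concept carries exactly one equivalence axiom
#' giving its necessary-and-sufficient conditions; unit-bearing concepts
#' additionally carry an existential `isRepresentedBy` axiom naming their
#' units and a universal closure axiom with the
#' "or not RepresentationalUnitInTNMClassification" escape.
#'
#' @param version TNM version; only `"7"` is implemented.
#' @param base_iri Base IRI under which concepts are exported to OWL.
#' @return An object of class `tnm_axiom_set`: a list with `concepts`
#'   (tibble: `name`, `category`), `relations` (tibble: `name`, `inverse`),
#'   `axioms` (list of kind/operand records), `units` (tibble mapping each
#'   unit-bearing defined concept to its axis, code value and unit concepts)
#'   and `base_iri`.
#' @examples
#' ax <- build_axiom_set()
#' glance(ax)
#' @export
build_axiom_set <- function(version = "7",
                            base_iri = "http://example.org/tnmo/colorectal7#") {
  if (!identical(as.character(version), "7")) {
    rlang::abort(paste0("Only TNM version \"7\" is implemented; got: ", version))
  }

  relations <- tibble::tibble(
    name = c("represents", "isRepresentedBy", "locatedIn", "isIncludedIn",
             "hasPart", "isBearerOf", "projectsOnto"),
    inverse = c("isRepresentedBy", "represents", NA, NA, NA, NA, NA)
  )

  concepts <- list()
  axioms <- list()
  declare <- function(names, category) {
    concepts[[length(concepts) + 1]] <<- tibble::tibble(name = names, category = category)
  }
  add <- function(kind, lhs = NULL, rhs = NULL, operands = NULL) {
    axioms[[length(axioms) + 1]] <<- list(
      kind = kind, lhs = as_expr(lhs),
      rhs = if (!is.null(rhs)) as_expr(rhs),
      operands = if (!is.null(operands)) lapply(operands, as_expr)
    )
  }
  sub <- function(lhs, rhs) add("subClassOf", lhs, rhs)
  equiv <- function(lhs, rhs) add("equivalentTo", lhs, rhs)
  disjoint <- function(names) add("disjointClasses", operands = as.list(names))

  # --- upper-level stubs and primitive vocabulary ----------------------------
  declare(c("MaterialObject", "Quality", "InformationObject"), "upper")
  declare(c("MalignantAnatomicalStructure", "PrimaryTumour", "TumourAggregate",
            .cn$tum, .cn$agg, "LymphNode", "ColonAndRectumRegionalLymphNode",
            "MetastasisOfColonAndRectumTumour", "TumourDeposit", "Peritoneum",
            "DistantHostOrgan"), "domain")
  declare(unname(depth_concepts), "anatomy")
  declare(c("CardinalityValueRegion", unname(region_concepts)), "value_region")
  declare(c("Confinement", "Invasive", "Confined",
            "Cardinality", "MetastaticRegionalLymphNodeCardinality",
            "DistantMetastasisOrganCardinality",
            "EpistemicQuality", "PrimaryTumourEpistemicStatus",
            "RegionalLymphNodeEpistemicStatus",
            "DistantMetastasisEpistemicStatus",
            "NoAssessment", "NoEvidence"), "quality")
  declare(.cn$unit_root, "unit_root")

  sub("MalignantAnatomicalStructure", "MaterialObject")
  sub("PrimaryTumour", "MalignantAnatomicalStructure")
  sub(.cn$tum, "PrimaryTumour")
  sub(.cn$agg, "TumourAggregate")
  sub("TumourAggregate", "MaterialObject")
  sub("LymphNode", "MaterialObject")
  sub("ColonAndRectumRegionalLymphNode", "LymphNode")
  sub("MetastasisOfColonAndRectumTumour", "MalignantAnatomicalStructure")
  sub("TumourDeposit", "MalignantAnatomicalStructure")
  for (a in unname(depth_concepts)) sub(a, "MaterialObject")
  sub("Peritoneum", "MaterialObject")
  sub("DistantHostOrgan", "MaterialObject")
  for (r in unname(region_concepts)) sub(r, "CardinalityValueRegion")
  sub("Confinement", "Quality")
  sub("Cardinality", "Quality")
  sub("MetastaticRegionalLymphNodeCardinality", "Cardinality")
  sub("DistantMetastasisOrganCardinality", "Cardinality")
  sub("EpistemicQuality", "Quality")
  for (q in c("PrimaryTumourEpistemicStatus", "RegionalLymphNodeEpistemicStatus",
              "DistantMetastasisEpistemicStatus"))
    sub(q, "EpistemicQuality")
  sub(.cn$unit_root, "InformationObject")

  disjoint(unname(depth_concepts))
  disjoint(c("Invasive", "Confined"))
  disjoint(c("NoAssessment", "NoEvidence"))
  disjoint(region_concepts[c("C1", "C2OR3", "C4TO6", "C7PLUS")])
  disjoint(region_concepts[c("C1", "C2PLUS")])

  # --- representational units: one concept per code value and modifier -------
  unit_specs <- dplyr::bind_rows(
    tidyr::expand_grid(axis = "T", value = tnm_vocab$T, modifier = c("c", "p")),
    tidyr::expand_grid(axis = "N", value = tnm_vocab$N, modifier = c("c", "p")),
    tibble::tibble(axis = "M", value = c("0", "1a", "1b", "1a", "1b"),
                   modifier = c("c", "c", "c", "p", "p"))
  )
  unit_specs$unit <- unit_name(unit_specs$axis, unit_specs$value, unit_specs$modifier)
  declare(unit_specs$unit, "unit")
  for (u in unit_specs$unit) sub(u, .cn$unit_root)
  for (ax in c("T", "N", "M")) {
    for (mod in c("c", "p")) {
      members <- unit_specs$unit[unit_specs$axis == ax & unit_specs$modifier == mod]
      if (length(members) > 1) disjoint(members)
    }
  }

  # --- defined concepts: one equivalence per staging criterion ---------------
  defined <- list()  # name -> list(axis, value, expr)
  define <- function(name, expr, axis = NA, value = NA) {
    declare(name, "defined")
    equiv(name, expr)
    defined[[name]] <<- list(axis = axis, value = value)
  }
  t_epi <- function(v) quality_some("PrimaryTumourEpistemicStatus", c_named(v))
  invasive <- quality_some("Confinement", c_named("Invasive"))
  confined <- quality_some("Confinement", c_named("Confined"))
  included_in <- function(x) c_some("isIncludedIn", as_expr(x))

  define("PrimaryTumourOfColonAndRectumWithoutAssessment",
         c_and(c_named(.cn$tum), t_epi("NoAssessment")), "T", "X")
  define("PrimaryTumourOfColonAndRectumWithoutEvidence",
         c_and(c_named(.cn$tum), t_epi("NoEvidence")), "T", "0")
  define("CarcinomaInSituOfColonAndRectum",
         c_and(c_named(.cn$tum),
               included_in(c_or(c_named(depth_concepts[["EPITHELIUM"]]),
                                c_named(depth_concepts[["LAMINA_PROPRIA"]])))),
         "T", "is")
  invasive_t <- function(name, depths, value) {
    fillers <- lapply(unname(depth_concepts[depths]), c_named)
    filler <- if (length(fillers) == 1) fillers[[1]] else do.call(c_or, fillers)
    define(name, c_and(c_named(.cn$tum), invasive, included_in(filler)), "T", value)
  }
  invasive_t("InvasiveTumourOfSubmucosaOfColonAndRectum", "SUBMUCOSA", "1")
  invasive_t("InvasiveTumourOfMuscularisPropriaOfColonAndRectum", "MUSCULARIS_PROPRIA", "2")
  invasive_t("InvasiveTumourOfSubserosaOfColonAndRectum", "SUBSEROSA", "3")
  invasive_t("InvasiveTumourOfAdventitiaOfColonAndRectum", "ADVENTITIA", "3")
  invasive_t("InvasiveTumourOfVisceralPeritoneumOfColonAndRectum", "VISCERAL_PERITONEUM", "4a")
  invasive_t("InvasiveTumourOfOtherOrgansOfColonAndRectum", "OTHER_ORGANS", "4b")

  # N axis: metastatic regional lymph nodes and tumour deposits
  define("MetastaticLymphNodeOfColonAndRectumTumour",
         c_and(c_named("LymphNode"),
               c_some("hasPart", c_named("MetastasisOfColonAndRectumTumour"))))
  define("MetastaticRegionalLymphNodeOfColonAndRectumTumour",
         c_and(c_named("MetastaticLymphNodeOfColonAndRectumTumour"),
               c_named("ColonAndRectumRegionalLymphNode")))
  n_epi <- function(v) quality_some("RegionalLymphNodeEpistemicStatus", c_named(v))
  n_card <- function(region_expr) {
    c_some("isBearerOf", c_and(c_named("MetastaticRegionalLymphNodeCardinality"),
                               c_some("projectsOnto", region_expr),
                               c_only("projectsOnto", region_expr)))
  }
  define("TumourOfColonAndRectumWithoutRegionalLymphNodeAssessment",
         c_and(c_named(.cn$agg), n_epi("NoAssessment")), "N", "X")
  define("TumourOfColonAndRectumWithoutRegionalLymphNodeMetastasis",
         c_and(c_named(.cn$agg), n_epi("NoEvidence"),
               c_not(c_some("hasPart", c_named("TumourDeposit")))),
         "N", "0")
  define("TumourOfColonAndRectumWithTumourDepositsWithoutRegionalLymphNodeMetastasis",
         c_and(c_named(.cn$agg), n_epi("NoEvidence"),
               c_some("hasPart", c_named("TumourDeposit"))),
         "N", "1c")
  has_mrln <- c_some("hasPart", c_named("MetastaticRegionalLymphNodeOfColonAndRectumTumour"))
  define("TumourOfColonAndRectumWith1to3MetastaticRegionalLymphNodes",
         c_and(c_named(.cn$agg), has_mrln,
               n_card(c_or(c_named(region_concepts[["C1"]]),
                           c_named(region_concepts[["C2OR3"]])))))
  define("TumourOfColonAndRectumWith1MetastaticRegionalLymphNode",
         c_and(c_named("TumourOfColonAndRectumWith1to3MetastaticRegionalLymphNodes"),
               n_card(c_named(region_concepts[["C1"]]))),
         "N", "1a")
  define("TumourOfColonAndRectumWith2or3MetastaticRegionalLymphNodes",
         c_and(c_named("TumourOfColonAndRectumWith1to3MetastaticRegionalLymphNodes"),
               n_card(c_named(region_concepts[["C2OR3"]]))),
         "N", "1b")
  define("TumourOfColonAndRectumWith4to6MetastaticRegionalLymphNodes",
         c_and(c_named(.cn$agg), has_mrln, n_card(c_named(region_concepts[["C4TO6"]]))),
         "N", "2a")
  define("TumourOfColonAndRectumWith7OrMoreMetastaticRegionalLymphNodes",
         c_and(c_named(.cn$agg), has_mrln, n_card(c_named(region_concepts[["C7PLUS"]]))),
         "N", "2b")

  # M axis: distant metastases exclude regional lymph nodes as location
  define("DistantMetastasisOfColonAndRectumTumour",
         c_and(c_named("MetastasisOfColonAndRectumTumour"),
               c_not(included_in("ColonAndRectumRegionalLymphNode"))))
  has_dm <- c_some("hasPart", c_named("DistantMetastasisOfColonAndRectumTumour"))
  peritoneal_dm <- c_some("hasPart",
                          c_and(c_named("DistantMetastasisOfColonAndRectumTumour"),
                                included_in("Peritoneum")))
  m_card <- function(region) {
    quality_some("DistantMetastasisOrganCardinality", c_named(region_concepts[[region]]))
  }
  define("TumourOfColonAndRectumWithDistantMetastasis",
         c_and(c_named(.cn$agg), has_dm))
  define("TumourOfColonAndRectumWithoutDistantMetastasis",
         c_and(c_named(.cn$agg),
               quality_some("DistantMetastasisEpistemicStatus", c_named("NoEvidence")),
               c_not(has_dm)),
         "M", "0")
  define("TumourOfColonAndRectumWithDistantMetastasisInOneOrgan",
         c_and(c_named("TumourOfColonAndRectumWithDistantMetastasis"),
               m_card("C1"), c_not(peritoneal_dm)),
         "M", "1a")
  define("TumourOfColonAndRectumWithDistantMetastasisInMultipleOrgansOrPeritoneum",
         c_and(c_named("TumourOfColonAndRectumWithDistantMetastasis"),
               c_or(m_card("C2PLUS"), peritoneal_dm)),
         "M", "1b")

  # --- isRepresentedBy axioms with the closure idiom -------------------------
  unit_rows <- list()
  for (name in names(defined)) {
    d <- defined[[name]]
    if (is.na(d$axis)) next
    units <- if (d$axis == "M") {
      if (d$value == "0") unit_name("M", "0", "c") else
        unit_name("M", d$value, c("c", "p"))
    } else {
      unit_name(d$axis, d$value, c("c", "p"))
    }
    unit_disj <- do.call(c_or, lapply(units, c_named))
    sub(name, c_some("isRepresentedBy", unit_disj))
    sub(name, c_only("isRepresentedBy",
                     c_or(unit_disj, c_not(c_named(.cn$unit_root)))))
    unit_rows[[length(unit_rows) + 1]] <- tibble::tibble(
      concept = name, axis = d$axis, value = d$value,
      units = list(units)
    )
  }

  out <- list(
    concepts = dplyr::distinct(dplyr::bind_rows(concepts)),
    relations = relations,
    axioms = axioms,
    units = dplyr::bind_rows(unit_rows),
    base_iri = base_iri,
    version = "7"
  )
  class(out) <- "tnm_axiom_set"
  out
}

#' @export
print.tnm_axiom_set <- function(x, ...) {
  kinds <- vapply(x$axioms, function(a) a$kind, "")
  cat("<tnm_axiom_set> colorectal TNM v", x$version, "\n", sep = "")
  cat("  concepts:  ", nrow(x$concepts),
      " (", sum(x$concepts$category == "unit"), " representational units)\n", sep = "")
  cat("  relations: ", nrow(x$relations), "\n", sep = "")
  cat("  axioms:    ", length(x$axioms),
      " (", sum(kinds == "subClassOf"), " subClassOf, ",
      sum(kinds == "equivalentTo"), " equivalentTo, ",
      sum(kinds == "disjointClasses"), " disjointClasses)\n", sep = "")
  invisible(x)
}

# canonical multiset of axiom strings; the round-trip comparison key
axiom_strings <- function(axioms) {
  sort(vapply(axioms, axiom_string, ""))
}
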