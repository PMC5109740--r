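# Brute-force model checking of the axiom set over single-specimen instance
# models (ABoxes). Each canonical state is rendered as a small relational
# structure: a tumour-aggregate individual, a primary-tumour individual,
# lymph-node / metastasis / tumour-deposit individuals, and quality
# individuals projecting onto value regions. Defined concepts are then
# evaluated set-theoretically, in declaration order (definitions only refer
# to earlier ones, so one ordered pass reaches the fixpoint; a second pass
# asserts stability).

abox_new <- function() {
  list(individuals = character(),
       types = list(),  # individual -> character vector of primitive concepts
       edges = list())  # list of c(s, rel, o)
}

abox_add <- function(abox, ind, types = character()) {
  abox$individuals <- union(abox$individuals, ind)
  abox$types[[ind]] <- union(abox$types[[ind]], types)
  abox
}

abox_edge <- function(abox, s, rel, o) {
  abox$edges[[length(abox$edges) + 1]] <- c(s, rel, o)
  abox
}

# Quality individual `q` of class `quality` projecting onto a value
# individual of class(es) `value_types`, borne by `bearer`.
abox_quality <- function(abox, bearer, q, quality, value_types) {
  v <- paste0(q, "_value")
  abox <- abox_add(abox, q, c(quality, "Quality"))
  abox <- abox_add(abox, v, value_types)
  abox <- abox_edge(abox, q, "projectsOnto", v)
  abox_edge(abox, bearer, "isBearerOf", q)
}

# Build the instance model of one canonical state (one row of
# enumerate_canonical_states()).
build_abox <- function(state) {
  abox <- abox_new()
  abox <- abox_add(abox, "agg", c("TumourOfColonAndRectumAggregate",
                                  "TumourAggregate", "MaterialObject"))
  abox <- abox_add(abox, "tum", c("ColonAndRectumTumour", "PrimaryTumour",
                                  "MalignantAnatomicalStructure", "MaterialObject"))
  abox <- abox_edge(abox, "agg", "hasPart", "tum")

  # T axis
  if (state$t_state %in% c("NO_ASSESSMENT", "NO_EVIDENCE")) {
    abox <- abox_quality(abox, "tum", "q_t_epi", "PrimaryTumourEpistemicStatus",
                         if (state$t_state == "NO_ASSESSMENT") "NoAssessment" else "NoEvidence")
  } else {
    wall <- paste0("wall_", tolower(state$t_state))
    abox <- abox_add(abox, wall, depth_concepts[[state$t_state]])
    abox <- abox_edge(abox, "tum", "isIncludedIn", wall)
    growth <- if (invasion_rank(state$t_state) > 1L) "Invasive" else "Confined"
    abox <- abox_quality(abox, "tum", "q_growth", "Confinement", growth)
  }

  # N axis
  if (state$n_state == "NO_ASSESSMENT") {
    abox <- abox_quality(abox, "agg", "q_n_epi", "RegionalLymphNodeEpistemicStatus",
                         "NoAssessment")
  } else if (state$n_region == "NONE") {
    abox <- abox_quality(abox, "agg", "q_n_epi", "RegionalLymphNodeEpistemicStatus",
                         "NoEvidence")
  } else {
    abox <- abox_add(abox, "ln", c("LymphNode", "ColonAndRectumRegionalLymphNode"))
    abox <- abox_add(abox, "ln_met", "MetastasisOfColonAndRectumTumour")
    abox <- abox_edge(abox, "ln", "hasPart", "ln_met")
    abox <- abox_edge(abox, "ln_met", "isIncludedIn", "ln")
    abox <- abox_edge(abox, "agg", "hasPart", "ln")
    abox <- abox_quality(abox, "agg", "q_n_card",
                         "MetastaticRegionalLymphNodeCardinality",
                         region_concepts[[state$n_region]])
  }
  if (isTRUE(state$deposits)) {
    abox <- abox_add(abox, "dep", c("TumourDeposit", "MalignantAnatomicalStructure"))
    abox <- abox_edge(abox, "agg", "hasPart", "dep")
  }

  # M axis
  if (state$m_region == "NONE") {
    abox <- abox_quality(abox, "agg", "q_m_epi", "DistantMetastasisEpistemicStatus",
                         "NoEvidence")
  } else {
    first_organ_types <- if (isTRUE(state$peritoneal)) "Peritoneum" else "DistantHostOrgan"
    abox <- abox_add(abox, "organ1", first_organ_types)
    abox <- abox_add(abox, "dm1", "MetastasisOfColonAndRectumTumour")
    abox <- abox_edge(abox, "dm1", "isIncludedIn", "organ1")
    abox <- abox_edge(abox, "agg", "hasPart", "dm1")
    if (state$m_region == "C2PLUS") {
      abox <- abox_add(abox, "organ2", "DistantHostOrgan")
      abox <- abox_add(abox, "dm2", "MetastasisOfColonAndRectumTumour")
      abox <- abox_edge(abox, "dm2", "isIncludedIn", "organ2")
      abox <- abox_edge(abox, "agg", "hasPart", "dm2")
    }
    abox <- abox_quality(abox, "agg", "q_m_card", "DistantMetastasisOrganCardinality",
                         region_concepts[[state$m_region]])
  }
  abox
}

# Evaluate a concept expression to its extension (set of individuals) given
# the current extension environment `ext` (name -> character vector).
eval_expr <- function(e, abox, ext) {
  switch(e$type,
    named = ext[[e$name]] %||% character(),
    and = Reduce(intersect, lapply(e$args, eval_expr, abox = abox, ext = ext),
                 accumulate = FALSE),
    or = unique(unlist(lapply(e$args, eval_expr, abox = abox, ext = ext))),
    not = setdiff(abox$individuals, eval_expr(e$arg, abox, ext)),
    some = {
      filler <- eval_expr(e$filler, abox, ext)
      edges <- abox$by_rel[[e$rel]]
      if (is.null(edges)) character() else unique(edges$s[edges$o %in% filler])
    },
    only = {
      filler <- eval_expr(e$filler, abox, ext)
      edges <- abox$by_rel[[e$rel]]
      offending <- if (is.null(edges)) character() else
        unique(edges$s[!edges$o %in% filler])
      setdiff(abox$individuals, offending)
    },
    rlang::abort(paste0("Unknown expression type: ", e$type))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Primitive extensions from asserted types, then defined concepts evaluated
# from their equivalence axioms.
model_extensions <- function(abox, axioms) {
  edges <- do.call(rbind, abox$edges)
  edges <- data.frame(s = edges[, 1], rel = edges[, 2], o = edges[, 3])
  abox$by_rel <- split(edges[, c("s", "o")], edges$rel)
  ext <- list()
  for (ind in abox$individuals) {
    for (ty in abox$types[[ind]]) ext[[ty]] <- union(ext[[ty]], ind)
  }
  equivs <- Filter(function(a) a$kind == "equivalentTo", axioms$axioms)
  for (pass in 1:2) {
    changed <- FALSE
    for (a in equivs) {
      val <- sort(eval_expr(a$rhs, abox, ext))
      if (!identical(val, sort(ext[[a$lhs$name]] %||% character()))) changed <- TRUE
      ext[[a$lhs$name]] <- val
    }
    if (pass == 2 && changed) {
      rlang::abort("Definition evaluation did not stabilise; circular definitions?")
    }
  }
  ext
}

#' Realize one canonical state against the axiom set
#'
#' The semantic oracle of the package: instead of running the compiled
#' staging rules, the state is rendered as a finite instance model and every
#' defined concept's equivalence axiom is evaluated set-theoretically over
#' it. The representational units reachable from the matched unit-bearing
#' concepts via their `isRepresentedBy` axioms give the ontology's own
#' T/N/M answer, independently of [tnm_classify()].
#'
#' @param state A one-row data frame from [enumerate_canonical_states()].
#' @param axioms A `tnm_axiom_set` from [build_axiom_set()].
#' @return A list: `matched` (character vector of defined concepts with a
#'   non-empty extension containing the aggregate or tumour individual) and
#'   `codes` (tibble `axis`, `value` — exactly one row per axis for a
#'   well-formed axiom set).
#' @examples
#' states <- enumerate_canonical_states()
#' realize_instance(states[1, ], build_axiom_set())$codes
#' @export
realize_instance <- function(state, axioms) {
  stopifnot(inherits(axioms, "tnm_axiom_set"))
  state <- check_canonical_state(state)
  abox <- build_abox(state)
  ext <- model_extensions(abox, axioms)

  defined <- axioms$units$concept
  matched <- defined[purrr::map_lgl(defined, function(nm) {
    any(c("agg", "tum") %in% ext[[nm]])
  })]
  codes <- axioms$units[axioms$units$concept %in% matched, c("axis", "value")]
  if (!setequal(codes$axis, c("T", "N", "M")) || nrow(codes) != 3) {
    rlang::abort(paste0(
      "State is not realized by exactly one unit-bearing concept per axis ",
      "(matched: ", paste(matched, collapse = ", "), ")"
    ))
  }
  list(matched = matched,
       codes = dplyr::arrange(codes, factor(.data$axis, levels = c("T", "N", "M"))),
       extensions = ext)
}

check_canonical_state <- function(state) {
  state <- tibble::as_tibble(state)
  needed <- c("t_state", "n_state", "n_region", "deposits", "m_region", "peritoneal")
  missing <- setdiff(needed, names(state))
  if (nrow(state) != 1 || length(missing) > 0) {
    rlang::abort(paste0(
      "`state` must be one row with columns ",
      paste(needed, collapse = ", ")
    ))
  }
  key <- do.call(paste, c(state[needed], sep = "|"))
  if (!key %in% canonical_state_keys()) {
    rlang::abort(paste0("State outside the canonical space: ", key))
  }
  state
}

.canonical_cache <- new.env(parent = emptyenv())

canonical_state_keys <- function() {
  if (is.null(.canonical_cache$keys)) {
    space <- enumerate_canonical_states()
    needed <- c("t_state", "n_state", "n_region", "deposits", "m_region", "peritoneal")
    .canonical_cache$keys <- do.call(paste, c(space[needed], sep = "|"))
  }
  .canonical_cache$keys
}
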