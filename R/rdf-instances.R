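# Instance (ABox) graphs for pathology records: one tumour-aggregate
# individual per specimen with its primary tumour, metastatic regional
# lymph node, tumour deposit and distant metastasis individuals, qualities
# projecting onto cardinality value regions, and represents-links to the
# representational units of the assigned codes. Counts are encoded as
# value-region membership, with the raw integer kept as an annotation so
# the graph round-trips exactly.

default_instance_iri <- "http://example.org/tnmo/instances#"

#' Write pathology records as an RDF instance graph
#'
#' @param records A tibble of valid pathology records.
#' @param base_iri Ontology base IRI (concept and relation IRIs).
#' @param instance_iri Base IRI for the generated individuals.
#' @param units Also assert `isRepresentedBy` links from the tumour and
#'   aggregate individuals to individuals of the assigned representational
#'   unit classes (runs the classifier on the records).
#' @return A `tnm_graph` tibble; serialize with [write_graph()].
#' @examples
#' g <- write_rdf_instances(table5_fixture()$records)
#' nrow(read_rdf_instances(g))
#' @export
write_rdf_instances <- function(records,
                                base_iri = "http://example.org/tnmo/colorectal7#",
                                instance_iri = default_instance_iri,
                                units = TRUE) {
  records <- as_tnm_records(records)
  stop_on_invalid(records)
  if (nrow(records) == 0) return(empty_graph())
  cls <- function(x) paste0(base_iri, x)
  rel <- function(x) paste0(base_iri, x)
  a_type <- paste0(RDF, "type")

  code_units <- NULL
  if (units) {
    code_units <- list(T = assign_t(records), N = assign_n(records),
                       M = assign_m(records))
  }

  out <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    id <- r$specimen_id
    ind <- function(x) paste0(instance_iri, x, "_", id)
    emit <- function(...) out[[length(out) + 1]] <<- triple(...)
    emit_lit <- function(...) out[[length(out) + 1]] <<- lit(...)
    emit_int <- function(...) out[[length(out) + 1]] <<- int_lit(...)
    quality <- function(bearer, stem, quality_class, value_class, raw = NULL) {
      q <- ind(stem); v <- ind(paste0(stem, "_value"))
      emit(q, a_type, cls(quality_class))
      emit(v, a_type, cls(value_class))
      emit(q, rel("projectsOnto"), v)
      emit(bearer, rel("isBearerOf"), q)
      if (!is.null(raw)) emit_int(q, paste0(base_iri, "rawCount"), raw)
    }

    agg <- ind("aggregate"); tum <- ind("tumour")
    emit(agg, a_type, cls("TumourOfColonAndRectumAggregate"))
    emit_lit(agg, paste0(base_iri, "specimenId"), id)
    emit_lit(agg, paste0(base_iri, "assessmentMode"), r$assessment_mode)
    emit_int(agg, paste0(base_iri, "regionalLymphNodesExamined"), r$rln_examined)
    emit(tum, a_type, cls("ColonAndRectumTumour"))
    emit(agg, rel("hasPart"), tum)

    # T axis
    if (r$t_epistemic != "ASSESSED") {
      quality(tum, "t_epistemic", "PrimaryTumourEpistemicStatus",
              if (r$t_epistemic == "NO_ASSESSMENT") "NoAssessment" else "NoEvidence")
    } else {
      wall <- ind("wall")
      emit(wall, a_type, cls(depth_concepts[[r$invasion]]))
      emit(tum, rel("isIncludedIn"), wall)
      quality(tum, "growth", "Confinement",
              if (r$growth == "INFILTRATIVE") "Invasive" else "Confined")
    }

    # N axis
    if (r$n_epistemic == "NO_ASSESSMENT") {
      quality(agg, "n_epistemic", "RegionalLymphNodeEpistemicStatus", "NoAssessment")
    } else if (r$rln_positive == 0L) {
      quality(agg, "n_epistemic", "RegionalLymphNodeEpistemicStatus", "NoEvidence")
    } else {
      ln <- ind("lymph_node"); met <- ind("ln_metastasis")
      emit(ln, a_type, cls("ColonAndRectumRegionalLymphNode"))
      emit(ln, a_type, cls("LymphNode"))
      emit(met, a_type, cls("MetastasisOfColonAndRectumTumour"))
      emit(ln, rel("hasPart"), met)
      emit(met, rel("isIncludedIn"), ln)
      emit(agg, rel("hasPart"), ln)
      quality(agg, "n_cardinality", "MetastaticRegionalLymphNodeCardinality",
              region_concepts[[region_for("REGIONAL_LN", r$rln_positive)]],
              raw = r$rln_positive)
    }
    if (r$tumour_deposits) {
      dep <- ind("deposit")
      emit(dep, a_type, cls("TumourDeposit"))
      emit(agg, rel("hasPart"), dep)
    }

    # M axis
    if (r$distant_organ_count == 0L) {
      quality(agg, "m_epistemic", "DistantMetastasisEpistemicStatus", "NoEvidence")
    } else {
      organ1 <- ind("distant_organ1"); dm1 <- ind("distant_metastasis1")
      emit(organ1, a_type,
           cls(if (r$peritoneal_mets) "Peritoneum" else "DistantHostOrgan"))
      emit(dm1, a_type, cls("MetastasisOfColonAndRectumTumour"))
      emit(dm1, rel("isIncludedIn"), organ1)
      emit(agg, rel("hasPart"), dm1)
      if (r$distant_organ_count >= 2L) {
        organ2 <- ind("distant_organ2"); dm2 <- ind("distant_metastasis2")
        emit(organ2, a_type, cls("DistantHostOrgan"))
        emit(dm2, a_type, cls("MetastasisOfColonAndRectumTumour"))
        emit(dm2, rel("isIncludedIn"), organ2)
        emit(agg, rel("hasPart"), dm2)
      }
      quality(agg, "m_cardinality", "DistantMetastasisOrganCardinality",
              region_concepts[[region_for("DISTANT_ORGANS", r$distant_organ_count)]],
              raw = r$distant_organ_count)
    }

    if (units) {
      unit_ind <- function(axis, bearer) {
        row <- code_units[[axis]][i, ]
        modifier <- if (axis == "M") {
          if (row$modifier == "p") "p" else "c"
        } else row$modifier
        u <- ind(paste0("unit_", tolower(axis)))
        emit(u, a_type, cls(unit_name(axis, row$value, modifier)))
        emit(bearer, rel("isRepresentedBy"), u)
      }
      unit_ind("T", tum)
      unit_ind("N", agg)
      unit_ind("M", agg)
    }
  }
  as_graph(out)
}

#' Read pathology records back from an RDF instance graph
#'
#' Inverse of [write_rdf_instances()] up to specimen ordering. Each
#' tumour-aggregate individual must have a primary-tumour part; otherwise an
#' error names the offending individual.
#'
#' @param graph A `tnm_graph` tibble in the [write_rdf_instances()] pattern.
#' @param base_iri Ontology base IRI used when the graph was written.
#' @return A tibble of pathology records.
#' @export
read_rdf_instances <- function(graph,
                               base_iri = "http://example.org/tnmo/colorectal7#") {
  if (nrow(graph) == 0) return(canonical_records(enumerate_canonical_states()[0, ]))
  cls <- function(x) paste0(base_iri, x)
  a_type <- paste0(RDF, "type")
  index <- split(graph$o, paste0(graph$s, "\r", graph$p))
  lookup <- function(s, p) index[[paste0(s, "\r", p)]] %||% character()
  types_of <- function(s) lookup(s, a_type)
  objs <- function(s, p) lookup(s, cls(p))
  lit_of <- function(s, p) {
    v <- lookup(s, paste0(base_iri, p))
    if (length(v) == 0) NA_character_ else v[[1]]
  }
  has_type <- function(s, x) cls(x) %in% types_of(s)

  aggs <- sort(graph$s[graph$p == a_type & graph$o == cls("TumourOfColonAndRectumAggregate")])
  out <- vector("list", length(aggs))
  for (k in seq_along(aggs)) {
    agg <- aggs[k]
    parts <- objs(agg, "hasPart")
    tum <- parts[vapply(parts, has_type, TRUE, x = "ColonAndRectumTumour")]
    if (length(tum) != 1) {
      rlang::abort(paste0("Aggregate individual lacks a primary tumour part: ", agg))
    }
    qualities <- objs(agg, "isBearerOf")
    quality_value <- function(bearer_qualities, quality_class) {
      q <- bearer_qualities[vapply(bearer_qualities, has_type, TRUE, x = quality_class)]
      if (length(q) == 0) return(NULL)
      list(node = q[[1]],
           value_types = types_of(objs(q[[1]], "projectsOnto")[[1]]))
    }

    # T axis
    t_q <- quality_value(objs(tum, "isBearerOf"), "PrimaryTumourEpistemicStatus")
    if (!is.null(t_q)) {
      t_epi <- if (cls("NoAssessment") %in% t_q$value_types) "NO_ASSESSMENT" else "NO_EVIDENCE"
      invasion <- NA_character_; growth <- NA_character_
    } else {
      t_epi <- "ASSESSED"
      wall <- objs(tum, "isIncludedIn")
      wall_types <- local_of(base_iri, unlist(lapply(wall, types_of)))
      invasion <- names(depth_concepts)[match(wall_types, depth_concepts)]
      invasion <- invasion[!is.na(invasion)][1]
      if (is.na(invasion)) {
        rlang::abort(paste0("Tumour individual lacks an invasion-site link: ", tum))
      }
      g_q <- quality_value(objs(tum, "isBearerOf"), "Confinement")
      growth <- if (!is.null(g_q) && cls("Invasive") %in% g_q$value_types)
        "INFILTRATIVE" else "CONFINED"
    }

    # N axis
    n_epi_q <- quality_value(qualities, "RegionalLymphNodeEpistemicStatus")
    n_card_q <- quality_value(qualities, "MetastaticRegionalLymphNodeCardinality")
    if (!is.null(n_card_q)) {
      n_epi <- "ASSESSED"
      rln_positive <- as.integer(lit_of(n_card_q$node, "rawCount"))
    } else if (!is.null(n_epi_q)) {
      if (cls("NoAssessment") %in% n_epi_q$value_types) {
        n_epi <- "NO_ASSESSMENT"
      } else {
        n_epi <- "ASSESSED"
      }
      rln_positive <- 0L
    } else {
      rlang::abort(paste0(
        "Aggregate lacks both a regional-lymph-node cardinality and an epistemic quality: ",
        agg))
    }
    deposits <- any(vapply(parts, has_type, TRUE, x = "TumourDeposit"))

    # M axis
    m_card_q <- quality_value(qualities, "DistantMetastasisOrganCardinality")
    if (!is.null(m_card_q)) {
      organs <- as.integer(lit_of(m_card_q$node, "rawCount"))
      dms <- parts[vapply(parts, has_type, TRUE, x = "MetastasisOfColonAndRectumTumour")]
      peritoneal <- any(vapply(dms, function(dm) {
        any(vapply(objs(dm, "isIncludedIn"), has_type, TRUE, x = "Peritoneum"))
      }, TRUE))
    } else {
      organs <- 0L; peritoneal <- FALSE
    }

    rln_examined <- as.integer(lit_of(agg, "regionalLymphNodesExamined"))
    out[[k]] <- tnm_records(
      specimen_id = lit_of(agg, "specimenId"),
      t_epistemic = t_epi, invasion = invasion, growth = growth,
      n_epistemic = n_epi,
      rln_examined = if (is.na(rln_examined)) rln_positive else rln_examined,
      rln_positive = rln_positive,
      tumour_deposits = deposits,
      distant_organ_count = organs, peritoneal_mets = peritoneal,
      assessment_mode = lit_of(agg, "assessmentMode")
    )
  }
  dplyr::bind_rows(out)
}
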