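# Decision logic compiled from the defined tumour / tumour-aggregate concepts
# of the colorectal TNM v7 axiom set. Each assignment also reports the name of
# the defined concept it corresponds to, so every code is traceable to its
# axiom (see build_axiom_set()).

t_concept_map <- c(
  EPITHELIUM          = "CarcinomaInSituOfColonAndRectum",
  LAMINA_PROPRIA      = "CarcinomaInSituOfColonAndRectum",
  SUBMUCOSA           = "InvasiveTumourOfSubmucosaOfColonAndRectum",
  MUSCULARIS_PROPRIA  = "InvasiveTumourOfMuscularisPropriaOfColonAndRectum",
  SUBSEROSA           = "InvasiveTumourOfSubserosaOfColonAndRectum",
  ADVENTITIA          = "InvasiveTumourOfAdventitiaOfColonAndRectum",
  VISCERAL_PERITONEUM = "InvasiveTumourOfVisceralPeritoneumOfColonAndRectum",
  OTHER_ORGANS        = "InvasiveTumourOfOtherOrgansOfColonAndRectum"
)

t_value_map <- c(
  EPITHELIUM = "is", LAMINA_PROPRIA = "is", SUBMUCOSA = "1",
  MUSCULARIS_PROPRIA = "2", SUBSEROSA = "3", ADVENTITIA = "3",
  VISCERAL_PERITONEUM = "4a", OTHER_ORGANS = "4b"
)

axis_tbl <- function(records, axis, value, concept, modifier) {
  rank <- tnm_rank(axis, value)
  code <- render_code(axis, value, modifier)
  tibble::tibble(
    specimen_id = records$specimen_id,
    axis = axis, value = value, modifier = modifier,
    code = code, rank = rank, concept = concept
  )
}

#' Assign one TNM axis to pathology records
#'
#' `assign_t()` maps the deepest invasion site to the T code (epithelium or
#' lamina propria: Tis; submucosa: T1; muscularis propria: T2; subserosa or
#' adventitia: T3; visceral peritoneum: T4a; adjacent organs: T4b), with TX /
#' T0 for unassessed / no-evidence records. `assign_n()` maps the count of
#' tumour-positive regional lymph nodes (1: N1a; 2-3: N1b; 4-6: N2a; 7 or
#' more: N2b), with N1c for tumour deposits without nodal metastases, N0 for
#' neither and NX when unassessed; deposits alongside positive nodes are
#' ignored and the count governs. `assign_m()` maps the number of distantly
#' involved organs (0: M0; one organ, not the peritoneum: M1a; several organs
#' or the peritoneum: M1b).
#'
#' The T and N codes carry the `p`/`c` prefix of the record's assessment
#' mode; M codes are rendered unprefixed, as staging reports print them,
#' though the underlying code keeps a `p` modifier for pathologically
#' confirmed metastases.
#'
#' @param records A data frame of pathology records passing
#'   [validate_records()] without error-severity violations.
#' @return A tibble with one row per record: `specimen_id`, `axis`, `value`,
#'   `modifier`, `code` (rendered, e.g. `"pT3"`), `rank` and `concept` (the
#'   defined ontology concept the rule compiles).
#' @examples
#' assign_n(tnm_records(invasion = "SUBSEROSA", rln_examined = 20,
#'                      rln_positive = 0, tumour_deposits = TRUE))
#' @export
assign_t <- function(records) {
  records <- as_tnm_records(records)
  stop_on_invalid(records)
  modifier <- ifelse(records$assessment_mode == "PATHOLOGICAL", "p", "c")
  value <- dplyr::case_when(
    records$t_epistemic == "NO_ASSESSMENT" ~ "X",
    records$t_epistemic == "NO_EVIDENCE" ~ "0",
    TRUE ~ unname(t_value_map[records$invasion])
  )
  concept <- dplyr::case_when(
    records$t_epistemic == "NO_ASSESSMENT" ~ "PrimaryTumourOfColonAndRectumWithoutAssessment",
    records$t_epistemic == "NO_EVIDENCE" ~ "PrimaryTumourOfColonAndRectumWithoutEvidence",
    TRUE ~ unname(t_concept_map[records$invasion])
  )
  axis_tbl(records, "T", value, concept, modifier)
}

#' @rdname assign_t
#' @export
assign_n <- function(records) {
  records <- as_tnm_records(records)
  stop_on_invalid(records)
  modifier <- ifelse(records$assessment_mode == "PATHOLOGICAL", "p", "c")
  pos <- records$rln_positive
  value <- dplyr::case_when(
    records$n_epistemic == "NO_ASSESSMENT" ~ "X",
    pos == 0L & !records$tumour_deposits ~ "0",
    pos == 0L & records$tumour_deposits ~ "1c",
    pos == 1L ~ "1a",
    pos <= 3L ~ "1b",
    pos <= 6L ~ "2a",
    TRUE ~ "2b"
  )
  concept <- dplyr::case_when(
    records$n_epistemic == "NO_ASSESSMENT" ~ "TumourOfColonAndRectumWithoutRegionalLymphNodeAssessment",
    pos == 0L & !records$tumour_deposits ~ "TumourOfColonAndRectumWithoutRegionalLymphNodeMetastasis",
    pos == 0L ~ "TumourOfColonAndRectumWithTumourDepositsWithoutRegionalLymphNodeMetastasis",
    pos == 1L ~ "TumourOfColonAndRectumWith1MetastaticRegionalLymphNode",
    pos <= 3L ~ "TumourOfColonAndRectumWith2or3MetastaticRegionalLymphNodes",
    pos <= 6L ~ "TumourOfColonAndRectumWith4to6MetastaticRegionalLymphNodes",
    TRUE ~ "TumourOfColonAndRectumWith7OrMoreMetastaticRegionalLymphNodes"
  )
  axis_tbl(records, "N", value, concept, modifier)
}

#' @rdname assign_t
#' @export
assign_m <- function(records) {
  records <- as_tnm_records(records)
  stop_on_invalid(records)
  organs <- records$distant_organ_count
  value <- dplyr::case_when(
    organs == 0L ~ "0",
    organs == 1L & !records$peritoneal_mets ~ "1a",
    TRUE ~ "1b"
  )
  concept <- dplyr::case_when(
    organs == 0L ~ "TumourOfColonAndRectumWithoutDistantMetastasis",
    organs == 1L & !records$peritoneal_mets ~ "TumourOfColonAndRectumWithDistantMetastasisInOneOrgan",
    TRUE ~ "TumourOfColonAndRectumWithDistantMetastasisInMultipleOrgansOrPeritoneum"
  )
  modifier <- ifelse(
    organs >= 1L & records$assessment_mode == "PATHOLOGICAL", "p", "none"
  )
  out <- axis_tbl(records, "M", value, concept, modifier)
  # staging reports print the M axis without a prefix
  out$code <- render_code("M", value, "none")
  out
}

#' Classify pathology records into TNM codes
#'
#' Runs all three axis rules and assembles one classification per record:
#' the three codes, the rendered TNM string (e.g. `"pT3pN1cM0"`) and, as
#' provenance, the defined ontology concept matched on each axis.
#'
#' @inheritParams assign_t
#' @return A tibble of class `tnm_classification`, one row per record, with
#'   columns `specimen_id`, `t`, `n`, `m` (rendered per-axis codes),
#'   `tnm` (the concatenated string) and `t_concept`, `n_concept`,
#'   `m_concept`.
#' @examples
#' tnm_classify(tnm_records(invasion = "SUBSEROSA",
#'                          rln_examined = 31, rln_positive = 0))
#' @export
tnm_classify <- function(records) {
  records <- as_tnm_records(records)
  t_ax <- assign_t(records)
  n_ax <- assign_n(records)
  m_ax <- assign_m(records)
  out <- tibble::tibble(
    specimen_id = records$specimen_id,
    t = t_ax$code, n = n_ax$code, m = m_ax$code,
    tnm = paste0(t_ax$code, n_ax$code, m_ax$code),
    t_concept = t_ax$concept, n_concept = n_ax$concept, m_concept = m_ax$concept
  )
  class(out) <- c("tnm_classification", class(out))
  out
}
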