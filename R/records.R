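record_columns <- c(
  "specimen_id", "t_epistemic", "invasion", "growth", "n_epistemic",
  "rln_examined", "rln_positive", "tumour_deposits",
  "distant_organ_count", "peritoneal_mets", "assessment_mode"
)

#' Build a tibble of pathology records
#'
#' One row per specimen, holding the staging-relevant findings: how far the
#' primary tumour invades the gut wall and whether it is infiltrative, how
#' many regional lymph nodes were examined and how many were tumour-positive,
#' whether pericolorectal tumour deposits (satellites) were seen, the number
#' of distantly involved organs, and whether the peritoneum is among them.
#'
#' @param specimen_id Character specimen identifiers.
#' @param t_epistemic,n_epistemic Epistemic status of the T and N axes
#'   (see [epistemic_statuses]); the N axis admits only `ASSESSED` and
#'   `NO_ASSESSMENT`.
#' @param invasion Deepest invasion site (see [invasion_depths]); required
#'   (and only allowed) when `t_epistemic == "ASSESSED"`.
#' @param growth `"CONFINED"` or `"INFILTRATIVE"`; same requirement as
#'   `invasion`.
#' @param rln_examined,rln_positive Counts of regional lymph nodes inspected
#'   and found tumour-positive.
#' @param tumour_deposits Logical: tumour deposits / satellites present.
#' @param distant_organ_count Number of distantly involved organs or sites.
#' @param peritoneal_mets Logical: intraperitoneal metastases present.
#' @param assessment_mode `"PATHOLOGICAL"` (p prefix) or `"CLINICAL"` (c).
#' @return A tibble with one row per record and the canonical column set.
#' @examples
#' tnm_records(invasion = "SUBSEROSA", rln_examined = 31, rln_positive = 0)
#' @export
tnm_records <- function(specimen_id = NULL,
                        t_epistemic = "ASSESSED",
                        invasion = NA_character_,
                        growth = NA_character_,
                        n_epistemic = "ASSESSED",
                        rln_examined = 0L,
                        rln_positive = 0L,
                        tumour_deposits = FALSE,
                        distant_organ_count = 0L,
                        peritoneal_mets = FALSE,
                        assessment_mode = "PATHOLOGICAL") {
  df <- tibble::tibble(
    t_epistemic = t_epistemic,
    invasion = invasion,
    growth = growth,
    n_epistemic = n_epistemic,
    rln_examined = as.integer(rln_examined),
    rln_positive = as.integer(rln_positive),
    tumour_deposits = as.logical(tumour_deposits),
    distant_organ_count = as.integer(distant_organ_count),
    peritoneal_mets = as.logical(peritoneal_mets),
    assessment_mode = assessment_mode
  )
  # default growth: infiltrative wherever invasion is past the lamina propria
  fix <- !is.na(df$invasion) & is.na(df$growth)
  df$growth[fix] <- ifelse(invasion_rank(df$invasion[fix]) > 1L,
                           "INFILTRATIVE", "CONFINED")
  df$specimen_id <- if (is.null(specimen_id)) as.character(seq_len(nrow(df))) else
    as.character(specimen_id)
  df[, record_columns]
}

as_tnm_records <- function(records) {
  missing <- setdiff(record_columns, names(records))
  if (length(missing) > 0) {
    rlang::abort(paste0("Missing record column(s): ", paste(missing, collapse = ", ")))
  }
  tibble::as_tibble(records)[, record_columns]
}

#' Validate pathology records against the staging-model invariants
#'
#' Checks every record for internal consistency and returns the violations as
#' data, one row per violation, rather than raising an error. Violations of
#' severity `"error"` make a record unclassifiable; severity `"warning"`
#' flags suspicious but still classifiable input (currently: an assessed N
#' axis with zero nodes examined).
#'
#' @param records A data frame of pathology records (see [tnm_records]).
#' @return A tibble with columns `row`, `specimen_id`, `field`, `severity`
#'   and `violation`; zero rows when every invariant holds.
#' @examples
#' validate_records(tnm_records(invasion = "SUBSEROSA", rln_examined = 31))
#' @export
validate_records <- function(records) {
  records <- as_tnm_records(records)
  out <- list()
  flag <- function(idx, field, severity, msg) {
    if (!any(idx, na.rm = TRUE)) return()
    i <- which(idx)
    out[[length(out) + 1]] <<- tibble::tibble(
      row = i, specimen_id = records$specimen_id[i],
      field = field, severity = severity, violation = msg
    )
  }

  flag(!records$t_epistemic %in% epistemic_statuses, "t_epistemic", "error",
       "t_epistemic outside {ASSESSED, NO_ASSESSMENT, NO_EVIDENCE}")
  flag(!records$n_epistemic %in% c("ASSESSED", "NO_ASSESSMENT"), "n_epistemic",
       "error", "n_epistemic outside {ASSESSED, NO_ASSESSMENT}")
  flag(!records$assessment_mode %in% assessment_modes, "assessment_mode",
       "error", "assessment_mode outside {CLINICAL, PATHOLOGICAL}")
  flag(!is.na(records$invasion) & !records$invasion %in% invasion_depths,
       "invasion", "error", "unknown invasion depth")
  flag(!is.na(records$growth) & !records$growth %in% growth_patterns,
       "growth", "error", "unknown growth pattern")

  assessed <- records$t_epistemic == "ASSESSED"
  flag(assessed & (is.na(records$invasion) | is.na(records$growth)),
       "invasion", "error", "invasion and growth required when the T axis is assessed")
  flag(!assessed & (!is.na(records$invasion) | !is.na(records$growth)),
       "invasion", "error", "invasion/growth must be absent unless the T axis is assessed")

  known_depth <- !is.na(records$invasion) & records$invasion %in% invasion_depths
  flag(known_depth & invasion_rank(records$invasion) > 1L &
         !is.na(records$growth) & records$growth == "CONFINED",
       "growth", "error",
       "invasion beyond the lamina propria is incompatible with a confined growth pattern")

  for (f in c("rln_examined", "rln_positive", "distant_organ_count")) {
    flag(is.na(records[[f]]) | records[[f]] < 0L, f, "error",
         paste0(f, " must be a non-negative integer"))
  }
  flag(records$rln_positive > records$rln_examined, "rln_positive", "error",
       "rln_positive exceeds rln_examined")
  flag(records$peritoneal_mets & records$distant_organ_count < 1L,
       "peritoneal_mets", "error",
       "peritoneal metastases imply at least one distantly involved organ")
  flag(records$n_epistemic == "ASSESSED" & records$rln_examined == 0L,
       "rln_examined", "warning",
       "N axis assessed although no regional lymph nodes were examined")

  if (length(out) == 0) {
    return(tibble::tibble(row = integer(), specimen_id = character(),
                          field = character(), severity = character(),
                          violation = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$row, .data$field)
}

stop_on_invalid <- function(records) {
  v <- dplyr::filter(validate_records(records), .data$severity == "error")
  if (nrow(v) > 0) {
    rlang::abort(paste0(
      "Invalid pathology record(s):\n",
      paste0("  row ", v$row, " [", v$field, "]: ", v$violation, collapse = "\n")
    ))
  }
  invisible(records)
}
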