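#' Tabular dialect for pathology-record files
#'
#' A dialect maps external column headers and vocabulary terms onto the
#' canonical record fields. The default dialect uses the published example
#' table's headers ("Invasion of", "rLN", "tp rLN", "TD/ Sat.", "dMT",
#' "ip dMT", optionally the expert code columns "T_P", "N_P", "M_P") and its
#' invasion-site terms; yes/no flags are parsed case-insensitively. The
#' "dMT" column is read as the number of distantly involved organs/sites.
#'
#' @param columns Named character vector: record field -> external header.
#' @param invasion_terms Named character vector: external term -> invasion
#'   depth value.
#' @return A list of class `tnm_dialect`.
#' @examples
#' table5_dialect()$invasion_terms[["Visc. peritoneum"]]
#' @export
table5_dialect <- function(columns = NULL, invasion_terms = NULL) {
  d <- list(
    columns = columns %||% c(
      invasion = "Invasion of", rln_examined = "rLN", rln_positive = "tp rLN",
      tumour_deposits = "TD/ Sat.", distant_organ_count = "dMT",
      peritoneal_mets = "ip dMT",
      gold_t = "T_P", gold_n = "N_P", gold_m = "M_P",
      specimen_id = "Specimen", n_assessed = "rLN assessed"
    ),
    invasion_terms = invasion_terms %||% c(
      "Epithelium" = "EPITHELIUM",
      "Lamina propria" = "LAMINA_PROPRIA",
      "Submucosa" = "SUBMUCOSA",
      "Muscular layer" = "MUSCULARIS_PROPRIA",
      "Subserosa" = "SUBSEROSA",
      "Adventitia" = "ADVENTITIA",
      "Visc. peritoneum" = "VISCERAL_PERITONEUM",
      "Other" = "OTHER_ORGANS",
      "No assessment" = "NO_ASSESSMENT",
      "No evidence" = "NO_EVIDENCE"
    )
  )
  class(d) <- "tnm_dialect"
  d
}

parse_flag <- function(x, column, rows) {
  v <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(v %in% c("yes", "y", "true", "1") ~ TRUE,
                          v %in% c("no", "n", "false", "0") ~ FALSE,
                          TRUE ~ NA)
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    rlang::abort(paste0("Unparseable yes/no value in `", column, "`, row(s) ",
                        paste(rows[bad], collapse = ", "), ": ",
                        paste(unique(x[bad]), collapse = ", ")))
  }
  out
}

parse_count <- function(x, column, rows) {
  out <- suppressWarnings(as.integer(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    rlang::abort(paste0("Non-integer count in `", column, "`, row(s) ",
                        paste(rows[bad], collapse = ", ")))
  }
  out
}

#' Read pathology records from a delimited file
#'
#' @param path Path to a headered CSV/TSV file (delimiter inferred from the
#'   extension; `.tsv` reads tab-separated).
#' @param dialect A [table5_dialect()] describing headers and vocabulary.
#' @param gold Also parse the expert-code columns, when present.
#' @return With `gold = FALSE`, a tibble of pathology records. With
#'   `gold = TRUE`, a list `records` + `gold` (expert codes per specimen,
#'   `NULL` when the file has no expert columns).
#' @examples
#' path <- system.file("extdata", "table5_colorectal_tnm.csv",
#'                     package = "tnmstage")
#' read_records(path)
#' @export
read_records <- function(path, dialect = table5_dialect(), gold = FALSE) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  cols <- dialect$columns
  required <- cols[c("invasion", "rln_examined", "rln_positive",
                     "tumour_deposits", "distant_organ_count", "peritoneal_mets")]
  missing <- setdiff(unname(required), names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0("Input lacks required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  rows <- seq_len(nrow(raw))
  if (nrow(raw) == 0) {
    empty <- canonical_records(enumerate_canonical_states()[0, ])
    return(if (gold) list(records = empty, gold = NULL) else empty)
  }

  term <- trimws(raw[[cols[["invasion"]]]])
  unknown <- !term %in% names(dialect$invasion_terms)
  if (any(unknown)) {
    rlang::abort(paste0("Unknown invasion term in row(s) ",
                        paste(rows[unknown], collapse = ", "), ": ",
                        paste(unique(term[unknown]), collapse = ", ")))
  }
  mapped <- unname(dialect$invasion_terms[term])
  epistemic <- ifelse(mapped %in% c("NO_ASSESSMENT", "NO_EVIDENCE"),
                      mapped, "ASSESSED")

  ids <- if (cols[["specimen_id"]] %in% names(raw)) raw[[cols[["specimen_id"]]]] else
    as.character(rows)
  # optional column: records whose regional nodes could not be assessed (NX)
  n_epi <- if (cols[["n_assessed"]] %in% names(raw)) {
    ifelse(parse_flag(raw[[cols[["n_assessed"]]]], cols[["n_assessed"]], rows),
           "ASSESSED", "NO_ASSESSMENT")
  } else "ASSESSED"
  records <- tnm_records(
    specimen_id = ids,
    t_epistemic = epistemic,
    invasion = ifelse(epistemic == "ASSESSED", mapped, NA_character_),
    growth = NA_character_,
    n_epistemic = n_epi,
    rln_examined = parse_count(raw[[cols[["rln_examined"]]]], cols[["rln_examined"]], rows),
    rln_positive = parse_count(raw[[cols[["rln_positive"]]]], cols[["rln_positive"]], rows),
    tumour_deposits = parse_flag(raw[[cols[["tumour_deposits"]]]], cols[["tumour_deposits"]], rows),
    distant_organ_count = parse_count(raw[[cols[["distant_organ_count"]]]],
                                      cols[["distant_organ_count"]], rows),
    peritoneal_mets = parse_flag(raw[[cols[["peritoneal_mets"]]]], cols[["peritoneal_mets"]], rows),
    assessment_mode = "PATHOLOGICAL"
  )
  if (!gold) return(records)

  gold_cols <- cols[c("gold_t", "gold_n", "gold_m")]
  gold_tbl <- NULL
  if (all(gold_cols %in% names(raw))) {
    gold_tbl <- tibble::tibble(
      specimen_id = records$specimen_id,
      t = raw[[gold_cols[["gold_t"]]]],
      n = raw[[gold_cols[["gold_n"]]]],
      m = raw[[gold_cols[["gold_m"]]]]
    )
    gold_tbl$tnm <- paste0(gold_tbl$t, gold_tbl$n, gold_tbl$m)
  }
  list(records = records, gold = gold_tbl)
}

#' Write pathology records to a delimited file
#'
#' Inverse of [read_records()] for the canonical fields, using the dialect's
#' headers and vocabulary.
#'
#' @inheritParams read_records
#' @param records A tibble of pathology records.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, dialect = table5_dialect()) {
  records <- as_tnm_records(records)
  cols <- dialect$columns
  back <- stats::setNames(names(dialect$invasion_terms), dialect$invasion_terms)
  term <- dplyr::case_when(
    records$t_epistemic == "NO_ASSESSMENT" ~ back[["NO_ASSESSMENT"]],
    records$t_epistemic == "NO_EVIDENCE" ~ back[["NO_EVIDENCE"]],
    TRUE ~ unname(back[records$invasion])
  )
  out <- tibble::tibble(
    !!cols[["specimen_id"]] := records$specimen_id,
    !!cols[["invasion"]] := term,
    !!cols[["rln_examined"]] := records$rln_examined,
    !!cols[["rln_positive"]] := records$rln_positive,
    !!cols[["tumour_deposits"]] := ifelse(records$tumour_deposits, "yes", "no"),
    !!cols[["distant_organ_count"]] := records$distant_organ_count,
    !!cols[["peritoneal_mets"]] := ifelse(records$peritoneal_mets, "yes", "no"),
    !!cols[["n_assessed"]] := ifelse(records$n_epistemic == "ASSESSED", "yes", "no")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Classification report with optional expert agreement
#'
#' Joins predicted codes with expert ("gold") codes by specimen and reports,
#' per record, whether all three axes match, plus an overall agreement
#' percentage.
#'
#' @param results A `tnm_classification` tibble from [tnm_classify()].
#' @param gold Optional tibble of expert codes (`specimen_id`, `t`, `n`,
#'   `m`), e.g. from [table5_fixture()].
#' @param path Optional output file; `.json` writes records plus summary as
#'   JSON, anything else the per-record table as CSV.
#' @return A tibble of class `tnm_report` with per-record columns (and
#'   `gold_*`/`match` columns when `gold` is given); the agreement summary
#'   is available via [glance()].
#' @examples
#' fx <- table5_fixture()
#' rep <- write_report(tnm_classify(fx$records), gold = fx$gold)
#' glance(rep)
#' @export
write_report <- function(results, gold = NULL, path = NULL) {
  out <- tibble::as_tibble(results)[, c("specimen_id", "t", "n", "m", "tnm")]
  if (!is.null(gold)) {
    gold <- tibble::as_tibble(gold)
    unmatched <- setdiff(out$specimen_id, gold$specimen_id)
    if (length(unmatched) > 0) {
      rlang::abort(paste0("No expert codes for specimen(s): ",
                          paste(unmatched, collapse = ", ")))
    }
    gold_ren <- dplyr::rename(gold[, c("specimen_id", "t", "n", "m")],
                              gold_t = "t", gold_n = "n", gold_m = "m")
    out <- dplyr::left_join(out, gold_ren, by = "specimen_id")
    out$match <- out$t == out$gold_t & out$n == out$gold_n & out$m == out$gold_m
  }
  class(out) <- c("tnm_report", class(out))
  if (!is.null(path)) {
    if (grepl("\\.json$", path)) {
      jsonlite::write_json(list(records = tibble::as_tibble(out),
                                summary = as.list(glance(out))),
                           path, auto_unbox = TRUE, digits = NA)
    } else {
      readr::write_csv(tibble::as_tibble(out), path, progress = FALSE)
    }
  }
  out
}

#' @param x A `tnm_report`.
#' @describeIn write_report One-row summary: number of records, matches and
#'   the agreement percentage (`NA` without expert codes).
#' @export
glance.tnm_report <- function(x, ...) {
  has_gold <- "match" %in% names(x)
  tibble::tibble(
    n_records = nrow(x),
    n_matching = if (has_gold) sum(x$match) else NA_integer_,
    agreement_pct = if (has_gold && nrow(x) > 0) 100 * sum(x$match) / nrow(x)
                    else NA_real_
  )
}
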