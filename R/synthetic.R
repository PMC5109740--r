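# Canonical record space: the staging criteria only see (i) the T-axis state
# (unassessed / no evidence / one of 8 invasion depths), (ii) the N-axis
# state (unassessed, or 0 positive nodes vs. one of 4 positive-count regions,
# crossed with the tumour-deposit flag), and (iii) the M-axis state (no
# distant disease, or 1 vs >=2 involved organs, with or without the
# peritoneum among them). Enumerating one representative per cell covers
# every distinguishable input.

#' Enumerate the canonical record space
#'
#' Returns every staging-relevant equivalence class of pathology records:
#' 10 T states x 11 N states x 5 M states = 550 canonical states. Each state
#' materializes to a concrete valid record via [canonical_records()] using
#' the smallest count in each cardinality region (1, 2, 4, 7; 2 for multiple
#' distant organs).
#'
#' @return A tibble with columns `state_id`, `t_state`, `n_state`,
#'   `n_region`, `deposits`, `m_region`, `peritoneal`.
#' @examples
#' nrow(enumerate_canonical_states())
#' @export
enumerate_canonical_states <- function() {
  t_states <- c("NO_ASSESSMENT", "NO_EVIDENCE", invasion_depths)
  n_states <- dplyr::bind_rows(
    tibble::tibble(n_state = "NO_ASSESSMENT", n_region = "NONE", deposits = FALSE),
    tidyr::expand_grid(n_state = "ASSESSED",
                       n_region = c("NONE", "C1", "C2OR3", "C4TO6", "C7PLUS"),
                       deposits = c(FALSE, TRUE))
  )
  m_states <- tibble::tribble(
    ~m_region, ~peritoneal,
    "NONE",    FALSE,
    "C1",      FALSE,
    "C1",      TRUE,
    "C2PLUS",  FALSE,
    "C2PLUS",  TRUE
  )
  out <- tidyr::expand_grid(
    t_state = t_states,
    tidyr::nesting(n_state = n_states$n_state, n_region = n_states$n_region,
                   deposits = n_states$deposits),
    tidyr::nesting(m_region = m_states$m_region, peritoneal = m_states$peritoneal)
  )
  out$state_id <- seq_len(nrow(out))
  out[, c("state_id", "t_state", "n_state", "n_region", "deposits",
          "m_region", "peritoneal")]
}

region_representative <- c(C1 = 1L, C2OR3 = 2L, C4TO6 = 4L, C7PLUS = 7L,
                           C2PLUS = 2L, NONE = 0L)

#' Materialize canonical states as pathology records
#'
#' @param states A data frame of canonical states
#'   (see [enumerate_canonical_states()]).
#' @param rln_offset Non-negative number of tumour-free examined nodes added
#'   on top of the positive count (examined = positive + offset).
#' @return A tibble of valid pathology records, one per state, with
#'   `specimen_id` equal to the state id.
#' @export
canonical_records <- function(states, rln_offset = 10L) {
  states <- tibble::as_tibble(states)
  assessed_t <- !states$t_state %in% c("NO_ASSESSMENT", "NO_EVIDENCE")
  pos <- unname(region_representative[states$n_region])
  tnm_records(
    specimen_id = as.character(states$state_id),
    t_epistemic = ifelse(assessed_t, "ASSESSED", states$t_state),
    invasion = ifelse(assessed_t, states$t_state, NA_character_),
    growth = NA_character_,  # filled by tnm_records() from the depth
    n_epistemic = states$n_state,
    rln_examined = pos + as.integer(rln_offset),
    rln_positive = pos,
    tumour_deposits = states$deposits,
    distant_organ_count = unname(region_representative[states$m_region]),
    peritoneal_mets = states$peritoneal,
    assessment_mode = "PATHOLOGICAL"
  )
}

#' Sample random valid pathology records
#'
#' Draws canonical states uniformly and materializes them with counts drawn
#' uniformly within each cardinality region (2-or-3 region: 2 or 3; 4-to-6:
#' 4, 5 or 6; 7-or-more: 7 to 15; several distant organs: 2 to 4), plus a
#' random number of tumour-free examined nodes. Reproducible for a fixed
#' seed; every output passes [validate_records()] without error.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @return A tibble of `n` pathology records.
#' @examples
#' sample_records(5, seed = 1)
#' @export
sample_records <- function(n, seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0) return(canonical_records(enumerate_canonical_states()[0, ]))
  space <- enumerate_canonical_states()
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  states <- space[sample.int(nrow(space), n, replace = TRUE), ]
  states$state_id <- seq_len(n)
  draw_in <- function(region) {
    lo <- c(C1 = 1L, C2OR3 = 2L, C4TO6 = 4L, C7PLUS = 7L, C2PLUS = 2L)[region]
    hi <- c(C1 = 1L, C2OR3 = 3L, C4TO6 = 6L, C7PLUS = 15L, C2PLUS = 4L)[region]
    as.integer(lo + floor(stats::runif(length(region)) * (hi - lo + 1L)))
  }
  recs <- canonical_records(states)
  has_n <- states$n_region != "NONE"
  recs$rln_positive[has_n] <- draw_in(states$n_region[has_n])
  recs$rln_examined <- recs$rln_positive + sample.int(30L, n, replace = TRUE)
  has_m <- states$m_region != "NONE"
  recs$distant_organ_count[has_m] <- draw_in(states$m_region[has_m])
  recs
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' The 15 published example records with expert codes
#'
#' Loads the packaged fixture of 15 exemplary colorectal pathology records
#' together with the pathologist's manual TNM v7 codes, as used for the
#' agreement evaluation.
#'
#' @return A list with `records` (tibble of 15 pathology records) and `gold`
#'   (tibble: `specimen_id`, `t`, `n`, `m`, `tnm`).
#' @examples
#' table5_fixture()$gold
#' @export
table5_fixture <- function() {
  path <- system.file("extdata", "table5_colorectal_tnm.csv",
                      package = "tnmstage", mustWork = TRUE)
  parsed <- read_records(path, dialect = table5_dialect(), gold = TRUE)
  parsed
}
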