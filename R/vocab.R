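#' @keywords internal
"_PACKAGE"

#' Invasion depth levels of the colorectal gut wall
#'
#' Ordered vocabulary of primary-tumour invasion sites, from the epithelium
#' outward to invasion of adjacent organs. The position in the vector is the
#' anatomical depth rank used by the staging rules (epithelium has rank 0,
#' other organs rank 7).
#'
#' @format Character vector of length 8.
#' @export
invasion_depths <- c(
  "EPITHELIUM", "LAMINA_PROPRIA", "SUBMUCOSA", "MUSCULARIS_PROPRIA",
  "SUBSEROSA", "ADVENTITIA", "VISCERAL_PERITONEUM", "OTHER_ORGANS"
)

#' Growth-pattern and epistemic-status vocabularies
#'
#' `growth_patterns` distinguishes tumours confined to their layer from
#' infiltrative ones. `epistemic_statuses` captures whether an axis was
#' assessed at all (`ASSESSED`), could not be assessed (`NO_ASSESSMENT`,
#' the X codes), or was assessed with no evidence of tumour (`NO_EVIDENCE`,
#' the 0 codes on the T axis).
#'
#' @format Character vectors.
#' @export
growth_patterns <- c("CONFINED", "INFILTRATIVE")

#' @rdname growth_patterns
#' @export
epistemic_statuses <- c("ASSESSED", "NO_ASSESSMENT", "NO_EVIDENCE")

#' @rdname growth_patterns
#' @export
assessment_modes <- c("CLINICAL", "PATHOLOGICAL")

#' Depth rank of an invasion site
#'
#' @param depth Character vector of invasion-depth values
#'   (see [invasion_depths]).
#' @return Integer rank 0-7, `NA` for `NA` input.
#' @examples
#' invasion_rank(c("EPITHELIUM", "SUBSEROSA"))
#' @export
invasion_rank <- function(depth) {
  match(depth, invasion_depths) - 1L
}

# Cardinality value regions: integer intervals standing in for raw counts.
# Regions within one axis partition the positive integers.
cardinality_regions_tbl <- function() {
  tibble::tribble(
    ~axis,            ~label,    ~lower, ~upper,
    "REGIONAL_LN",    "C1",      1L,     1L,
    "REGIONAL_LN",    "C2OR3",   2L,     3L,
    "REGIONAL_LN",    "C4TO6",   4L,     6L,
    "REGIONAL_LN",    "C7PLUS",  7L,     NA_integer_,
    "DISTANT_ORGANS", "C1",      1L,     1L,
    "DISTANT_ORGANS", "C2PLUS",  2L,     NA_integer_
  )
}

#' Cardinality value regions
#'
#' The staging criteria never use raw counts directly: counts of metastatic
#' regional lymph nodes and of distantly involved organs are abstracted into
#' disjoint integer intervals ("value regions"), e.g. 2-or-3 metastatic
#' regional nodes. `cardinality_regions()` lists the regions per axis;
#' `region_for()` returns the unique region containing a positive count.
#'
#' @param axis `"REGIONAL_LN"` or `"DISTANT_ORGANS"`.
#' @param count Positive integer vector of counts. A zero count is not a
#'   region: it is handled upstream as absence of evidence.
#' @return `cardinality_regions()`: a tibble with columns `axis`, `label`,
#'   `lower`, `upper` (`NA` upper = unbounded). `region_for()`: character
#'   vector of region labels.
#' @examples
#' region_for("REGIONAL_LN", c(1, 2, 6, 7))
#' @export
cardinality_regions <- function(axis = c("REGIONAL_LN", "DISTANT_ORGANS")) {
  axis <- match.arg(axis)
  dplyr::filter(cardinality_regions_tbl(), .data$axis == !!axis)
}

#' @rdname cardinality_regions
#' @export
region_for <- function(axis, count) {
  axis <- match.arg(axis, c("REGIONAL_LN", "DISTANT_ORGANS"))
  count <- as.integer(count)
  if (any(is.na(count)) || any(count < 1L)) {
    rlang::abort("`count` must be >= 1; a zero count is NoEvidence, not a region.")
  }
  regions <- cardinality_regions(axis)
  idx <- purrr::map_int(count, function(k) {
    which(regions$lower <= k & (is.na(regions$upper) | k <= regions$upper))
  })
  regions$label[idx]
}

# --- TNM code vocabulary -----------------------------------------------------

tnm_vocab <- list(
  T = c("X", "0", "is", "1", "2", "3", "4a", "4b"),
  N = c("X", "0", "1a", "1b", "1c", "2a", "2b"),
  M = c("0", "1a", "1b")
)

# Severity rank within an axis; X (and T0) are unranked.
tnm_ranks <- list(
  T = c(X = NA, `0` = NA, is = 1, `1` = 2, `2` = 3, `3` = 4, `4a` = 5, `4b` = 6),
  N = c(X = NA, `0` = 0, `1a` = 1, `1b` = 2, `1c` = 3, `2a` = 4, `2b` = 5),
  M = c(`0` = 0, `1a` = 1, `1b` = 2)
)

#' Severity rank of a TNM code value within its axis
#'
#' Used by the monotonicity checks: deeper invasion must never lower the T
#' rank, more positive nodes never the N rank. Unassessable codes (TX, NX)
#' and T0 carry no rank.
#'
#' @param axis `"T"`, `"N"` or `"M"` (scalar).
#' @param value Character vector of code values from the axis vocabulary,
#'   e.g. `"4a"`, `"1c"`.
#' @return Numeric rank, `NA` where the code is unranked.
#' @examples
#' tnm_rank("N", c("0", "1c", "2b"))
#' @export
tnm_rank <- function(axis, value) {
  axis <- match.arg(axis, c("T", "N", "M"))
  bad <- !value %in% tnm_vocab[[axis]]
  if (any(bad)) {
    rlang::abort(paste0(
      "Unknown ", axis, " code value(s): ",
      paste(unique(value[bad]), collapse = ", ")
    ))
  }
  unname(tnm_ranks[[axis]][value])
}

# Render one code, e.g. ("T","3","p") -> "pT3". The M axis prints unprefixed.
render_code <- function(axis, value, modifier) {
  prefix <- ifelse(modifier %in% c("c", "p"), modifier, "")
  paste0(prefix, axis, value)
}
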