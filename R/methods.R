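#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy views of an axiom set
#'
#' `tidy()` returns one row per axiom with its kind and a canonical textual
#' rendering; `glance()` a one-row structural summary (concept, unit,
#' relation and per-kind axiom counts).
#'
#' @param x A `tnm_axiom_set`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tnm_axiom_set <- function(x, ...) {
  tibble::tibble(
    kind = vapply(x$axioms, function(a) a$kind, ""),
    axiom = vapply(x$axioms, axiom_string, "")
  )
}

#' @rdname tidy.tnm_axiom_set
#' @export
glance.tnm_axiom_set <- function(x, ...) {
  kinds <- vapply(x$axioms, function(a) a$kind, "")
  tibble::tibble(
    n_concepts = nrow(x$concepts),
    n_units = sum(x$concepts$category == "unit"),
    n_defined = sum(x$concepts$category == "defined"),
    n_relations = nrow(x$relations),
    n_axioms = length(x$axioms),
    n_subclass = sum(kinds == "subClassOf"),
    n_equivalent = sum(kinds == "equivalentTo"),
    n_disjoint = sum(kinds == "disjointClasses")
  )
}

#' Plot the code distribution of a classification
#'
#' Bar chart of assigned codes per axis, the quick visual check that a
#' cohort's staging distribution looks plausible.
#'
#' @param object A `tnm_classification` from [tnm_classify()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(tnm_classify(table5_fixture()$records))
#' @export
autoplot.tnm_classification <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object)[, c("t", "n", "m")],
                              dplyr::everything(),
                              names_to = "axis", values_to = "code")
  long$axis <- factor(toupper(long$axis), levels = c("T", "N", "M"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$code)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$axis), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "specimens",
                  title = "Assigned TNM codes per axis") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tnm_classification
#' @details For a `tnm_report` with expert codes, `autoplot()` draws a
#'   per-specimen agreement strip instead.
#' @export
autoplot.tnm_report <- function(object, ...) {
  if (!"match" %in% names(object)) {
    rlang::abort("Report has no expert codes; nothing to compare.")
  }
  df <- tibble::as_tibble(object)
  df$specimen_id <- factor(df$specimen_id, levels = df$specimen_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$specimen_id, y = 1,
                                   fill = .data$match)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey25", `FALSE` = "firebrick"),
                               name = "all axes match") +
    ggplot2::labs(x = "specimen", y = NULL,
                  title = "Agreement with expert TNM codes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @importFrom rlang .data :=
NULL
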