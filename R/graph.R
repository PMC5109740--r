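# Minimal RDF triple store used for both the OWL export and the instance
# graphs. Terms are plain strings: blank nodes start with "_:", everything
# else in `s`/`p` is an IRI; `o_type` distinguishes IRIs from literals and
# `o_dt` carries an optional literal datatype IRI.

RDF  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL  <- "http://www.w3.org/2002/07/owl#"
XSD  <- "http://www.w3.org/2001/XMLSchema#"

empty_graph <- function() {
  g <- tibble::tibble(s = character(), p = character(), o = character(),
                      o_type = character(), o_dt = character())
  class(g) <- c("tnm_graph", class(g))
  g
}

triple <- function(s, p, o, o_type = "iri", o_dt = NA_character_) {
  tibble::tibble(s = s, p = p, o = as.character(o), o_type = o_type, o_dt = o_dt)
}

lit <- function(s, p, o, dt = NA_character_) triple(s, p, o, "literal", dt)
int_lit <- function(s, p, o) lit(s, p, o, paste0(XSD, "integer"))

as_graph <- function(triples) {
  g <- dplyr::distinct(dplyr::bind_rows(triples))
  if (!inherits(g, "tnm_graph")) class(g) <- c("tnm_graph", class(g))
  g
}

is_bnode <- function(x) startsWith(x, "_:")

# --- Turtle (line-based N-Triples subset, valid Turtle) ----------------------

escape_lit <- function(x) {
  x <- gsub("\\\\", "\\\\\\\\", x)
  x <- gsub("\"", "\\\\\"", x)
  gsub("\n", "\\\\n", x)
}

unescape_lit <- function(x) {
  x <- gsub("\\\\n", "\n", x)
  x <- gsub("\\\\\"", "\"", x)
  gsub("\\\\\\\\", "\\\\", x)
}

ttl_term <- function(x, type = "iri", dt = NA_character_) {
  if (type == "literal") {
    out <- paste0("\"", escape_lit(x), "\"")
    return(ifelse(is.na(dt), out, paste0(out, "^^<", dt, ">")))
  }
  ifelse(is_bnode(x), x, paste0("<", x, ">"))
}

#' Serialize / parse an RDF graph
#'
#' `write_graph()` serializes a triple-store tibble to Turtle (emitted as
#' the line-based N-Triples subset, which any Turtle parser accepts) or
#' RDF/XML; `read_graph()` parses either format back. Round-tripping
#' preserves the triple set exactly.
#'
#' @param graph A `tnm_graph` tibble (columns `s`, `p`, `o`, `o_type`,
#'   `o_dt`).
#' @param path Output/input file path; `write_graph()` also accepts `NULL`
#'   to return the serialized text.
#' @param format `"turtle"` or `"rdfxml"`.
#' @return `write_graph()`: the serialized text, invisibly when written to a
#'   file. `read_graph()`: a `tnm_graph` tibble.
#' @export
write_graph <- function(graph, path = NULL, format = c("turtle", "rdfxml")) {
  format <- match.arg(format)
  text <- if (format == "turtle") graph_to_turtle(graph) else graph_to_rdfxml(graph)
  if (is.null(path)) return(text)
  writeLines(text, path, useBytes = TRUE)
  invisible(text)
}

#' @rdname write_graph
#' @param text Serialized graph text, as an alternative to `path`.
#' @export
read_graph <- function(path = NULL, format = c("turtle", "rdfxml"), text = NULL) {
  format <- match.arg(format)
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (format == "turtle") turtle_to_graph(text) else rdfxml_to_graph(text)
}

graph_to_turtle <- function(graph) {
  if (nrow(graph) == 0) return("")
  paste0(
    ttl_term(graph$s), " ", ttl_term(graph$p), " ",
    mapply(ttl_term, graph$o, graph$o_type, graph$o_dt, USE.NAMES = FALSE),
    " .", collapse = "\n"
  )
}

turtle_to_graph <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "@")]
  if (length(lines) == 0) return(empty_graph())
  m <- regmatches(lines, regexec(
    "^(<[^>]*>|_:[A-Za-z0-9]+)\\s+<([^>]*)>\\s+(.*?)\\s*\\.$", lines))
  bad <- vapply(m, length, 0L) != 4
  if (any(bad)) {
    rlang::abort(paste0("Unparseable Turtle line(s): ",
                        paste(utils::head(lines[bad], 3), collapse = " | ")))
  }
  strip <- function(x) ifelse(startsWith(x, "<"), substr(x, 2, nchar(x) - 1L), x)
  s <- strip(vapply(m, `[[`, "", 2))
  p <- vapply(m, `[[`, "", 3)
  obj <- vapply(m, `[[`, "", 4)

  o <- character(length(obj)); o_type <- character(length(obj))
  o_dt <- rep(NA_character_, length(obj))
  for (i in seq_along(obj)) {
    t <- obj[i]
    if (startsWith(t, "\"")) {
      mm <- regmatches(t, regexec("^\"((?:[^\"\\\\]|\\\\.)*)\"(?:\\^\\^<([^>]*)>)?$", t))[[1]]
      o[i] <- unescape_lit(mm[2]); o_type[i] <- "literal"
      if (length(mm) >= 3 && nzchar(mm[3])) o_dt[i] <- mm[3]
    } else {
      o[i] <- strip(t); o_type[i] <- "iri"
    }
  }
  as_graph(tibble::tibble(s = s, p = p, o = o, o_type = o_type, o_dt = o_dt))
}

# --- RDF/XML via xml2 --------------------------------------------------------

split_iri <- function(iri) {
  pos <- regexpr("[#/][^#/]*$", iri)
  ns <- substr(iri, 1, pos)
  local <- substr(iri, pos + 1L, nchar(iri))
  if (pos < 0 || !nzchar(local) || grepl("^[0-9]", local)) {
    rlang::abort(paste0("Cannot form an XML QName for predicate IRI: ", iri))
  }
  c(ns = ns, local = local)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

graph_to_rdfxml <- function(graph) {
  preds <- unique(graph$p)
  parts <- t(vapply(preds, split_iri, c(ns = "", local = "")))
  nss <- unique(parts[, "ns"])
  prefix_of <- stats::setNames(paste0("n", seq_along(nss)), nss)
  prefix_of[RDF] <- "rdf"
  decls <- paste0(" xmlns:", unname(prefix_of), "=\"", xml_escape(names(prefix_of)), "\"",
                  collapse = "")
  qname <- function(p) {
    sp <- split_iri(p)
    paste0(prefix_of[[sp[["ns"]]]], ":", sp[["local"]])
  }
  body <- character()
  for (subj in unique(graph$s)) {
    attr <- if (is_bnode(subj)) {
      paste0(" rdf:nodeID=\"", substr(subj, 3, nchar(subj)), "\"")
    } else {
      paste0(" rdf:about=\"", xml_escape(subj), "\"")
    }
    rows <- graph[graph$s == subj, ]
    props <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      q <- qname(rows$p[i])
      props[i] <- if (rows$o_type[i] == "literal") {
        dt <- if (!is.na(rows$o_dt[i]))
          paste0(" rdf:datatype=\"", xml_escape(rows$o_dt[i]), "\"") else ""
        paste0("    <", q, dt, ">", xml_escape(rows$o[i]), "</", q, ">")
      } else if (is_bnode(rows$o[i])) {
        paste0("    <", q, " rdf:nodeID=\"", substr(rows$o[i], 3, nchar(rows$o[i])), "\"/>")
      } else {
        paste0("    <", q, " rdf:resource=\"", xml_escape(rows$o[i]), "\"/>")
      }
    }
    body <- c(body, paste0("  <rdf:Description", attr, ">"), props,
              "  </rdf:Description>")
  }
  paste(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
          paste0("<rdf:RDF", decls, ">"), body, "</rdf:RDF>"),
        collapse = "\n")
}

rdfxml_to_graph <- function(text) {
  doc <- xml2::read_xml(text)
  ns_map <- xml2::xml_ns(doc)
  resolve <- function(name) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2) paste0(ns_map[[parts[1]]], parts[2]) else name
  }
  out <- list()
  for (desc in xml2::xml_children(doc)) {
    about <- xml2::xml_attr(desc, "about")
    node_id <- xml2::xml_attr(desc, "nodeID")
    subj <- if (!is.na(about)) about else paste0("_:", node_id)
    for (prop in xml2::xml_children(desc)) {
      p <- resolve(xml2::xml_name(prop, ns_map))
      res <- xml2::xml_attr(prop, "resource")
      oid <- xml2::xml_attr(prop, "nodeID")
      if (!is.na(res)) {
        out[[length(out) + 1]] <- triple(subj, p, res)
      } else if (!is.na(oid)) {
        out[[length(out) + 1]] <- triple(subj, p, paste0("_:", oid))
      } else {
        dt <- xml2::xml_attr(prop, "datatype")
        out[[length(out) + 1]] <- lit(subj, p, xml2::xml_text(prop), dt)
      }
    }
  }
  if (length(out) == 0) return(empty_graph())
  as_graph(out)
}

# set-equality of two graphs up to blank-node renaming is not needed here:
# serializers keep blank-node labels stable, so plain set equality applies
same_graph <- function(a, b) {
  key <- function(g) {
    sort(paste(g$s, g$p, g$o, g$o_type, ifelse(is.na(g$o_dt), "", g$o_dt),
               sep = "\r"))
  }
  identical(key(a), key(b))
}
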