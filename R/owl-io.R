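# OWL 2 export of the axiom set. Turtle and RDF/XML go through the RDF
# mapping of OWL (restrictions and boolean connectives as blank nodes, RDF
# lists for operands); functional syntax is written and parsed directly.

iri_of <- function(axioms, name) paste0(axioms$base_iri, name)

local_of <- function(base_iri, iri) {
  ifelse(startsWith(iri, base_iri), substring(iri, nchar(base_iri) + 1L), iri)
}

# --- axioms -> triples -------------------------------------------------------

owl_graph <- function(axioms) {
  base <- axioms$base_iri
  counter <- new.env(); counter$n <- 0L
  bnode <- function() {
    counter$n <- counter$n + 1L
    paste0("_:b", counter$n)
  }
  out <- list()
  emit <- function(...) out[[length(out) + 1]] <<- triple(...)

  rdf_list <- function(nodes) {
    if (length(nodes) == 0) return(paste0(RDF, "nil"))
    head <- bnode(); cur <- head
    for (i in seq_along(nodes)) {
      emit(cur, paste0(RDF, "first"), nodes[[i]])
      nxt <- if (i == length(nodes)) paste0(RDF, "nil") else bnode()
      emit(cur, paste0(RDF, "rest"), nxt)
      cur <- nxt
    }
    head
  }
  expr_node <- function(e) {
    switch(e$type,
      named = paste0(base, e$name),
      and = , or = {
        b <- bnode()
        emit(b, paste0(RDF, "type"), paste0(OWL, "Class"))
        key <- if (e$type == "and") "intersectionOf" else "unionOf"
        emit(b, paste0(OWL, key), rdf_list(lapply(e$args, expr_node)))
        b
      },
      not = {
        b <- bnode()
        emit(b, paste0(RDF, "type"), paste0(OWL, "Class"))
        emit(b, paste0(OWL, "complementOf"), expr_node(e$arg))
        b
      },
      some = , only = {
        b <- bnode()
        emit(b, paste0(RDF, "type"), paste0(OWL, "Restriction"))
        emit(b, paste0(OWL, "onProperty"), paste0(base, e$rel))
        key <- if (e$type == "some") "someValuesFrom" else "allValuesFrom"
        emit(b, paste0(OWL, key), expr_node(e$filler))
        b
      }
    )
  }

  emit(sub("#$|/$", "", base), paste0(RDF, "type"), paste0(OWL, "Ontology"))
  for (cname in axioms$concepts$name) {
    emit(paste0(base, cname), paste0(RDF, "type"), paste0(OWL, "Class"))
  }
  for (i in seq_len(nrow(axioms$relations))) {
    emit(paste0(base, axioms$relations$name[i]), paste0(RDF, "type"),
         paste0(OWL, "ObjectProperty"))
  }
  inv <- axioms$relations[!is.na(axioms$relations$inverse), ]
  inv <- inv[inv$name < inv$inverse, ]
  for (i in seq_len(nrow(inv))) {
    emit(paste0(base, inv$name[i]), paste0(OWL, "inverseOf"),
         paste0(base, inv$inverse[i]))
  }
  for (ax in axioms$axioms) {
    switch(ax$kind,
      subClassOf = emit(expr_node(ax$lhs), paste0(RDFS, "subClassOf"),
                        expr_node(ax$rhs)),
      equivalentTo = emit(expr_node(ax$lhs), paste0(OWL, "equivalentClass"),
                          expr_node(ax$rhs)),
      disjointClasses = {
        b <- bnode()
        emit(b, paste0(RDF, "type"), paste0(OWL, "AllDisjointClasses"))
        emit(b, paste0(OWL, "members"), rdf_list(lapply(ax$operands, expr_node)))
      }
    )
  }
  as_graph(out)
}

# --- triples -> axioms -------------------------------------------------------

graph_to_axioms <- function(graph, base_iri) {
  obj_of <- function(s, p) graph$o[graph$s == s & graph$p == p]
  read_list <- function(node) {
    out <- list()
    while (node != paste0(RDF, "nil")) {
      out[[length(out) + 1]] <- obj_of(node, paste0(RDF, "first"))
      node <- obj_of(node, paste0(RDF, "rest"))
    }
    out
  }
  read_expr <- function(node) {
    if (!is_bnode(node)) return(c_named(local_of(base_iri, node)))
    on_prop <- obj_of(node, paste0(OWL, "onProperty"))
    if (length(on_prop) == 1) {
      rel <- local_of(base_iri, on_prop)
      some <- obj_of(node, paste0(OWL, "someValuesFrom"))
      if (length(some) == 1) return(c_some(rel, read_expr(some)))
      return(c_only(rel, read_expr(obj_of(node, paste0(OWL, "allValuesFrom")))))
    }
    compl <- obj_of(node, paste0(OWL, "complementOf"))
    if (length(compl) == 1) return(c_not(read_expr(compl)))
    inter <- obj_of(node, paste0(OWL, "intersectionOf"))
    if (length(inter) == 1) {
      return(do.call(c_and, lapply(read_list(inter), read_expr)))
    }
    union <- obj_of(node, paste0(OWL, "unionOf"))
    if (length(union) == 1) {
      return(do.call(c_or, lapply(read_list(union), read_expr)))
    }
    rlang::abort(paste0("Blank node is not a recognised class expression: ", node))
  }

  axioms <- list()
  for (i in which(graph$p == paste0(RDFS, "subClassOf"))) {
    axioms[[length(axioms) + 1]] <- list(
      kind = "subClassOf", lhs = read_expr(graph$s[i]), rhs = read_expr(graph$o[i]))
  }
  for (i in which(graph$p == paste0(OWL, "equivalentClass"))) {
    axioms[[length(axioms) + 1]] <- list(
      kind = "equivalentTo", lhs = read_expr(graph$s[i]), rhs = read_expr(graph$o[i]))
  }
  adc <- graph$s[graph$p == paste0(RDF, "type") &
                   graph$o == paste0(OWL, "AllDisjointClasses")]
  for (node in adc) {
    members <- read_list(obj_of(node, paste0(OWL, "members")))
    axioms[[length(axioms) + 1]] <- list(
      kind = "disjointClasses", operands = lapply(members, read_expr))
  }

  type_is <- function(what) {
    s <- graph$s[graph$p == paste0(RDF, "type") & graph$o == paste0(OWL, what)]
    sort(local_of(base_iri, s[!is_bnode(s)]))
  }
  inv_rows <- which(graph$p == paste0(OWL, "inverseOf"))
  list(
    axioms = axioms,
    concepts = type_is("Class"),
    relations = type_is("ObjectProperty"),
    inverses = tibble::tibble(
      a = local_of(base_iri, graph$s[inv_rows]),
      b = local_of(base_iri, graph$o[inv_rows])
    )
  )
}

# --- functional syntax -------------------------------------------------------

fs_expr <- function(e) {
  switch(e$type,
    named = paste0(":", e$name),
    and = paste0("ObjectIntersectionOf(", paste(vapply(e$args, fs_expr, ""),
                                                collapse = " "), ")"),
    or = paste0("ObjectUnionOf(", paste(vapply(e$args, fs_expr, ""),
                                        collapse = " "), ")"),
    not = paste0("ObjectComplementOf(", fs_expr(e$arg), ")"),
    some = paste0("ObjectSomeValuesFrom(:", e$rel, " ", fs_expr(e$filler), ")"),
    only = paste0("ObjectAllValuesFrom(:", e$rel, " ", fs_expr(e$filler), ")")
  )
}

owl_functional <- function(axioms) {
  lines <- c(
    paste0("Prefix(:=<", axioms$base_iri, ">)"),
    paste0("Prefix(owl:=<", OWL, ">)"),
    paste0("Ontology(<", sub("#$|/$", "", axioms$base_iri), ">"),
    paste0("Declaration(Class(:", axioms$concepts$name, "))"),
    paste0("Declaration(ObjectProperty(:", axioms$relations$name, "))")
  )
  inv <- axioms$relations[!is.na(axioms$relations$inverse), ]
  inv <- inv[inv$name < inv$inverse, ]
  lines <- c(lines, paste0("InverseObjectProperties(:", inv$name, " :", inv$inverse, ")"))
  for (ax in axioms$axioms) {
    lines <- c(lines, switch(ax$kind,
      subClassOf = paste0("SubClassOf(", fs_expr(ax$lhs), " ", fs_expr(ax$rhs), ")"),
      equivalentTo = paste0("EquivalentClasses(", fs_expr(ax$lhs), " ",
                            fs_expr(ax$rhs), ")"),
      disjointClasses = paste0("DisjointClasses(",
                               paste(vapply(ax$operands, fs_expr, ""),
                                     collapse = " "), ")")
    ))
  }
  paste(c(lines, ")"), collapse = "\n")
}

fs_tokenize <- function(text) {
  text <- gsub("\\)", " ) ", gsub("\\(", " ( ", text))
  tokens <- strsplit(text, "\\s+")[[1]]
  tokens[nzchar(tokens)]
}

# recursive-descent parse of one s-expression starting at pos; returns
# list(value, next_pos). Heads are OWL keywords; leaves are :Name tokens.
fs_parse_sexpr <- function(tokens, pos) {
  head <- tokens[pos]
  stopifnot(tokens[pos + 1] == "(")
  pos <- pos + 2
  args <- list()
  while (tokens[pos] != ")") {
    if (pos + 1 <= length(tokens) && tokens[pos + 1] == "(") {
      parsed <- fs_parse_sexpr(tokens, pos)
      args[[length(args) + 1]] <- parsed$value
      pos <- parsed$next_pos
    } else {
      args[[length(args) + 1]] <- tokens[pos]
      pos <- pos + 1
    }
  }
  list(value = list(head = head, args = args), next_pos = pos + 1)
}

fs_to_expr <- function(x) {
  if (is.character(x)) return(c_named(sub("^:", "", x)))
  switch(x$head,
    ObjectIntersectionOf = do.call(c_and, lapply(x$args, fs_to_expr)),
    ObjectUnionOf = do.call(c_or, lapply(x$args, fs_to_expr)),
    ObjectComplementOf = c_not(fs_to_expr(x$args[[1]])),
    ObjectSomeValuesFrom = c_some(sub("^:", "", x$args[[1]]), fs_to_expr(x$args[[2]])),
    ObjectAllValuesFrom = c_only(sub("^:", "", x$args[[1]]), fs_to_expr(x$args[[2]])),
    rlang::abort(paste0("Unknown class-expression constructor: ", x$head))
  )
}

parse_functional <- function(text) {
  # drop prefix declarations and the Ontology(...) shell
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[!grepl("^\\s*Prefix\\(", lines)]
  body <- paste(lines, collapse = "\n")
  body <- sub("^\\s*Ontology\\(\\s*<[^>]*>", "", body)
  body <- sub("\\)\\s*$", "", body)
  tokens <- fs_tokenize(body)

  axioms <- list(); concepts <- character(); relations <- character()
  inverses <- list()
  pos <- 1
  while (pos <= length(tokens)) {
    parsed <- fs_parse_sexpr(tokens, pos)
    pos <- parsed$next_pos
    x <- parsed$value
    name1 <- function() sub("^:", "", x$args[[1]]$args[[1]])
    switch(x$head,
      Declaration = {
        if (x$args[[1]]$head == "Class") concepts <- c(concepts, name1())
        else relations <- c(relations, name1())
      },
      InverseObjectProperties = {
        inverses[[length(inverses) + 1]] <- tibble::tibble(
          a = sub("^:", "", x$args[[1]]), b = sub("^:", "", x$args[[2]]))
      },
      SubClassOf = {
        axioms[[length(axioms) + 1]] <- list(
          kind = "subClassOf", lhs = fs_to_expr(x$args[[1]]),
          rhs = fs_to_expr(x$args[[2]]))
      },
      EquivalentClasses = {
        axioms[[length(axioms) + 1]] <- list(
          kind = "equivalentTo", lhs = fs_to_expr(x$args[[1]]),
          rhs = fs_to_expr(x$args[[2]]))
      },
      DisjointClasses = {
        axioms[[length(axioms) + 1]] <- list(
          kind = "disjointClasses", operands = lapply(x$args, fs_to_expr))
      },
      rlang::abort(paste0("Unknown axiom constructor: ", x$head))
    )
  }
  list(axioms = axioms, concepts = sort(concepts), relations = sort(relations),
       inverses = dplyr::bind_rows(inverses))
}

# --- public surface ----------------------------------------------------------

#' Export / parse the axiom set as an OWL 2 ontology
#'
#' `export_owl()` serializes a built axiom set to Turtle, RDF/XML or OWL
#' functional syntax under the set's base IRI. `parse_owl()` reads any of
#' the three back into an axiom list; re-parsing an export yields the same
#' axiom multiset (see [owl_axiom_strings()] for the canonical comparison
#' key).
#'
#' @param axioms A `tnm_axiom_set` from [build_axiom_set()] (for
#'   `export_owl`).
#' @param path File to write/read; `export_owl(path = NULL)` returns the
#'   document text.
#' @param syntax `"turtle"`, `"rdfxml"` or `"functional"`.
#' @param text Document text, as an alternative to `path` in `parse_owl()`.
#' @return `export_owl()`: the document text (invisibly when written).
#'   `parse_owl()`: a list with `axioms`, `concepts`, `relations`,
#'   `inverses`.
#' @examples
#' ax <- build_axiom_set()
#' doc <- export_owl(ax, syntax = "functional")
#' length(parse_owl(text = doc, syntax = "functional")$axioms)
#' @export
export_owl <- function(axioms, path = NULL,
                       syntax = c("turtle", "rdfxml", "functional")) {
  stopifnot(inherits(axioms, "tnm_axiom_set"))
  syntax <- match.arg(syntax)
  text <- switch(syntax,
    turtle = graph_to_turtle(owl_graph(axioms)),
    rdfxml = graph_to_rdfxml(owl_graph(axioms)),
    functional = owl_functional(axioms)
  )
  if (is.null(path)) return(text)
  writeLines(text, path, useBytes = TRUE)
  invisible(text)
}

#' @rdname export_owl
#' @param base_iri Base IRI used to shorten concept IRIs back to local
#'   names when parsing the RDF-based syntaxes.
#' @export
parse_owl <- function(path = NULL, syntax = c("turtle", "rdfxml", "functional"),
                      text = NULL,
                      base_iri = "http://example.org/tnmo/colorectal7#") {
  syntax <- match.arg(syntax)
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (syntax == "functional") return(parse_functional(text))
  graph <- if (syntax == "turtle") turtle_to_graph(text) else rdfxml_to_graph(text)
  graph_to_axioms(graph, base_iri)
}

#' @rdname export_owl
#' @param x A `tnm_axiom_set` or the result of `parse_owl()`.
#' @export
owl_axiom_strings <- function(x) {
  axiom_strings(if (inherits(x, "tnm_axiom_set")) x$axioms else x$axioms)
}
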