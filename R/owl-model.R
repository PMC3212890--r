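#' OWL property restrictions and class definitions
#'
#' The matchmaking subset covers `owl:Restriction` with `someValuesFrom`,
#' `allValuesFrom`, `minCardinality` and `hasValue`, plus `owl:intersectionOf`
#' and `rdfs:subClassOf` to named classes. Classification is structural:
#' restrictions are checked directly against asserted triples, with no DL
#' entailment, so the checker works wherever a reasoner is unavailable.
#'
#' @param property plain IRI of the restricted property
#' @param kind one of `"someValuesFrom"`, `"allValuesFrom"`,
#'   `"minCardinality"`, `"hasValue"`
#' @param filler for the ValuesFrom kinds a plain class/datatype IRI, for
#'   `hasValue` an encoded term (see [iri()] / [lit()]); must be `NULL` for
#'   `minCardinality`
#' @param min_count threshold (>= 1) for `minCardinality`; distinct RDF terms
#'   are counted, so two syntactically different literals count as two
#' @return an `owl_restriction`
#' @export
owl_restriction <- function(property,
                            kind = c("someValuesFrom", "allValuesFrom",
                                     "minCardinality", "hasValue"),
                            filler = NULL, min_count = NULL) {
  kind <- match.arg(kind)
  if (kind == "minCardinality") {
    stopifnot(is.null(filler), !is.null(min_count), min_count >= 1L)
  } else {
    stopifnot(!is.null(filler), is.null(min_count))
  }
  structure(list(property = property, kind = kind, filler = filler,
                 min_count = if (is.null(min_count)) NULL else as.integer(min_count)),
            class = "owl_restriction")
}

#' @export
format.owl_restriction <- function(x, ...) {
  detail <- switch(x$kind,
    minCardinality = sprintf(">= %d values", x$min_count),
    hasValue = sprintf("value %s", x$filler),
    sprintf("%s <%s>", x$kind, x$filler)
  )
  sprintf("[<%s> %s]", x$property, detail)
}

#' @export
print.owl_restriction <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @rdname owl_restriction
#' @param class_iri plain IRI of the class
#' @param restrictions list of [owl_restriction()] (may be empty: such a
#'   class matches every node, like `owl:Thing`)
#' @param superclasses character vector of named superclass IRIs
#' @export
owl_class <- function(class_iri, restrictions = list(), superclasses = character()) {
  stopifnot(is.character(class_iri), nzchar(class_iri))
  structure(list(iri = class_iri, restrictions = restrictions,
                 superclasses = unique(superclasses)),
            class = "owl_class")
}

#' @rdname owl_restriction
#' @param classes list of [owl_class()] (named by IRI, or unnamed)
#' @param datatype_properties plain IRIs declared `owl:DatatypeProperty`
#' @export
ontology <- function(classes = list(), datatype_properties = character()) {
  if (is.null(names(classes)) && length(classes) > 0L) {
    names(classes) <- vapply(classes, function(c) c$iri, character(1))
  }
  structure(list(classes = classes,
                 datatype_properties = unique(datatype_properties)),
            class = "owl_ontology")
}

#' Load an ontology document
#'
#' Reads the supported OWL subset from an RDF document. Class definitions may
#' use `rdfs:subClassOf` and/or `owl:equivalentClass` with named classes,
#' restriction nodes and `owl:intersectionOf` lists (nested intersections are
#' flattened). Unsupported constructs (`owl:unionOf`, `owl:complementOf`,
#' restriction nodes without a recognised kind) produce warnings and are
#' excluded from matchmaking — never silently dropped.
#'
#' @param source document text, or a plain IRI to retrieve through `fetch`
#' @param fetch optional resolver contract as in [resolve_by_reference()]
#' @param media_type media type of `source` when it is document text
#' @return an [ontology()]
#' @export
load_ontology <- function(source, fetch = NULL, media_type = MEDIA_N3) {
  if (!is.null(fetch) && grepl("^[A-Za-z][A-Za-z0-9+.-]*://", source)) {
    doc <- fetch(source)
    g <- parse_graph(doc$body, doc$media_type)
  } else {
    g <- parse_graph(source, media_type)
  }
  ontology_from_graph(g)
}

rdf_list_members <- function(g, head) {
  out <- character(0)
  cur <- head
  seen <- character(0)
  while (cur != iri(RDF$nil)) {
    if (cur %in% seen) stop_parse("cyclic RDF collection")
    seen <- c(seen, cur)
    first <- graph_match(g, s = cur, p = iri(RDF$first))$o
    rest <- graph_match(g, s = cur, p = iri(RDF$rest))$o
    if (length(first) != 1L || length(rest) != 1L) {
      stop_parse("malformed RDF collection node")
    }
    out <- c(out, first)
    cur <- rest
  }
  out
}

ontology_from_graph <- function(g) {
  class_subjects <- graph_match(g, p = iri(RDF$type), o = iri(OWL$Class))$s
  class_subjects <- class_subjects[is_iri_term(class_subjects)]

  parse_restriction <- function(node) {
    prop <- graph_match(g, s = node, p = iri(OWL$onProperty))$o
    if (length(prop) != 1L || !is_iri_term(prop)) {
      warn_sadi("restriction node without a single owl:onProperty; excluded",
                class = "sadi_owl_warning")
      return(NULL)
    }
    some <- graph_match(g, s = node, p = iri(OWL$someValuesFrom))$o
    allv <- graph_match(g, s = node, p = iri(OWL$allValuesFrom))$o
    minc <- graph_match(g, s = node, p = iri(OWL$minCardinality))$o
    hasv <- graph_match(g, s = node, p = iri(OWL$hasValue))$o
    if (length(some) == 1L && is_iri_term(some)) {
      owl_restriction(term_iri(prop), "someValuesFrom", filler = term_iri(some))
    } else if (length(allv) == 1L && is_iri_term(allv)) {
      owl_restriction(term_iri(prop), "allValuesFrom", filler = term_iri(allv))
    } else if (length(minc) == 1L && is_literal_term(minc)) {
      owl_restriction(term_iri(prop), "minCardinality",
                      min_count = as.integer(lit_value(minc)))
    } else if (length(hasv) == 1L) {
      owl_restriction(term_iri(prop), "hasValue", filler = hasv)
    } else {
      warn_sadi(sprintf("restriction on <%s> has no supported kind; excluded",
                        term_iri(prop)),
                class = "sadi_owl_warning")
      NULL
    }
  }

  # returns list(restrictions =, superclasses =) for one class expression node
  parse_expr <- function(node, depth = 0L) {
    if (depth > 16L) stop_parse("class expression nesting too deep")
    res <- list(restrictions = list(), superclasses = character(0))
    if (is_iri_term(node)) {
      res$superclasses <- term_iri(node)
      return(res)
    }
    if (graph_contains(g, node, iri(RDF$type), iri(OWL$Restriction)) ||
        nrow(graph_match(g, s = node, p = iri(OWL$onProperty))) > 0L) {
      r <- parse_restriction(node)
      if (!is.null(r)) res$restrictions <- list(r)
      return(res)
    }
    inter <- graph_match(g, s = node, p = iri(OWL$intersectionOf))$o
    if (length(inter) == 1L) {
      for (member in rdf_list_members(g, inter)) {
        sub <- parse_expr(member, depth + 1L)
        res$restrictions <- c(res$restrictions, sub$restrictions)
        res$superclasses <- c(res$superclasses, sub$superclasses)
      }
      return(res)
    }
    if (nrow(graph_match(g, s = node, p = iri(OWL$unionOf))) > 0L ||
        nrow(graph_match(g, s = node, p = iri(OWL$complementOf))) > 0L) {
      warn_sadi("owl:unionOf/owl:complementOf are outside the matchmaking subset; excluded",
                class = "sadi_owl_warning")
      return(res)
    }
    warn_sadi("unrecognised class expression node; excluded",
              class = "sadi_owl_warning")
    res
  }

  classes <- list()
  for (cs in unique(class_subjects)) {
    restrictions <- list()
    supers <- character(0)
    exprs <- c(graph_match(g, s = cs, p = iri(RDFS$subClassOf))$o,
               graph_match(g, s = cs, p = iri(OWL$equivalentClass))$o)
    for (e in exprs) {
      sub <- parse_expr(e)
      restrictions <- c(restrictions, sub$restrictions)
      supers <- c(supers, sub$superclasses)
    }
    # an intersection asserted directly on the named class
    for (inter in graph_match(g, s = cs, p = iri(OWL$intersectionOf))$o) {
      for (member in rdf_list_members(g, inter)) {
        sub <- parse_expr(member)
        restrictions <- c(restrictions, sub$restrictions)
        supers <- c(supers, sub$superclasses)
      }
    }
    cls <- owl_class(term_iri(cs), restrictions, setdiff(supers, OWL$Thing))
    classes[[cls$iri]] <- cls
  }
  dt_props <- graph_match(g, p = iri(RDF$type), o = iri(OWL$DatatypeProperty))$s
  ontology(classes, term_iri(dt_props[is_iri_term(dt_props)]))
}

restriction_closure <- function(cls, ont, seen = character(0)) {
  if (cls$iri %in% seen) return(list())
  out <- cls$restrictions
  for (sup in cls$superclasses) {
    sup_def <- ont$classes[[sup]]
    if (!is.null(sup_def)) {
      out <- c(out, restriction_closure(sup_def, ont, c(seen, cls$iri)))
    }
  }
  out
}

XSD_NS <- "http://www.w3.org/2001/XMLSchema#"

# is encoded term `value` a member of class/datatype `filler_iri`?
term_member_of <- function(g, value, filler_iri, ont, stack) {
  if (filler_iri == OWL$Thing) return(TRUE)
  if (startsWith(filler_iri, XSD_NS) ||
      filler_iri == paste0(NS$rdfs, "Literal")) {
    if (!is_literal_term(value)) return(FALSE)
    if (filler_iri == paste0(NS$rdfs, "Literal")) return(TRUE)
    dt <- lit_datatype(value)
    if (is.na(dt)) dt <- XSD$string  # plain literal
    return(dt == filler_iri)
  }
  cls <- ont$classes[[filler_iri]]
  if (is.null(cls)) {
    stop(sadi_error(
      sprintf("restriction filler class <%s> is not defined in the ontology", filler_iri),
      "sadi_unknown_class_error", class_iri = filler_iri
    ))
  }
  if (is_literal_term(value)) return(FALSE)
  if (graph_contains(g, value, iri(RDF$type), iri(filler_iri))) return(TRUE)
  key <- paste(value, filler_iri)
  if (key %in% stack) return(FALSE)  # cyclic structural dependency
  node_satisfies(g, value, cls, ont, c(stack, key))$satisfied
}

check_restriction <- function(g, node_term, r, ont, stack) {
  values <- graph_match(g, s = node_term, p = iri(r$property))$o
  switch(r$kind,
    someValuesFrom = any(vapply(values, term_member_of, logical(1),
                                g = g, filler_iri = r$filler, ont = ont,
                                stack = stack)),
    allValuesFrom = all(vapply(values, term_member_of, logical(1),
                               g = g, filler_iri = r$filler, ont = ont,
                               stack = stack)),
    minCardinality = length(unique(values)) >= r$min_count,
    hasValue = r$filler %in% values
  )
}

node_satisfies <- function(g, node_term, cls, ont, stack = character(0)) {
  unmet <- list()
  for (r in restriction_closure(cls, ont)) {
    ok <- check_restriction(g, node_term, r, ont, stack)
    if (!ok) unmet[[length(unmet) + 1L]] <- r
  }
  list(satisfied = length(unmet) == 0L, unmet = unmet)
}

#' Structurally classify a node against an OWL class
#'
#' Checks every property restriction of `cls` and, recursively, of its named
#' superclasses against the triples asserted about `node` in `g`.
#' `someValuesFrom` over a named class accepts a value either explicitly
#' typed with that class or itself structurally satisfying it;
#' `minCardinality` counts distinct RDF terms; `hasValue` requires the exact
#' term; `allValuesFrom` checks all present values and is vacuously true when
#' none are present. An explicit `rdf:type` assertion of `cls` itself is
#' deliberately *not* sufficient: restrictions are always checked.
#'
#' @param g an [rdf_graph()]
#' @param node plain IRI of the individual
#' @param cls an [owl_class()]
#' @param ont the [ontology()] providing named classes referenced by fillers
#'   and superclasses; a filler class absent from `ont` is an error, never a
#'   silent pass
#' @return `list(satisfied = <logical>, unmet = <list of owl_restriction>)`
#' @export
satisfies <- function(g, node, cls, ont) {
  stopifnot(inherits(cls, "owl_class"), inherits(ont, "owl_ontology"))
  node_satisfies(g, iri(node), cls, ont)
}

#' Properties a service attaches
#'
#' The semantic signature of a service is the set of properties restricted in
#' its output class (including inherited restrictions) but not in its input
#' class: precisely the predicates the service's decoration adds. This set is
#' what a discovery registry indexes.
#'
#' @param input_cls,output_cls [owl_class()] definitions
#' @param ont the [ontology()] for superclass closure
#' @return character vector of plain property IRIs (sorted)
#' @export
attached_properties <- function(input_cls, output_cls, ont) {
  props <- function(cls) {
    unique(vapply(restriction_closure(cls, ont), function(r) r$property, character(1)))
  }
  sort(setdiff(props(output_cls), props(input_cls)))
}
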