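#' Service description documents
#'
#' A service endpoint answers HTTP GET with an RDF document describing its
#' single operation: an instance of the myGrid/Moby `serviceDescription`
#' class carrying the service name, free-text description, authority, and —
#' through its one operation node — the input class, the output class and an
#' optional secondary-parameter (configuration) class. Exactly one operation
#' is representable; descriptions with zero or several operations are
#' rejected.
#'
#' @param name short service name
#' @param endpoint plain IRI of the service endpoint
#' @param input_class,output_class plain IRIs of the I/O OWL classes
#' @param description_text human-readable description
#' @param parameter_class optional plain IRI of the secondary-parameter class
#' @param authority authority string (DNS-style)
#' @param async_capable annotation only: the protocol is self-describing at
#'   invocation time (202 vs 200), so clients never rely on this flag
#' @return a `service_description`
#' @export
service_description <- function(name, endpoint, input_class, output_class,
                                description_text = "", parameter_class = NULL,
                                authority = "", async_capable = FALSE) {
  stopifnot(is.character(name), nzchar(endpoint),
            nzchar(input_class), nzchar(output_class))
  structure(
    list(name = name, endpoint = endpoint,
         description_text = description_text,
         input_class = input_class, output_class = output_class,
         parameter_class = parameter_class,
         authority = authority, async_capable = isTRUE(async_capable)),
    class = "service_description"
  )
}

#' @export
print.service_description <- function(x, ...) {
  cat(sprintf("<service '%s' at %s>\n  input:  %s\n  output: %s\n",
              x$name, x$endpoint, x$input_class, x$output_class))
  if (!is.null(x$parameter_class)) cat("  params:", x$parameter_class, "\n")
  invisible(x)
}

#' Emit a description graph
#'
#' @param d a [service_description()]
#' @return an [rdf_graph()] that [parse_description()] maps back to `d`
#' @export
emit_description <- function(d) {
  stopifnot(inherits(d, "service_description"))
  svc <- iri(d$endpoint)
  op <- blank("operation")
  s <- c(svc, svc, svc, svc, svc, svc)
  p <- c(iri(RDF$type), iri(MYGRID$hasServiceNameText),
         iri(MYGRID$hasServiceDescriptionText), iri(MYGRID$authoritative),
         iri(SADI$asyncCapable), iri(MYGRID$hasOperation))
  o <- c(iri(MYGRID$serviceDescription), lit(d$name),
         lit(d$description_text), lit(d$authority),
         lit(if (d$async_capable) "true" else "false", datatype = XSD$boolean),
         op)
  inp <- blank("input")
  outp <- blank("output")
  s <- c(s, op, op, op, inp, outp)
  p <- c(p, iri(RDF$type), iri(MYGRID$inputParameter), iri(MYGRID$outputParameter),
         iri(MYGRID$objectType), iri(MYGRID$objectType))
  o <- c(o, iri(MYGRID$operation), inp, outp,
         iri(d$input_class), iri(d$output_class))
  if (!is.null(d$parameter_class)) {
    parm <- blank("params")
    s <- c(s, op, parm)
    p <- c(p, iri(MYGRID$secondaryParameter), iri(MYGRID$objectType))
    o <- c(o, parm, iri(d$parameter_class))
  }
  rdf_graph(s, p, o)
}

one_object <- function(g, s, p, what, required = TRUE) {
  hits <- graph_match(g, s = s, p = p)$o
  if (length(hits) == 0L) {
    if (required) stop_parse(sprintf("service description is missing %s", what))
    return(NULL)
  }
  if (length(hits) > 1L) {
    stop_parse(sprintf("service description has multiple %s", what))
  }
  hits
}

#' Parse a description graph
#'
#' @param g an [rdf_graph()] containing exactly one `serviceDescription` node
#' @return a [service_description()]
#' @export
parse_description <- function(g) {
  svc <- graph_match(g, p = iri(RDF$type), o = iri(MYGRID$serviceDescription))$s
  if (length(svc) != 1L) {
    stop_parse(sprintf("expected exactly one serviceDescription node, found %d",
                       length(svc)))
  }
  if (!is_iri_term(svc)) stop_parse("serviceDescription node must be IRI-named")
  op <- graph_match(g, s = svc, p = iri(MYGRID$hasOperation))$o
  if (length(op) != 1L) {
    stop_parse(sprintf(
      "a service exposes exactly one operation; found %d", length(op)))
  }
  inp <- one_object(g, op, iri(MYGRID$inputParameter), "an input parameter")
  outp <- one_object(g, op, iri(MYGRID$outputParameter), "an output parameter")
  input_class <- one_object(g, inp, iri(MYGRID$objectType),
                            "the input parameter's objectType")
  output_class <- one_object(g, outp, iri(MYGRID$objectType),
                             "the output parameter's objectType")
  parm <- one_object(g, op, iri(MYGRID$secondaryParameter),
                     "secondary parameters", required = FALSE)
  parameter_class <- if (!is.null(parm)) {
    term_iri(one_object(g, parm, iri(MYGRID$objectType),
                        "the secondary parameter's objectType"))
  }
  get_lit <- function(p) {
    v <- one_object(g, svc, iri(p), p, required = FALSE)
    if (is.null(v)) "" else lit_value(v)
  }
  service_description(
    name = get_lit(MYGRID$hasServiceNameText),
    endpoint = term_iri(svc),
    description_text = get_lit(MYGRID$hasServiceDescriptionText),
    input_class = term_iri(input_class),
    output_class = term_iri(output_class),
    parameter_class = parameter_class,
    authority = get_lit(MYGRID$authoritative),
    async_capable = identical(get_lit(SADI$asyncCapable), "true")
  )
}
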