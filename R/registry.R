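#' A property-indexed service registry
#'
#' The registry stores, for every registered endpoint, the parsed
#' description, the loaded input/output class definitions, and the computed
#' set of *attached properties* — the predicates the service's output class
#' restricts beyond its input class (inherited restrictions included). That
#' set is the registry's index: it is what makes "which services can tell me
#' X about this node?" answerable.
#'
#' @return an empty `sadi_registry`
#' @export
sadi_registry <- function() {
  reg <- new.env(parent = emptyenv())
  reg$records <- list()  # endpoint -> record
  class(reg) <- "sadi_registry"
  reg
}

#' @export
print.sadi_registry <- function(x, ...) {
  cat(sprintf("<sadi_registry: %d service%s>\n", length(x$records),
              if (length(x$records) == 1L) "" else "s"))
  for (rec in registry_records(x)) {
    cat(sprintf("  %s  [attaches: %s]\n", rec$description$endpoint,
                paste(rec$attached, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname sadi_registry
#' @param reg a `sadi_registry`
#' @return records in deterministic (endpoint-lexicographic) order
#' @export
registry_records <- function(reg) {
  if (length(reg$records) == 0L) return(list())
  reg$records[order(names(reg$records), method = "radix")]
}

#' Register a service
#'
#' Fetches the endpoint's description, resolves both class IRIs through the
#' ontology loader, computes the attached-property index entry and stores
#' the record. An invalid description or unresolvable ontology refuses
#' registration with a diagnostic error. Re-registering an endpoint replaces
#' its record; indexes stay consistent because they are derived from the
#' record set.
#'
#' @param reg a [sadi_registry()]
#' @param endpoint plain IRI of the service endpoint
#' @param transport a transport function
#' @param ont_loader a class resolver, see [class_loader()]
#' @return the stored record, invisibly
#' @export
register <- function(reg, endpoint, transport, ont_loader) {
  d <- tryCatch(fetch_description(endpoint, transport), error = function(e) e)
  if (inherits(d, "error")) {
    stop_protocol(sprintf("registration refused for <%s>: %s",
                          endpoint, conditionMessage(d)))
  }
  inp <- tryCatch(ont_loader(d$input_class), error = function(e) e)
  outp <- tryCatch(ont_loader(d$output_class), error = function(e) e)
  for (x in list(inp, outp)) {
    if (inherits(x, "error")) {
      stop_protocol(sprintf("registration refused for <%s>: %s",
                            endpoint, conditionMessage(x)))
    }
  }
  ont <- ontology(c(inp$ontology$classes, outp$ontology$classes),
                  c(inp$ontology$datatype_properties,
                    outp$ontology$datatype_properties))
  rec <- structure(list(
    description = d,
    input_def = inp$class,
    output_def = outp$class,
    ontology = ont,
    attached = attached_properties(inp$class, outp$class, ont),
    alive = TRUE,
    last_checked = Sys.time()
  ), class = "registry_record")
  reg$records[[endpoint]] <- rec
  invisible(rec)
}

live_records <- function(reg, include_dead = FALSE) {
  recs <- registry_records(reg)
  if (include_dead) recs else Filter(function(r) isTRUE(r$alive), recs)
}

#' Discovery queries
#'
#' `find_by_input_instance()` returns the services able to consume `node`:
#' by default a service matches if the node structurally satisfies its input
#' class *or* is explicitly typed with it. Restriction-based matching is the
#' default path because it admits data produced under a different ontological
#' framework, so long as it carries the required properties; `match`
#' restricts to one path. `find_by_property()` returns the services whose
#' attached-property index contains the predicate. `property_menu()` combines
#' the two into the "menu of relationships" a discovery UI offers for a
#' selected node: every property some matching service can attach, mapped to
#' the services that attach it.
#'
#' Dead services (see [check_alive()]) are excluded unless `include_dead`.
#'
#' @param reg a [sadi_registry()]
#' @param g an [rdf_graph()] providing the node's properties
#' @param node plain IRI of the candidate input node
#' @param match `"both"` (default), `"restriction"` or `"type"`
#' @param include_dead include services last seen dead
#' @return a list of registry records (deterministic order); for
#'   `property_menu()` a named list: property IRI -> list of records
#' @export
find_by_input_instance <- function(reg, g, node,
                                   match = c("both", "restriction", "type"),
                                   include_dead = FALSE) {
  match <- match.arg(match)
  Filter(function(rec) {
    by_type <- graph_contains(g, iri(node), iri(RDF$type), iri(rec$input_def$iri))
    if (match == "type") return(by_type)
    by_restriction <- satisfies(g, node, rec$input_def, rec$ontology)$satisfied
    if (match == "restriction") by_restriction else by_type || by_restriction
  }, live_records(reg, include_dead))
}

#' @rdname find_by_input_instance
#' @param predicate plain property IRI
#' @export
find_by_property <- function(reg, predicate, include_dead = FALSE) {
  Filter(function(rec) predicate %in% rec$attached,
         live_records(reg, include_dead))
}

#' @rdname find_by_input_instance
#' @export
property_menu <- function(reg, g, node, match = c("both", "restriction", "type"),
                          include_dead = FALSE) {
  matches <- find_by_input_instance(reg, g, node, match = match,
                                    include_dead = include_dead)
  menu <- list()
  props <- sort(unique(unlist(lapply(matches, `[[`, "attached"))))
  for (p in props) {
    menu[[p]] <- Filter(function(rec) p %in% rec$attached, matches)
  }
  menu
}

#' Liveness monitoring
#'
#' Re-fetches the endpoint's description. A transport failure or unparseable
#' answer marks the record dead (never an exception); a successful fetch
#' whose description differs from the registered one keeps the record alive
#' but flags staleness in the returned record's `stale` field.
#'
#' @param reg a [sadi_registry()]
#' @param endpoint plain IRI of a registered service
#' @param transport a transport function
#' @return the updated record, invisibly
#' @export
check_alive <- function(reg, endpoint, transport) {
  rec <- reg$records[[endpoint]]
  if (is.null(rec)) stop_protocol(sprintf("<%s> is not registered", endpoint))
  fetched <- tryCatch(fetch_description(endpoint, transport), error = function(e) e)
  rec$alive <- !inherits(fetched, "error")
  rec$stale <- rec$alive && !identical(fetched, rec$description)
  rec$last_checked <- Sys.time()
  reg$records[[endpoint]] <- rec
  invisible(rec)
}

#' Persist a registry to a single plain-text file
#'
#' The store is deterministic: one N3 block per registered endpoint (its
#' description document), separated by a record marker. Loading re-derives
#' every record and index through the ontology loader, so the store never
#' duplicates derivable state.
#'
#' @param reg a [sadi_registry()]
#' @param path file path
#' @param ont_loader a class resolver, see [class_loader()]
#' @return `registry_load()` returns a rebuilt [sadi_registry()]
#' @export
registry_save <- function(reg, path) {
  blocks <- vapply(registry_records(reg), function(rec) {
    serialize_n3(emit_description(rec$description))
  }, character(1))
  writeLines(paste(blocks, collapse = "\n#=record=#\n"), path)
  invisible(path)
}

#' @rdname registry_save
#' @export
registry_load <- function(path, ont_loader) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  reg <- sadi_registry()
  blocks <- strsplit(text, "#=record=#", fixed = TRUE)[[1]]
  for (b in blocks) {
    if (!nzchar(trimws(b))) next
    d <- parse_description(parse_graph(b, MEDIA_N3))
    inp <- ont_loader(d$input_class)
    outp <- ont_loader(d$output_class)
    ont <- ontology(c(inp$ontology$classes, outp$ontology$classes),
                    c(inp$ontology$datatype_properties,
                      outp$ontology$datatype_properties))
    reg$records[[d$endpoint]] <- structure(list(
      description = d, input_def = inp$class, output_def = outp$class,
      ontology = ont,
      attached = attached_properties(inp$class, outp$class, ont),
      alive = TRUE, last_checked = Sys.time()
    ), class = "registry_record")
  }
  reg
}
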