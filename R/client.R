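#' Fetch and parse a service's interface document
#'
#' @param endpoint plain IRI of the service endpoint
#' @param transport a transport function (see [in_memory_transport()])
#' @return a [service_description()]
#' @export
fetch_description <- function(endpoint, transport) {
  resp <- transport(http_request("GET", endpoint))
  if (resp$status != 200L) {
    stop_protocol(sprintf("GET <%s> answered status %d", endpoint, resp$status))
  }
  parse_description(parse_graph(resp$body, resp$content_type))
}

#' Pre-flight validation of an invocation graph
#'
#' Optional client-side aid: checks every root typed with the service's input
#' class against that class's property restrictions, so a doomed invocation
#' can be caught before any POST. Providers themselves never require this —
#' they extract roots purely by `rdf:type`.
#'
#' @param g an [rdf_graph()]
#' @param d a [service_description()]
#' @param ont_loader `function(class_iri)` returning
#'   `list(class = owl_class, ontology = ontology)` (see [class_loader()])
#' @return list of `list(node =, unmet =)` entries, one per unsatisfied
#'   root; empty when all roots validate
#' @export
validate_input <- function(g, d, ont_loader) {
  loaded <- ont_loader(d$input_class)
  roots <- extract_typed_roots(g, d$input_class)
  out <- list()
  for (r in roots) {
    chk <- satisfies(g, r, loaded$class, loaded$ontology)
    if (!chk$satisfied) {
      out[[length(out) + 1L]] <- list(node = r, unmet = chk$unmet)
    }
  }
  out
}

#' Resolve classes against local or remote ontology documents
#'
#' Returns an `ont_loader` contract: given a class IRI it fetches (and
#' caches) the defining ontology document — located by stripping the
#' fragment — and returns the class definition together with its ontology.
#' A class IRI whose document does not define it is an error naming the IRI.
#'
#' @param fetch a fetch contract as in [resolve_by_reference()]
#' @return `function(class_iri) -> list(class =, ontology =)`
#' @export
class_loader <- function(fetch) {
  cache <- new.env(parent = emptyenv())
  function(class_iri) {
    doc_iri <- sub("#.*$", "", class_iri)
    ont <- cache[[doc_iri]]
    if (is.null(ont)) {
      ont <- load_ontology(doc_iri, fetch = fetch)
      cache[[doc_iri]] <- ont
    }
    cls <- ont$classes[[class_iri]]
    if (is.null(cls)) {
      stop(sadi_error(
        sprintf("class <%s> is not defined by its ontology document <%s>",
                class_iri, doc_iri),
        "sadi_unknown_class_error", class_iri = class_iri
      ))
    }
    list(class = cls, ontology = ont)
  }
}

#' Polling policy for asynchronous invocations
#'
#' @param max_polls per-root budget of poll requests before the root is
#'   recorded as failed
#' @param default_retry_after wait used when a response carries no
#'   `Retry-After` header (seconds)
#' @param sleep the waiting primitive, `function(seconds)`; injectable so
#'   in-memory tests complete immediately
#' @return a `poll_policy`
#' @export
poll_policy <- function(max_polls = 60L, default_retry_after = 5,
                        sleep = Sys.sleep) {
  structure(list(max_polls = as.integer(max_polls),
                 default_retry_after = default_retry_after, sleep = sleep),
            class = "poll_policy")
}

#' Invoke a service
#'
#' POSTs the invocation graph to the endpoint and assembles one result graph
#' per input root. A 200 answer is split by root directly. A 202 answer is
#' completed transparently: each root's `rdfs:isDefinedBy` poll IRI is
#' dereferenced, honouring `Retry-After` and re-calling on 302, until 200 —
#' so the caller sees no difference between a synchronous and an
#' asynchronous service. A `params` graph, when given, is merged into the
#' POSTed body as an independent graph within the same invocation message.
#'
#' @param endpoint plain IRI of the service endpoint
#' @param g invocation [rdf_graph()] with at least one root typed with the
#'   service's input class
#' @param transport a transport function
#' @param params optional [rdf_graph()] carrying a control-parameter instance
#' @param policy a [poll_policy()]
#' @param media_type serialization for the POST body
#' @param description optional pre-fetched [service_description()] (skips
#'   the GET)
#' @return an `invocation_result`: `list(merged =, per_root =, failures =)`
#'   where `per_root` maps each root IRI to its output graph and `failures`
#'   maps failed roots to diagnostic strings
#' @export
invoke <- function(endpoint, g, transport, params = NULL,
                   policy = poll_policy(), media_type = MEDIA_RDFXML,
                   description = NULL) {
  stopifnot(inherits(g, "rdf_graph"))
  if (graph_size(g) == 0L) {
    stop_protocol("invocation graph is empty: nothing to invoke")
  }
  d <- if (is.null(description)) fetch_description(endpoint, transport) else description
  roots <- extract_typed_roots(g, d$input_class)
  if (length(roots) == 0L) {
    stop_protocol(sprintf(
      "invocation graph has no root typed with the service input class <%s>",
      d$input_class))
  }
  body_graph <- if (is.null(params)) g else graph_union(g, params)
  resp <- transport(http_request(
    "POST", endpoint, body = serialize_graph(body_graph, media_type),
    content_type = media_type, accept = media_type))

  failures <- list()
  per_root <- list()
  if (resp$status == 200L) {
    out <- parse_graph(resp$body, resp$content_type)
    per_root <- map_outputs(roots, out)
    for (r in roots) {
      diag <- graph_match(per_root[[r]], s = iri(r), p = iri(SADI$serviceError))
      if (!is.null(per_root[[r]]) && nrow(diag) > 0L) {
        failures[[r]] <- lit_value(diag$o[1])
        per_root[[r]] <- NULL
      }
    }
  } else if (resp$status == 202L) {
    stub <- parse_graph(resp$body, resp$content_type)
    retry <- resp$headers[["Retry-After"]]
    for (r in roots) {
      poll_iris <- graph_match(stub, s = iri(r), p = iri(RDFS$isDefinedBy))$o
      if (length(poll_iris) == 0L) {
        failures[[r]] <- "202 stub carries no poll IRI for this root"
        next
      }
      res <- poll_until_complete(term_iri(poll_iris[1]), transport, policy, retry)
      if (is.null(res$graph)) failures[[r]] <- res$error else per_root[[r]] <- res$graph
    }
  } else {
    for (r in roots) {
      failures[[r]] <- sprintf("service answered status %d: %s", resp$status, resp$body)
    }
  }
  merged <- Reduce(graph_union, per_root, accumulate = FALSE, init = rdf_graph())
  structure(list(merged = merged, per_root = per_root, failures = failures),
            class = "invocation_result")
}

poll_until_complete <- function(poll_iri, transport, policy, retry_after) {
  url <- poll_iri
  for (k in seq_len(policy$max_polls)) {
    resp <- transport(http_request("GET", url))
    if (resp$status == 200L) {
      return(list(graph = parse_graph(resp$body, resp$content_type)))
    }
    if (resp$status == 302L) {
      loc <- resp$headers[["Location"]]
      if (!is.null(loc)) url <- loc
      wait <- resp$headers[["Retry-After"]]
      if (is.null(wait)) wait <- retry_after
      if (is.null(wait)) wait <- policy$default_retry_after
      policy$sleep(as.numeric(wait))
      next
    }
    return(list(error = sprintf("poll answered status %d: %s", resp$status, resp$body)))
  }
  list(error = sprintf("poll budget exhausted after %d polls", policy$max_polls))
}

#' Map a multiplexed output graph back to its input roots
#'
#' Because every service preserves the input URI, no mark-up is needed to
#' match outputs to inputs: the output graph is partitioned by forward
#' reachability (outgoing edges) from each input root IRI. Decorations are
#' properties *of* the root, so inverse edges are not followed. Triples
#' unreachable from any root are returned in the `"unmapped"` attribute.
#'
#' @param input_roots character vector of plain root IRIs
#' @param out the response [rdf_graph()]
#' @return named list: root IRI -> [rdf_graph()]; attribute `unmapped` holds
#'   the left-over graph
#' @export
map_outputs <- function(input_roots, out) {
  df <- out$triples
  reach_rows <- function(root_term) {
    frontier <- root_term
    seen <- character(0)
    rows <- rep(FALSE, nrow(df))
    while (length(frontier) > 0L) {
      cur <- frontier[1]
      frontier <- frontier[-1]
      if (cur %in% seen) next
      seen <- c(seen, cur)
      hit <- df$s == cur
      rows <- rows | hit
      nxt <- df$o[hit]
      frontier <- c(frontier, nxt[!is_literal_term(nxt) & !(nxt %in% seen)])
    }
    rows
  }
  covered <- rep(FALSE, nrow(df))
  per_root <- list()
  for (r in input_roots) {
    rows <- reach_rows(iri(r))
    covered <- covered | rows
    sub <- df[rows, , drop = FALSE]
    per_root[[r]] <- rdf_graph(sub$s, sub$p, sub$o)
  }
  left <- df[!covered, , drop = FALSE]
  attr(per_root, "unmapped") <- rdf_graph(left$s, left$p, left$o)
  per_root
}
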