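#' HTTP messages
#'
#' The stack models an HTTP exchange as plain lists so the same handlers can
#' sit behind any transport. Statuses used: 200 (complete result), 202
#' (accepted, poll later), 302 (pending, re-call `Location`), 400 (client
#' fault), 404 (unknown/expired poll address), 500 (provider fault).
#'
#' @param status integer HTTP status
#' @param body response/request body text
#' @param content_type media type of `body`
#' @param headers named list of additional headers (`Retry-After`,
#'   `Location`)
#' @return an `http_response`
#' @export
http_response <- function(status, body = "", content_type = NULL, headers = list()) {
  structure(list(status = as.integer(status), body = body,
                 content_type = content_type, headers = headers),
            class = "http_response")
}

#' @rdname http_response
#' @param method "GET" or "POST"
#' @param url request IRI
#' @param accept media type the client prefers for the response
#' @export
http_request <- function(method, url, body = NULL, content_type = NULL,
                         accept = MEDIA_RDFXML) {
  structure(list(method = method, url = url, body = body,
                 content_type = content_type, accept = accept),
            class = "http_request")
}

#' Define a service implementation
#'
#' A service is its description plus a provider-supplied annotation function.
#' The host owns the whole messaging protocol; the provider writes only the
#' business logic that decorates one root.
#'
#' `annotate(input, root, params)` receives the full invocation graph, one
#' root IRI, and the extracted parameter instance (or `NULL`), and returns an
#' [rdf_graph()] of triples to attach. It must be pure with respect to the
#' host (no shared mutable state between roots), so multiplexed roots may be
#' processed in any order; every returned triple should hang off the root.
#'
#' @param description a [service_description()]
#' @param annotate the annotation contract (see Details)
#' @param mode `"sync"` or `"async"`
#' @param async_delay_polls number of pending polls an async task answers
#'   with 302 before the result is computed and served (models a long-running
#'   computation; default 1)
#' @param retry_after value of the `Retry-After` header, seconds (default 5)
#' @return a `sadi_service`
#' @export
sadi_service <- function(description, annotate, mode = c("sync", "async"),
                         async_delay_polls = 1L, retry_after = 5L) {
  mode <- match.arg(mode)
  stopifnot(inherits(description, "service_description"), is.function(annotate),
            async_delay_polls >= 0L, retry_after >= 1L)
  structure(list(description = description, annotate = annotate, mode = mode,
                 async_delay_polls = as.integer(async_delay_polls),
                 retry_after = as.integer(retry_after)),
            class = "sadi_service")
}

#' Create a host for a service
#'
#' The host holds the mutable protocol state (pending asynchronous tasks);
#' the service definition itself stays immutable.
#'
#' @param svc a [sadi_service()]
#' @param task_retention_s seconds a completed task stays retrievable before
#'   polls answer 404 (default one hour)
#' @return a `sadi_host` environment
#' @export
service_host <- function(svc, task_retention_s = 3600) {
  stopifnot(inherits(svc, "sadi_service"))
  host <- new.env(parent = emptyenv())
  host$svc <- svc
  host$tasks <- new.env(parent = emptyenv())
  host$counter <- 0L
  host$task_retention_s <- task_retention_s
  class(host) <- "sadi_host"
  host
}

#' Service-side protocol handlers
#'
#' `handle_get()` answers GET on the endpoint with the service interface
#' document (RDF/XML). `handle_post()` answers POST with either the complete
#' decorated graph (200, synchronous mode) or per-root polling stubs (202,
#' asynchronous mode). `handle_poll()` answers GET on a task IRI with 302
#' while pending and 200 with that root's output graph once complete.
#'
#' The POST body is a bare RDF document — never HTTP FORM encoding. Requests
#' that do not parse, carry an unsupported media type, or contain no root
#' typed with the input class are client faults (400). A provider annotation
#' function that raises marks its root with a diagnostic triple
#' (`serviceError`); the response is 500 only when every root failed,
#' otherwise the surviving outputs are returned (multiplexed runs are
#' independent).
#'
#' @param host a [service_host()]
#' @param body POSTed document text
#' @param media_type media type of `body`
#' @param accept media type for the response (default RDF/XML)
#' @param task_id task identifier from the poll IRI path (`.../task/<id>`)
#' @return an [http_response()]
#' @export
handle_get <- function(host) {
  g <- emit_description(host$svc$description)
  http_response(200L, serialize_graph(g, MEDIA_RDFXML), MEDIA_RDFXML)
}

client_fault <- function(message) {
  http_response(400L, message, "text/plain")
}

parse_invocation <- function(host, body, media_type) {
  d <- host$svc$description
  g <- tryCatch(parse_graph(body, media_type), error = function(e) e)
  if (inherits(g, "error")) {
    return(list(fault = client_fault(conditionMessage(g))))
  }
  roots <- withCallingHandlers(
    extract_typed_roots(g, d$input_class),
    sadi_blank_root_warning = function(w) invokeRestart("muffleWarning")
  )
  if (length(roots) == 0L) {
    return(list(fault = client_fault(sprintf(
      "no input instance found: expected at least one root with rdf:type <%s>",
      d$input_class))))
  }
  params <- if (!is.null(d$parameter_class)) {
    p <- tryCatch(extract_parameters(g, d$parameter_class), error = function(e) e)
    if (inherits(p, "error")) {
      return(list(fault = client_fault(conditionMessage(p))))
    }
    p
  }
  list(graph = g, roots = roots, params = params)
}

# run the provider's annotate for one root; returns list(graph=, ok=)
run_root <- function(host, g, root, params) {
  d <- host$svc$description
  res <- tryCatch(host$svc$annotate(g, root, params), error = function(e) e)
  if (inherits(res, "error")) {
    return(list(ok = FALSE, graph = rdf_graph(
      iri(root), iri(SADI$serviceError), lit(conditionMessage(res)))))
  }
  stopifnot(inherits(res, "rdf_graph"))
  out <- graph_add(res, iri(root), iri(RDF$type), iri(d$output_class))
  list(ok = TRUE, graph = out)
}

#' @rdname handle_get
#' @export
handle_post <- function(host, body, media_type, accept = MEDIA_RDFXML) {
  inv <- parse_invocation(host, body, media_type)
  if (!is.null(inv$fault)) return(inv$fault)
  out_type <- tryCatch(normalize_media_type(accept), error = function(e) MEDIA_RDFXML)
  if (host$svc$mode == "sync") {
    runs <- lapply(inv$roots, function(r) run_root(host, inv$graph, r, inv$params))
    out <- Reduce(graph_union, lapply(runs, `[[`, "graph"))
    all_failed <- !any(vapply(runs, `[[`, logical(1), "ok"))
    http_response(if (all_failed) 500L else 200L,
                  serialize_graph(out, out_type), out_type)
  } else {
    stub <- rdf_graph()
    for (r in inv$roots) {
      host$counter <- host$counter + 1L
      id <- sprintf("%d", host$counter)
      poll_iri <- paste0(host$svc$description$endpoint, "/task/", id)
      host$tasks[[id]] <- list(
        root = r, graph = inv$graph, params = inv$params,
        remaining = host$svc$async_delay_polls,
        result = NULL, poll_iri = poll_iri, created = Sys.time()
      )
      stub <- graph_add(
        stub,
        c(iri(r), iri(r)),
        c(iri(RDF$type), iri(RDFS$isDefinedBy)),
        c(iri(host$svc$description$output_class), iri(poll_iri))
      )
    }
    http_response(202L, serialize_graph(stub, out_type), out_type,
                  headers = list(`Retry-After` = host$svc$retry_after))
  }
}

#' @rdname handle_get
#' @export
handle_poll <- function(host, task_id, accept = MEDIA_RDFXML) {
  task <- host$tasks[[task_id]]
  if (is.null(task)) {
    return(http_response(404L, sprintf("unknown task: %s", task_id), "text/plain"))
  }
  if (as.numeric(Sys.time()) - as.numeric(task$created) > host$task_retention_s) {
    rm(list = task_id, envir = host$tasks)
    return(http_response(404L, sprintf("task expired: %s", task_id), "text/plain"))
  }
  out_type <- tryCatch(normalize_media_type(accept), error = function(e) MEDIA_RDFXML)
  if (task$remaining > 0L) {
    task$remaining <- task$remaining - 1L
    host$tasks[[task_id]] <- task
    return(http_response(302L, "", NULL, headers = list(
      Location = task$poll_iri, `Retry-After` = host$svc$retry_after)))
  }
  if (is.null(task$result)) {
    task$result <- run_root(host, task$graph, task$root, task$params)
    host$tasks[[task_id]] <- task
  }
  http_response(if (task$result$ok) 200L else 500L,
                serialize_graph(task$result$graph, out_type), out_type)
}

#' Extract the control-parameter instance from an invocation graph
#'
#' Settable parameters travel as an independent RDF graph inside the same
#' invocation message: a node typed with the service's declared parameter
#' class, whose property values configure the run. Absence means the
#' service's defaults apply; more than one parameter node is an ambiguous
#' configuration and an error.
#'
#' @param g an [rdf_graph()]
#' @param parameter_class plain IRI of the declared parameter class
#' @return `NULL`, or `list(node =, values =)` where `values` maps property
#'   IRIs to lists of encoded terms
#' @export
extract_parameters <- function(g, parameter_class) {
  if (is.null(parameter_class)) return(NULL)
  nodes <- graph_match(g, p = iri(RDF$type), o = iri(parameter_class))$s
  if (length(nodes) == 0L) return(NULL)
  if (length(nodes) > 1L) {
    stop_protocol(sprintf(
      "ambiguous configuration: %d nodes typed with parameter class <%s>",
      length(nodes), parameter_class))
  }
  rows <- graph_match(g, s = nodes)
  rows <- rows[rows$p != iri(RDF$type), , drop = FALSE]
  values <- split(rows$o, term_iri(rows$p))
  structure(list(node = if (is_iri_term(nodes)) term_iri(nodes) else nodes,
                 values = values),
            class = "parameter_instance")
}
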