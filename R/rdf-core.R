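#' Parse an RDF document
#'
#' Two serializations are accepted on the wire: RDF/XML
#' (`application/rdf+xml`) and N3 (`text/rdf+n3`, Turtle-compatible subset).
#' Any other media type raises a `sadi_media_type_error`; a payload that does
#' not parse raises a `sadi_parse_error` — the two faults are distinct so the
#' HTTP layer can answer each correctly.
#'
#' @param payload document text (character scalar or raw vector)
#' @param media_type `"application/rdf+xml"` or `"text/rdf+n3"` (parameters
#'   such as `; charset=...` are ignored)
#' @return an [rdf_graph()]
#' @seealso [serialize_graph()]
#' @export
parse_graph <- function(payload, media_type) {
  if (is.raw(payload)) payload <- rawToChar(payload)
  stopifnot(is.character(payload), length(payload) == 1L)
  switch(normalize_media_type(media_type),
    "application/rdf+xml" = parse_rdfxml(payload),
    "text/rdf+n3" = parse_n3(payload)
  )
}

#' Serialize a graph
#'
#' Round-trip guarantee: the output reparses (with [parse_graph()]) to a graph
#' isomorphic to `g` in either serialization.
#'
#' @param g an [rdf_graph()]
#' @param media_type target media type, as in [parse_graph()]
#' @return document text (character scalar)
#' @export
serialize_graph <- function(g, media_type) {
  stopifnot(inherits(g, "rdf_graph"))
  switch(normalize_media_type(media_type),
    "application/rdf+xml" = serialize_rdfxml(g),
    "text/rdf+n3" = serialize_n3(g)
  )
}

normalize_media_type <- function(media_type) {
  stopifnot(is.character(media_type), length(media_type) == 1L)
  mt <- tolower(trimws(sub(";.*$", "", media_type)))
  if (!mt %in% c(MEDIA_RDFXML, MEDIA_N3)) stop_media_type(media_type)
  mt
}

#' Extract the typed roots of an invocation graph
#'
#' A service identifies its units of work by looking for subjects explicitly
#' carrying `rdf:type <class_iri>`; no reasoning is involved. Only IRI-named
#' subjects qualify: roots must be resolvable, preservable URIs, so blank
#' subjects typed with the class are reported through a warning diagnostic
#' and skipped.
#'
#' @param g an [rdf_graph()]
#' @param class_iri plain IRI string of the class
#' @return character vector of root IRIs in lexicographic order (possibly
#'   empty)
#' @export
extract_typed_roots <- function(g, class_iri) {
  hits <- graph_match(g, p = iri(RDF$type), o = iri(class_iri))
  blanks <- hits$s[is_blank_term(hits$s)]
  if (length(blanks) > 0L) {
    warn_sadi(
      sprintf("blank-node subject(s) typed with <%s> cannot be service roots: %s",
              class_iri, paste(blanks, collapse = ", ")),
      class = "sadi_blank_root_warning"
    )
  }
  sort(unique(term_iri(hits$s[is_iri_term(hits$s)])))
}

#' Resolve a pass-by-reference node
#'
#' Large inputs and outputs may travel by reference: a node annotated with
#' `rdfs:isDefinedBy <url>` promises that dereferencing the URL yields the
#' node's missing triples. This follows every such annotation on `node`
#' (recursively, on documents that add further annotations to the same node)
#' up to `depth_limit`, merging what is retrieved. The original graph is not
#' modified; a failing fetch produces a warning and a partial merge; cycles
#' terminate.
#'
#' @param g an [rdf_graph()]
#' @param node plain IRI string of the node being resolved
#' @param fetch a resolver: `function(url)` returning
#'   `list(body = <text>, media_type = <type>)` (injectable; see
#'   [local_fetcher()])
#' @param depth_limit maximum recursion depth (default 1: only references
#'   present in `g` itself are followed)
#' @return the merged [rdf_graph()]
#' @export
resolve_by_reference <- function(g, node, fetch, depth_limit = 1L) {
  stopifnot(depth_limit >= 0L, is.function(fetch))
  merged <- g
  seen <- character(0)
  frontier_refs <- function(gr) {
    refs <- graph_match(gr, s = iri(node), p = iri(RDFS$isDefinedBy))$o
    setdiff(term_iri(refs[is_iri_term(refs)]), seen)
  }
  depth <- 0L
  while (depth < depth_limit) {
    refs <- frontier_refs(merged)
    if (length(refs) == 0L) break
    for (url in refs) {
      seen <- c(seen, url)
      doc <- tryCatch(fetch(url), error = function(e) e)
      if (inherits(doc, "error")) {
        warn_sadi(sprintf("could not resolve reference <%s>: %s",
                          url, conditionMessage(doc)),
                  class = "sadi_reference_warning")
        next
      }
      add <- tryCatch(parse_graph(doc$body, doc$media_type), error = function(e) e)
      if (inherits(add, "error")) {
        warn_sadi(sprintf("reference <%s> did not parse: %s",
                          url, conditionMessage(add)),
                  class = "sadi_reference_warning")
        next
      }
      merged <- graph_union(merged, add)
    }
    depth <- depth + 1L
  }
  merged
}

#' Build a fetch contract over local documents
#'
#' Returns a `function(url)` resolving IRIs against an in-memory map, so that
#' ontology loading and pass-by-reference tests never touch the network. Each
#' map entry is `list(body =, media_type =)`.
#'
#' @param docs named list: IRI -> `list(body, media_type)`
#' @return a fetch function
#' @export
local_fetcher <- function(docs) {
  force(docs)
  function(url) {
    hit <- docs[[url]]
    if (is.null(hit)) stop_transport(sprintf("no document at <%s>", url))
    hit
  }
}
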