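#' In-memory transport over a set of hosted services
#'
#' A transport is any `function(req)` taking an [http_request()] and
#' returning an [http_response()]. This one routes requests to hosted
#' services without sockets, implementing the full GET / POST / poll contract
#' of the protocol, so the entire stack runs offline and deterministically.
#' Requests for an unknown endpoint raise a `sadi_transport_error`.
#'
#' @param hosts a list of [service_host()] objects (or a `fixture_catalogue`)
#' @return a transport function
#' @export
in_memory_transport <- function(hosts) {
  if (inherits(hosts, "fixture_catalogue")) hosts <- hosts$hosts
  if (inherits(hosts, "sadi_host")) hosts <- list(hosts)
  endpoints <- vapply(hosts, function(h) h$svc$description$endpoint, character(1))
  function(req) {
    stopifnot(inherits(req, "http_request"))
    hit <- which(endpoints == req$url)
    if (length(hit) == 1L) {
      host <- hosts[[hit]]
      if (req$method == "GET") return(handle_get(host))
      if (req$method == "POST") {
        return(handle_post(host, req$body, req$content_type, accept = req$accept))
      }
      stop_transport(sprintf("unsupported method %s on %s", req$method, req$url))
    }
    task_hit <- which(startsWith(req$url, paste0(endpoints, "/task/")))
    if (length(task_hit) == 1L && req$method == "GET") {
      host <- hosts[[task_hit]]
      id <- substring(req$url, nchar(endpoints[task_hit]) + nchar("/task/") + 1L)
      return(handle_poll(host, id, accept = req$accept))
    }
    stop_transport(sprintf("no service at <%s>", req$url))
  }
}
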