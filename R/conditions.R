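# Condition constructors. Every fault the stack can raise is a classed
# condition so callers (and the HTTP layer) can map faults to behaviour
# without string matching.

sadi_error <- function(message, class, ...) {
  structure(
    class = c(class, "sadi_error", "error", "condition"),
    list(message = message, ...)
  )
}

stop_media_type <- function(media_type) {
  stop(sadi_error(
    sprintf("unsupported media type: %s (supported: %s, %s)",
            media_type, MEDIA_RDFXML, MEDIA_N3),
    "sadi_media_type_error", media_type = media_type
  ))
}

stop_parse <- function(message, ...) {
  stop(sadi_error(message, "sadi_parse_error", ...))
}

stop_protocol <- function(message, ...) {
  stop(sadi_error(message, "sadi_protocol_error", ...))
}

stop_transport <- function(message, ...) {
  stop(sadi_error(message, "sadi_transport_error", ...))
}

stop_unsupported_query <- function(feature) {
  stop(sadi_error(
    sprintf("unsupported query feature: %s (only SELECT over one basic graph pattern)", feature),
    "sadi_unsupported_query_error", feature = feature
  ))
}

warn_sadi <- function(message, class = "sadi_warning", ...) {
  warning(structure(
    class = c(class, "sadi_warning", "warning", "condition"),
    list(message = message, ...)
  ))
}
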