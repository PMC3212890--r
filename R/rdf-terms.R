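#' RDF terms
#'
#' Terms are encoded as character strings in N-Triples style, which makes a
#' graph a plain three-column character table with set semantics:
#'
#' * IRI: `<http://example.org/x>`
#' * blank node: `_:b1`
#' * literal: `"lexical"`, `"lexical"@en`, or `"lexical"^^<datatypeIRI>`
#'
#' Service-level APIs (roots, endpoints, class IRIs) take and return plain
#' IRI strings; the encoded form appears only inside graphs.
#'
#' @param x an IRI string (absolute: must carry a scheme)
#' @return the encoded term, a length-one character vector
#' @examples
#' iri("http://example.org/a")
#' lit("Guy Incognito")
#' lit("1", datatype = "http://www.w3.org/2001/XMLSchema#integer")
#' @export
iri <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x) || !grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x)) {
    stop_parse(sprintf("not an absolute IRI: '%s'", x))
  }
  paste0("<", x, ">")
}

#' @rdname iri
#' @param label blank node label (no leading `_:`)
#' @export
blank <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  paste0("_:", label)
}

#' @rdname iri
#' @param value literal lexical form
#' @param datatype optional datatype IRI (mutually exclusive with `lang`)
#' @param lang optional language tag (mutually exclusive with `datatype`)
#' @export
lit <- function(value, datatype = NULL, lang = NULL) {
  stopifnot(length(value) == 1L)
  if (!is.null(datatype) && !is.null(lang)) {
    stop("a literal cannot carry both a datatype and a language tag")
  }
  out <- paste0('"', escape_lit(as.character(value)), '"')
  if (!is.null(lang)) out <- paste0(out, "@", lang)
  if (!is.null(datatype)) out <- paste0(out, "^^<", datatype, ">")
  out
}

escape_lit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_lit <- function(x) {
  # Walk escape pairs left to right so "\\n" stays a literal backslash-n.
  vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      if (chars[i] == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        out <- c(out, switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t",
          "\\" = "\\", "\"" = "\"", nxt
        ))
        i <- i + 2L
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Term predicates and accessors
#'
#' Vectorized over encoded terms.
#'
#' @param term encoded term(s), see [iri()]
#' @return logical vector for predicates; character for accessors
#' @export
is_iri_term <- function(term) startsWith(term, "<")

#' @rdname is_iri_term
#' @export
is_blank_term <- function(term) startsWith(term, "_:")

#' @rdname is_iri_term
#' @export
is_literal_term <- function(term) startsWith(term, '"')

#' @rdname is_iri_term
#' @export
term_iri <- function(term) {
  bad <- !is_iri_term(term)
  if (any(bad)) stop_parse(sprintf("not an IRI term: %s", term[bad][1]))
  sub(">$", "", sub("^<", "", term))
}

#' @rdname is_iri_term
#' @export
lit_value <- function(term) {
  m <- regmatches(term, regexec('^"((?:[^"\\\\]|\\\\.)*)"', term))
  vapply(seq_along(term), function(i) {
    if (!is_literal_term(term[i]) || length(m[[i]]) < 2L) {
      stop_parse(sprintf("not a literal term: %s", term[i]))
    }
    unescape_lit(m[[i]][2])
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname is_iri_term
#' @export
lit_datatype <- function(term) {
  m <- regmatches(term, regexec('\\^\\^<([^>]*)>$', term))
  vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_, character(1))
}

#' @rdname is_iri_term
#' @export
lit_lang <- function(term) {
  m <- regmatches(term, regexec('"@([A-Za-z][A-Za-z0-9-]*)$', term))
  vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_, character(1))
}
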