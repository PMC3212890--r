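#' RDF graphs
#'
#' An `rdf_graph` is an unordered set of triples held as a three-column
#' character data frame of encoded terms (see [iri()]). Adding a duplicate
#' triple is a no-op; graph equality is RDF graph isomorphism (equality up to
#' a bijection of blank-node labels), tested with [graph_isomorphic()].
#'
#' @param s,p,o character vectors of encoded terms (recycled to equal length)
#' @return an `rdf_graph`
#' @examples
#' g <- rdf_graph(
#'   s = iri("http://example.org/x"),
#'   p = iri("http://xmlns.com/foaf/0.1/name"),
#'   o = lit("Guy Incognito")
#' )
#' graph_size(g)
#' @export
rdf_graph <- function(s = character(), p = character(), o = character()) {
  df <- data.frame(s = as.character(s), p = as.character(p),
                   o = as.character(o), stringsAsFactors = FALSE)
  bad <- !is_iri_term(df$p)
  if (any(bad)) stop_parse(sprintf("predicate must be an IRI: %s", df$p[bad][1]))
  if (any(is_literal_term(df$s))) stop_parse("subject must not be a literal")
  df <- unique(df)
  rownames(df) <- NULL
  structure(list(triples = df), class = "rdf_graph")
}

#' @rdname rdf_graph
#' @param g,h graphs
#' @export
triples <- function(g) g$triples

#' @rdname rdf_graph
#' @export
graph_size <- function(g) nrow(g$triples)

#' @rdname rdf_graph
#' @export
graph_add <- function(g, s, p, o) {
  rdf_graph(c(g$triples$s, s), c(g$triples$p, p), c(g$triples$o, o))
}

#' @rdname rdf_graph
#' @export
graph_union <- function(g, h) {
  rdf_graph(c(g$triples$s, h$triples$s),
            c(g$triples$p, h$triples$p),
            c(g$triples$o, h$triples$o))
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph: %d triple%s>\n", graph_size(x),
              if (graph_size(x) == 1L) "" else "s"))
  if (graph_size(x) > 0L) {
    df <- x$triples[order(x$triples$s, x$triples$p, x$triples$o), ]
    apply(utils::head(df, 20L), 1L,
          function(r) cat(" ", r[1], r[2], r[3], ".\n"))
    if (nrow(df) > 20L) cat("  ...\n")
  }
  invisible(x)
}

#' Match triples against an optional subject/predicate/object mask
#'
#' @param g an [rdf_graph()]
#' @param s,p,o encoded terms, or `NULL` for a wildcard position
#' @return the matching rows as a data frame of encoded terms
#' @export
graph_match <- function(g, s = NULL, p = NULL, o = NULL) {
  df <- g$triples
  keep <- rep(TRUE, nrow(df))
  if (!is.null(s)) keep <- keep & df$s == s
  if (!is.null(p)) keep <- keep & df$p == p
  if (!is.null(o)) keep <- keep & df$o == o
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

graph_contains <- function(g, s, p, o) {
  any(g$triples$s == s & g$triples$p == p & g$triples$o == o)
}

triple_keys <- function(df) paste(df$s, df$p, df$o)

graph_equal_exact <- function(g, h) {
  setequal(triple_keys(g$triples), triple_keys(h$triples))
}

blank_nodes <- function(g) {
  df <- g$triples
  sort(unique(c(df$s[is_blank_term(df$s)], df$o[is_blank_term(df$o)])))
}

# Colour refinement: a deterministic signature per blank node, iterated until
# the partition stops splitting. Used both to prune the isomorphism search
# and as a canonical ordering aid.
refine_colors <- function(g) {
  df <- g$triples
  bn <- blank_nodes(g)
  if (length(bn) == 0L) return(setNames(character(0), character(0)))
  color <- setNames(rep("0", length(bn)), bn)
  repeat {
    sig <- vapply(bn, function(b) {
      out_rows <- df[df$s == b, , drop = FALSE]
      in_rows <- df[df$o == b, , drop = FALSE]
      parts <- c(
        paste0("S|", out_rows$p, "|",
               ifelse(is_blank_term(out_rows$o), color[out_rows$o], out_rows$o)),
        paste0("O|", in_rows$p, "|",
               ifelse(is_blank_term(in_rows$s), color[in_rows$s], in_rows$s))
      )
      paste0(color[b], "#", paste(sort(parts), collapse = ";"))
    }, character(1))
    new_color <- setNames(as.character(match(sig, sort(unique(sig)))), bn)
    if (identical(split(bn, color[bn]), split(bn, new_color[bn]))) break
    color <- new_color
  }
  color
}

#' Test two graphs for RDF graph isomorphism
#'
#' Ground triples must agree exactly; blank nodes are matched by a bijection,
#' found by colour refinement followed by backtracking within colour classes.
#'
#' @param g,h graphs
#' @param max_candidates cap on the backtracking search size
#' @return `TRUE` or `FALSE`
#' @export
graph_isomorphic <- function(g, h, max_candidates = 1e5) {
  if (graph_size(g) != graph_size(h)) return(FALSE)
  bg <- blank_nodes(g); bh <- blank_nodes(h)
  if (length(bg) != length(bh)) return(FALSE)

  dg <- g$triples; dh <- h$triples
  ground_g <- dg[!is_blank_term(dg$s) & !is_blank_term(dg$o), , drop = FALSE]
  ground_h <- dh[!is_blank_term(dh$s) & !is_blank_term(dh$o), , drop = FALSE]
  if (!setequal(triple_keys(ground_g), triple_keys(ground_h))) return(FALSE)
  if (length(bg) == 0L) return(TRUE)

  cg <- refine_colors(g); ch <- refine_colors(h)
  if (!identical(sort(as.character(cg)), sort(as.character(ch)))) return(FALSE)

  keys_h <- triple_keys(dh)
  candidates <- lapply(bg, function(b) bh[ch[bh] == cg[[b]]])
  names(candidates) <- bg
  # order most-constrained-first
  bg <- bg[order(vapply(candidates, length, integer(1)))]

  n_tried <- 0L
  assign_next <- function(i, mapping, used) {
    if (i > length(bg)) {
      sub <- dg
      for (col in c("s", "o")) {
        idx <- is_blank_term(sub[[col]])
        sub[[col]][idx] <- mapping[sub[[col]][idx]]
      }
      return(setequal(triple_keys(sub), keys_h))
    }
    b <- bg[i]
    for (cand in candidates[[b]]) {
      if (cand %in% used) next
      n_tried <<- n_tried + 1L
      if (n_tried > max_candidates) {
        stop("isomorphism search exceeded max_candidates")
      }
      mapping[b] <- cand
      if (assign_next(i + 1L, mapping, c(used, cand))) return(TRUE)
    }
    FALSE
  }
  assign_next(1L, setNames(character(length(bg)), bg), character(0))
}
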