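# Independent oracles, written before (and kept independent of) the
# implementation paths they check.

# Brute-force structural classification: iterative restriction gathering and
# direct enumeration over the triple table, no shared code with satisfies().
oracle_satisfies <- function(g, node_iri, cls, ont, depth = 0L) {
  if (depth > 12L) return(FALSE)
  df <- triples(g)
  node_term <- paste0("<", node_iri, ">")

  all_restrictions <- list()
  queue <- list(cls)
  seen <- character(0)
  while (length(queue) > 0L) {
    c0 <- queue[[1]]
    queue <- queue[-1]
    if (c0$iri %in% seen) next
    seen <- c(seen, c0$iri)
    all_restrictions <- c(all_restrictions, c0$restrictions)
    for (s in c0$superclasses) {
      if (!is.null(ont$classes[[s]])) queue <- c(queue, list(ont$classes[[s]]))
    }
  }

  member <- function(value, filler) {
    if (filler == "http://www.w3.org/2002/07/owl#Thing") return(TRUE)
    if (startsWith(filler, "http://www.w3.org/2001/XMLSchema#")) {
      if (!startsWith(value, '"')) return(FALSE)
      dt <- regmatches(value, regexec("\\^\\^<([^>]*)>$", value))[[1]]
      dt <- if (length(dt) == 2L) dt[2] else "http://www.w3.org/2001/XMLSchema#string"
      return(dt == filler)
    }
    fcls <- ont$classes[[filler]]
    if (is.null(fcls)) stop(sprintf("oracle: unknown filler class %s", filler))
    if (startsWith(value, '"')) return(FALSE)
    typed <- any(df$s == value &
                   df$p == "<http://www.w3.org/1999/02/22-rdf-syntax-ns#type>" &
                   df$o == paste0("<", filler, ">"))
    if (typed) return(TRUE)
    if (!startsWith(value, "<")) return(FALSE)
    oracle_satisfies(g, substr(value, 2L, nchar(value) - 1L), fcls, ont, depth + 1L)
  }

  for (r in all_restrictions) {
    vals <- df$o[df$s == node_term & df$p == paste0("<", r$property, ">")]
    ok <- switch(r$kind,
      someValuesFrom = {
        hit <- FALSE
        for (v in vals) if (member(v, r$filler)) { hit <- TRUE; break }
        hit
      },
      allValuesFrom = {
        bad <- FALSE
        for (v in vals) if (!member(v, r$filler)) { bad <- TRUE; break }
        !bad
      },
      minCardinality = length(unique(vals)) >= r$min_count,
      hasValue = r$filler %in% vals
    )
    if (!ok) return(FALSE)
  }
  TRUE
}

# Naive BGP matcher: cartesian enumeration of candidate rows per pattern,
# then a consistency filter — no incremental joins.
oracle_bgp <- function(g, patterns, select_vars) {
  df <- triples(g)
  if (nrow(df) == 0L || length(patterns) == 0L) return(list())
  row_sets <- lapply(patterns, function(p) seq_len(nrow(df)))
  grid <- expand.grid(row_sets, KEEP.OUT.ATTRS = FALSE)
  sols <- list()
  for (gi in seq_len(nrow(grid))) {
    binding <- character(0)
    ok <- TRUE
    for (pi in seq_along(patterns)) {
      row <- df[grid[gi, pi], ]
      for (pos in c("s", "p", "o")) {
        want <- patterns[[pi]][[pos]]
        got <- row[[pos]]
        if (startsWith(want, "?")) {
          if (want %in% names(binding)) {
            if (binding[[want]] != got) { ok <- FALSE; break }
          } else {
            binding[[want]] <- got
          }
        } else if (want != got) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) sols[[length(sols) + 1L]] <- binding[select_vars[select_vars %in% names(binding)]]
  }
  unique(sols)
}

# Random graphs for serialization round-trip properties. Literals include
# the characters that stress both escapers.
random_graph <- function(n_triples, n_blanks = 2L) {
  subjects <- c(sprintf("<http://example.org/s%d>", 1:4),
                if (n_blanks > 0L) sprintf("_:b%d", seq_len(n_blanks)))
  preds <- sprintf("<http://example.org/p%d>", 1:6)
  nasty <- c("plain", "with \"quotes\"", "line\nbreak", "tab\there",
             "<xml> & entities", "café", "back\\slash")
  rand_obj <- function() {
    k <- sample(5L, 1L)
    if (k == 1L) sample(subjects, 1L)
    else if (k == 2L) sprintf("<http://example.org/o%d>", sample(9L, 1L))
    else if (k == 3L) lit(sample(nasty, 1L))
    else if (k == 4L) lit(sample(nasty, 1L), lang = sample(c("en", "fr"), 1L))
    else lit(as.character(sample(99L, 1L)),
             datatype = "http://www.w3.org/2001/XMLSchema#integer")
  }
  s <- sample(subjects, n_triples, replace = TRUE)
  p <- sample(preds, n_triples, replace = TRUE)
  o <- vapply(seq_len(n_triples), function(i) rand_obj(), character(1))
  rdf_graph(s, p, o)
}

no_sleep <- poll_policy(sleep = function(s) invisible(NULL))

hello_greeting_query <- paste0(
  "PREFIX hello: <http://sadiframework.org/examples/hello.owl#>\n",
  "SELECT ?greeting WHERE {\n",
  "  <http://sadiframework.org/examples/hello-input.rdf#1> hello:greeting ?greeting .\n}")
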