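#' Parse a SELECT query over one basic graph pattern
#'
#' Supported subset: `PREFIX` declarations, `SELECT ?v ...` or `SELECT *`,
#' and a `WHERE` block holding a conjunction of triple patterns separated by
#' `.`. Positions are variables (`?name`), IRIs (`<...>` or prefixed names,
#' with `a` for `rdf:type` in predicate position), or literals. Anything
#' beyond the subset (`OPTIONAL`, `FILTER`, `UNION`, ...) raises an explicit
#' unsupported-feature error rather than a misparse.
#'
#' @param text query text
#' @return `list(select = <character>, patterns = <list>)`; each pattern is
#'   `list(s =, p =, o =)` with variables as `"?name"` strings and everything
#'   else as encoded terms
#' @export
parse_query <- function(text) {
  for (feature in c("OPTIONAL", "FILTER", "UNION", "GRAPH", "MINUS", "SERVICE",
                    "CONSTRUCT", "DESCRIBE", "\\bASK\\b", "ORDER BY", "GROUP BY",
                    "LIMIT", "OFFSET")) {
    if (grepl(feature, text, ignore.case = TRUE)) {
      stop_unsupported_query(gsub("\\\\b", "", feature))
    }
  }
  prefixes <- c()
  pm <- gregexpr("(?i)PREFIX\\s+([A-Za-z_][A-Za-z0-9_.-]*)?:\\s*<([^>]*)>",
                 text, perl = TRUE)
  for (m in regmatches(text, pm)[[1]]) {
    parts <- regmatches(m, regexec(
      "(?i)PREFIX\\s+([A-Za-z_][A-Za-z0-9_.-]*)?:\\s*<([^>]*)>", m, perl = TRUE))[[1]]
    pfx <- if (is.na(parts[2]) || !nzchar(parts[2])) "%default%" else parts[2]
    prefixes[pfx] <- parts[3]
  }
  sm <- regmatches(text, regexec(
    "(?is)SELECT\\s+(.*?)\\s*WHERE\\s*\\{(.*)\\}", text, perl = TRUE))[[1]]
  if (length(sm) != 3L) stop_parse("query must be 'SELECT ... WHERE { ... }'")
  select_clause <- sm[2]
  body <- sm[3]
  select_vars <- regmatches(select_clause,
                            gregexpr("\\?[A-Za-z_][A-Za-z0-9_]*", select_clause))[[1]]
  if (length(select_vars) == 0L && !grepl("\\*", select_clause)) {
    stop_parse("SELECT clause names no variables")
  }

  token_re <- paste0(
    "(\\?[A-Za-z_][A-Za-z0-9_]*)",                                  # var
    "|(<[^>]*>)",                                                   # iri
    "|(\"(?:[^\"\\\\]|\\\\.)*\"(?:@[A-Za-z][A-Za-z0-9-]*|\\^\\^<[^>]*>|\\^\\^[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]+)?)", # literal
    "|([A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_][A-Za-z0-9_.-]*)",      # pname
    "|(\\ba\\b)",                                                   # rdf:type
    "|(\\.)"                                                        # separator
  )
  toks <- regmatches(body, gregexpr(token_re, body, perl = TRUE))[[1]]
  expand <- function(tok, position) {
    if (startsWith(tok, "?")) return(tok)
    if (tok == "a") {
      if (position != 2L) stop_parse("'a' is only valid in predicate position")
      return(iri(RDF$type))
    }
    if (startsWith(tok, "<")) return(iri(substr(tok, 2L, nchar(tok) - 1L)))
    if (startsWith(tok, "\"")) {
      pn_dt <- regmatches(tok, regexec(
        "\\^\\^([A-Za-z_][A-Za-z0-9_.-]*):([A-Za-z0-9_.-]+)$", tok))[[1]]
      if (length(pn_dt) == 3L) {
        base <- prefixes[pn_dt[2]]
        if (is.na(base)) stop_parse(sprintf("undeclared prefix: '%s:'", pn_dt[2]))
        return(paste0(sub("\\^\\^.*$", "", tok), "^^<", base, pn_dt[3], ">"))
      }
      return(tok)  # already in encoded form
    }
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    pfx <- if (nzchar(parts[1])) parts[1] else "%default%"
    base <- prefixes[pfx]
    if (is.na(base)) stop_parse(sprintf("undeclared prefix: '%s:'", pfx))
    iri(paste0(unname(base), paste(parts[-1], collapse = ":")))
  }
  patterns <- list()
  buf <- character(0)
  flush_pattern <- function(buf) {
    if (length(buf) == 0L) return(NULL)
    if (length(buf) != 3L) {
      stop_parse(sprintf("triple pattern has %d terms, expected 3: %s",
                         length(buf), paste(buf, collapse = " ")))
    }
    list(s = expand(buf[1], 1L), p = expand(buf[2], 2L), o = expand(buf[3], 3L))
  }
  for (tok in toks) {
    if (tok == ".") {
      pat <- flush_pattern(buf)
      if (!is.null(pat)) patterns[[length(patterns) + 1L]] <- pat
      buf <- character(0)
    } else {
      buf <- c(buf, tok)
    }
  }
  pat <- flush_pattern(buf)
  if (!is.null(pat)) patterns[[length(patterns) + 1L]] <- pat
  if (length(patterns) == 0L) stop_parse("query has no triple patterns")
  unknown_vars <- setdiff(select_vars, unlist(lapply(patterns, function(p) {
    Filter(function(x) startsWith(x, "?"), unlist(p))
  })))
  if (length(unknown_vars) > 0L) {
    stop_parse(sprintf("SELECT variable(s) not in the pattern: %s",
                       paste(unknown_vars, collapse = ", ")))
  }
  if (length(select_vars) == 0L) {
    select_vars <- unique(unlist(lapply(patterns, function(p) {
      Filter(function(x) startsWith(x, "?"), unlist(p))
    })))
  }
  list(select = select_vars, patterns = patterns)
}

is_qvar <- function(x) startsWith(x, "?")

#' Plan a query against a registry
#'
#' Each pattern with a bound (IRI) predicate is annotated with the services
#' that attach that predicate. Patterns are then ordered so that a pattern
#' whose subject variable is produced (appears as object) by an earlier
#' serviced pattern follows its producer; ties keep textual order, so the
#' plan is deterministic. Patterns whose predicate matches no service are
#' recorded as unservable — the query may still succeed if the seed data
#' covers them.
#'
#' @param patterns pattern list from [parse_query()]
#' @param reg a [sadi_registry()]
#' @return a `query_plan`: `list(order =, patterns =, bindings =,
#'   unservable =)` with `bindings` and `unservable` indexed like `patterns`
#' @export
plan <- function(patterns, reg) {
  n <- length(patterns)
  bindings <- vector("list", n)
  for (i in seq_len(n)) {
    p <- patterns[[i]]$p
    bindings[[i]] <- if (!is_qvar(p)) find_by_property(reg, term_iri(p)) else list()
  }
  produces <- lapply(seq_len(n), function(i) {
    o <- patterns[[i]]$o
    if (length(bindings[[i]]) > 0L && is_qvar(o)) o else character(0)
  })
  # Kahn's algorithm with stable (textual) tie-break
  deps <- lapply(seq_len(n), function(i) {
    s <- patterns[[i]]$s
    if (!is_qvar(s)) return(integer(0))
    which(vapply(seq_len(n), function(j) j != i && s %in% produces[[j]], logical(1)))
  })
  order_out <- integer(0)
  placed <- rep(FALSE, n)
  while (length(order_out) < n) {
    ready <- which(!placed & vapply(seq_len(n), function(i) {
      all(placed[deps[[i]]])
    }, logical(1)))
    if (length(ready) == 0L) {  # dependency cycle: fall back to textual order
      ready <- which(!placed)[1]
    }
    nxt <- ready[1]
    order_out <- c(order_out, nxt)
    placed[nxt] <- TRUE
  }
  structure(list(
    order = order_out,
    patterns = patterns,
    bindings = bindings,
    unservable = vapply(seq_len(n), function(i) {
      !is_qvar(patterns[[i]]$p) && length(bindings[[i]]) == 0L
    }, logical(1))
  ), class = "query_plan")
}

# conjunctive BGP matching by incremental binding extension
bgp_solutions <- function(g, patterns, select_vars) {
  df <- g$triples
  bindings <- list(character(0))
  for (pat in patterns) {
    nxt <- list()
    for (b in bindings) {
      inst <- function(x) if (is_qvar(x) && x %in% names(b)) b[[x]] else x
      s <- inst(pat$s); p <- inst(pat$p); o <- inst(pat$o)
      keep <- rep(TRUE, nrow(df))
      if (!is_qvar(s)) keep <- keep & df$s == s
      if (!is_qvar(p)) keep <- keep & df$p == p
      if (!is_qvar(o)) keep <- keep & df$o == o
      rows <- df[keep, , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        b2 <- b
        ok <- TRUE
        for (pos in c("s", "p", "o")) {
          x <- pat[[pos]]
          if (is_qvar(x)) {
            v <- rows[[pos]][k]
            if (x %in% names(b2)) {
              if (b2[[x]] != v) { ok <- FALSE; break }
            } else {
              b2[[x]] <- v
            }
          }
        }
        if (ok) nxt[[length(nxt) + 1L]] <- b2
      }
    }
    bindings <- nxt
    if (length(bindings) == 0L) break
  }
  sols <- lapply(bindings, function(b) b[intersect(select_vars, names(b))])
  unique(sols)
}

#' Answer a query by discovering and invoking services
#'
#' The resolver walks the plan: for every serviced pattern it collects
#' candidate input nodes from the working store (nodes explicitly typed with
#' the service's input class, plus nodes structurally satisfying it), adds
#' the input-class typing, invokes the service (multiplexed over candidates),
#' and merges the decorated outputs into the store with per-triple
#' provenance. Each (service, input node) pair is invoked at most once per
#' resolution, so cyclic plans terminate. When several services attach the
#' same predicate, all discovered candidates are invoked (within `limits`)
#' and their outputs unioned. Finally the basic graph pattern is evaluated
#' over the accumulated store by conjunctive matching.
#'
#' @param query query text or the result of [parse_query()]
#' @param reg a [sadi_registry()]
#' @param seed an [rdf_graph()] of initially known triples
#' @param transport a transport function
#' @param limits `list(max_invocations =, max_inputs_per_service =)`
#' @param policy a [poll_policy()] for asynchronous services
#' @param candidate_mode `"both"` (default), `"restriction"` or `"type"`:
#'   how store nodes qualify as inputs for a discovered service
#' @return `list(solutions =, store =, failures =, limit_hit =)`:
#'   `solutions` is a list of named vectors (variable -> encoded term),
#'   `store` is `list(graph =, provenance =)` where provenance maps each
#'   triple to `"seed"` or the producing endpoint, `failures` records
#'   per-service invocation faults, and `limit_hit` flags a truncated
#'   resolution
#' @export
resolve <- function(query, reg, seed, transport,
                    limits = list(max_invocations = 100L,
                                  max_inputs_per_service = 100L),
                    policy = poll_policy(),
                    candidate_mode = c("both", "restriction", "type")) {
  candidate_mode <- match.arg(candidate_mode)
  q <- if (is.character(query)) parse_query(query) else query
  stopifnot(inherits(seed, "rdf_graph"))
  store <- seed
  provenance <- stats::setNames(rep("seed", graph_size(seed)),
                                triple_keys(seed$triples))
  pl <- plan(q$patterns, reg)
  invoked <- character(0)
  n_invocations <- 0L
  limit_hit <- FALSE
  failures <- list()

  eligible_nodes <- function(rec) {
    nodes <- unique(store$triples$s[is_iri_term(store$triples$s)])
    keep <- vapply(nodes, function(nd) {
      by_type <- graph_contains(store, nd, iri(RDF$type), iri(rec$input_def$iri))
      if (candidate_mode == "type") return(by_type)
      by_restr <- satisfies(store, term_iri(nd), rec$input_def, rec$ontology)$satisfied
      if (candidate_mode == "restriction") by_restr else by_type || by_restr
    }, logical(1))
    nodes[keep]
  }

  forward_closure <- function(node_terms) {
    rows <- rep(FALSE, nrow(store$triples))
    for (nt in node_terms) {
      frontier <- nt
      seen <- character(0)
      while (length(frontier) > 0L) {
        cur <- frontier[1]; frontier <- frontier[-1]
        if (cur %in% seen) next
        seen <- c(seen, cur)
        hit <- store$triples$s == cur
        rows <- rows | hit
        nxt <- store$triples$o[hit]
        frontier <- c(frontier, nxt[!is_literal_term(nxt)])
      }
    }
    sub <- store$triples[rows, , drop = FALSE]
    rdf_graph(sub$s, sub$p, sub$o)
  }

  for (i in pl$order) {
    recs <- pl$bindings[[i]]
    if (length(recs) == 0L) next
    pat <- pl$patterns[[i]]
    for (rec in recs) {
      endpoint <- rec$description$endpoint
      cand <- if (!is_qvar(pat$s)) {
        if (is_iri_term(pat$s)) intersect(pat$s, eligible_nodes(rec)) else character(0)
      } else {
        eligible_nodes(rec)
      }
      cand <- cand[!(paste(endpoint, cand) %in% invoked)]
      if (length(cand) == 0L) next
      if (n_invocations >= limits$max_invocations) { limit_hit <- TRUE; break }
      if (length(cand) > limits$max_inputs_per_service) {
        limit_hit <- TRUE
        cand <- cand[seq_len(limits$max_inputs_per_service)]
      }
      inv_graph <- forward_closure(cand)
      inv_graph <- graph_add(inv_graph, cand,
                             rep(iri(RDF$type), length(cand)),
                             rep(iri(rec$input_def$iri), length(cand)))
      res <- tryCatch(
        invoke(endpoint, inv_graph, transport, policy = policy,
               description = rec$description),
        error = function(e) e
      )
      invoked <- c(invoked, paste(endpoint, cand))
      n_invocations <- n_invocations + 1L
      if (inherits(res, "error")) {
        failures[[endpoint]] <- conditionMessage(res)
        next
      }
      if (length(res$failures) > 0L) {
        failures[[endpoint]] <- sprintf("%d root(s) failed", length(res$failures))
      }
      new_rows <- res$merged$triples
      new_keys <- triple_keys(new_rows)
      fresh <- !(new_keys %in% names(provenance))
      provenance[new_keys[fresh]] <- endpoint
      store <- graph_union(store, res$merged)
    }
  }
  list(
    solutions = bgp_solutions(store, q$patterns, q$select),
    store = list(graph = store, provenance = provenance),
    failures = failures,
    limit_hit = limit_hit
  )
}
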