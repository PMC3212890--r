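# N3 (Turtle-compatible subset) reader and writer.
#
# Supported on input: @prefix, IRIs, prefixed names, `a`, blank node labels,
# anonymous blank nodes `[ ... ]`, collections `( ... )`, object/predicate
# lists with `,` and `;`, plain/typed/language literals, bare integers,
# decimals and booleans, comments. Not supported (by design): @base, named
# graphs, TriG, quoted graphs, paths.

n3_tokenize <- function(text) {
  tokens <- list()
  n <- nchar(text)
  pos <- 1L
  push <- function(type, value) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value)
  peek_chunk <- function(k = 64L) substr(text, pos, min(n, pos + k - 1L))
  match_at <- function(re) {
    m <- regexpr(re, substr(text, pos, min(n, pos + 4095L)), perl = TRUE)
    if (m == 1L) substr(text, pos, pos + attr(m, "match.length") - 1L) else NA_character_
  }
  while (pos <= n) {
    ch <- substr(text, pos, pos)
    if (grepl("^[ \t\r\n]$", ch)) { pos <- pos + 1L; next }
    if (ch == "#") {
      nl <- regexpr("\n", substr(text, pos, n), fixed = TRUE)
      if (nl == -1L) break
      pos <- pos + nl
      next
    }
    if (ch == "<") {
      m <- match_at("^<[^<>\"{}|^`\\\\ ]*>")
      if (is.na(m)) stop_parse(sprintf("malformed IRI near: %s", peek_chunk()))
      push("iri", substr(m, 2L, nchar(m) - 1L))
      pos <- pos + nchar(m)
      next
    }
    if (ch == '"') {
      m <- match_at('^"(?:[^"\\\\]|\\\\.)*"')
      if (is.na(m)) stop_parse(sprintf("unterminated string near: %s", peek_chunk()))
      push("string", substr(m, 2L, nchar(m) - 1L))
      pos <- pos + nchar(m)
      lt <- match_at("^@[A-Za-z][A-Za-z0-9-]*")
      if (!is.na(lt)) {
        push("langtag", substr(lt, 2L, nchar(lt)))
        pos <- pos + nchar(lt)
      } else if (substr(text, pos, pos + 1L) == "^^") {
        push("dtype_marker", "^^")
        pos <- pos + 2L
      }
      next
    }
    if (substr(text, pos, pos + 1L) == "_:") {
      m <- match_at("^_:[A-Za-z0-9][A-Za-z0-9_-]*")
      if (is.na(m)) stop_parse(sprintf("malformed blank node label near: %s", peek_chunk()))
      push("blank", substr(m, 3L, nchar(m)))
      pos <- pos + nchar(m)
      next
    }
    if (ch == "@") {
      m <- match_at("^@[A-Za-z]+")
      kw <- substr(m, 2L, nchar(m))
      if (identical(kw, "prefix")) push("at_prefix", kw)
      else stop_parse(sprintf("unsupported directive: @%s", kw))
      pos <- pos + nchar(m)
      next
    }
    if (ch %in% c(".", ";", ",", "[", "]", "(", ")")) {
      push(ch, ch)
      pos <- pos + 1L
      next
    }
    m <- match_at("^[+-]?[0-9]+(\\.[0-9]+)?")
    if (!is.na(m)) {
      push("number", m)
      pos <- pos + nchar(m)
      next
    }
    m <- match_at("^[A-Za-z_][A-Za-z0-9_.-]*")
    word <- if (is.na(m)) "" else m
    follow <- substr(text, pos + nchar(word), pos + nchar(word))
    if (nzchar(word) && follow != ":") {
      while (endsWith(word, ".")) word <- substr(word, 1L, nchar(word) - 1L)
      if (word == "a") { push("kw_a", "a"); pos <- pos + 1L; next }
      if (word %in% c("true", "false")) {
        push("boolean", word)
        pos <- pos + nchar(word)
        next
      }
      stop_parse(sprintf("unexpected token near: %s", peek_chunk()))
    }
    m <- match_at("^(?:[A-Za-z_][A-Za-z0-9_.-]*)?:(?:[A-Za-z0-9_][A-Za-z0-9_.-]*)?")
    if (!is.na(m)) {
      while (endsWith(m, ".")) m <- substr(m, 1L, nchar(m) - 1L)
      push("pname", m)
      pos <- pos + nchar(m)
      next
    }
    stop_parse(sprintf("unexpected character '%s' near: %s", ch, peek_chunk()))
  }
  tokens
}

parse_n3 <- function(text) {
  tokens <- n3_tokenize(text)
  env <- new.env(parent = emptyenv())
  env$prefixes <- character(0)
  env$i <- 1L
  env$gen <- 0L
  acc <- list(s = character(0), p = character(0), o = character(0))
  emit <- function(s, p, o) {
    force(s); force(p); force(o)  # nested terms emit their own triples first
    acc$s[length(acc$s) + 1L] <<- s
    acc$p[length(acc$p) + 1L] <<- p
    acc$o[length(acc$o) + 1L] <<- o
  }
  peek <- function() if (env$i <= length(tokens)) tokens[[env$i]] else NULL
  advance <- function() { t <- peek(); env$i <- env$i + 1L; t }
  expect <- function(type) {
    t <- advance()
    if (is.null(t) || t$type != type) {
      stop_parse(sprintf("expected '%s', got '%s'", type,
                         if (is.null(t)) "<end of document>" else t$value))
    }
    t
  }
  expand_pname <- function(pn) {
    parts <- regmatches(pn, regexec("^([^:]*):(.*)$", pn))[[1]]
    pfx <- parts[2]; local <- parts[3]
    if (!nzchar(pfx)) pfx <- "%default%"  # "" is not addressable as a name in R
    base <- env$prefixes[pfx]
    if (is.na(base)) stop_parse(sprintf("undeclared prefix: '%s:'", pfx))
    iri(paste0(unname(base), local))
  }
  fresh_blank <- function() {
    env$gen <- env$gen + 1L
    blank(sprintf("gen%d", env$gen))
  }
  read_literal <- function(str_tok) {
    # lexical is kept in its escaped source form, which matches our encoding
    encoded <- paste0('"', str_tok$value, '"')
    t <- peek()
    if (!is.null(t) && t$type == "langtag") {
      advance()
      return(paste0(encoded, "@", t$value))
    }
    if (!is.null(t) && t$type == "dtype_marker") {
      advance()
      dt <- advance()
      dt_iri <- switch(dt$type,
        iri = dt$value,
        pname = term_iri(expand_pname(dt$value)),
        stop_parse("expected datatype IRI after ^^")
      )
      return(paste0(encoded, "^^<", dt_iri, ">"))
    }
    encoded
  }
  read_term <- function(as_verb = FALSE) {
    t <- advance()
    if (is.null(t)) stop_parse("unexpected end of document")
    switch(t$type,
      iri = iri(t$value),
      pname = expand_pname(t$value),
      kw_a = if (as_verb) iri(RDF$type) else stop_parse("'a' is only a predicate"),
      blank = blank(paste0("u_", t$value)),
      string = read_literal(t),
      number = if (grepl("\\.", t$value)) {
        lit(t$value, datatype = XSD$decimal)
      } else {
        lit(t$value, datatype = XSD$integer)
      },
      boolean = lit(t$value, datatype = XSD$boolean),
      "[" = {
        b <- fresh_blank()
        if (!is.null(peek()) && peek()$type != "]") read_po_list(b)
        expect("]")
        b
      },
      "(" = read_collection(),
      stop_parse(sprintf("unexpected token: '%s'", t$value))
    )
  }
  read_collection <- function() {
    items <- list()
    while (!is.null(peek()) && peek()$type != ")") {
      items[[length(items) + 1L]] <- read_term()
    }
    expect(")")
    if (length(items) == 0L) return(iri(RDF$nil))
    head_b <- fresh_blank()
    cur <- head_b
    for (k in seq_along(items)) {
      emit(cur, iri(RDF$first), items[[k]])
      nxt <- if (k < length(items)) fresh_blank() else iri(RDF$nil)
      emit(cur, iri(RDF$rest), nxt)
      cur <- nxt
    }
    head_b
  }
  read_po_list <- function(subject) {
    repeat {
      verb <- read_term(as_verb = TRUE)
      if (!is_iri_term(verb)) stop_parse("predicate must be an IRI")
      repeat {
        emit(subject, verb, read_term())
        if (!is.null(peek()) && peek()$type == ",") advance() else break
      }
      t <- peek()
      if (!is.null(t) && t$type == ";") {
        advance()
        # tolerate trailing ';' before '.' or ']'
        t2 <- peek()
        if (is.null(t2) || t2$type %in% c(".", "]")) break
      } else break
    }
  }
  while (!is.null(peek())) {
    if (peek()$type == "at_prefix") {
      advance()
      pn <- expect("pname")$value
      pfx <- sub(":.*$", "", pn)
      if (!endsWith(pn, ":") || !identical(paste0(pfx, ":"), pn)) {
        stop_parse(sprintf("malformed @prefix declaration: '%s'", pn))
      }
      if (!nzchar(pfx)) pfx <- "%default%"
      target <- expect("iri")$value
      env$prefixes[pfx] <- target
      expect(".")
      next
    }
    subject <- read_term()
    if (is_literal_term(subject)) stop_parse("subject must not be a literal")
    read_po_list(subject)
    expect(".")
  }
  rdf_graph(acc$s, acc$p, acc$o)
}

# Writer: grouped by subject, well-known prefixes applied where the suffix is
# a clean local name; everything else in full <IRI> form. Encoded literals are
# already valid N3 tokens and pass through unchanged.
WELL_KNOWN_PREFIXES <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#",
  xsd = "http://www.w3.org/2001/XMLSchema#",
  foaf = "http://xmlns.com/foaf/0.1/",
  mygrid = "http://www.mygrid.org.uk/mygrid-moby-service#"
)

n3_term <- function(term, used) {
  if (is_iri_term(term)) {
    full <- term_iri(term)
    for (pfx in names(WELL_KNOWN_PREFIXES)) {
      base <- WELL_KNOWN_PREFIXES[[pfx]]
      if (startsWith(full, base)) {
        local <- substr(full, nchar(base) + 1L, nchar(full))
        if (grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)) {
          used[[pfx]] <- TRUE
          return(list(text = paste0(pfx, ":", local), used = used))
        }
      }
    }
    return(list(text = term, used = used))
  }
  if (is_literal_term(term)) {
    dt <- lit_datatype(term)
    if (!is.na(dt)) {
      for (pfx in names(WELL_KNOWN_PREFIXES)) {
        base <- WELL_KNOWN_PREFIXES[[pfx]]
        if (startsWith(dt, base)) {
          local <- substr(dt, nchar(base) + 1L, nchar(dt))
          if (grepl("^[A-Za-z_][A-Za-z0-9_-]*$", local)) {
            used[[pfx]] <- TRUE
            body <- sub("\\^\\^<[^>]*>$", "", term)
            return(list(text = paste0(body, "^^", pfx, ":", local), used = used))
          }
        }
      }
    }
  }
  list(text = term, used = used)
}

serialize_n3 <- function(g) {
  if (graph_size(g) == 0L) return("# empty RDF graph\n")
  df <- g$triples[order(g$triples$s, g$triples$p, g$triples$o), , drop = FALSE]
  used <- list()
  body_lines <- character(0)
  for (subj in unique(df$s)) {
    rows <- df[df$s == subj, , drop = FALSE]
    st <- n3_term(subj, used); used <- st$used
    po <- character(0)
    for (pred in unique(rows$p)) {
      objs <- rows$o[rows$p == pred]
      pt <- if (pred == iri(RDF$type)) {
        list(text = "a", used = used)
      } else {
        n3_term(pred, used)
      }
      used <- pt$used
      otexts <- character(0)
      for (ob in objs) {
        ot <- n3_term(ob, used); used <- ot$used
        otexts <- c(otexts, ot$text)
      }
      po <- c(po, paste0("    ", pt$text, " ", paste(otexts, collapse = ", ")))
    }
    body_lines <- c(body_lines, paste0(st$text, "\n", paste(po, collapse = " ;\n"), " .\n"))
  }
  header <- vapply(names(used), function(pfx) {
    sprintf("@prefix %s: <%s> .", pfx, WELL_KNOWN_PREFIXES[[pfx]])
  }, character(1))
  paste0(
    if (length(header)) paste0(paste(header, collapse = "\n"), "\n\n") else "",
    paste(body_lines, collapse = "\n")
  )
}
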