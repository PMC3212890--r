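# RDF/XML reader and writer (xml2 does the XML layer).
#
# Reader coverage: rdf:RDF documents, rdf:Description and typed node
# elements, rdf:about / rdf:nodeID, property elements with rdf:resource,
# rdf:nodeID, rdf:datatype, xml:lang (inherited), nested node elements,
# rdf:parseType="Resource" and "Collection", and non-RDF property attributes
# as literal triples. rdf:ID and xml:base are not supported (documents on
# this wire always use absolute IRIs).

RDF_XML_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

rx_qname <- function(node, nsmap) {
  q <- xml2::xml_name(node, ns = nsmap)
  if (grepl(":", q, fixed = TRUE)) {
    parts <- strsplit(q, ":", fixed = TRUE)[[1]]
    uri <- nsmap[[parts[1]]]
    if (is.null(uri) || is.na(uri)) stop_parse(sprintf("unresolved XML prefix: %s", parts[1]))
    paste0(uri, paste(parts[-1], collapse = ":"))
  } else {
    stop_parse(sprintf("element '%s' has no XML namespace", q))
  }
}

rx_attrs <- function(node, nsmap) {
  at <- xml2::xml_attrs(node, ns = nsmap)
  if (length(at) == 0L) return(at)
  full <- vapply(names(at), function(nm) {
    if (grepl(":", nm, fixed = TRUE)) {
      parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (parts[1] == "xml") return(nm)  # xml:lang etc. stay prefixed
      uri <- nsmap[[parts[1]]]
      if (is.null(uri) || is.na(uri)) return(nm)
      paste0(uri, paste(parts[-1], collapse = ":"))
    } else nm
  }, character(1))
  names(at) <- full
  at
}

parse_rdfxml <- function(text) {
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) stop_parse(paste("malformed XML:", conditionMessage(e))))
  nsmap <- xml2::xml_ns(doc)
  if (!"http://www.w3.org/XML/1998/namespace" %in% unclass(nsmap)) {
    nsmap <- structure(c(unclass(nsmap),
                         xml = "http://www.w3.org/XML/1998/namespace"),
                       class = class(nsmap))
  }
  acc <- new.env(parent = emptyenv())
  acc$s <- character(0); acc$p <- character(0); acc$o <- character(0)
  acc$gen <- 0L
  emit <- function(s, p, o) {
    force(s); force(p); force(o)  # nested node elements emit first
    acc$s[length(acc$s) + 1L] <- s
    acc$p[length(acc$p) + 1L] <- p
    acc$o[length(acc$o) + 1L] <- o
  }
  fresh_blank <- function() {
    acc$gen <- acc$gen + 1L
    blank(sprintf("x%d", acc$gen))
  }

  parse_node_element <- function(el, lang) {
    at <- rx_attrs(el, nsmap)
    qn <- rx_qname(el, nsmap)
    if (!is.na(at[paste0("xml:", "lang")])) lang <- unname(at["xml:lang"])
    subj <-
      if (!is.na(at[paste0(RDF_XML_NS, "about")])) {
        iri(unname(at[paste0(RDF_XML_NS, "about")]))
      } else if (!is.na(at[paste0(RDF_XML_NS, "nodeID")])) {
        blank(paste0("u_", unname(at[paste0(RDF_XML_NS, "nodeID")])))
      } else {
        fresh_blank()
      }
    if (qn != paste0(RDF_XML_NS, "Description")) {
      emit(subj, iri(RDF$type), iri(qn))
    }
    # property attributes
    for (nm in names(at)) {
      if (startsWith(nm, RDF_XML_NS) || startsWith(nm, "xml") || !grepl("^[a-z]+://", nm)) next
      emit(subj, iri(nm), lit(unname(at[nm]), lang = if (nzchar(lang)) lang else NULL))
    }
    for (child in xml2::xml_children(el)) {
      parse_property_element(subj, child, lang)
    }
    subj
  }

  parse_property_element <- function(subj, el, lang) {
    at <- rx_attrs(el, nsmap)
    pred <- iri(rx_qname(el, nsmap))
    if (!is.na(at["xml:lang"])) lang <- unname(at["xml:lang"])
    parse_type <- at[paste0(RDF_XML_NS, "parseType")]
    if (!is.na(at[paste0(RDF_XML_NS, "resource")])) {
      emit(subj, pred, iri(unname(at[paste0(RDF_XML_NS, "resource")])))
      return(invisible())
    }
    if (!is.na(at[paste0(RDF_XML_NS, "nodeID")])) {
      emit(subj, pred, blank(paste0("u_", unname(at[paste0(RDF_XML_NS, "nodeID")]))))
      return(invisible())
    }
    if (!is.na(parse_type) && parse_type == "Resource") {
      b <- fresh_blank()
      emit(subj, pred, b)
      for (child in xml2::xml_children(el)) parse_property_element(b, child, lang)
      return(invisible())
    }
    if (!is.na(parse_type) && parse_type == "Collection") {
      items <- vapply(xml2::xml_children(el), parse_node_element, character(1), lang = lang)
      if (length(items) == 0L) {
        emit(subj, pred, iri(RDF$nil))
        return(invisible())
      }
      cur <- fresh_blank()
      emit(subj, pred, cur)
      for (k in seq_along(items)) {
        emit(cur, iri(RDF$first), items[[k]])
        nxt <- if (k < length(items)) fresh_blank() else iri(RDF$nil)
        emit(cur, iri(RDF$rest), nxt)
        cur <- nxt
      }
      return(invisible())
    }
    kids <- xml2::xml_children(el)
    if (length(kids) > 0L) {
      if (length(kids) > 1L) stop_parse("property element with multiple node-element children")
      obj <- parse_node_element(kids[[1]], lang)
      emit(subj, pred, obj)
      return(invisible())
    }
    dt <- at[paste0(RDF_XML_NS, "datatype")]
    txt <- xml2::xml_text(el)
    emit(subj, pred, lit(txt,
                         datatype = if (!is.na(dt)) unname(dt) else NULL,
                         lang = if (is.na(dt) && nzchar(lang)) lang else NULL))
    invisible()
  }

  root <- xml2::xml_root(doc)
  root_qn <- rx_qname(root, nsmap)
  if (root_qn == paste0(RDF_XML_NS, "RDF")) {
    for (child in xml2::xml_children(root)) parse_node_element(child, "")
  } else {
    # a single node element as document root is legal RDF/XML
    parse_node_element(root, "")
  }
  rdf_graph(acc$s, acc$p, acc$o)
}

# --- writer ------------------------------------------------------------

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xml_escape_attr <- function(x) {
  x <- xml_escape_text(x)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  gsub("\n", "&#10;", x, fixed = TRUE)
}

# Split an IRI into (namespace, local) where local is a valid NCName suffix.
split_qname <- function(full) {
  m <- regexpr("[A-Za-z_][A-Za-z0-9_.-]*$", full)
  if (m == -1L || m == 1L) {
    stop_parse(sprintf("cannot derive an XML qualified name for predicate IRI: %s", full))
  }
  local <- regmatches(full, m)
  list(ns = substr(full, 1L, m - 1L), local = local)
}

serialize_rdfxml <- function(g) {
  df <- g$triples[order(g$triples$s, g$triples$p, g$triples$o), , drop = FALSE]
  # assign prefixes for every predicate namespace
  ns_tab <- new.env(parent = emptyenv())
  ns_tab$map <- c("http://www.w3.org/1999/02/22-rdf-syntax-ns#" = "rdf")
  prefix_for <- function(ns) {
    hit <- ns_tab$map[ns]
    if (!is.na(hit)) return(unname(hit))
    known <- WELL_KNOWN_PREFIXES[WELL_KNOWN_PREFIXES == ns]
    pfx <- if (length(known)) names(known)[1] else sprintf("ns%d", length(ns_tab$map))
    ns_tab$map[ns] <- pfx
    pfx
  }
  pred_parts <- lapply(unique(df$p), function(p) {
    parts <- split_qname(term_iri(p))
    parts$prefix <- prefix_for(parts$ns)
    parts
  })
  names(pred_parts) <- unique(df$p)

  lines <- character(0)
  for (subj in unique(df$s)) {
    rows <- df[df$s == subj, , drop = FALSE]
    subj_attr <- if (is_blank_term(subj)) {
      sprintf('rdf:nodeID="%s"', xml_escape_attr(substring(subj, 3L)))
    } else {
      sprintf('rdf:about="%s"', xml_escape_attr(term_iri(subj)))
    }
    props <- vapply(seq_len(nrow(rows)), function(k) {
      pp <- pred_parts[[rows$p[k]]]
      tag <- paste0(pp$prefix, ":", pp$local)
      ob <- rows$o[k]
      if (is_iri_term(ob)) {
        sprintf('    <%s rdf:resource="%s"/>', tag, xml_escape_attr(term_iri(ob)))
      } else if (is_blank_term(ob)) {
        sprintf('    <%s rdf:nodeID="%s"/>', tag, xml_escape_attr(substring(ob, 3L)))
      } else {
        dt <- lit_datatype(ob); lang <- lit_lang(ob)
        extra <- if (!is.na(dt)) {
          sprintf(' rdf:datatype="%s"', xml_escape_attr(dt))
        } else if (!is.na(lang)) {
          sprintf(' xml:lang="%s"', xml_escape_attr(lang))
        } else ""
        sprintf("    <%s%s>%s</%s>", tag, extra, xml_escape_text(lit_value(ob)), tag)
      }
    }, character(1))
    lines <- c(lines,
               sprintf("  <rdf:Description %s>", subj_attr),
               props,
               "  </rdf:Description>")
  }
  ns_decls <- vapply(names(ns_tab$map), function(ns) {
    sprintf('xmlns:%s="%s"', ns_tab$map[[ns]], xml_escape_attr(ns))
  }, character(1))
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    "<rdf:RDF ", paste(ns_decls, collapse = "\n         "), ">\n",
    paste(lines, collapse = "\n"),
    if (length(lines)) "\n" else "",
    "</rdf:RDF>\n"
  )
}
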