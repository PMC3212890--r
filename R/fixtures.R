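#' The hello worked example and synthetic fixture generators
#'
#' The reference corpus re-creates the canonical "Hello" service: input class
#' `NamedIndividual` (at least one `foaf:name`), output class
#' `GreetedIndividual` (adds a `greeting` datatype property), greeting
#' template `"Hello, <name>!"`, endpoint
#' `http://sadiframework.org/examples/hello`. Everything is generated in
#' code so the whole stack is testable offline.
#'
#' @name fixtures
NULL

#' Well-known IRIs of the hello reference corpus
#'
#' Named list: `endpoint`, `ontology_doc`, `NamedIndividual`,
#' `GreetedIndividual`, `greeting`, `input_root`.
#'
#' @export
HELLO <- list(
  endpoint = "http://sadiframework.org/examples/hello",
  ontology_doc = "http://sadiframework.org/examples/hello.owl",
  NamedIndividual = "http://sadiframework.org/examples/hello.owl#NamedIndividual",
  GreetedIndividual = "http://sadiframework.org/examples/hello.owl#GreetedIndividual",
  greeting = "http://sadiframework.org/examples/hello.owl#greeting",
  input_root = "http://sadiframework.org/examples/hello-input.rdf#1"
)

hello_ontology_text <- function() {
  paste0(
    "@prefix owl: <", NS$owl, "> .\n",
    "@prefix rdfs: <", NS$rdfs, "> .\n",
    "@prefix xsd: <", NS$xsd, "> .\n",
    "@prefix foaf: <", NS$foaf, "> .\n",
    "@prefix hello: <", HELLO$ontology_doc, "#> .\n\n",
    "hello:NamedIndividual a owl:Class ;\n",
    "    rdfs:subClassOf [ a owl:Restriction ;\n",
    "        owl:onProperty foaf:name ;\n",
    "        owl:minCardinality \"1\"^^xsd:nonNegativeInteger ] .\n\n",
    "hello:GreetedIndividual a owl:Class ;\n",
    "    rdfs:subClassOf [ a owl:Restriction ;\n",
    "        owl:onProperty hello:greeting ;\n",
    "        owl:someValuesFrom xsd:string ] .\n\n",
    "hello:greeting a owl:DatatypeProperty .\n"
  )
}

#' Build the hello reference service
#'
#' For each `foaf:name` value carried by a root, the service attaches one
#' `greeting` triple with the value `"Hello, <name>!"`.
#'
#' @param mode `"sync"` or `"async"`
#' @param async_delay_polls pending polls before an async task completes
#' @return a [sadi_service()]
#' @export
build_hello <- function(mode = c("sync", "async"), async_delay_polls = 1L) {
  mode <- match.arg(mode)
  d <- service_description(
    name = "Hello",
    endpoint = HELLO$endpoint,
    description_text = "Returns a greeting for each named individual.",
    input_class = HELLO$NamedIndividual,
    output_class = HELLO$GreetedIndividual,
    authority = "sadiframework.org",
    async_capable = mode == "async"
  )
  annotate <- function(input, root, params) {
    names_ <- graph_match(input, s = iri(root), p = iri(FOAF$name))$o
    names_ <- names_[is_literal_term(names_)]
    g <- rdf_graph()
    for (nm in names_) {
      g <- graph_add(g, iri(root), iri(HELLO$greeting),
                     lit(paste0("Hello, ", lit_value(nm), "!")))
    }
    g
  }
  sadi_service(d, annotate, mode = mode, async_delay_polls = async_delay_polls)
}

#' The hello invocation graph (one named individual)
#'
#' @param name the `foaf:name` value (default the reference corpus value)
#' @param root plain IRI of the input individual
#' @return an [rdf_graph()]
#' @export
hello_input_graph <- function(name = "Guy Incognito", root = HELLO$input_root) {
  rdf_graph(
    s = c(iri(root), iri(root)),
    p = c(iri(RDF$type), iri(FOAF$name)),
    o = c(iri(HELLO$NamedIndividual), lit(name))
  )
}

#' Fixture catalogues
#'
#' A catalogue bundles hosted services, a local IRI -> document map for every
#' ontology any of them references, and a corpus of paired
#' invocation/response messages, so that [in_memory_transport()] and
#' [class_loader()] can serve the whole stack offline.
#'
#' @param hosts list of [service_host()]
#' @param ontologies named list: document IRI -> `list(body, media_type)`
#' @param messages named list of `list(request =, response =)` text pairs
#' @return a `fixture_catalogue`
#' @export
fixture_catalogue <- function(hosts = list(), ontologies = list(),
                              messages = list()) {
  structure(list(hosts = hosts, ontologies = ontologies, messages = messages),
            class = "fixture_catalogue")
}

#' @rdname fixture_catalogue
#' @param catalogue a `fixture_catalogue`
#' @return `catalogue_fetcher()`: a fetch contract over the catalogue's
#'   ontology documents; `catalogue_loader()`: a class resolver over them
#' @export
catalogue_fetcher <- function(catalogue) local_fetcher(catalogue$ontologies)

#' @rdname fixture_catalogue
#' @export
catalogue_loader <- function(catalogue) class_loader(catalogue_fetcher(catalogue))

#' Build the hello catalogue, optionally with decoy services
#'
#' Decoy services are structurally valid services whose input classes demand
#' properties the hello input does not carry; they exercise discovery
#' selectivity. Decoy `i` consumes nodes with property `p<i>` and attaches
#' `q<i>`.
#'
#' @param mode hello service mode
#' @param n_decoys number of decoy services
#' @param async_delay_polls forwarded to [build_hello()]
#' @return a [fixture_catalogue()]
#' @export
build_hello_catalogue <- function(mode = "sync", n_decoys = 0L,
                                  async_delay_polls = 1L) {
  hosts <- list(hello = service_host(build_hello(mode, async_delay_polls)))
  onts <- list()
  onts[[HELLO$ontology_doc]] <- list(body = hello_ontology_text(),
                                     media_type = MEDIA_N3)
  for (i in seq_len(n_decoys)) {
    base <- sprintf("http://example.org/decoy%d", i)
    doc <- paste0(base, "/onto.owl")
    onts[[doc]] <- list(body = paste0(
      "@prefix owl: <", NS$owl, "> .\n",
      "@prefix rdfs: <", NS$rdfs, "> .\n",
      "@prefix xsd: <", NS$xsd, "> .\n",
      "<", doc, "#In> a owl:Class ;\n",
      "  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty <", base, "/p> ;\n",
      "    owl:someValuesFrom xsd:string ] .\n",
      "<", doc, "#Out> a owl:Class ;\n",
      "  rdfs:subClassOf [ a owl:Restriction ; owl:onProperty <", base, "/q> ;\n",
      "    owl:someValuesFrom xsd:string ] .\n"
    ), media_type = MEDIA_N3)
    d <- service_description(
      name = sprintf("Decoy %d", i),
      endpoint = base,
      input_class = paste0(doc, "#In"),
      output_class = paste0(doc, "#Out"),
      authority = "example.org"
    )
    annotate <- local({
      q_prop <- paste0(base, "/q")
      function(input, root, params) {
        rdf_graph(iri(root), iri(q_prop), lit("decoy"))
      }
    })
    hosts[[sprintf("decoy%d", i)]] <-
      service_host(sadi_service(d, annotate, mode = "sync"))
  }
  msg <- serialize_graph(hello_input_graph(), MEDIA_RDFXML)
  resp <- handle_post(hosts$hello, msg, MEDIA_RDFXML)
  messages <- if (mode == "sync") {
    list(hello = list(request = msg, response = resp$body))
  } else list()
  fixture_catalogue(hosts, onts, messages)
}

#' Synthetic service-chain specification
#'
#' @param chain_length number of chained services (>= 2)
#' @param seed integer seed; generation is reproducible from it
#' @param n_services,property_pool_size sizes for [generate_matchmaking_cases()]
#'   catalogues (chains take their size from `chain_length`)
#' @param restriction_depth 1 = restrictions on the class itself, 2 = one
#'   level of named superclass carrying further restrictions
#' @return a `synthetic_spec`
#' @export
synthetic_spec <- function(chain_length = 2L, seed = 1L, n_services = 5L,
                           property_pool_size = 8L, restriction_depth = 2L) {
  stopifnot(restriction_depth %in% 1:2, seed == as.integer(seed))
  structure(list(chain_length = as.integer(chain_length),
                 seed = as.integer(seed),
                 n_services = as.integer(n_services),
                 property_pool_size = as.integer(property_pool_size),
                 restriction_depth = as.integer(restriction_depth)),
            class = "synthetic_spec")
}

#' Build a deterministic service chain
#'
#' Service `i` of the chain consumes nodes carrying property `p<i-1>` and
#' attaches `p<i>` with a closed-form value IRI, so service `i+1`'s input
#' class is satisfied exactly after service `i` has run. The seed root
#' carries `p0`. The returned object includes the chain query and its known
#' single solution, making end-to-end resolution checkable against the
#' generator itself.
#'
#' @param spec a [synthetic_spec()] with `chain_length >= 2`
#' @param mode service mode for every chain member
#' @return list: `catalogue`, `seed_graph`, `root`, `query`, `expected`
#'   (named encoded-term vector, one entry per chain variable)
#' @export
build_chain <- function(spec, mode = c("sync", "async")) {
  mode <- match.arg(mode)
  k <- spec$chain_length
  if (k < 2L) stop("chain_length must be >= 2")
  base <- sprintf("http://example.org/chain%d", spec$seed)
  doc <- paste0(base, "/onto.owl")
  prop <- function(i) paste0(base, "/p", i)
  cls_in <- function(i) paste0(doc, "#In", i)
  cls_out <- function(i) paste0(doc, "#Out", i)

  ont_lines <- c(
    paste0("@prefix owl: <", NS$owl, "> ."),
    paste0("@prefix rdfs: <", NS$rdfs, "> ."),
    paste0("@prefix xsd: <", NS$xsd, "> .")
  )
  for (i in seq_len(k)) {
    ont_lines <- c(ont_lines,
      paste0("<", cls_in(i), "> a owl:Class ; rdfs:subClassOf [ a owl:Restriction ; ",
             "owl:onProperty <", prop(i - 1L), "> ; owl:minCardinality ",
             "\"1\"^^xsd:nonNegativeInteger ] ."),
      paste0("<", cls_out(i), "> a owl:Class ; rdfs:subClassOf [ a owl:Restriction ; ",
             "owl:onProperty <", prop(i), "> ; owl:someValuesFrom owl:Thing ] .")
    )
  }
  onts <- list()
  onts[[doc]] <- list(body = paste(ont_lines, collapse = "\n"),
                      media_type = MEDIA_N3)

  hosts <- list()
  for (i in seq_len(k)) {
    d <- service_description(
      name = sprintf("chain step %d", i),
      endpoint = paste0(base, "/s", i),
      input_class = cls_in(i),
      output_class = cls_out(i),
      authority = "example.org"
    )
    annotate <- local({
      p_i <- prop(i)
      step <- i
      function(input, root, params) {
        rdf_graph(iri(root), iri(p_i), iri(paste0(root, "/v", step)))
      }
    })
    hosts[[sprintf("s%d", i)]] <- service_host(
      sadi_service(d, annotate, mode = mode))
  }

  root <- paste0(base, "/data#1")
  seed_graph <- rdf_graph(iri(root), iri(prop(0L)), lit("seed"))
  vars <- sprintf("?v%d", seq_len(k))
  query <- paste0(
    "SELECT ", paste(vars, collapse = " "), " WHERE {\n",
    paste(sprintf("  <%s> <%s> %s .", root, vapply(seq_len(k), prop, character(1)), vars),
          collapse = "\n"),
    "\n}"
  )
  expected <- stats::setNames(
    vapply(seq_len(k), function(i) iri(paste0(root, "/v", i)), character(1)),
    vars
  )
  list(catalogue = fixture_catalogue(hosts, onts), seed_graph = seed_graph,
       root = root, query = query, expected = expected)
}

#' Generate labelled matchmaking cases
#'
#' Produces reproducible `(graph, class, ontology, expected)` cases spanning
#' every supported restriction kind, with positives and negatives balanced by
#' construction (labels alternate). Satisfied restrictions are planted with
#' conforming values; violated ones with missing, mistyped or undersized
#' value sets. With `restriction_depth` 2, half the classes also inherit a
#' restriction from a named superclass.
#'
#' @param spec a [synthetic_spec()]; `n_services` is read as the number of
#'   cases per restriction kind
#' @return list of cases: `list(graph =, class =, ontology =, expected =)`
#' @export
generate_matchmaking_cases <- function(spec) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  kinds <- c("someValuesFrom", "allValuesFrom", "minCardinality", "hasValue")
  base <- sprintf("http://example.org/mm%d", spec$seed)
  props <- sprintf("%s/prop%d", base, seq_len(spec$property_pool_size))
  node <- paste0(base, "/node")
  filler_cls_iri <- paste0(base, "/onto.owl#Filler")
  filler_prop <- paste0(base, "/fillerProp")

  cases <- list()
  idx <- 0L
  for (kind in kinds) {
    for (j in seq_len(spec$n_services)) {
      idx <- idx + 1L
      expected <- idx %% 2L == 0L
      p <- sample(props, 1L)
      g <- rdf_graph()
      restriction <- NULL
      filler_defs <- list()

      if (kind == "someValuesFrom") {
        use_class_filler <- stats::runif(1) < 0.5
        if (use_class_filler) {
          restriction <- owl_restriction(p, "someValuesFrom", filler = filler_cls_iri)
          filler_defs[[filler_cls_iri]] <- owl_class(
            filler_cls_iri,
            list(owl_restriction(filler_prop, "minCardinality", min_count = 1L)))
          v <- iri(paste0(base, "/val", j))
          if (expected) {
            if (stats::runif(1) < 0.5) {
              g <- graph_add(g, iri(node), iri(p), v)
              g <- graph_add(g, v, iri(RDF$type), iri(filler_cls_iri))
            } else {  # structural membership, no explicit type
              g <- graph_add(g, iri(node), iri(p), v)
              g <- graph_add(g, v, iri(filler_prop), lit("x"))
            }
          } else if (stats::runif(1) < 0.5) {
            g <- graph_add(g, iri(node), iri(p), v)  # value in no way a Filler
          }
        } else {
          restriction <- owl_restriction(p, "someValuesFrom", filler = XSD$string)
          if (expected) {
            g <- graph_add(g, iri(node), iri(p), lit(sprintf("v%d", j)))
          } else if (stats::runif(1) < 0.5) {
            g <- graph_add(g, iri(node), iri(p), iri(paste0(base, "/notlit")))
          }
        }
      } else if (kind == "allValuesFrom") {
        restriction <- owl_restriction(p, "allValuesFrom", filler = XSD$string)
        n_vals <- sample(0:3, 1L)
        if (expected) {
          for (v in seq_len(n_vals)) {
            g <- graph_add(g, iri(node), iri(p), lit(sprintf("ok%d", v)))
          }
        } else {
          for (v in seq_len(max(n_vals, 0L))) {
            g <- graph_add(g, iri(node), iri(p), lit(sprintf("ok%d", v)))
          }
          g <- graph_add(g, iri(node), iri(p), iri(paste0(base, "/bad")))
        }
      } else if (kind == "minCardinality") {
        m <- sample(1:3, 1L)
        restriction <- owl_restriction(p, "minCardinality", min_count = m)
        n_vals <- if (expected) m + sample(0:1, 1L) else m - 1L
        for (v in seq_len(n_vals)) {
          g <- graph_add(g, iri(node), iri(p), lit(sprintf("c%d", v)))
        }
      } else {
        tok <- lit(sprintf("tok%d", j))
        restriction <- owl_restriction(p, "hasValue", filler = tok)
        if (expected) {
          g <- graph_add(g, iri(node), iri(p), tok)
        } else if (stats::runif(1) < 0.5) {
          g <- graph_add(g, iri(node), iri(p), lit(sprintf("other%d", j)))
        }
      }

      # noise triples on unrelated properties never affect the label
      noise_props <- sample(setdiff(props, p), sample(0:2, 1L))
      for (np in noise_props) {
        g <- graph_add(g, iri(node), iri(np), lit("noise"))
      }

      cls_iri <- sprintf("%s/onto.owl#C%d", base, idx)
      restrictions <- list(restriction)
      supers <- character(0)
      classes <- filler_defs
      if (spec$restriction_depth == 2L && idx %% 3L == 0L) {
        sup_iri <- sprintf("%s/onto.owl#S%d", base, idx)
        sup_p <- sample(setdiff(props, c(p, noise_props)), 1L)
        sup_ok <- expected  # superclass restriction shares the case label
        classes[[sup_iri]] <- owl_class(
          sup_iri, list(owl_restriction(sup_p, "minCardinality", min_count = 1L)))
        supers <- sup_iri
        if (sup_ok) g <- graph_add(g, iri(node), iri(sup_p), lit("sup"))
        # if !sup_ok the superclass restriction is unmet, matching expected=FALSE
      }
      cls <- owl_class(cls_iri, restrictions, supers)
      classes[[cls_iri]] <- cls
      cases[[idx]] <- list(
        graph = g, node = node, class = cls,
        ontology = ontology(classes), expected = expected
      )
    }
  }
  cases
}
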