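hello_ont <- function() {
  cat <- build_hello_catalogue()
  load_ontology(cat$ontologies[[HELLO$ontology_doc]]$body)
}

test_that("the hello ontology loads with the documented class shapes", {
  ont <- hello_ont()
  ni <- ont$classes[[HELLO$NamedIndividual]]
  expect_length(ni$restrictions, 1L)
  expect_equal(ni$restrictions[[1]]$kind, "minCardinality")
  expect_equal(ni$restrictions[[1]]$property, "http://xmlns.com/foaf/0.1/name")
  expect_equal(ni$restrictions[[1]]$min_count, 1L)

  gi <- ont$classes[[HELLO$GreetedIndividual]]
  expect_length(gi$restrictions, 1L)
  expect_equal(gi$restrictions[[1]]$kind, "someValuesFrom")
  expect_equal(gi$restrictions[[1]]$property, HELLO$greeting)
  expect_true(HELLO$greeting %in% ont$datatype_properties)
})

test_that("nested intersections flatten and restriction-free classes load", {
  doc <- paste0(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .\n",
    "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .\n",
    "<http://x.org/o#Free> a owl:Class .\n",
    "<http://x.org/o#Three> a owl:Class ; owl:intersectionOf (\n",
    "  [ a owl:Restriction ; owl:onProperty <http://x.org/p1> ; owl:someValuesFrom xsd:string ]\n",
    "  [ a owl:Restriction ; owl:onProperty <http://x.org/p2> ; owl:minCardinality \"2\"^^xsd:nonNegativeInteger ]\n",
    "  [ owl:intersectionOf ( [ a owl:Restriction ; owl:onProperty <http://x.org/p3> ;\n",
    "      owl:hasValue \"fixed\" ] ) ]\n",
    ") ."
  )
  ont <- load_ontology(doc)
  expect_length(ont$classes[["http://x.org/o#Free"]]$restrictions, 0L)
  three <- ont$classes[["http://x.org/o#Three"]]
  expect_length(three$restrictions, 3L)
  expect_setequal(vapply(three$restrictions, `[[`, character(1), "property"),
                  c("http://x.org/p1", "http://x.org/p2", "http://x.org/p3"))
  # a restriction-free class matches any node at all
  chk <- satisfies(rdf_graph(), "http://x.org/anything",
                   ont$classes[["http://x.org/o#Free"]], ont)
  expect_true(chk$satisfied)
})

test_that("unsupported constructs warn and are excluded, never silently dropped", {
  doc <- paste0(
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .\n",
    "<http://x.org/o#U> a owl:Class ; rdfs:subClassOf [\n",
    "  owl:unionOf ( <http://x.org/o#A> <http://x.org/o#B> ) ] .\n",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .\n"
  )
  # reorder prefix before use
  doc <- paste0("@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .\n", doc)
  expect_warning(ont <- load_ontology(doc), class = "sadi_owl_warning")
  expect_length(ont$classes[["http://x.org/o#U"]]$restrictions, 0L)
})

test_that("hello input satisfies NamedIndividual; bare nodes do not", {
  ont <- hello_ont()
  ni <- ont$classes[[HELLO$NamedIndividual]]
  g <- hello_input_graph()
  expect_true(satisfies(g, HELLO$input_root, ni, ont)$satisfied)

  chk <- satisfies(rdf_graph(), "http://example.org/empty", ni, ont)
  expect_false(chk$satisfied)
  expect_length(chk$unmet, 1L)
  expect_equal(chk$unmet[[1]]$property, "http://xmlns.com/foaf/0.1/name")
})

test_that("explicit typing alone never substitutes for the restrictions", {
  ont <- hello_ont()
  ni <- ont$classes[[HELLO$NamedIndividual]]
  mistyped <- rdf_graph(
    iri("http://example.org/fraud"),
    iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"),
    iri(HELLO$NamedIndividual)
  )
  expect_false(satisfies(mistyped, "http://example.org/fraud", ni, ont)$satisfied)
})

test_that("cardinality counts distinct RDF terms", {
  ont <- ontology(list(owl_class(
    "http://x.org/o#C2",
    list(owl_restriction("http://x.org/p", "minCardinality", min_count = 2L))
  )))
  cls <- ont$classes[["http://x.org/o#C2"]]
  two_distinct <- rdf_graph(
    s = rep(iri("http://x.org/n"), 2),
    p = rep(iri("http://x.org/p"), 2),
    o = c(lit("a"), lit("b"))
  )
  expect_true(satisfies(two_distinct, "http://x.org/n", cls, ont)$satisfied)
  duplicated_term <- rdf_graph(
    s = rep(iri("http://x.org/n"), 2),
    p = rep(iri("http://x.org/p"), 2),
    o = c(lit("a"), lit("a"))
  )
  expect_false(satisfies(duplicated_term, "http://x.org/n", cls, ont)$satisfied)
})

test_that("a filler class missing from the ontology is an error, not a pass", {
  ont <- ontology(list(owl_class(
    "http://x.org/o#C",
    list(owl_restriction("http://x.org/p", "someValuesFrom",
                         filler = "http://x.org/o#Ghost"))
  )))
  g <- rdf_graph(iri("http://x.org/n"), iri("http://x.org/p"), iri("http://x.org/v"))
  expect_error(satisfies(g, "http://x.org/n", ont$classes[[1]], ont),
               class = "sadi_unknown_class_error")
})

test_that("satisfaction agrees with the brute-force oracle on generated cases", {
  cases <- generate_matchmaking_cases(synthetic_spec(seed = 11L, n_services = 30L))
  for (cs in cases) {
    mine <- satisfies(cs$graph, cs$node, cs$class, cs$ontology)$satisfied
    expect_identical(mine, cs$expected)
    expect_identical(mine, oracle_satisfies(cs$graph, cs$node, cs$class, cs$ontology))
  }
})

test_that("satisfaction is monotone under graph growth (allValuesFrom excluded)", {
  cases <- generate_matchmaking_cases(synthetic_spec(seed = 5L, n_services = 15L))
  set.seed(99)
  for (cs in cases) {
    has_avf <- any(vapply(cs$class$restrictions, `[[`, character(1), "kind") ==
                     "allValuesFrom")
    if (has_avf || !cs$expected) next
    grown <- graph_union(cs$graph, random_graph(10L))
    expect_true(satisfies(grown, cs$node, cs$class, cs$ontology)$satisfied)
  }
})

test_that("attached properties are the output-minus-input restricted set", {
  cat <- build_hello_catalogue()
  ont <- load_ontology(cat$ontologies[[HELLO$ontology_doc]]$body)
  expect_equal(
    attached_properties(ont$classes[[HELLO$NamedIndividual]],
                        ont$classes[[HELLO$GreetedIndividual]], ont),
    HELLO$greeting
  )
  # identical classes attach nothing; set-difference oracle on built classes
  mk <- function(props) {
    owl_class("http://x.org/o#T", lapply(props, function(p) {
      owl_restriction(p, "someValuesFrom", filler = "http://www.w3.org/2002/07/owl#Thing")
    }))
  }
  ont0 <- ontology(list())
  abc <- sprintf("http://x.org/%s", c("a", "b", "c"))
  expect_equal(attached_properties(mk(abc[2]), mk(abc), ont0), sort(abc[c(1, 3)]))
  for (cls in list(mk(character(0)), mk(abc),
                   ont$classes[[HELLO$NamedIndividual]])) {
    expect_length(attached_properties(cls, cls, ont), 0L)
  }
})

test_that("inherited restrictions participate through named superclasses", {
  sup <- owl_class("http://x.org/o#Sup",
                   list(owl_restriction("http://x.org/ps", "minCardinality",
                                        min_count = 1L)))
  sub <- owl_class("http://x.org/o#Sub",
                   list(owl_restriction("http://x.org/pb", "minCardinality",
                                        min_count = 1L)),
                   superclasses = "http://x.org/o#Sup")
  ont <- ontology(list(sup, sub))
  only_own <- rdf_graph(iri("http://x.org/n"), iri("http://x.org/pb"), lit("x"))
  expect_false(satisfies(only_own, "http://x.org/n", sub, ont)$satisfied)
  both <- graph_add(only_own, iri("http://x.org/n"), iri("http://x.org/ps"), lit("y"))
  expect_true(satisfies(both, "http://x.org/n", sub, ont)$satisfied)
})
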