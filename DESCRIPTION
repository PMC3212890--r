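Package: sadi
Title: Semantic Web Services by Graph Decoration: Hosting, Discovery and
    Query-Driven Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A working stack for the semantic web service design pattern in
    which services consume and produce typed RDF instances of OWL classes and
    act as annotators: the URI of each input individual is preserved and the
    service attaches new predicate/value pairs until the individual satisfies
    the output class. Provides an RDF graph substrate (RDF/XML and N3
    serializations, typed-root extraction, pass-by-reference resolution),
    structural classification of individuals against OWL property
    restrictions, a service-description document model, a service-hosting
    kernel implementing the synchronous and asynchronous (202/302/Retry-After
    polling) invocation protocol with multiplexing and control parameters, a
    generic client, a property-indexed discovery registry, and a resolver
    that answers basic-graph-pattern queries by discovering and invoking
    services to dynamically populate a query-specific triplestore.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
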