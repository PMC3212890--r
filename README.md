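# sadi

Semantic web services as graph decorators: a hosting kernel, client,
discovery registry and query resolver for the design pattern in which every
service consumes and produces typed RDF individuals and acts as an
*annotator* — it attaches new predicate/value pairs to its input node and
returns it with the **same URI**, now an instance of the service's output
OWL class.

The package is aimed at anyone building or studying semantic data
integration for the life sciences: the pattern exists because
bioinformatics services are overwhelmingly stateless, atomic and
transformative, so a service's whole meaning can be captured by the
*relationship* it attaches (a gene *encodes* a protein, a pathway *has
participant* a gene) rather than by its algorithm.

## The model in brief

A service interface is a pair of OWL-DL classes. The input class's property
restrictions state what a node must carry to qualify; the output class's
restrictions state what the service adds. For a service with input class
`I` and output class `O`, its semantic signature is the **attached
property** set

```
attached(service) = properties restricted in O (incl. inherited)
                  \ properties restricted in I (incl. inherited)
```

which is what the registry indexes and what discovery queries ("what could
I learn about this node?") run against. Instance qualification is decided
*structurally* — each restriction (`someValuesFrom`, `allValuesFrom`,
`minCardinality` over distinct terms, `hasValue`) is checked against
asserted triples, with no DL entailment — so data modelled under a foreign
ontology qualifies whenever it carries the required properties.

On the wire everything is plain HTTP: `GET` endpoint → RDF interface
document; `POST` of an RDF graph (RDF/XML or N3, any number of input
roots) → decorated graph. Asynchronous services answer 202 with a per-root
`rdfs:isDefinedBy` poll IRI and `Retry-After`; polling yields 302 while
pending, then 200 with a response identical in shape to the synchronous
one. The bundled resolver answers basic-graph-pattern `SELECT` queries by
intercepting bound predicates, invoking the services that attach them, and
accumulating a query-specific triplestore with per-triple provenance.

## Worked example

```r
library(sadi)

cat_ <- build_hello_catalogue(n_decoys = 2)   # hello service + 2 decoys
tr   <- in_memory_transport(cat_)

# 1. GET the interface document
fetch_description("http://sadiframework.org/examples/hello", tr)
#> <service 'Hello' at http://sadiframework.org/examples/hello>
#>   input:  http://sadiframework.org/examples/hello.owl#NamedIndividual
#>   output: http://sadiframework.org/examples/hello.owl#GreetedIndividual

# 2. POST an individual carrying foaf:name "Guy Incognito"
res <- invoke("http://sadiframework.org/examples/hello", hello_input_graph(), tr)
res$per_root[["http://sadiframework.org/examples/hello-input.rdf#1"]]
#> <rdf_graph: 2 triples>
#>   <http://sadiframework.org/examples/hello-input.rdf#1> <http://sadiframework.org/examples/hello.owl#greeting> "Hello, Guy Incognito!" .
#>   <http://sadiframework.org/examples/hello-input.rdf#1> <http://www.w3.org/1999/02/22-rdf-syntax-ns#type> <http://sadiframework.org/examples/hello.owl#GreetedIndividual> .
```

The root URI is unchanged, the node is now typed with the output class, and
the decoration is the `greeting` property the output class promised. The
same two facts drive discovery and querying:

```r
reg <- sadi_registry()
for (h in cat_$hosts)
  register(reg, h$svc$description$endpoint, tr, catalogue_loader(cat_))

# "what could services tell me about this node?" -- only hello matches,
# and what it offers is the greeting property
names(property_menu(reg, hello_input_graph(),
                    "http://sadiframework.org/examples/hello-input.rdf#1"))
#> [1] "http://sadiframework.org/examples/hello.owl#greeting"

# answer a query by invoking whatever services attach the queried predicate
q <- 'PREFIX hello: <http://sadiframework.org/examples/hello.owl#>
      SELECT ?g WHERE {
        <http://sadiframework.org/examples/hello-input.rdf#1> hello:greeting ?g }'
resolve(q, reg, hello_input_graph(), tr)$solutions
#> [[1]]
#>                         ?g
#> "\"Hello, Guy Incognito!\""
```

The query answer — one binding, the literal `"Hello, Guy Incognito!"` — was
not in any store when the query was posed; the resolver discovered the hello
service by the `greeting` predicate, invoked it on the seed node, and
evaluated the pattern over the graph it had just built.

A thin command-line front end for the resolver is available as
`Rscript scripts/sadi-query.R --query q.rq --seed-data seed.n3`.

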