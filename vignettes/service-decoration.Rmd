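---
title: "Semantic web services as graph decorators: the model behind sadi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic web services as graph decorators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadi)
```

## The design pattern

This package implements a web-service design pattern for semantic data
integration, of the kind used to interconnect bioinformatics resources. Its
two load-bearing commitments are:

1. **Service inputs and outputs are typed RDF individuals of OWL classes.** A
   service's interface is a pair of OWL class definitions: the *input class*
   whose property restrictions state what data the service requires, and the
   *output class* whose restrictions state what it will add.
2. **The URI of the output individual is the URI of the input individual.**
   Every service is an *annotator*: it attaches new predicate/value pairs to
   the node it was given, and never renames it.

Everything else in the stack follows from these two constraints. Because
outputs are decorations of inputs, the mapping between them in a batched
("multiplexed") invocation is recoverable by URI identity alone, with no
message scaffold. Because the added predicates are declared in the output
class, the *function* of a service is the set of properties it attaches —
which is an indexable, queryable object, and the basis of discovery.

The protocol is plain HTTP. `GET` on an endpoint returns the service
interface document; `POST` of an RDF document (never FORM encoding) invokes
it; standard response codes do the rest (200 complete, 202 accepted with
polling, 302 pending, 400/404/500 faults).

## The messaging kernel

An invocation body is an RDF graph in one of two serializations, declared by
`Content-Type`: `application/rdf+xml` or `text/rdf+n3`. The provider does no
reasoning on input: it extracts the *typed roots* — IRI-named subjects
carrying `rdf:type` of the input class — and runs its annotation function
once per root. Roots must be IRIs (a blank node cannot be preserved or
re-resolved); blank subjects typed with the input class are diagnosed and
skipped rather than silently processed.

```{r}
host <- service_host(build_hello())
body <- serialize_graph(hello_input_graph(), "application/rdf+xml")
resp <- handle_post(host, body, "application/rdf+xml")
out <- parse_graph(resp$body, resp$content_type)
graph_match(out, p = iri(HELLO$greeting))
```

Graph equality throughout the package — and throughout its tests — is RDF
graph isomorphism (equality up to a bijection of blank-node labels),
computed by colour refinement with a bounded backtracking fallback. Response
concatenation order is deliberately unspecified, so nothing may compare
serialized bytes.

### Asynchronous services

A long-running service answers the POST immediately with status 202. In the
202 body each input root is decorated with `rdfs:isDefinedBy` pointing to a
temporary per-root poll IRI; dereferencing that IRI yields 302 (with
`Location` and `Retry-After`) while pending and 200 with that root's output
graph when complete — at which point the response is indistinguishable from
a synchronous one. The client in this package follows the whole dance
transparently, so callers never branch on the service's mode.

Within a single R process, "computation proceeds after the response" is
realized by deferred execution: the task is registered at POST time and
evaluated at poll time, after a configurable number of pending polls
(`async_delay_polls`, default 1) that exercise the 302 path. This models a
long-running job faithfully at the protocol level while keeping the host
deterministic and testable.

The 202 stub also re-types each root with the output class. The protocol
would work either way; typing the stub makes the 202 body a well-formed
(if incomplete) output-class instance, and the choice is reversible without
touching clients, which key on `rdfs:isDefinedBy` only.

### Multiplexing and partial failure

A body may carry any number of typed roots; the response is the
concatenation of independent per-root runs, so hosting is trivially
parallelizable and the multiplexed response is isomorphic to the union of
single-root responses. When a provider's annotation function raises for one
root, that root is marked with a `serviceError` diagnostic triple and the
surviving roots are returned normally; the response status is 500 only when
*every* root failed. A single HTTP status cannot express a partial outcome,
and discarding healthy results because a sibling failed would contradict the
independence of multiplexed runs.

### Control parameters

Because the POST is non-parameterized, service configuration travels *inside*
the invocation graph: a node typed with the service's declared parameter
class, carrying property values. Absence means defaults; two parameter nodes
are ambiguous and rejected. The parameter class is advertised in the
description document under a `secondaryParameter` node.

### Pass-by-reference

Large data need not travel inline: a node annotated with
`rdfs:isDefinedBy <url>` promises that the URL resolves to its missing
triples. `resolve_by_reference()` merges referenced documents with a
default recursion depth of 1 — the protocol gives no recursion rule, and one
level covers the publish-a-pointer idiom while keeping retrieval bounded;
deeper chains are opt-in via `depth_limit`. Fetch failures degrade to a
warning and a partial merge; cycles terminate via a visited set.

## Structural classification

Matchmaking — "does this node qualify as input to that service?" — is decided
*structurally*: each property restriction is checked directly against the
asserted triples, with no description-logic entailment. This keeps providers
implementable in environments without a reasoner, makes the decision
procedure transparent, and is the semantics the discovery behaviour needs. A
hook for a full reasoner would slot in behind `satisfies()` without touching
the call sites.

The supported OWL subset is `owl:Restriction` with `someValuesFrom`,
`allValuesFrom`, `minCardinality` and `hasValue`, combined through
`owl:intersectionOf` and `rdfs:subClassOf` to named classes. This covers
every construct the reference examples and the discovery semantics require.
`unionOf`/`complementOf` produce a load-time warning and are excluded from
matchmaking — never silently dropped. The precise rules:

* `someValuesFrom C`: some value is explicitly typed `C` **or** itself
  structurally satisfies `C` (recursion guarded against cycles); for a
  datatype filler, some literal value of that datatype (plain literals count
  as strings).
* `allValuesFrom C`: every present value conforms; vacuously true when the
  property is absent. This is the one non-monotone construct: a growing
  graph can break it, so it is excluded from the monotonicity property test
  and covered by the oracle suite instead.
* `minCardinality n`: at least `n` *distinct RDF terms* — two syntactically
  different literals are two values, duplicates are one.
* `hasValue t`: the exact term is present.

An explicit `rdf:type` assertion of the class being checked is deliberately
**not** a shortcut: restrictions are always verified, so a mistyped node
cannot smuggle itself past validation. A filler class missing from the
ontology is an error naming the IRI, never a silent pass.

The input class of the bundled hello fixture encodes "at least one name" as
`minCardinality 1` on `foaf:name`. A `someValuesFrom` on a string-valued
name is also expressible and also supported; the cardinality form was chosen
for the fixture because it states "at least one predicate of this kind"
without constraining the value space, and the test suite exercises both
forms through the generated matchmaking corpus.

## Discovery and the attached-property index

A service's *attached properties* are those restricted in its output class
(inherited restrictions included — superclass restrictions are part of what
an instance must carry, so the registry indexes them too) minus those
restricted in its input class. The registry stores one record per endpoint
and answers three queries: services consuming a given node, services
attaching a given predicate, and the *property menu* — for a selected node,
every property some matching service could attach, mapped to those services.

Node-to-service matching defaults to the structural path (with the by-type
lookup as a union fast path): a node produced under a different ontological
framework qualifies as input so long as it carries the required properties,
which is precisely the interoperability the pattern exists for. Dead
services (a liveness probe is included) are retained but excluded from
discovery by default.

## Query-driven composition

The resolver answers conjunctive basic-graph-pattern `SELECT` queries by
treating bound predicates as discovery keys: for each pattern it finds the
services that attach that predicate, invokes them on the store's eligible
nodes (multiplexed), merges the decorated outputs into a query-specific
working store with per-triple provenance, and finally evaluates the pattern
conjunction over the accumulated store. The database needed to answer the
query is thus built *by* asking it.

Design choices where the behaviour was genuinely open:

* **SPARQL subset.** `SELECT` over one conjunctive BGP; `OPTIONAL`, `FILTER`,
  `UNION` and friends raise explicit unsupported-feature errors. The
  interception mechanism — predicate to services to invocation — is separable
  from any reasoning engine, and structural matching replaces DL reasoning
  during candidate selection.
* **Plan order.** A pattern whose subject variable is produced (as object) by
  an earlier serviced pattern runs after its producer; ties keep textual
  order, so plans are deterministic. Unservable patterns (bound predicate, no
  service) never abort resolution; they only constrain evaluation.
* **Fixed point.** Each (service, input node) pair is invoked at most once
  per resolution, which bounds work and terminates cycles.
* **Multiple providers.** When several services attach the queried predicate,
  all are invoked (within `limits`) and results unioned. Preferring one
  provider would require quality metadata the description document does not
  carry; the union is the conservative choice and is documented as a
  divergence point.
* **Limits.** `max_invocations` (default 100) and `max_inputs_per_service`
  (default 100) bound a resolution; exhaustion flags `limit_hit` and returns
  partial results rather than failing.

## The synthetic generators

`build_chain()` emulates the canonical composition scenario: a pipeline in
which each service's attached property is exactly the next service's input
requirement (a pathway–participant–encodes style chain), with closed-form
expected answers so end-to-end resolution is checkable against the generator
itself. `generate_matchmaking_cases()` produces labelled
(graph, class, ontology) cases spanning every supported restriction kind,
with labels alternating by construction (so positives sit at 50%) and
distractor triples that never affect the label.

What these generators deliberately do **not** model: network latency and
partial connectivity, ontologies with modelling errors or contradictory
axioms, very large stores (the in-memory graph table is quadratic-unfriendly
beyond ~10⁵ triples), OWL constructs outside the subset, and adversarial
serializations. Passing tests therefore demonstrate protocol and
matchmaking correctness under clean conditions, not robustness against
malformed third-party data.

Problem sizes in the checks: serialization round-trips use 30 random
50-triple graphs per dialect; the matchmaking agreement suite uses 1000
generated cases against an independent brute-force checker; discovery
index-consistency uses 100 random catalogues; resolver-versus-pipeline uses
chains of length 2–4. All sizes are the package's own choices for a suite
that a maintainer re-runs on every change.

## Numerical and protocol constants

* Media types: `application/rdf+xml`, `text/rdf+n3`; anything else is a
  distinct protocol error (the dialects are fixed by the pattern; these are
  their conventional type strings).
* `Retry-After`: 5 s default (the header is mandated; its value is not).
* Completed async tasks are retrievable for 1 h, then 404.
* Client poll budget: 60 polls per root, honouring `Retry-After`, with the
  waiting primitive injectable so in-process tests complete immediately.
* Extracted roots are returned in lexicographic order — no order is
  semantically meaningful, and determinism makes behaviour reproducible.
* Extra input triples unrelated to any root are readable by the annotation
  function but never echoed into the output, which keeps the synchronous and
  asynchronous response shapes identical and checkable.

## Known limitations

* Structural classification is weaker than DL entailment: equivalences,
  property hierarchies and inverse properties are invisible to it.
* The transport contract is in-memory; the handlers implement the full HTTP
  semantics (statuses, headers, content negotiation) and any socket layer
  can be bolted onto `function(req) -> response`, but none ships here.
* Output-to-input mapping follows outgoing edges only; a service that
  decorates by *inverse* properties would need its outputs mapped by other
  means.
* The N3 reader covers the Turtle-compatible subset used on this wire, not
  full N3 (no paths, rules, or quoted graphs); the RDF/XML reader does not
  support `rdf:ID`/`xml:base` relative naming, since the pattern requires
  absolute, resolvable IRIs throughout.
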