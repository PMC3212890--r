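test_that("the query parser handles the supported subset", {
  q <- parse_query(hello_greeting_query)
  expect_equal(q$select, "?greeting")
  expect_length(q$patterns, 1L)
  expect_equal(q$patterns[[1]]$s,
               iri("http://sadiframework.org/examples/hello-input.rdf#1"))
  expect_equal(q$patterns[[1]]$p, iri(HELLO$greeting))
  expect_equal(q$patterns[[1]]$o, "?greeting")

  q2 <- parse_query(paste0(
    "PREFIX ex: <http://example.org/>\n",
    "SELECT ?b ?c WHERE { ?a ex:p1 ?b . ?b a ex:Cls . ?b ex:p2 \"lit\" . ",
    "?b ex:p3 ?c }"))
  expect_length(q2$patterns, 4L)
  expect_equal(q2$patterns[[2]]$p, iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"))
  expect_equal(q2$patterns[[3]]$o, lit("lit"))
})

test_that("features outside the subset are explicit unsupported errors", {
  for (bad in c(
    "SELECT ?x WHERE { ?x ?p ?y OPTIONAL { ?y ?q ?z } }",
    "SELECT ?x WHERE { ?x ?p ?y FILTER(?y > 3) }",
    "SELECT ?x WHERE { { ?x ?p ?y } UNION { ?x ?q ?y } }"
  )) {
    expect_error(parse_query(bad), class = "sadi_unsupported_query_error")
  }
  expect_error(parse_query("ASK { ?x ?p ?y }"),
               class = "sadi_unsupported_query_error")
})

test_that("planning binds serviced patterns and orders by production", {
  cat <- build_hello_catalogue(n_decoys = 2L)
  tr <- in_memory_transport(cat)
  loader <- catalogue_loader(cat)
  reg <- sadi_registry()
  for (h in cat$hosts) register(reg, h$svc$description$endpoint, tr, loader)

  q <- parse_query(hello_greeting_query)
  pl <- plan(q$patterns, reg)
  expect_length(pl$bindings[[1]], 1L)
  expect_equal(pl$bindings[[1]][[1]]$description$endpoint, HELLO$endpoint)
  expect_false(pl$unservable[1])

  # an unservable predicate is recorded but does not abort planning
  q2 <- parse_query(paste0("SELECT ?x WHERE { ?x <http://example.org/nosvc> ?y . ",
                           "?x ?anyp ?z }"))
  pl2 <- plan(q2$patterns, reg)
  expect_true(pl2$unservable[1])
  expect_false(pl2$unservable[2])  # variable predicate: store-only, not unservable

  # chain: the pattern producing a subject precedes the pattern consuming it
  ch <- build_chain(synthetic_spec(chain_length = 2L, seed = 3L))
  trc <- in_memory_transport(ch$catalogue)
  regc <- sadi_registry()
  for (h in ch$catalogue$hosts) {
    register(regc, h$svc$description$endpoint, trc, catalogue_loader(ch$catalogue))
  }
  qc <- parse_query(paste0(
    "SELECT ?y WHERE { ?v <http://example.org/chain3/p2> ?y . ",
    "<http://example.org/chain3/data#1> <http://example.org/chain3/p1> ?v }"))
  plc <- plan(qc$patterns, regc)
  expect_equal(plc$order, c(2L, 1L))
})

test_that("the greeting query resolves to the single expected binding", {
  cat <- build_hello_catalogue(n_decoys = 3L)
  tr <- in_memory_transport(cat)
  loader <- catalogue_loader(cat)
  reg <- sadi_registry()
  for (h in cat$hosts) register(reg, h$svc$description$endpoint, tr, loader)

  ans <- resolve(hello_greeting_query, reg, hello_input_graph(), tr,
                 policy = no_sleep)
  expect_length(ans$solutions, 1L)
  expect_equal(unname(ans$solutions[[1]]["?greeting"]), lit("Hello, Guy Incognito!"))
})

test_that("with no usable services the store stays the seed", {
  reg <- sadi_registry()
  seed <- hello_input_graph()
  ans <- resolve("SELECT ?g WHERE { ?x <http://example.org/absent> ?g }",
                 reg, seed, function(req) stop("no network"), policy = no_sleep)
  expect_length(ans$solutions, 0L)
  expect_true(graph_isomorphic(ans$store$graph, seed))
  expect_true(all(ans$store$provenance == "seed"))
})

test_that("resolution equals the hand-wired client pipeline on chains", {
  for (len in 2:4) {
    ch <- build_chain(synthetic_spec(chain_length = len, seed = 20L + len))
    tr <- in_memory_transport(ch$catalogue)
    loader <- catalogue_loader(ch$catalogue)
    reg <- sadi_registry()
    for (h in ch$catalogue$hosts) {
      register(reg, h$svc$description$endpoint, tr, loader)
    }
    ans <- resolve(ch$query, reg, ch$seed_graph, tr, policy = no_sleep)

    # manual pipeline: invoke each chain service in order, merging outputs
    store <- ch$seed_graph
    for (i in seq_len(len)) {
      host <- ch$catalogue$hosts[[sprintf("s%d", i)]]
      d <- host$svc$description
      inv <- graph_add(store, iri(ch$root),
                       iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"),
                       iri(d$input_class))
      res <- invoke(d$endpoint, inv, tr, policy = no_sleep)
      store <- graph_union(store, res$merged)
    }
    q <- parse_query(ch$query)
    manual <- oracle_bgp(store, q$patterns, q$select)

    expect_length(ans$solutions, 1L)
    expect_setequal(
      vapply(ans$solutions, function(b) paste(b[q$select], collapse = "|"), character(1)),
      vapply(manual, function(b) paste(b[q$select], collapse = "|"), character(1)))
    expect_equal(ans$solutions[[1]][names(ch$expected)], ch$expected)
  }
})

test_that("seed-only queries reduce to plain BGP matching", {
  reg <- sadi_registry()
  set.seed(31)
  for (k in 1:10) {
    g <- random_graph(20L, n_blanks = 0L)
    q <- parse_query(paste0(
      "SELECT ?s ?o WHERE { ?s <http://example.org/p1> ?o . ",
      "?s <http://example.org/p2> ?w }"))
    ans <- resolve(q, reg, g, function(req) stop("offline"), policy = no_sleep)
    expected <- oracle_bgp(g, q$patterns, q$select)
    key <- function(b) paste(b["?s"], b["?o"])
    expect_setequal(vapply(ans$solutions, key, character(1)),
                    vapply(expected, key, character(1)))
  }
})

test_that("resolution is idempotent and provenance covers every new triple", {
  ch <- build_chain(synthetic_spec(chain_length = 3L, seed = 9L))
  tr <- in_memory_transport(ch$catalogue)
  loader <- catalogue_loader(ch$catalogue)
  reg <- sadi_registry()
  for (h in ch$catalogue$hosts) register(reg, h$svc$description$endpoint, tr, loader)

  a1 <- resolve(ch$query, reg, ch$seed_graph, tr, policy = no_sleep)
  a2 <- resolve(ch$query, reg, ch$seed_graph, tr, policy = no_sleep)
  expect_identical(a1$solutions, a2$solutions)
  expect_true(graph_isomorphic(a1$store$graph, a2$store$graph))

  df <- triples(a1$store$graph)
  keys <- paste(df$s, df$p, df$o)
  expect_true(all(keys %in% names(a1$store$provenance)))
  non_seed <- a1$store$provenance[a1$store$provenance != "seed"]
  endpoints <- vapply(registry_records(reg),
                      function(r) r$description$endpoint, character(1))
  expect_true(all(non_seed %in% endpoints))
  # store growth is monotone over the seed
  seed_df <- triples(ch$seed_graph)
  expect_true(all(paste(seed_df$s, seed_df$p, seed_df$o) %in% keys))
})

test_that("invocation limits truncate politely and flag the truncation", {
  ch <- build_chain(synthetic_spec(chain_length = 2L, seed = 13L))
  tr <- in_memory_transport(ch$catalogue)
  loader <- catalogue_loader(ch$catalogue)
  reg <- sadi_registry()
  for (h in ch$catalogue$hosts) register(reg, h$svc$description$endpoint, tr, loader)
  ans <- resolve(ch$query, reg, ch$seed_graph, tr, policy = no_sleep,
                 limits = list(max_invocations = 1L, max_inputs_per_service = 10L))
  expect_true(ans$limit_hit)
  expect_length(ans$solutions, 0L)  # second chain step never ran
})
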