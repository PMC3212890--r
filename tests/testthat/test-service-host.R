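fig_input_body <- function(...) {
  gs <- list(...)
  g <- Reduce(graph_union, gs)
  serialize_graph(g, "application/rdf+xml")
}

test_that("GET returns a stable, parseable interface document", {
  host <- service_host(build_hello())
  r1 <- handle_get(host)
  r2 <- handle_get(host)
  expect_equal(r1$status, 200L)
  expect_equal(r1$content_type, "application/rdf+xml")
  expect_identical(r1$body, r2$body)  # stateless
  expect_identical(parse_description(parse_graph(r1$body, r1$content_type)),
                   build_hello()$description)
})

test_that("a synchronous POST decorates the root and preserves its URI", {
  host <- service_host(build_hello())
  resp <- handle_post(host, fig_input_body(hello_input_graph()),
                      "application/rdf+xml")
  expect_equal(resp$status, 200L)
  out <- parse_graph(resp$body, resp$content_type)
  expect_equal(extract_typed_roots(out, HELLO$GreetedIndividual), HELLO$input_root)
  greet <- graph_match(out, s = iri(HELLO$input_root), p = iri(HELLO$greeting))
  expect_equal(lit_value(greet$o), "Hello, Guy Incognito!")
})

test_that("multiplexed invocation equals the union of single-root runs", {
  host <- service_host(build_hello())
  roots <- sprintf("http://example.org/people#%d", 1:3)
  singles <- lapply(seq_along(roots), function(i) {
    g <- hello_input_graph(name = sprintf("Person %d", i), root = roots[i])
    parse_graph(handle_post(host, fig_input_body(g), "application/rdf+xml")$body,
                "application/rdf+xml")
  })
  gs <- lapply(seq_along(roots), function(i) {
    hello_input_graph(name = sprintf("Person %d", i), root = roots[i])
  })
  multi <- parse_graph(
    handle_post(host, do.call(fig_input_body, gs), "application/rdf+xml")$body,
    "application/rdf+xml")
  expect_true(graph_isomorphic(multi, Reduce(graph_union, singles)))
  expect_setequal(extract_typed_roots(multi, HELLO$GreetedIndividual), roots)
})

test_that("client faults answer 400 with a useful diagnostic", {
  host <- service_host(build_hello())
  # unparseable body
  expect_equal(handle_post(host, "<broken", "application/rdf+xml")$status, 400L)
  # unsupported media type
  expect_equal(handle_post(host, "{}", "application/json")$status, 400L)
  # typed with the wrong class
  wrong <- rdf_graph(iri("http://example.org/x"),
                     iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"),
                     iri("http://example.org/OtherClass"))
  resp <- handle_post(host, serialize_graph(wrong, "application/rdf+xml"),
                      "application/rdf+xml")
  expect_equal(resp$status, 400L)
  expect_match(resp$body, HELLO$NamedIndividual, fixed = TRUE)
})

test_that("a failing root is diagnosed without harming its siblings", {
  d <- build_hello()$description
  fragile <- sadi_service(d, function(input, root, params) {
    if (grepl("bad", root)) stop("boom")
    nm <- graph_match(input, s = iri(root),
                      p = iri("http://xmlns.com/foaf/0.1/name"))$o
    rdf_graph(iri(root), iri(HELLO$greeting),
              lit(paste0("Hello, ", lit_value(nm[1]), "!")))
  })
  host <- service_host(fragile)
  good <- hello_input_graph(name = "Ada", root = "http://example.org/good")
  bad <- hello_input_graph(name = "Bob", root = "http://example.org/bad")

  resp <- handle_post(host, fig_input_body(good, bad), "application/rdf+xml")
  expect_equal(resp$status, 200L)  # partial success
  out <- parse_graph(resp$body, resp$content_type)
  expect_equal(
    lit_value(graph_match(out, s = iri("http://example.org/good"),
                          p = iri(HELLO$greeting))$o),
    "Hello, Ada!")
  diag <- graph_match(out, s = iri("http://example.org/bad"),
                      p = iri("http://sadiframework.org/ontology/service.owl#serviceError"))
  expect_equal(nrow(diag), 1L)

  all_bad <- handle_post(host, fig_input_body(bad), "application/rdf+xml")
  expect_equal(all_bad$status, 500L)
})

test_that("asynchronous POST returns per-root poll stubs and Retry-After", {
  host <- service_host(build_hello("async", async_delay_polls = 1L))
  roots <- sprintf("http://example.org/people#%d", 1:3)
  gs <- lapply(roots, function(r) hello_input_graph(root = r))
  resp <- handle_post(host, do.call(fig_input_body, gs), "application/rdf+xml")
  expect_equal(resp$status, 202L)
  expect_true(resp$headers[["Retry-After"]] >= 1)
  stub <- parse_graph(resp$body, resp$content_type)
  poll_iris <- vapply(roots, function(r) {
    hits <- graph_match(stub, s = iri(r),
                        p = iri("http://www.w3.org/2000/01/rdf-schema#isDefinedBy"))
    expect_equal(nrow(hits), 1L)
    hits$o
  }, character(1))
  expect_equal(length(unique(poll_iris)), 3L)
  # stubs re-type the root with the output class, data not yet attached
  expect_setequal(extract_typed_roots(stub, HELLO$GreetedIndividual), roots)
  expect_equal(nrow(graph_match(stub, p = iri(HELLO$greeting))), 0L)
})

test_that("polling answers 302 while pending, then the synchronous graph", {
  sync_host <- service_host(build_hello())
  async_host <- service_host(build_hello("async", async_delay_polls = 2L))
  body <- fig_input_body(hello_input_graph())
  resp <- handle_post(async_host, body, "application/rdf+xml")
  stub <- parse_graph(resp$body, resp$content_type)
  poll_iri <- graph_match(stub, s = iri(HELLO$input_root),
                          p = iri("http://www.w3.org/2000/01/rdf-schema#isDefinedBy"))$o
  task_id <- sub("^.*/task/", "", term_iri(poll_iri))

  p1 <- handle_poll(async_host, task_id)
  expect_equal(p1$status, 302L)
  expect_equal(p1$headers[["Location"]], term_iri(poll_iri))
  p2 <- handle_poll(async_host, task_id)
  expect_equal(p2$status, 302L)
  p3 <- handle_poll(async_host, task_id)
  expect_equal(p3$status, 200L)

  sync_graph <- parse_graph(
    handle_post(sync_host, body, "application/rdf+xml")$body, "application/rdf+xml")
  expect_true(graph_isomorphic(parse_graph(p3$body, p3$content_type), sync_graph))
  expect_equal(handle_poll(async_host, "no-such-task")$status, 404L)
})

test_that("a malformed async body registers no tasks", {
  host <- service_host(build_hello("async"))
  expect_equal(handle_post(host, "<broken", "application/rdf+xml")$status, 400L)
  expect_length(ls(host$tasks), 0L)
})

test_that("control parameters are extracted by their declared class", {
  pc <- "http://example.org/o#Config"
  limit_p <- "http://example.org/o#limit"
  g <- rdf_graph(
    s = c(iri("http://example.org/cfg"), iri("http://example.org/cfg")),
    p = c(iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"), iri(limit_p)),
    o = c(iri(pc), lit("5", datatype = "http://www.w3.org/2001/XMLSchema#integer"))
  )
  pi <- extract_parameters(g, pc)
  expect_equal(pi$node, "http://example.org/cfg")
  expect_equal(lit_value(pi$values[[limit_p]]), "5")

  expect_null(extract_parameters(rdf_graph(), pc))
  two <- graph_add(g, iri("http://example.org/cfg2"),
                   iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"), iri(pc))
  expect_error(extract_parameters(two, pc), class = "sadi_protocol_error")
})

test_that("a parameterized service reads its configuration from the message", {
  pc <- "http://example.org/o#Config"
  rep_p <- "http://example.org/o#repeat"
  d <- service_description(
    name = "Echo", endpoint = "http://example.org/echo",
    input_class = HELLO$NamedIndividual, output_class = HELLO$GreetedIndividual,
    parameter_class = pc
  )
  svc <- sadi_service(d, function(input, root, params) {
    n <- if (is.null(params)) 1L else as.integer(lit_value(params$values[[rep_p]]))
    g <- rdf_graph()
    for (k in seq_len(n)) {
      g <- graph_add(g, iri(root), iri(HELLO$greeting), lit(sprintf("hi %d", k)))
    }
    g
  })
  host <- service_host(svc)
  params_g <- rdf_graph(
    s = c(iri("http://example.org/cfg"), iri("http://example.org/cfg")),
    p = c(iri("http://www.w3.org/1999/02/22-rdf-syntax-ns#type"), iri(rep_p)),
    o = c(iri(pc), lit("3"))
  )
  resp <- handle_post(host, fig_input_body(hello_input_graph(), params_g),
                      "application/rdf+xml")
  out <- parse_graph(resp$body, resp$content_type)
  expect_equal(nrow(graph_match(out, p = iri(HELLO$greeting))), 3L)

  # without the params graph the service default applies
  resp0 <- handle_post(host, fig_input_body(hello_input_graph()), "application/rdf+xml")
  out0 <- parse_graph(resp0$body, resp0$content_type)
  expect_equal(nrow(graph_match(out0, p = iri(HELLO$greeting))), 1L)
})

test_that("repeat invocations of the same body are isomorphic", {
  host <- service_host(build_hello())
  body <- fig_input_body(hello_input_graph())
  g1 <- parse_graph(handle_post(host, body, "application/rdf+xml")$body,
                    "application/rdf+xml")
  g2 <- parse_graph(handle_post(host, body, "application/rdf+xml")$body,
                    "application/rdf+xml")
  expect_true(graph_isomorphic(g1, g2))
})

test_that("responses honour the requested serialization", {
  host <- service_host(build_hello())
  body <- fig_input_body(hello_input_graph())
  resp <- handle_post(host, body, "application/rdf+xml", accept = "text/rdf+n3")
  expect_equal(resp$content_type, "text/rdf+n3")
  out <- parse_graph(resp$body, "text/rdf+n3")
  expect_equal(extract_typed_roots(out, HELLO$GreetedIndividual), HELLO$input_root)
})
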