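#!/usr/bin/env Rscript

# Thin command-line front end for the resolver: answer a basic-graph-pattern
# query over a seed RDF document against the bundled fixture services.
#
# Usage:
#   Rscript scripts/sadi-query.R --query q.rq --seed-data seed.n3 \
#       [--format rdfxml|n3] [--out solutions.tsv] [--store-out store.n3]
#
# The registry is populated from the in-package hello catalogue (with
# decoys); point --chain-length at a synthetic chain instead to experiment
# with multi-service composition.

suppressPackageStartupMessages(library(sadi))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(query = NULL, seed_data = NULL, format = "n3",
            out = "", store_out = "", chain_length = 0L)
i <- 1L
while (i <= length(args)) {
  key <- args[i]
  val <- if (i < length(args)) args[i + 1L] else NULL
  switch(key,
    "--query" = { opt$query <- val },
    "--seed-data" = { opt$seed_data <- val },
    "--format" = { opt$format <- val },
    "--out" = { opt$out <- val },
    "--store-out" = { opt$store_out <- val },
    "--chain-length" = { opt$chain_length <- as.integer(val) },
    stop("unknown argument: ", key)
  )
  i <- i + 2L
}
if (is.null(opt$query) || is.null(opt$seed_data)) {
  stop("both --query and --seed-data are required")
}
media <- switch(opt$format, rdfxml = "application/rdf+xml", n3 = "text/rdf+n3",
                stop("--format must be rdfxml or n3"))

seed <- parse_graph(paste(readLines(opt$seed_data, warn = FALSE), collapse = "\n"),
                    media)
qtext <- paste(readLines(opt$query, warn = FALSE), collapse = "\n")

cat_ <- if (opt$chain_length >= 2L) {
  build_chain(synthetic_spec(chain_length = opt$chain_length, seed = 1L))$catalogue
} else {
  build_hello_catalogue(n_decoys = 3L)
}
tr <- in_memory_transport(cat_)
loader <- catalogue_loader(cat_)
reg <- sadi_registry()
for (h in cat_$hosts) register(reg, h$svc$description$endpoint, tr, loader)

ans <- resolve(qtext, reg, seed, tr,
               policy = poll_policy(sleep = function(s) invisible(NULL)))

q <- parse_query(qtext)
header <- paste(q$select, collapse = "\t")
rows <- vapply(ans$solutions, function(b) {
  paste(vapply(q$select, function(v) {
    if (v %in% names(b)) b[[v]] else ""
  }, character(1)), collapse = "\t")
}, character(1))
tsv <- c(header, rows)
if (nzchar(opt$out)) writeLines(tsv, opt$out) else writeLines(tsv)

if (nzchar(opt$store_out)) {
  writeLines(serialize_graph(ans$store$graph, "text/rdf+n3"), opt$store_out)
}
message(sprintf("%d solution(s); store holds %d triple(s)",
                length(ans$solutions), graph_size(ans$store$graph)))
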