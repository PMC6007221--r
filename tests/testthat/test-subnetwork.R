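chain_assembly <- function() {
  assembly_from_statements(data.frame(
    subject = c("p(HGNC:S)", "p(HGNC:A)", "p(HGNC:B)"),
    relation = "increases",
    object = c("p(HGNC:A)", "p(HGNC:B)", 'bp(GO:"target process")'),
    citation_type = "PubMed", citation_id = as.character(1:3),
    stringsAsFactors = FALSE
  ))
}

diamond_assembly <- function() {
  assembly_from_statements(data.frame(
    subject = c("p(HGNC:S)", "p(HGNC:S)", "p(HGNC:A)", "p(HGNC:B)"),
    relation = c("increases", "decreases", "increases", "increases"),
    object = c("p(HGNC:A)", "p(HGNC:B)", 'bp(GO:"target process")',
               'bp(GO:"target process")'),
    citation_type = "PubMed", citation_id = as.character(1:4),
    stringsAsFactors = FALSE
  ))
}

test_that("a linear chain yields itself as the single shortest path", {
  sn <- shortest_path_union(chain_assembly(), "p(HGNC:S)", 'bp(GO:"target process")')
  expect_length(sn$path_registry, 1)
  expect_length(sn$path_registry[[1]], 1)
  expect_equal(sn$pairs$length, 3L)
  expect_setequal(sn$nodes, c("p(HGNC:S)", "p(HGNC:A)", "p(HGNC:B)",
                              'bp(GO:"target process")'))
  expect_equal(nrow(sn$edges), 3L)
})

test_that("a diamond retains both tied shortest paths", {
  sn <- shortest_path_union(diamond_assembly(), "p(HGNC:S)", 'bp(GO:"target process")')
  expect_length(sn$path_registry[[1]], 2)
  expect_equal(length(sn$nodes), 4L)
  lens <- vapply(sn$path_registry[[1]], length, integer(1))
  expect_true(all(lens == lens[1]))  # tied paths have equal length
  # single-path mode keeps one
  one <- shortest_path_union(diamond_assembly(), "p(HGNC:S)",
                             'bp(GO:"target process")', all_paths = FALSE)
  expect_length(one$path_registry[[1]], 1)
})

test_that("path sets equal exhaustive enumeration on random small graphs", {
  for (seed in 1:30) {
    a <- random_causal_assembly(seed, n_nodes = 8, p_edge = 0.25)
    keys <- a$entities$key
    src <- keys[1]; snk <- keys[8]
    oracle <- oracle_shortest_paths(a$relations$subject, a$relations$object, src, snk)
    sn <- tryCatch(
      suppressWarnings(shortest_path_union(a, src, snk)),
      comorbnet_invalid_query = function(e) NULL
    )
    got <- if (is.null(sn)) list() else sn$path_registry[[pair_key <- paste(src, "->", snk)]] %||% list()
    expect_equal(length(got), length(oracle), info = paste("seed", seed))
    if (length(oracle)) {
      expect_identical(vapply(got, paste, character(1), collapse = "|"),
                       vapply(oracle, paste, character(1), collapse = "|"))
      # path lengths equal BFS distances from igraph
      d <- igraph::distances(assembly_igraph(a, causal_only = TRUE),
                             v = src, to = snk, mode = "out")
      expect_equal(length(oracle[[1]]) - 1L, as.integer(d))
    }
  }
})

test_that("association edges are excluded from causal paths unless requested", {
  a <- assembly_from_statements(data.frame(
    subject = c("p(HGNC:S)", "p(HGNC:S)", "p(HGNC:A)"),
    relation = c("association", "increases", "increases"),
    object = c('bp(GO:"target process")', "p(HGNC:A)", 'bp(GO:"target process")'),
    citation_type = "PubMed", citation_id = as.character(1:3),
    stringsAsFactors = FALSE
  ))
  causal <- shortest_path_union(a, "p(HGNC:S)", 'bp(GO:"target process")')
  expect_equal(causal$pairs$length, 2L)  # the 1-edge association shortcut is ignored
  loose <- shortest_path_union(a, "p(HGNC:S)", 'bp(GO:"target process")',
                               causal_only = FALSE)
  expect_equal(loose$pairs$length, 1L)
})

test_that("unreachable pairs are recorded and the undirected fallback flags them", {
  a <- assembly_from_statements(data.frame(
    subject = c("p(HGNC:A)", "p(HGNC:A)", "p(HGNC:B)"),
    relation = "increases",
    object = c("p(HGNC:S)", "p(HGNC:B)", 'bp(GO:"target process")'),
    citation_type = "PubMed", citation_id = c("1", "2", "3"), stringsAsFactors = FALSE
  ))
  expect_warning(
    sn <- shortest_path_union(a, "p(HGNC:S)", 'bp(GO:"target process")'),
    "empty subnetwork"
  )
  expect_equal(nrow(sn$unreachable_pairs), 1L)
  expect_length(sn$nodes, 0)

  fb <- shortest_path_union(a, "p(HGNC:S)", 'bp(GO:"target process")',
                            direction = "undirected-fallback")
  expect_identical(fb$pairs$status, "fallback")
  expect_equal(fb$pairs$length, 3L)

  expect_warning(
    shortest_path_union(a, c("p(HGNC:S)", "p(HGNC:MISSING)"),
                        'bp(GO:"target process")',
                        direction = "undirected-fallback"),
    "not found"
  )
  expect_error(
    suppressWarnings(shortest_path_union(a, "p(HGNC:MISSING)",
                                         'bp(GO:"target process")')),
    class = "comorbnet_invalid_query"
  )
  expect_error(shortest_path_union(a, "p(HGNC:S)", "p(HGNC:S)"),
               class = "comorbnet_invalid_query")
})

test_that("extraction is idempotent: re-running on the subnetwork keeps path lengths", {
  for (seed in c(3, 9, 17)) {
    sim <- simulate_assembly(graph_sim_config(seed = seed))
    sn <- suppressWarnings(shortest_path_union(sim$assembly, sim$truth$pairs$source,
                                               sim$truth$pairs$sink))
    again <- suppressWarnings(shortest_path_union(subnetwork_assembly(sn),
                                                  sim$truth$pairs$source,
                                                  sim$truth$pairs$sink))
    ok <- sn$pairs$status != "unreachable"
    merged <- merge(sn$pairs[ok, ], again$pairs, by = c("source", "sink"))
    expect_equal(merged$length.x, merged$length.y)
  }
})

test_that("upstream controllers require causal edges into two distinct pairs", {
  # u regulates nodes on both the chain pair and a second disjoint pair
  a <- assembly_from_statements(data.frame(
    subject = c("p(HGNC:S)", "p(HGNC:A)", "p(HGNC:S2)",
                "p(HGNC:U)", "p(HGNC:U)", "p(HGNC:V)"),
    relation = "increases",
    object = c("p(HGNC:A)", 'bp(GO:"target process")', 'bp(GO:"second process")',
               "p(HGNC:A)", "p(HGNC:S2)", "p(HGNC:A)"),
    citation_type = "PubMed", citation_id = as.character(1:6),
    stringsAsFactors = FALSE
  ))
  sn <- shortest_path_union(a, c("p(HGNC:S)", "p(HGNC:S2)"),
                            c('bp(GO:"target process")', 'bp(GO:"second process")'))
  base_lengths <- sn$pairs$length
  aug <- add_upstream_controllers(a, sn)
  expect_identical(aug$controllers, "p(HGNC:U)")   # V touches only one pair
  expect_false("p(HGNC:V)" %in% aug$nodes)
  # augmentation adds, never removes, and leaves registered paths untouched
  expect_true(all(sn$nodes %in% aug$nodes))
  expect_true(all(rownames(sn$edges) %in% rownames(aug$edges)) || nrow(aug$edges) >= nrow(sn$edges))
  expect_identical(aug$path_registry, sn$path_registry)
  expect_identical(aug$pairs$length, base_lengths)
})

test_that("planted controllers are recovered exactly from simulations", {
  for (seed in c(2, 5)) {
    sim <- simulate_assembly(graph_sim_config(seed = seed))
    sn <- suppressWarnings(shortest_path_union(sim$assembly, sim$truth$pairs$source,
                                               sim$truth$pairs$sink))
    aug <- add_upstream_controllers(sim$assembly, sn)
    expect_identical(aug$controllers, sim$truth$controller)
  }
})

test_that("summaries order nodes deterministically and list every path", {
  sn <- shortest_path_union(diamond_assembly(), "p(HGNC:S)", 'bp(GO:"target process")')
  s <- render_summary(sn)
  expect_identical(s$nodes$role,
                   c("source", "interior", "interior", "sink"))
  expect_equal(nrow(s$paths), 2L)
  expect_true(all(grepl("^p\\(HGNC:S\\) -> ", s$paths$path)))
  # empty subnetwork gives empty tables
  empty <- suppressWarnings(shortest_path_union(
    assembly_from_statements(data.frame(
      subject = "p(HGNC:X)", relation = "increases", object = "p(HGNC:S)",
      citation_type = "PubMed", citation_id = "1", stringsAsFactors = FALSE
    )),
    "p(HGNC:S)", "p(HGNC:X)"
  ))
  es <- render_summary(empty)
  expect_equal(nrow(es$nodes), 0L)
  expect_equal(nrow(es$paths), 0L)
})

test_that("GraphML export writes vertex and edge attributes", {
  p <- withr::local_tempfile(fileext = ".graphml")
  sn <- shortest_path_union(diamond_assembly(), "p(HGNC:S)", 'bp(GO:"target process")')
  write_graphml(sn, p)
  xml <- readLines(p, warn = FALSE)
  expect_true(any(grepl("<graphml", xml)))
  expect_true(any(grepl("relation", xml)))
})
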