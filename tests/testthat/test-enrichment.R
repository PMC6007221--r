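test_that("seed genes map to subgraphs containing them as gene-like entities", {
  a <- toy_assembly()
  m <- map_seed_genes(a, c("GABRA1", "NOPE"))
  expect_identical(m[["Gaba subgraph"]], "GABRA1")
  expect_length(m[["Adenosine subgraph"]], 0)  # ADORA1 is there, GABRA1 is not
  expect_true(all(lengths(map_seed_genes(a, "NOPE")) == 0))
  # case-insensitive matching
  expect_identical(map_seed_genes(a, "gabra1")[["Gaba subgraph"]], "GABRA1")
  # abundance entities are not gene-like: adenosine never maps
  expect_true(all(lengths(map_seed_genes(a, "ADENOSINE")) == 0))
})

test_that("mapping on planted simulations equals the ground truth", {
  for (seed in c(11, 12)) {
    sim <- simulate_assembly(graph_sim_config(seed = seed))
    m <- map_seed_genes(sim$assembly, sim$truth$seed_genes)
    for (lb in sim$truth$planted_labels) {
      expect_setequal(m[[lb]], sim$truth$seed_genes)
    }
  }
})

test_that("scores combine coverage and specificity with hypergeometric companion", {
  a <- toy_assembly()
  # Gaba subgraph holds exactly one gene-like entity, GABRA1
  s <- score_subgraph(a, "Gaba subgraph", "GABRA1")
  expect_equal(s$coverage, 1)
  expect_equal(s$specificity, 1)
  expect_equal(s$score, 1)

  s0 <- score_subgraph(a, "Gaba subgraph", "ADORA1")
  expect_equal(s0$score, 0)
  expect_length(s0$mapped_genes, 0)

  # score is 0 iff nothing maps; otherwise strictly positive
  tab <- score_subgraphs(a, c("GABRA1", "ADORA1"))
  expect_identical(tab$score == 0, tab$n_mapped == 0L)
})

test_that("hypergeometric tails equal exhaustive enumeration on small universes", {
  grid <- expand.grid(N = c(5, 8, 12), K = c(2, 4), n = c(1, 3, 5))
  for (i in seq_len(nrow(grid))) {
    N <- grid$N[i]; K <- grid$K[i]; n <- grid$n[i]
    for (k in 0:min(K, n)) {
      expect_equal(
        stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
        oracle_hyper_tail(N, K, n, k),
        tolerance = 1e-12
      )
    }
  }

  # end-to-end on a 5-gene toy assembly with 2 subgraphs
  stmts <- data.frame(
    subject = sprintf("p(HGNC:G%d)", c(1, 2, 3, 4)),
    relation = "increases",
    object = sprintf("p(HGNC:G%d)", c(2, 3, 4, 5)),
    citation_type = "PubMed", citation_id = as.character(1:4),
    subgraphs = I(list("S1", "S1", "S2", "S2")), stringsAsFactors = FALSE
  )
  a <- assembly_from_statements(stmts)
  s <- score_subgraph(a, "S1", c("G1", "G2"))  # universe 5, seeds 2, draw 3
  expect_equal(s$hypergeom_p, oracle_hyper_tail(5, 2, 3, s$n_mapped))
})

test_that("top-percentile selection keeps two of twelve distinct candidates and honors ties", {
  twelve <- data.frame(
    label = sprintf("net%02d", 1:12), n_mapped = 1L,
    score = seq(0.05, 0.93, length.out = 12), stringsAsFactors = FALSE
  )
  expect_identical(select_top_percentile(twelve, 0.10),
                   sort(twelve$label[11:12]))

  one <- twelve[5, ]
  expect_identical(select_top_percentile(one, 0.10), one$label)

  tied <- data.frame(label = c("a", "b", "c"), n_mapped = 1L, score = 0.4,
                     stringsAsFactors = FALSE)
  expect_setequal(select_top_percentile(tied, 0.10), c("a", "b", "c"))

  none <- data.frame(label = "a", n_mapped = 0L, score = 0, stringsAsFactors = FALSE)
  expect_warning(sel <- select_top_percentile(none, 0.10), "empty selection")
  expect_length(sel, 0)
  expect_error(select_top_percentile(twelve, 1.2), class = "comorbnet_invalid_input")
})

test_that("selection size is bounded, non-empty for candidates, and monotone in fraction", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:15, 1)
    sc <- data.frame(
      label = sprintf("l%02d", seq_len(n)),
      n_mapped = sample(0:3, n, replace = TRUE),
      score = stats::runif(n), stringsAsFactors = FALSE
    )
    sc$score[sc$n_mapped == 0] <- 0
    if (!any(sc$n_mapped >= 1)) sc$n_mapped[1] <- 1L
    prev <- character(0)
    for (f in c(0.05, 0.1, 0.25, 0.5, 0.9)) {
      sel <- select_top_percentile(sc, f)
      expect_gte(length(sel), 1)
      expect_lte(length(sel), sum(sc$n_mapped >= 1))
      expect_true(all(prev %in% sel))  # raising the fraction never shrinks selection
      prev <- sel
    }
  }
})

test_that("scores are invariant to relation order and entity relabeling", {
  a <- random_assembly(21, n_entities = 10, n_relations = 16,
                       min_labels_per_relation = 1)
  seeds <- toupper(a$entities$name[a$entities$func %in% c("protein", "gene", "rna")])[1:2]
  base <- score_subgraphs(a, seeds)

  perm <- sample(nrow(a$relations))
  shuffled <- knowledge_assembly(a$entities, a$relations[perm, ],
                                 a$subgraph_inventory)
  got <- score_subgraphs(shuffled, seeds)
  expect_equal(got[order(got$label), names(base) != "mapped_genes"],
               base[order(base$label), names(base) != "mapped_genes"],
               ignore_attr = TRUE)
})

test_that("comparative enrichment intersects normalized labels across contexts", {
  a <- toy_assembly()
  same <- comparative_enrichment(a, a, c("GABRA1", "ADORA1"), fraction = 0.5)
  expect_identical(same$shared,
                   sort(normalize_subgraph_label(same$selected[[1]])))

  # disjoint inventories share nothing
  b <- assembly_from_statements(data.frame(
    subject = "p(HGNC:GABRA1)", relation = "increases", object = "p(HGNC:GABRB2)",
    citation_type = "PubMed", citation_id = "9",
    subgraphs = I(list("Unrelated block")), stringsAsFactors = FALSE
  ))
  cross <- comparative_enrichment(a, b, "GABRA1", fraction = 0.5)
  expect_length(cross$shared, 0)

  # suffix/case normalization: "Gaba sub-graph" matches "GABA subgraph"
  expect_identical(normalize_subgraph_label(c("Gaba sub-graph", "GABA subgraph")),
                   c("gaba", "gaba"))

  # planted two-context simulation shares its planted block
  simA <- simulate_assembly(graph_sim_config(seed = 31))
  simB <- simulate_assembly(graph_sim_config(seed = 32))
  both <- comparative_enrichment(simA$assembly, simB$assembly,
                                 simA$truth$seed_genes,
                                 context_labels = c("epilepsy", "ad"))
  expect_true(all(normalize_subgraph_label(simA$truth$planted_labels) %in% both$shared))
  expect_s3_class(both$shared_scores, "data.frame")
  expect_true(all(both$shared_scores$shared_label %in% both$shared))
})
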