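# Independent oracles used to cross-check the package's graph and
# combinatorial machinery. Deliberately implemented from first principles
# (union-find, recursive path enumeration, exhaustive draws) so they share no
# code with the implementation under test.

`%||%` <- function(x, y) if (is.null(x)) y else x

# connected components on the undirected projection, by union-find
oracle_components <- function(nodes, from, to) {
  if (!length(nodes)) return(0L)
  parent <- seq_along(nodes)
  idx <- function(k) match(k, nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_along(from)) {
    ri <- find(idx(from[e]))
    rj <- find(idx(to[e]))
    if (ri != rj) parent[ri] <- rj
  }
  length(unique(vapply(seq_along(nodes), find, integer(1))))
}

# all minimal-length directed simple paths, by exhaustive DFS enumeration
oracle_shortest_paths <- function(from, to, source, sink) {
  adj <- split(to, from)
  recurse <- function(cur, visited) {
    if (cur == sink) return(list(cur))
    out <- list()
    for (nxt in unique(adj[[cur]] %||% character(0))) {
      if (nxt %in% visited) next
      for (p in recurse(nxt, c(visited, nxt))) {
        out[[length(out) + 1L]] <- c(cur, p)
      }
    }
    out
  }
  if (!(source %in% c(from, to)) && source != sink) return(list())
  ps <- recurse(source, source)
  if (!length(ps)) return(list())
  ps <- ps[lengths(ps) == min(lengths(ps))]
  ps[order(vapply(ps, paste, character(1), collapse = "|"))]
}

# upper-tail hypergeometric by exhaustive enumeration of all draws
oracle_hyper_tail <- function(n_universe, n_white, n_draw, k_min) {
  if (n_draw == 0) return(as.numeric(k_min <= 0))
  draws <- utils::combn(n_universe, n_draw)
  hits <- colSums(draws <= n_white)  # white balls are 1..n_white
  mean(hits >= k_min)
}

# structural equality of assemblies (order-insensitive, line numbers ignored)
canonical_relations <- function(assembly) {
  rel <- assembly$relations
  sort(vapply(seq_len(nrow(rel)), function(i) {
    paste(rel$subject[i], rel$relation[i], rel$object[i],
          rel$citation_type[i], rel$citation_id[i],
          ifelse(is.na(rel$evidence[i]), "<NA>", rel$evidence[i]),
          paste(rel$subgraphs[[i]], collapse = "+"),
          sep = "\r")
  }, character(1)))
}

expect_isomorphic_assemblies <- function(a, b) {
  expect_setequal(a$entities$key, b$entities$key)
  expect_identical(canonical_relations(a), canonical_relations(b))
  expect_identical(sort(a$subgraph_inventory), sort(b$subgraph_inventory))
}

# randomly populated assembly exercising quoted names, multi-label relations,
# optional evidence and repeated citations
random_assembly <- function(seed, n_entities = 8, n_relations = 12,
                            labels = c("Gaba subgraph", "Mapk-erk subgraph", "Transport"),
                            min_labels_per_relation = 0,
                            drop_isolated = FALSE) {
  set.seed(seed)
  funcs <- sample(c("protein", "gene", "rna", "abundance", "bioprocess",
                    "pathology", "complex"), n_entities, replace = TRUE)
  ns <- ifelse(funcs %in% c("protein", "gene", "rna"), "HGNC",
               ifelse(funcs == "abundance", "CHEBI", "GO"))
  names_ <- ifelse(stats::runif(n_entities) < 0.3,
                   sprintf("entity name %d", seq_len(n_entities)),
                   sprintf("ENT%d", seq_len(n_entities)))
  entities <- data.frame(func = funcs, namespace = ns, name = names_,
                         stringsAsFactors = FALSE)
  keys <- comorbnet::entity_key(funcs, ns, names_)
  sub_i <- sample(n_entities, n_relations, replace = TRUE)
  obj_i <- vapply(sub_i, function(i) sample(setdiff(seq_len(n_entities), i), 1), integer(1))
  rels <- data.frame(
    subject = keys[sub_i],
    relation = sample(c("increases", "directly_increases", "decreases",
                        "directly_decreases", "regulates", "association",
                        "positive_correlation", "negative_correlation"),
                      n_relations, replace = TRUE),
    object = keys[obj_i],
    citation_type = "PubMed",
    citation_id = as.character(sample(100:105, n_relations, replace = TRUE)),
    evidence = ifelse(stats::runif(n_relations) < 0.5,
                      sprintf("evidence sentence %d", seq_len(n_relations)),
                      NA_character_),
    stringsAsFactors = FALSE
  )
  rels$subgraphs <- I(lapply(seq_len(n_relations), function(i) {
    k <- sample(min_labels_per_relation:length(labels), 1)
    sort(sample(labels, k))
  }))
  if (drop_isolated) {
    entities <- entities[keys %in% c(rels$subject, rels$object), , drop = FALSE]
  }
  comorbnet::knowledge_assembly(entities, rels)
}

# small fixed two-mechanism assembly used across tests
toy_assembly <- function() {
  stmts <- data.frame(
    subject = c("p(HGNC:GABRA1)", "p(HGNC:SCN1A)", "p(HGNC:ADORA1)",
                "a(CHEBI:adenosine)", "p(HGNC:SCN1A)"),
    relation = c("increases", "decreases", "increases", "increases", "association"),
    object = c('bp(GO:"inhibitory synaptic transmission")',
               'bp(GO:"neuronal action potential")',
               "a(CHEBI:adenosine)",
               'bp(GO:"inhibitory synaptic transmission")',
               "path(MESH:Epilepsy)"),
    citation_type = "PubMed",
    citation_id = c("1", "1", "2", "3", "3"),
    stringsAsFactors = FALSE
  )
  stmts$subgraphs <- I(list("Gaba subgraph", "Sodium channel subgraph",
                            "Adenosine subgraph", "Adenosine subgraph",
                            "Sodium channel subgraph"))
  comorbnet::assembly_from_statements(stmts)
}

# random small directed graph as an assembly of causal protein-protein edges
random_causal_assembly <- function(seed, n_nodes = 8, p_edge = 0.25) {
  set.seed(seed)
  nm <- sprintf("N%d", seq_len(n_nodes))
  entities <- data.frame(func = "protein", namespace = "HGNC", name = nm,
                         stringsAsFactors = FALSE)
  keys <- comorbnet::entity_key(entities$func, entities$namespace, entities$name)
  grid <- expand.grid(i = seq_len(n_nodes), j = seq_len(n_nodes))
  grid <- grid[grid$i != grid$j, ]
  keep <- stats::runif(nrow(grid)) < p_edge
  rels <- if (any(keep)) {
    g <- grid[keep, ]
    data.frame(
      subject = keys[g$i], relation = "increases", object = keys[g$j],
      citation_type = "PubMed", citation_id = as.character(seq_len(nrow(g))),
      stringsAsFactors = FALSE
    )
  } else {
    NULL
  }
  comorbnet::knowledge_assembly(entities, rels)
}
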