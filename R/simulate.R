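# Synthetic corpora and knowledge assemblies with planted ground truth, so
# that association scoring, enrichment selection, path extraction and
# controller recovery can all be validated end to end without any download.

#' Configuration for a synthetic literature corpus
#'
#' The generator emulates a document index: background documents with no
#' disease tag, per-disease document blocks, and joint blocks tagged with a
#' disease pair. Every document mentions each vocabulary gene independently
#' with the baseline probability; genes planted for the document's disease
#' context are mentioned with `enrichment_factor * baseline` instead
#' (document-level presence/absence, no mention counts).
#'
#' @param n_background_docs number of untagged background documents.
#' @param disease_docs named integer vector: documents per single disease.
#' @param pair_docs named integer vector: documents per disease pair, named
#'   `"A&B"`.
#' @param n_genes vocabulary size; symbols are `G0001`, `G0002`, ...
#' @param baseline per-document mention probability in (0, 1).
#' @param enrichment_factor multiplier (> 1 plants signal; 1 = null) applied
#'   to the baseline for planted genes; `factor * baseline` must be <= 1.
#' @param planted named list mapping a context (a disease name or `"A&B"`
#'   pair name) to the gene symbols planted for it; `NULL` plants
#'   `n_planted_genes` fresh symbols per pair context.
#' @param n_planted_genes planted genes per pair context when `planted` is
#'   `NULL`.
#' @param seed integer random seed.
#' @return object of class `corpus_sim_config`.
#' @export
corpus_sim_config <- function(n_background_docs = 400,
                              disease_docs = c(epilepsy = 0, diabetes = 0),
                              pair_docs = c("epilepsy&diabetes" = 200),
                              n_genes = 300,
                              baseline = 0.02,
                              enrichment_factor = 10,
                              planted = NULL,
                              n_planted_genes = 20,
                              seed = 1) {
  if (!is_scalar_number(baseline) || baseline <= 0 || baseline >= 1) {
    cn_stop("comorbnet_config_error", "baseline must lie strictly between 0 and 1")
  }
  if (!is_scalar_number(enrichment_factor) || enrichment_factor < 1 ||
      enrichment_factor * baseline > 1) {
    cn_stop("comorbnet_config_error",
            "enrichment_factor must be >= 1 with factor * baseline <= 1")
  }
  if (!is_scalar_number(n_genes) || n_genes < 1) {
    cn_stop("comorbnet_config_error", "n_genes must be a positive integer")
  }
  n_ctx_docs <- sum(disease_docs) + sum(pair_docs)
  if (n_background_docs < 1 || n_background_docs + n_ctx_docs < 2) {
    cn_stop("comorbnet_config_error",
            "at least one background document and two documents overall are required (background undefined otherwise)")
  }
  vocab <- sprintf("G%04d", seq_len(n_genes))
  if (is.null(planted)) {
    planted <- list()
    next_gene <- 1L
    for (ctx in names(pair_docs)) {
      take <- seq(next_gene, length.out = min(n_planted_genes, n_genes - next_gene + 1L))
      planted[[ctx]] <- vocab[take]
      next_gene <- next_gene + length(take)
    }
  }
  if (!all(unlist(planted, use.names = FALSE) %in% vocab)) {
    cn_stop("comorbnet_config_error", "planted gene sets must be subsets of the vocabulary")
  }
  known_ctx <- c(names(disease_docs), names(pair_docs))
  if (length(planted) && !all(names(planted) %in% known_ctx)) {
    cn_stop("comorbnet_config_error", "planted contexts must be declared disease or pair blocks")
  }
  structure(
    list(
      n_background_docs = as.integer(n_background_docs),
      disease_docs = disease_docs, pair_docs = pair_docs,
      n_genes = as.integer(n_genes), vocab = vocab,
      baseline = baseline, enrichment_factor = enrichment_factor,
      planted = planted, seed = as.integer(seed)
    ),
    class = "corpus_sim_config"
  )
}

sim_block <- function(vocab, n_docs, baseline, planted_genes, factor, prefix, start) {
  probs <- rep(baseline, length(vocab))
  probs[vocab %in% planted_genes] <- min(1, factor * baseline)
  draws <- matrix(stats::runif(length(vocab) * n_docs) < probs,
                  nrow = length(vocab))
  ids <- sprintf("%s%05d", prefix, seq(start, length.out = n_docs))
  genes <- lapply(seq_len(n_docs), function(j) vocab[draws[, j]])
  list(ids = ids, genes = setNames(genes, ids))
}

#' Simulate a literature corpus with planted gene-disease associations
#'
#' @param config a [corpus_sim_config()].
#' @return list with `index` (a [corpus_index()]) and `truth` (class
#'   `sim_ground_truth`: the planted gene sets per context and the config).
#'   Identical configs (including seed) give byte-identical serializations.
#' @export
simulate_corpus <- function(config = corpus_sim_config()) {
  stopifnot(inherits(config, "corpus_sim_config"))
  set.seed(config$seed)
  documents <- character(0)
  doc_diseases <- list()
  doc_genes <- list()
  counter <- 1L

  add_block <- function(n_docs, diseases, planted_genes) {
    if (n_docs < 1) return(invisible())
    blk <- sim_block(config$vocab, n_docs, config$baseline, planted_genes,
                     config$enrichment_factor, "D", counter)
    counter <<- counter + n_docs
    documents <<- c(documents, blk$ids)
    doc_diseases <<- c(doc_diseases, setNames(
      replicate(n_docs, diseases, simplify = FALSE), blk$ids))
    doc_genes <<- c(doc_genes, blk$genes)
    invisible()
  }

  add_block(config$n_background_docs, character(0), character(0))
  for (dz in names(config$disease_docs)) {
    add_block(config$disease_docs[[dz]], dz, config$planted[[dz]] %||% character(0))
  }
  for (pr in names(config$pair_docs)) {
    diseases <- strsplit(pr, "&", fixed = TRUE)[[1]]
    add_block(config$pair_docs[[pr]], diseases, config$planted[[pr]] %||% character(0))
  }

  index <- corpus_index(documents, doc_diseases, doc_genes)
  truth <- structure(
    list(planted_genes = config$planted, config = config),
    class = "sim_ground_truth"
  )
  list(index = index, truth = truth)
}

#' Configuration for a synthetic annotated knowledge assembly
#'
#' Builds labelled mechanism blocks of protein (gene-symbol) and biological
#' process entities with random causal edges inside and between blocks. Seed
#' (drug-target) genes are placed in every planted block with probability
#' `min(1, seed_enrichment_factor * seed_baseline_prob)` (1 under the
#' defaults: a drug target known to belong to a mechanism is a member of it,
#' not a probabilistic visitor) and in other blocks with the baseline
#' probability. Planted source-to-sink causal chains of a given length are
#' embedded; candidate noise edges that would shorten a planted path, create
#' a tied alternative, or fabricate a spurious shared controller (i.e. any
#' edge pointing into a planted-path node or the controller) are rejected
#' during sampling, and the generator asserts afterwards that every planted
#' path is still uniquely shortest.
#'
#' @param n_subgraphs number of mechanism blocks (labels `Mechanism 01`, ...).
#' @param genes_per_subgraph protein entities per block (excluding seeds).
#' @param bioprocesses_per_subgraph biological-process entities per block.
#' @param p_within probability of a random causal edge between two entities
#'   of the same block; must satisfy `0 < p_between <= p_within <= 1`.
#' @param p_between probability of a random causal edge between entities of
#'   different blocks.
#' @param planted_subgraphs indices of the blocks that receive the seed
#'   genes.
#' @param n_seed_genes number of seed genes (`SEED1`, ...).
#' @param seed_baseline_prob probability a seed gene appears in a non-planted
#'   block.
#' @param seed_enrichment_factor enrichment of seed presence in planted
#'   blocks; `factor * baseline` is capped at 1 and must be positive.
#' @param planted_paths list of `list(subgraph =, length =)` path
#'   specifications; each plants a fresh source protein, `length - 1`
#'   interior proteins and a bioprocess sink in that block.
#' @param plant_controller add one shared upstream controller with causal
#'   edges into the first two planted paths? Requires >= 2 planted paths.
#' @param seed integer random seed.
#' @return object of class `graph_sim_config`.
#' @export
graph_sim_config <- function(n_subgraphs = 8,
                             genes_per_subgraph = 10,
                             bioprocesses_per_subgraph = 3,
                             p_within = 0.12,
                             p_between = 0.01,
                             planted_subgraphs = c(1L, 2L),
                             n_seed_genes = 5,
                             seed_baseline_prob = 0.1,
                             seed_enrichment_factor = 10,
                             planted_paths = list(list(subgraph = 1L, length = 3L),
                                                  list(subgraph = 2L, length = 3L)),
                             plant_controller = TRUE,
                             seed = 1) {
  if (!is_scalar_number(p_within) || !is_scalar_number(p_between) ||
      p_between <= 0 || p_between > p_within || p_within > 1) {
    cn_stop("comorbnet_config_error", "edge probabilities must satisfy 0 < between <= within <= 1")
  }
  if (!length(planted_subgraphs) || any(planted_subgraphs < 1) ||
      any(planted_subgraphs > n_subgraphs)) {
    cn_stop("comorbnet_config_error", "planted subgraph indices must lie in 1..n_subgraphs")
  }
  if (!is_scalar_number(seed_baseline_prob) || seed_baseline_prob <= 0 ||
      seed_baseline_prob >= 1 || seed_enrichment_factor < 1) {
    cn_stop("comorbnet_config_error",
            "seed_baseline_prob must be in (0,1) and seed_enrichment_factor >= 1")
  }
  for (p in planted_paths) {
    if (is.null(p$subgraph) || is.null(p$length) || p$length < 1 ||
        p$subgraph < 1 || p$subgraph > n_subgraphs) {
      cn_stop("comorbnet_config_error", "each planted path needs a valid subgraph index and length >= 1")
    }
    if (p$length > genes_per_subgraph + bioprocesses_per_subgraph) {
      cn_stop("comorbnet_config_error", "planted path length exceeds its block size")
    }
  }
  if (plant_controller && length(planted_paths) < 2) {
    cn_stop("comorbnet_config_error", "a shared controller needs at least two planted paths")
  }
  structure(
    list(
      n_subgraphs = as.integer(n_subgraphs),
      genes_per_subgraph = as.integer(genes_per_subgraph),
      bioprocesses_per_subgraph = as.integer(bioprocesses_per_subgraph),
      p_within = p_within, p_between = p_between,
      planted_subgraphs = as.integer(planted_subgraphs),
      n_seed_genes = as.integer(n_seed_genes),
      seed_baseline_prob = seed_baseline_prob,
      seed_enrichment_factor = seed_enrichment_factor,
      planted_paths = planted_paths,
      plant_controller = isTRUE(plant_controller),
      seed = as.integer(seed)
    ),
    class = "graph_sim_config"
  )
}

#' Simulate an annotated knowledge assembly with planted ground truth
#'
#' @param config a [graph_sim_config()].
#' @return list with `assembly` (a [knowledge_assembly()]) and `truth`
#'   (class `sim_ground_truth`): `planted_labels`, `seed_genes`,
#'   `planted_paths` (list of node-key sequences), `pairs` (source/sink key
#'   data.frame), `controller` (key or `NA`), and the config.
#' @export
simulate_assembly <- function(config = graph_sim_config()) {
  stopifnot(inherits(config, "graph_sim_config"))
  set.seed(config$seed)
  labels <- sprintf("Mechanism %02d", seq_len(config$n_subgraphs))
  seed_genes <- sprintf("SEED%d", seq_len(config$n_seed_genes))
  p_seed_planted <- min(1, config$seed_enrichment_factor * config$seed_baseline_prob)

  protein <- function(name) data.frame(func = "protein", namespace = "HGNC",
                                       name = name, stringsAsFactors = FALSE)
  bioproc <- function(name) data.frame(func = "bioprocess", namespace = "GO",
                                       name = name, stringsAsFactors = FALSE)

  entities <- list()
  block_members <- vector("list", config$n_subgraphs)   # keys per block
  protected <- character(0)                             # no random in-edges
  path_truth <- list()
  pair_rows <- list()

  for (b in seq_len(config$n_subgraphs)) {
    base <- protein(sprintf("S%02dG%02d", b, seq_len(config$genes_per_subgraph)))
    bps <- bioproc(sprintf("S%02dBP%02d", b, seq_len(config$bioprocesses_per_subgraph)))
    ents <- rbind(base, bps)
    present <- if (b %in% config$planted_subgraphs) {
      stats::runif(config$n_seed_genes) < p_seed_planted
    } else {
      stats::runif(config$n_seed_genes) < config$seed_baseline_prob
    }
    if (any(present)) ents <- rbind(ents, protein(seed_genes[present]))
    entities[[b]] <- ents
    block_members[[b]] <- entity_key(ents$func, ents$namespace, ents$name)
  }

  # planted source -> interior -> ... -> sink chains on dedicated nodes
  chain_edges <- list()
  for (i in seq_along(config$planted_paths)) {
    spec <- config$planted_paths[[i]]
    b <- spec$subgraph
    src <- protein(sprintf("S%02dPSRC%d", b, i))
    interiors <- if (spec$length > 1) {
      protein(sprintf("S%02dPINT%d_%d", b, i, seq_len(spec$length - 1L)))
    } else {
      NULL
    }
    sink <- bioproc(sprintf("S%02dPSINK%d", b, i))
    path_ents <- rbind(src, interiors, sink)
    entities[[b]] <- rbind(entities[[b]], path_ents)
    keys <- entity_key(path_ents$func, path_ents$namespace, path_ents$name)
    block_members[[b]] <- c(block_members[[b]], keys)
    protected <- c(protected, keys)
    path_truth[[i]] <- keys
    pair_rows[[i]] <- data.frame(source = keys[1], sink = keys[length(keys)],
                                 stringsAsFactors = FALSE)
    chain_edges[[i]] <- data.frame(
      subject = keys[-length(keys)], relation = "increases", object = keys[-1],
      label = labels[b], stringsAsFactors = FALSE
    )
  }

  controller_key <- NA_character_
  controller_edges <- NULL
  if (config$plant_controller) {
    b <- config$planted_paths[[1]]$subgraph
    ctrl <- protein("CTRL1")
    entities[[b]] <- rbind(entities[[b]], ctrl)
    controller_key <- entity_key("protein", "HGNC", "CTRL1")
    protected <- c(protected, controller_key)
    # hit one on-path node of each of the first two planted paths; controller
    # edges carry no mechanism label (regulatory context, not mechanism
    # membership), so per-mechanism statistics are unaffected
    hit <- vapply(path_truth[1:2], function(p) p[min(2L, length(p))], character(1))
    controller_edges <- data.frame(
      subject = controller_key, relation = "increases", object = hit,
      label = NA_character_, stringsAsFactors = FALSE
    )
  }

  # random causal edges; edges into protected nodes are rejected outright
  sample_edges <- function(from_keys, to_keys, p, label) {
    to_keys <- setdiff(to_keys, protected)
    if (!length(from_keys) || !length(to_keys)) return(NULL)
    grid <- expand.grid(subject = from_keys, object = to_keys,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[grid$subject != grid$object, , drop = FALSE]
    keep <- stats::runif(nrow(grid)) < p
    if (!any(keep)) return(NULL)
    picked <- grid[keep, , drop = FALSE]
    picked$relation <- sample(CAUSAL_RELATIONS, nrow(picked), replace = TRUE)
    picked$label <- label
    picked[, c("subject", "relation", "object", "label")]
  }

  # within-block noise edges carry the block label; cross-block edges are
  # left unannotated (connections between mechanisms, not members of one)
  noise_edges <- list()
  for (b in seq_len(config$n_subgraphs)) {
    noise_edges[[length(noise_edges) + 1L]] <-
      sample_edges(block_members[[b]], block_members[[b]], config$p_within, labels[b])
  }
  for (b in seq_len(config$n_subgraphs)) {
    others <- setdiff(unlist(block_members), block_members[[b]])
    noise_edges[[length(noise_edges) + 1L]] <-
      sample_edges(block_members[[b]], others, config$p_between, NA_character_)
  }

  # anchor: every block member not yet an endpoint of a block-labelled edge
  # gets one outgoing labelled edge, so induced subgraphs contain all members
  all_noise <- do.call(rbind, noise_edges)
  anchor_edges <- list()
  for (b in seq_len(config$n_subgraphs)) {
    covered <- unique(c(
      unlist(lapply(chain_edges, function(e) {
        if (!is.null(e) && identical(e$label[1], labels[b])) c(e$subject, e$object)
        else character(0)
      })),
      if (!is.null(all_noise)) {
        blk <- all_noise[!is.na(all_noise$label) & all_noise$label == labels[b], ,
                         drop = FALSE]
        c(blk$subject, blk$object)
      } else character(0)
    ))
    lonely <- setdiff(block_members[[b]], covered)
    if (!length(lonely)) next
    targets_pool <- setdiff(block_members[[b]], protected)
    for (k in lonely) {
      pool <- setdiff(targets_pool, k)
      if (!length(pool)) next
      anchor_edges[[length(anchor_edges) + 1L]] <- data.frame(
        subject = k, relation = "regulates",
        object = pool[sample.int(length(pool), 1L)],
        label = labels[b], stringsAsFactors = FALSE
      )
    }
  }

  edges <- do.call(rbind, c(chain_edges, list(controller_edges), noise_edges, anchor_edges))
  rownames(edges) <- NULL
  relations <- data.frame(
    subject = edges$subject, relation = edges$relation, object = edges$object,
    citation_type = "PubMed",
    citation_id = sprintf("%d", 10000L + seq_len(nrow(edges))),
    stringsAsFactors = FALSE
  )
  relations$subgraphs <- I(lapply(edges$label, function(lb) {
    if (is.na(lb)) character(0) else lb
  }))

  all_entities <- unique(do.call(rbind, entities))
  assembly <- knowledge_assembly(all_entities, relations,
                                 subgraph_inventory = labels)

  # emission-time assertion: every planted path is still uniquely shortest
  if (length(path_truth)) {
    g <- assembly_igraph(assembly, causal_only = TRUE, directed = TRUE)
    for (i in seq_along(path_truth)) {
      p <- path_truth[[i]]
      d <- suppressWarnings(
        igraph::distances(g, v = p[1], to = p[length(p)], mode = "out"))
      if (!is.finite(d) || d != length(p) - 1L) {
        cn_stop("comorbnet_config_error",
                "internal generator error: planted path %d is no longer shortest", i)
      }
    }
  }

  truth <- structure(
    list(
      planted_labels = labels[config$planted_subgraphs],
      seed_genes = seed_genes,
      planted_paths = path_truth,
      pairs = do.call(rbind, pair_rows) %||% data.frame(source = character(0),
                                                        sink = character(0)),
      controller = controller_key,
      config = config
    ),
    class = "sim_ground_truth"
  )
  list(assembly = assembly, truth = truth)
}

#' Write a simulated corpus + assembly + ground truth side by side
#'
#' @param out_dir output directory (created if needed).
#' @param corpus_config a [corpus_sim_config()].
#' @param graph_config a [graph_sim_config()].
#' @return invisibly, the named character vector of written paths.
#' @export
simulate_to_files <- function(out_dir,
                              corpus_config = corpus_sim_config(),
                              graph_config = graph_sim_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim_c <- simulate_corpus(corpus_config)
  sim_a <- simulate_assembly(graph_config)
  paths <- c(
    corpus = file.path(out_dir, "corpus.tsv"),
    assembly = file.path(out_dir, "assembly.json"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  write_corpus_tsv(sim_c$index, paths[["corpus"]])
  write_nodelink(sim_a$assembly, paths[["assembly"]])
  truth <- list(
    planted_genes = sim_c$truth$planted_genes,
    planted_labels = I(sim_a$truth$planted_labels),
    planted_paths = sim_a$truth$planted_paths,
    controller = sim_a$truth$controller,
    seeds = list(corpus = corpus_config$seed, graph = graph_config$seed)
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
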