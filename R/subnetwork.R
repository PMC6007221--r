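# Mechanism-subnetwork extraction: the union of all tied shortest causal
# paths from drug-target sources to biological-process sinks, optionally
# augmented with common upstream controllers (direct causal regulators of
# on-path nodes belonging to at least two distinct source-sink pairs).

pair_key <- function(source, sink) paste(source, "->", sink)

#' Union of all shortest source-to-sink paths in an assembly
#'
#' For every (source, sink) pair, enumerates ALL unweighted shortest directed
#' paths over causal edges (association/correlation edges are excluded by
#' default) and unions them into one subnetwork. Relation polarity is carried
#' as edge metadata but does not affect path length. With
#' `direction = "undirected-fallback"`, pairs unreachable in the directed
#' graph are retried on the undirected projection and flagged.
#'
#' @param assembly a [knowledge_assembly()].
#' @param sources character vector of source entity keys (e.g. drug targets).
#' @param sinks character vector of sink entity keys (e.g. bioprocess or
#'   pathology nodes). Must be disjoint from `sources`.
#' @param causal_only restrict paths to causal relations? Default `TRUE`.
#' @param direction `"directed"` (default) or `"undirected-fallback"`.
#' @param all_paths keep all tied shortest paths (default) or just one per
#'   pair?
#' @return object of class `mechanism_subnetwork`: list with `nodes`,
#'   `entities`, `edges` (relation rows), `path_registry` (per-pair list of
#'   node sequences), `pairs` (data.frame with `source`, `sink`, `status` in
#'   ok/fallback/unreachable, and `length`), `controllers` (empty until
#'   [add_upstream_controllers()]), and `unreachable_pairs`.
#' @export
shortest_path_union <- function(assembly, sources, sinks, causal_only = TRUE,
                                direction = c("directed", "undirected-fallback"),
                                all_paths = TRUE) {
  stopifnot(inherits(assembly, "knowledge_assembly"))
  direction <- match.arg(direction)
  sources <- unique(as.character(sources))
  sinks <- unique(as.character(sinks))
  if (!length(sources) || !length(sinks)) {
    cn_stop("comorbnet_invalid_query", "sources and sinks must both be non-empty")
  }
  keys <- assembly$entities$key
  miss <- setdiff(c(sources, sinks), keys)
  if (length(miss)) {
    warning("identifiers not found in assembly: ", paste(miss, collapse = ", "))
  }
  sources <- intersect(sources, keys)
  sinks <- intersect(sinks, keys)
  if (!length(sources)) cn_stop("comorbnet_invalid_query", "no source identifier found in assembly")
  if (!length(sinks)) cn_stop("comorbnet_invalid_query", "no sink identifier found in assembly")
  if (length(intersect(sources, sinks))) {
    cn_stop("comorbnet_invalid_query", "sources and sinks must be disjoint")
  }

  g <- assembly_igraph(assembly, causal_only = causal_only, directed = TRUE)
  registry <- list()
  pair_rows <- list()
  for (s in sources) {
    for (t in sinks) {
      paths <- tryCatch(
        suppressWarnings(igraph::all_shortest_paths(g, from = s, to = t, mode = "out")$res),
        error = function(e) list()
      )
      status <- "ok"
      if (!length(paths) && direction == "undirected-fallback") {
        paths <- tryCatch(
          suppressWarnings(igraph::all_shortest_paths(g, from = s, to = t, mode = "all")$res),
          error = function(e) list()
        )
        if (length(paths)) status <- "fallback"
      }
      if (!length(paths)) {
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          source = s, sink = t, status = "unreachable", length = NA_integer_,
          stringsAsFactors = FALSE
        )
        next
      }
      node_paths <- lapply(paths, names)
      ord <- order(vapply(node_paths, paste, character(1), collapse = "|"))
      node_paths <- node_paths[ord]
      if (!all_paths) node_paths <- node_paths[1]
      registry[[pair_key(s, t)]] <- node_paths
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        source = s, sink = t, status = status,
        length = length(node_paths[[1]]) - 1L, stringsAsFactors = FALSE
      )
    }
  }
  pairs <- do.call(rbind, pair_rows)
  if (!length(registry)) {
    warning("no source-sink pair is reachable; empty subnetwork")
  }

  nodes <- unique(unlist(registry, use.names = FALSE)) %||% character(0)
  rel <- assembly$relations
  if (causal_only) rel <- rel[rel$relation %in% CAUSAL_RELATIONS, , drop = FALSE]
  keep_edge <- rep(FALSE, nrow(rel))
  fallback_pairs <- pairs$status == "fallback"
  for (pk in names(registry)) {
    undirected <- fallback_pairs[match(pk, pair_key(pairs$source, pairs$sink))]
    for (p in registry[[pk]]) {
      if (length(p) < 2) next
      from <- p[-length(p)]
      to <- p[-1]
      hit <- paste(rel$subject, rel$object, sep = "\r") %in% paste(from, to, sep = "\r")
      if (undirected) {
        hit <- hit | paste(rel$object, rel$subject, sep = "\r") %in%
          paste(from, to, sep = "\r")
      }
      keep_edge <- keep_edge | hit
    }
  }
  edges <- rel[keep_edge, , drop = FALSE]
  rownames(edges) <- NULL

  structure(
    list(
      nodes = sort(nodes),
      entities = assembly$entities[assembly$entities$key %in% nodes, , drop = FALSE],
      edges = edges,
      path_registry = registry,
      pairs = pairs,
      controllers = character(0),
      unreachable_pairs = pairs[pairs$status == "unreachable",
                                c("source", "sink"), drop = FALSE]
    ),
    class = "mechanism_subnetwork"
  )
}

#' @export
print.mechanism_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<mechanism_subnetwork> %d nodes, %d edges, %d path(s) over %d pair(s), %d controller(s), %d unreachable pair(s)\n",
    length(x$nodes), nrow(x$edges),
    sum(lengths(x$path_registry)), nrow(x$pairs) - nrow(x$unreachable_pairs),
    length(x$controllers), nrow(x$unreachable_pairs)
  ))
  invisible(x)
}

#' Add common upstream controllers to a mechanism subnetwork
#'
#' A node outside the subnetwork is added (with its connecting causal edges)
#' iff it has direct causal out-edges onto on-path nodes belonging to at
#' least two distinct source-sink pairs; such nodes provide regulatory
#' context shared between the extracted pathways. Registered paths and their
#' lengths are never modified.
#'
#' @param assembly the [knowledge_assembly()] the subnetwork was built from.
#' @param subnetwork a [shortest_path_union()] result over the same assembly.
#' @return the augmented `mechanism_subnetwork`, with controller keys in
#'   `$controllers`.
#' @export
add_upstream_controllers <- function(assembly, subnetwork) {
  stopifnot(inherits(assembly, "knowledge_assembly"),
            inherits(subnetwork, "mechanism_subnetwork"))
  registry <- subnetwork$path_registry
  if (!length(registry)) return(subnetwork)
  pair_nodes <- lapply(registry, function(paths) unique(unlist(paths, use.names = FALSE)))

  rel <- assembly$relations
  causal <- rel[rel$relation %in% CAUSAL_RELATIONS, , drop = FALSE]
  outside <- causal[!(causal$subject %in% subnetwork$nodes) &
                      causal$object %in% unlist(pair_nodes, use.names = FALSE), ,
                    drop = FALSE]
  if (!nrow(outside)) return(subnetwork)

  controllers <- character(0)
  keep_rows <- integer(0)
  for (u in unique(outside$subject)) {
    targets <- unique(outside$object[outside$subject == u])
    n_pairs <- sum(vapply(pair_nodes, function(pn) any(targets %in% pn), logical(1)))
    if (n_pairs >= 2L) {
      controllers <- c(controllers, u)
      keep_rows <- c(keep_rows, which(outside$subject == u))
    }
  }
  if (!length(controllers)) return(subnetwork)

  new_edges <- rbind(subnetwork$edges, outside[keep_rows, , drop = FALSE])
  rownames(new_edges) <- NULL
  nodes <- sort(unique(c(subnetwork$nodes, controllers)))
  subnetwork$nodes <- nodes
  subnetwork$entities <- assembly$entities[assembly$entities$key %in% nodes, , drop = FALSE]
  subnetwork$edges <- new_edges
  subnetwork$controllers <- sort(unique(controllers))
  subnetwork
}

#' Deterministic tabular summary of a mechanism subnetwork
#'
#' Orders nodes as sources first, then path interiors by distance from their
#' nearest source, then sinks, then controllers; also emits the edge table
#' and a per-pair path listing.
#'
#' @param subnetwork a [mechanism_subnetwork()].
#' @return list of class `subnetwork_summary` with data.frames `nodes`
#'   (`key`, `role`, `distance`), `edges`, and `paths` (`source`, `sink`,
#'   `length`, `path` as `a -> b -> c`).
#' @export
render_summary <- function(subnetwork) {
  stopifnot(inherits(subnetwork, "mechanism_subnetwork"))
  registry <- subnetwork$path_registry
  sources <- unique(subnetwork$pairs$source[subnetwork$pairs$status != "unreachable"])
  sinks <- unique(subnetwork$pairs$sink[subnetwork$pairs$status != "unreachable"])

  dist <- setNames(rep(Inf, length(subnetwork$nodes)), subnetwork$nodes)
  for (paths in registry) {
    for (p in paths) {
      d <- seq_along(p) - 1L
      dist[p] <- pmin(dist[p], d)
    }
  }
  role <- function(k) {
    if (k %in% subnetwork$controllers) "controller"
    else if (k %in% sources) "source"
    else if (k %in% sinks) "sink"
    else "interior"
  }
  nodes_df <- data.frame(
    key = subnetwork$nodes,
    role = vapply(subnetwork$nodes, role, character(1)),
    distance = as.numeric(dist[subnetwork$nodes]),
    stringsAsFactors = FALSE
  )
  role_rank <- c(source = 1, interior = 2, sink = 3, controller = 4)
  nodes_df <- nodes_df[order(role_rank[nodes_df$role], nodes_df$distance, nodes_df$key), ,
                       drop = FALSE]
  rownames(nodes_df) <- NULL

  edges_df <- subnetwork$edges[, c("subject", "relation", "object",
                                   "citation_type", "citation_id"), drop = FALSE]
  edges_df <- edges_df[order(edges_df$subject, edges_df$object, edges_df$relation,
                             edges_df$citation_type, edges_df$citation_id), , drop = FALSE]
  rownames(edges_df) <- NULL

  path_rows <- list()
  for (pk in sort(names(registry))) {
    for (p in registry[[pk]]) {
      path_rows[[length(path_rows) + 1L]] <- data.frame(
        source = p[1], sink = p[length(p)], length = length(p) - 1L,
        path = paste(p, collapse = " -> "), stringsAsFactors = FALSE
      )
    }
  }
  paths_df <- do.call(rbind, path_rows) %||% data.frame(
    source = character(0), sink = character(0), length = integer(0),
    path = character(0), stringsAsFactors = FALSE
  )
  if (nrow(paths_df)) {
    paths_df <- paths_df[order(paths_df$source, paths_df$sink, paths_df$path), ,
                         drop = FALSE]
    rownames(paths_df) <- NULL
  }
  structure(list(nodes = nodes_df, edges = edges_df, paths = paths_df),
            class = "subnetwork_summary")
}

#' @export
print.subnetwork_summary <- function(x, ...) {
  cat(sprintf("<subnetwork_summary> %d nodes, %d edges, %d paths\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$paths)))
  invisible(x)
}

#' Convert a mechanism subnetwork back to a knowledge assembly
#'
#' @param subnetwork a [mechanism_subnetwork()].
#' @return a [knowledge_assembly()] with the subnetwork's entities and edges.
#' @export
subnetwork_assembly <- function(subnetwork) {
  stopifnot(inherits(subnetwork, "mechanism_subnetwork"))
  knowledge_assembly(subnetwork$entities, subnetwork$edges)
}

#' Export an assembly or subnetwork to GraphML
#'
#' Vertices carry `func`, `namespace`, `name` attributes; edges carry
#' `relation` and citation attributes, for hand-off to visualization tools.
#'
#' @param x a [knowledge_assembly()] or [mechanism_subnetwork()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(x, path) {
  if (inherits(x, "mechanism_subnetwork")) x <- subnetwork_assembly(x)
  stopifnot(inherits(x, "knowledge_assembly"))
  g <- assembly_igraph(x, directed = TRUE)
  igraph::V(g)$func <- x$entities$func[match(igraph::V(g)$name, x$entities$key)]
  igraph::V(g)$namespace <- x$entities$namespace[match(igraph::V(g)$name, x$entities$key)]
  igraph::V(g)$label <- x$entities$name[match(igraph::V(g)$name, x$entities$key)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
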