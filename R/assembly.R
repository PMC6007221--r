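# Typed causal knowledge assemblies: biological entities connected by
# causal/associative relations, each backed by a citation and optionally
# annotated with mechanism subgraph labels.

BEL_FUNCTIONS <- c(
  abundance = "a", protein = "p", gene = "g", rna = "r",
  bioprocess = "bp", pathology = "path", complex = "complex"
)

CAUSAL_RELATIONS <- c("increases", "directly_increases",
                      "decreases", "directly_decreases", "regulates")
ALL_RELATIONS <- c(CAUSAL_RELATIONS,
                   "association", "positive_correlation", "negative_correlation")

GENE_LIKE_FUNCTIONS <- c("gene", "rna", "protein")

#' Canonical term string for a biological entity
#'
#' Entities are identified by the triple (function, namespace, name) and
#' rendered as `f(NS:Name)` with the name quoted when it contains characters
#' outside `[A-Za-z0-9_.-]`.
#'
#' @param func entity function, one of `r paste(names(BEL_FUNCTIONS), collapse=", ")`.
#' @param namespace short namespace string (e.g. HGNC, CHEBI, GO, MESH).
#' @param name entity name (may contain spaces; double quotes are not allowed).
#' @return character term string, e.g. `p(HGNC:SCN1A)`.
#' @export
entity_key <- function(func, namespace, name) {
  abbrev <- BEL_FUNCTIONS[func]
  quoted <- ifelse(grepl("[^A-Za-z0-9_.-]", name), paste0('"', name, '"'), name)
  sprintf("%s(%s:%s)", abbrev, namespace, quoted)
}

validate_entities <- function(entities) {
  need <- c("func", "namespace", "name")
  if (!is.data.frame(entities) || !all(need %in% names(entities))) {
    cn_stop("comorbnet_validation_error",
            "entities must be a data.frame with columns func, namespace, name")
  }
  if (nrow(entities)) {
    bad <- !(entities$func %in% names(BEL_FUNCTIONS))
    if (any(bad)) {
      cn_stop("comorbnet_validation_error", "unknown entity function '%s'",
              entities$func[bad][1])
    }
    if (any(!nzchar(entities$namespace)) || any(!nzchar(entities$name))) {
      cn_stop("comorbnet_validation_error", "entity namespace and name must be non-empty")
    }
    if (any(grepl('"', entities$namespace, fixed = TRUE)) ||
        any(grepl('"', entities$name, fixed = TRUE))) {
      cn_stop("comorbnet_validation_error",
              "double quotes are not allowed in namespaces or names")
    }
  }
  entities <- entities[, need, drop = FALSE]
  entities$key <- if (nrow(entities)) {
    entity_key(entities$func, entities$namespace, entities$name)
  } else character(0)
  if (anyDuplicated(entities$key)) {
    entities <- entities[!duplicated(entities$key), , drop = FALSE]
  }
  rownames(entities) <- NULL
  entities
}

empty_relations <- function() {
  data.frame(
    subject = character(0), relation = character(0), object = character(0),
    citation_type = character(0), citation_id = character(0),
    evidence = character(0), line = integer(0),
    subgraphs = I(list()), stringsAsFactors = FALSE
  )
}

validate_relations <- function(relations, entity_keys) {
  if (is.null(relations) || (is.data.frame(relations) && !nrow(relations))) {
    return(empty_relations())
  }
  need <- c("subject", "relation", "object", "citation_type", "citation_id")
  if (!is.data.frame(relations) || !all(need %in% names(relations))) {
    cn_stop("comorbnet_validation_error",
            "relations must be a data.frame with columns %s", paste(need, collapse = ", "))
  }
  if (is.null(relations$evidence)) relations$evidence <- NA_character_
  if (is.null(relations$line)) relations$line <- NA_integer_
  if (is.null(relations$subgraphs)) {
    relations$subgraphs <- I(replicate(nrow(relations), character(0), simplify = FALSE))
  }
  if (!is.list(relations$subgraphs)) {
    cn_stop("comorbnet_validation_error", "subgraphs must be a list column")
  }
  bad <- !(relations$relation %in% ALL_RELATIONS)
  if (any(bad)) {
    cn_stop("comorbnet_validation_error", "unknown relation '%s'", relations$relation[bad][1])
  }
  if (any(!nzchar(relations$citation_id)) || any(is.na(relations$citation_id))) {
    cn_stop("comorbnet_validation_error", "citation identifiers must be non-empty")
  }
  ev <- relations$evidence
  if (any(grepl('"', ev[!is.na(ev)], fixed = TRUE))) {
    cn_stop("comorbnet_validation_error", "double quotes are not allowed in evidence text")
  }
  missing_ep <- setdiff(unique(c(relations$subject, relations$object)), entity_keys)
  if (length(missing_ep)) {
    cn_stop("comorbnet_validation_error",
            "relation endpoint '%s' is not among the entities", missing_ep[1])
  }
  relations$subgraphs <- I(lapply(relations$subgraphs,
                                  function(s) sort(unique(as.character(s)))))
  rownames(relations) <- NULL
  relations[, c(need, "evidence", "line", "subgraphs")]
}

#' Construct a knowledge assembly
#'
#' A knowledge assembly is a typed causal graph: a set of biological entities
#' plus a multiset of relations (parallel edges from different citations are
#' kept separate), each carrying a citation, optional evidence text, and a
#' possibly empty set of mechanism subgraph labels.
#'
#' @param entities data.frame with columns `func` (one of
#'   `r paste(names(BEL_FUNCTIONS), collapse = ", ")`), `namespace`, `name`.
#' @param relations data.frame with columns `subject`, `relation`, `object`
#'   (subject/object are [entity_key()] strings), `citation_type`,
#'   `citation_id`, and optionally `evidence`, `line`, and a list column
#'   `subgraphs`.
#' @param subgraph_inventory optional character vector of known subgraph
#'   labels; must contain every label used on a relation. Defaults to the
#'   union of relation labels.
#' @return object of class `knowledge_assembly`.
#' @export
knowledge_assembly <- function(entities = NULL, relations = NULL,
                               subgraph_inventory = NULL) {
  if (is.null(entities)) {
    entities <- data.frame(func = character(0), namespace = character(0),
                           name = character(0), stringsAsFactors = FALSE)
  }
  entities <- validate_entities(entities)
  relations <- validate_relations(relations, entities$key)
  used <- as.character(sort(unique(unlist(relations$subgraphs, use.names = FALSE))))
  if (is.null(subgraph_inventory)) {
    subgraph_inventory <- used
  } else {
    subgraph_inventory <- sort(unique(as.character(subgraph_inventory)))
    missing <- setdiff(used, subgraph_inventory)
    if (length(missing)) {
      cn_stop("comorbnet_validation_error",
              "subgraph label '%s' used on a relation but absent from the inventory",
              missing[1])
    }
  }
  structure(
    list(entities = entities, relations = relations,
         subgraph_inventory = subgraph_inventory),
    class = "knowledge_assembly"
  )
}

#' @export
print.knowledge_assembly <- function(x, ...) {
  cat(sprintf("<knowledge_assembly> %d entities, %d relations, %d subgraph labels\n",
              nrow(x$entities), nrow(x$relations), length(x$subgraph_inventory)))
  invisible(x)
}

#' Build an assembly from statement-like rows
#'
#' Convenience constructor: each row gives subject and object as term strings
#' (e.g. `"p(HGNC:SCN1A)"`), a relation, a citation, and optional subgraph
#' labels; entities are derived from the terms.
#'
#' @param statements data.frame with columns `subject`, `relation`, `object`
#'   (term strings), `citation_type`, `citation_id`, optional `evidence` and
#'   list column `subgraphs`.
#' @param subgraph_inventory optional label inventory (see
#'   [knowledge_assembly()]).
#' @return a `knowledge_assembly`.
#' @export
assembly_from_statements <- function(statements, subgraph_inventory = NULL) {
  terms <- unique(c(statements$subject, statements$object))
  parsed <- lapply(terms, parse_bel_term)
  entities <- data.frame(
    func = vapply(parsed, `[[`, character(1), "func"),
    namespace = vapply(parsed, `[[`, character(1), "namespace"),
    name = vapply(parsed, `[[`, character(1), "name"),
    stringsAsFactors = FALSE
  )
  keys <- setNames(entity_key(entities$func, entities$namespace, entities$name), terms)
  statements$subject <- unname(keys[statements$subject])
  statements$object <- unname(keys[statements$object])
  knowledge_assembly(entities, statements, subgraph_inventory)
}

#' Induce the subgraph of an assembly carrying a given mechanism label
#'
#' @param assembly a [knowledge_assembly()].
#' @param label a subgraph label from the assembly's inventory.
#' @return a `knowledge_assembly` containing exactly the relations annotated
#'   with `label` and their endpoint entities; its inventory is `label`.
#' @export
induce_subgraph <- function(assembly, label) {
  stopifnot(inherits(assembly, "knowledge_assembly"))
  if (!is_nonempty_string(label) || !(label %in% assembly$subgraph_inventory)) {
    cn_stop("comorbnet_not_found",
            "unknown subgraph label '%s'; valid labels: %s",
            as.character(label)[1] %||% "<missing>",
            paste(assembly$subgraph_inventory, collapse = ", "))
  }
  keep <- vapply(assembly$relations$subgraphs, function(s) label %in% s, logical(1))
  rel <- assembly$relations[keep, , drop = FALSE]
  # the induced assembly is scoped to this one label
  rel$subgraphs <- I(replicate(nrow(rel), label, simplify = FALSE))
  eps <- unique(c(rel$subject, rel$object))
  ents <- assembly$entities[assembly$entities$key %in% eps, , drop = FALSE]
  knowledge_assembly(ents, rel, subgraph_inventory = label)
}

#' Convert an assembly to an igraph graph
#'
#' @param assembly a [knowledge_assembly()].
#' @param causal_only keep only causal relations
#'   (`r paste(CAUSAL_RELATIONS, collapse = ", ")`)?
#' @param directed build a directed graph?
#' @return an [igraph::graph] whose vertex names are entity keys; edges carry
#'   `relation`, `citation_type`, `citation_id` attributes. Entities without
#'   relations are isolated vertices.
#' @export
assembly_igraph <- function(assembly, causal_only = FALSE, directed = TRUE) {
  stopifnot(inherits(assembly, "knowledge_assembly"))
  rel <- assembly$relations
  if (causal_only) rel <- rel[rel$relation %in% CAUSAL_RELATIONS, , drop = FALSE]
  edges <- data.frame(
    from = rel$subject, to = rel$object, relation = rel$relation,
    citation_type = rel$citation_type, citation_id = rel$citation_id,
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(
    edges, directed = directed,
    vertices = data.frame(name = assembly$entities$key, stringsAsFactors = FALSE)
  )
}

count_components <- function(assembly) {
  if (!nrow(assembly$entities)) return(0L)
  g <- assembly_igraph(assembly, directed = TRUE)
  igraph::components(g, mode = "weak")$no
}

distinct_citations <- function(relations) {
  if (!nrow(relations)) return(0L)
  length(unique(paste(relations$citation_type, relations$citation_id, sep = "\r")))
}

#' Per-mechanism summary statistics of an assembly
#'
#' For every label in the inventory, reports the induced subgraph's entity
#' and relationship counts, the number of weakly connected components of its
#' undirected projection, and its number of distinct citations; a final
#' `Total` row summarizes the full assembly with distinct unions (so the
#' total citation count can be smaller than the per-label sum, since one
#' article can support several mechanisms).
#'
#' @param assembly a [knowledge_assembly()].
#' @return data.frame with columns `label`, `n_entities`, `n_relationships`,
#'   `n_connected_components`, `n_citations`; last row is `Total`.
#' @export
summarize_subgraphs <- function(assembly) {
  stopifnot(inherits(assembly, "knowledge_assembly"))
  labels <- assembly$subgraph_inventory
  rows <- lapply(labels, function(lb) {
    sub <- induce_subgraph(assembly, lb)
    data.frame(
      label = lb,
      n_entities = nrow(sub$entities),
      n_relationships = nrow(sub$relations),
      n_connected_components = count_components(sub),
      n_citations = distinct_citations(sub$relations),
      stringsAsFactors = FALSE
    )
  })
  total <- data.frame(
    label = "Total",
    n_entities = nrow(assembly$entities),
    n_relationships = nrow(assembly$relations),
    n_connected_components = count_components(assembly),
    n_citations = distinct_citations(assembly$relations),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, c(rows, list(total)))
  rownames(out) <- NULL
  out
}
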