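# Lossless node-link JSON serialization of knowledge assemblies. Top-level
# keys: entities[], relations[], subgraph_inventory[]. Entities are emitted
# sorted by (function, namespace, name); relations keep their row order.

nl_require <- function(x, field, where) {
  if (is.null(x)) {
    cn_stop("comorbnet_validation_error", "node-link JSON: missing field '%s.%s'",
            where, field)
  }
  x
}

nl_entity <- function(e, where) {
  list(
    func = as.character(nl_require(e[["function"]], "function", where)),
    namespace = as.character(nl_require(e$namespace, "namespace", where)),
    name = as.character(nl_require(e$name, "name", where))
  )
}

#' Write an assembly as node-link JSON
#'
#' @param assembly a [knowledge_assembly()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_nodelink <- function(assembly, path) {
  stopifnot(inherits(assembly, "knowledge_assembly"))
  ents <- assembly$entities
  ord <- order(ents$func, ents$namespace, ents$name, method = "radix")
  ents <- ents[ord, , drop = FALSE]
  ent_payload <- lapply(seq_len(nrow(ents)), function(i) {
    list(`function` = ents$func[i], namespace = ents$namespace[i], name = ents$name[i])
  })
  key_to_idx <- setNames(seq_len(nrow(ents)), ents$key)
  rel <- assembly$relations
  rel_payload <- lapply(seq_len(nrow(rel)), function(i) {
    entity_obj <- function(k) {
      j <- key_to_idx[[k]]
      list(`function` = ents$func[j], namespace = ents$namespace[j], name = ents$name[j])
    }
    r <- list(
      subject = entity_obj(rel$subject[i]),
      relation = rel$relation[i],
      object = entity_obj(rel$object[i]),
      citation = list(type = rel$citation_type[i], identifier = rel$citation_id[i]),
      subgraphs = I(as.character(rel$subgraphs[[i]]))
    )
    if (!is.na(rel$evidence[i])) r$evidence <- rel$evidence[i]
    r
  })
  payload <- list(
    entities = ent_payload,
    relations = rel_payload,
    subgraph_inventory = I(assembly$subgraph_inventory)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an assembly from node-link JSON
#'
#' @param path input file path.
#' @return a [knowledge_assembly()].
#' @export
read_nodelink <- function(path) {
  if (!file.exists(path)) cn_stop("comorbnet_io_error", "cannot read file '%s'", path)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ents_raw <- nl_require(x$entities, "entities", "$")
  rels_raw <- nl_require(x$relations, "relations", "$")
  inventory <- unlist(x$subgraph_inventory, use.names = FALSE)

  ents <- lapply(seq_along(ents_raw), function(i) {
    nl_entity(ents_raw[[i]], sprintf("entities[%d]", i))
  })
  entities <- data.frame(
    func = vapply(ents, `[[`, character(1), "func"),
    namespace = vapply(ents, `[[`, character(1), "namespace"),
    name = vapply(ents, `[[`, character(1), "name"),
    stringsAsFactors = FALSE
  )

  rel_rows <- lapply(seq_along(rels_raw), function(i) {
    r <- rels_raw[[i]]
    where <- sprintf("relations[%d]", i)
    s <- nl_entity(nl_require(r$subject, "subject", where), paste0(where, ".subject"))
    o <- nl_entity(nl_require(r$object, "object", where), paste0(where, ".object"))
    cit <- nl_require(r$citation, "citation", where)
    list(
      subject = entity_key(s$func, s$namespace, s$name),
      relation = as.character(nl_require(r$relation, "relation", where)),
      object = entity_key(o$func, o$namespace, o$name),
      citation_type = as.character(nl_require(cit$type, "citation.type", where)),
      citation_id = as.character(nl_require(cit$identifier, "citation.identifier", where)),
      evidence = if (is.null(r$evidence)) NA_character_ else as.character(r$evidence),
      subgraphs = sort(unique(unlist(r$subgraphs, use.names = FALSE) %||% character(0)))
    )
  })
  relations <- if (length(rel_rows)) {
    df <- data.frame(
      subject = vapply(rel_rows, `[[`, character(1), "subject"),
      relation = vapply(rel_rows, `[[`, character(1), "relation"),
      object = vapply(rel_rows, `[[`, character(1), "object"),
      citation_type = vapply(rel_rows, `[[`, character(1), "citation_type"),
      citation_id = vapply(rel_rows, `[[`, character(1), "citation_id"),
      evidence = vapply(rel_rows, `[[`, character(1), "evidence"),
      stringsAsFactors = FALSE
    )
    df$subgraphs <- I(lapply(rel_rows, `[[`, "subgraphs"))
    df
  } else {
    NULL
  }
  knowledge_assembly(entities, relations,
                     subgraph_inventory = if (is.null(inventory)) NULL else inventory)
}
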