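# Report assembly: TSV writers with a `#` metadata header, and the command
# bodies behind the umbrella command-line script shipped in
# inst/scripts/comorbnet.R.

report_header <- function(command, seed = NULL, config = NULL) {
  h <- c(
    sprintf("# comorbnet %s", as.character(utils::packageVersion("comorbnet"))),
    sprintf("# command: %s", command)
  )
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", seed))
  if (!is.null(config)) {
    h <- c(h, sprintf("# config: %s",
                      jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)))
  }
  h
}

write_report_tsv <- function(df, path, command, seed = NULL, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(report_header(command, seed, config), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Comorbidity pleiotropy report over a corpus index
#'
#' For each comorbidity term, runs the single-term query (documents and
#' associated genes), the AND-query joined with the index-disease term
#' (comorbidity-associated genes), and reports the pleiotropy rate against
#' the index disease's associated-gene total; rows are ordered by rate,
#' descending.
#'
#' @param corpus a [corpus_index()] (or path to a corpus TSV).
#' @param index_term disease term of the index disease (e.g. `"epilepsy"`).
#' @param comorbidity_terms character vector of comorbidity disease terms
#'   (may be empty: the report is then header-only).
#' @param out output TSV path, or `NULL` to skip writing.
#' @param pseudocount smoothing pseudocount (see [relative_entropy_score()]).
#' @param seed recorded in the metadata header (reports are deterministic;
#'   the seed documents the provenance of simulated corpora).
#' @return data.frame with columns `disease`, `n_documents`,
#'   `n_disease_genes`, `n_comorbidity_genes`, `pleiotropy_rate`, invisibly
#'   when `out` is given.
#' @export
cmd_pleiotropy <- function(corpus, index_term, comorbidity_terms, out = NULL,
                           pseudocount = 0.5, seed = NULL) {
  if (is.character(corpus)) corpus <- read_corpus_tsv(corpus)
  stopifnot(inherits(corpus, "corpus_index"))
  n_index <- length(associated_genes(corpus, index_term, pseudocount))
  if (n_index == 0) {
    cn_stop("comorbnet_invalid_input",
            "no gene is associated with index term '%s'", index_term)
  }
  rows <- lapply(comorbidity_terms, function(term) {
    docs <- run_query(corpus, disease_query(term))
    n_genes <- length(associated_genes(corpus, term, pseudocount))
    n_joint <- length(associated_genes(corpus, c(index_term, term), pseudocount))
    pr <- pleiotropy_rate(n_joint, n_index, term)
    data.frame(
      disease = term, n_documents = length(docs), n_disease_genes = n_genes,
      n_comorbidity_genes = n_joint, pleiotropy_rate = pr$rate_percent,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows) %||% data.frame(
    disease = character(0), n_documents = integer(0), n_disease_genes = integer(0),
    n_comorbidity_genes = integer(0), pleiotropy_rate = numeric(0),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    df <- df[order(-df$pleiotropy_rate, df$disease), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (!is.null(out)) {
    write_report_tsv(df, out, "pleiotropy", seed,
                     config = list(index_term = index_term,
                                   n_index_genes = n_index))
    return(invisible(df))
  }
  df
}

format_enrichment_df <- function(scores, selected) {
  data.frame(
    label = scores$label,
    n_mapped = scores$n_mapped,
    coverage = round(scores$coverage, 6),
    specificity = round(scores$specificity, 6),
    score = round(scores$score, 6),
    hypergeom_p = signif(scores$hypergeom_p, 6),
    selected = scores$label %in% selected,
    stringsAsFactors = FALSE
  )
}

#' Mechanism enrichment report for one assembly
#'
#' @param assembly a [knowledge_assembly()] (or path to node-link JSON).
#' @param seeds a [seed_set()], character vector, or path to a seed file.
#' @param fraction top fraction selected (see [select_top_percentile()]).
#' @param out output TSV path, or `NULL`.
#' @param seed recorded in the metadata header.
#' @return the enrichment data.frame (label, n_mapped, coverage, specificity,
#'   score, hypergeom_p, selected), invisibly when `out` is given.
#' @export
cmd_enrich <- function(assembly, seeds, fraction = 0.10, out = NULL, seed = NULL) {
  if (is.character(assembly)) assembly <- read_nodelink(assembly)
  if (is.character(seeds) && length(seeds) == 1 && file.exists(seeds)) {
    seeds <- read_seed_set(seeds)
  }
  scores <- score_subgraphs(assembly, seeds)
  selected <- select_top_percentile(scores, fraction)
  df <- format_enrichment_df(scores, selected)
  df <- df[order(-df$score, df$label), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(out)) {
    write_report_tsv(df, out, "enrich", seed, config = list(fraction = fraction))
    return(invisible(df))
  }
  df
}

#' Comparative mechanism enrichment report across two assemblies
#'
#' @param assemblies list of exactly two [knowledge_assembly()]s (or node-link
#'   JSON paths).
#' @param context_labels length-2 character vector naming the contexts.
#' @inheritParams cmd_enrich
#' @return data.frame with one column block per context plus the shared flag,
#'   invisibly when `out` is given.
#' @export
cmd_compare <- function(assemblies, seeds, fraction = 0.10,
                        context_labels = c("A", "B"), out = NULL, seed = NULL) {
  if (length(assemblies) != 2) {
    cn_stop("comorbnet_usage_error", "compare requires exactly two assemblies, got %d",
            length(assemblies))
  }
  assemblies <- lapply(assemblies, function(a) {
    if (is.character(a)) read_nodelink(a) else a
  })
  if (is.character(seeds) && length(seeds) == 1 && file.exists(seeds)) {
    seeds <- read_seed_set(seeds)
  }
  res <- comparative_enrichment(assemblies[[1]], assemblies[[2]], seeds, fraction,
                                context_labels = context_labels)
  blocks <- lapply(seq_along(res$contexts), function(i) {
    ctx <- res$contexts[i]
    df <- format_enrichment_df(res$scores[[i]], res$selected[[i]])
    df$normalized_label <- normalize_subgraph_label(df$label)
    names(df)[names(df) != "normalized_label"] <-
      paste(names(df)[names(df) != "normalized_label"], ctx, sep = "_")
    df
  })
  merged <- merge(blocks[[1]], blocks[[2]], by = "normalized_label", all = TRUE)
  merged$shared <- merged$normalized_label %in% res$shared
  merged <- merged[order(-merged$shared, merged$normalized_label), , drop = FALSE]
  rownames(merged) <- NULL
  if (!is.null(out)) {
    write_report_tsv(merged, out, "compare", seed,
                     config = list(fraction = fraction,
                                   contexts = I(res$contexts)))
    return(invisible(merged))
  }
  merged
}

#' Extract and export a mechanism subnetwork
#'
#' Runs [shortest_path_union()] (plus [add_upstream_controllers()] unless
#' disabled) and writes the subnetwork as node-link JSON, GraphML and a path
#' listing TSV under `out_dir`.
#'
#' @param assembly a [knowledge_assembly()] or node-link JSON path.
#' @param sources,sinks entity keys (or paths to one-key-per-line files).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param causal_only,direction see [shortest_path_union()].
#' @param controllers add common upstream controllers?
#' @param seed recorded in metadata headers.
#' @return the [mechanism_subnetwork()], invisibly when `out_dir` is given.
#' @export
cmd_paths <- function(assembly, sources, sinks, out_dir = NULL,
                      causal_only = TRUE, direction = "directed",
                      controllers = TRUE, seed = NULL) {
  if (is.character(assembly) && length(assembly) == 1 && file.exists(assembly)) {
    assembly <- read_nodelink(assembly)
  }
  read_keys <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      v <- trimws(readLines(x, warn = FALSE))
      v[nzchar(v) & !startsWith(v, "#")]
    } else {
      x
    }
  }
  sn <- shortest_path_union(assembly, read_keys(sources), read_keys(sinks),
                            causal_only = causal_only, direction = direction)
  if (controllers) sn <- add_upstream_controllers(assembly, sn)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_nodelink(subnetwork_assembly(sn), file.path(out_dir, "subnetwork.json"))
    write_graphml(sn, file.path(out_dir, "subnetwork.graphml"))
    summary <- render_summary(sn)
    write_report_tsv(summary$paths, file.path(out_dir, "paths.tsv"), "paths", seed)
    write_report_tsv(summary$nodes, file.path(out_dir, "nodes.tsv"), "paths", seed)
    return(invisible(sn))
  }
  sn
}

#' Per-mechanism summary report of an assembly
#'
#' @param assembly a [knowledge_assembly()], node-link JSON path, or BEL
#'   Script path (`.bel` extension).
#' @param out output TSV path, or `NULL`.
#' @param lenient tolerate out-of-dialect BEL lines (see
#'   [parse_bel_subset()])?
#' @param seed recorded in the metadata header.
#' @return the [summarize_subgraphs()] data.frame, invisibly when `out` is
#'   given.
#' @export
cmd_summarize <- function(assembly, out = NULL, lenient = FALSE, seed = NULL) {
  if (is.character(assembly) && length(assembly) == 1) {
    assembly <- if (grepl("\\.bel$", assembly, ignore.case = TRUE)) {
      read_bel(assembly, lenient = lenient)
    } else {
      read_nodelink(assembly)
    }
  }
  df <- summarize_subgraphs(assembly)
  skipped <- attr(assembly, "skipped")
  if (!is.null(skipped) && nrow(skipped)) {
    message(sprintf("summarize: %d out-of-dialect line(s) skipped", nrow(skipped)))
  }
  if (!is.null(out)) {
    write_report_tsv(df, out, "summarize", seed)
    return(invisible(df))
  }
  df
}
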