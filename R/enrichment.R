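# Seed-gene (drug-target) mechanism enrichment over annotated subgraphs.
# Scores are relative: they feed a top-percentile selection rule, not an
# absolute significance call; a hypergeometric tail probability is reported
# alongside as a calibrated companion.

DEFAULT_SYMBOL_NAMESPACES <- c("HGNC", "SYMBOL")

#' Construct a seed gene set
#'
#' @param genes non-empty character vector of gene symbols (uppercased).
#' @param provenance free-text description of where the set came from, e.g.
#'   `"carbamazepine targets, PharmGKB"`.
#' @return object of class `seed_set`.
#' @export
seed_set <- function(genes, provenance = "") {
  genes <- unique(toupper(as.character(genes)))
  genes <- genes[nzchar(genes) & !is.na(genes)]
  if (!length(genes)) {
    cn_stop("comorbnet_usage_error", "seed set must contain at least one gene symbol")
  }
  structure(list(genes = sort(genes), provenance = provenance), class = "seed_set")
}

#' Read a seed set from a text file (one symbol per line)
#'
#' Blank lines and `#` comment lines are ignored.
#'
#' @param path file path.
#' @param provenance free-text provenance.
#' @return a [seed_set()].
#' @export
read_seed_set <- function(path, provenance = path) {
  if (!file.exists(path)) cn_stop("comorbnet_io_error", "cannot read seed file '%s'", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    cn_stop("comorbnet_usage_error", "seed file '%s' contains no gene symbols", path)
  }
  seed_set(lines, provenance)
}

as_seed_genes <- function(seeds) {
  if (inherits(seeds, "seed_set")) seeds$genes else seed_set(seeds)$genes
}

# Uppercased symbols of gene-like entities (gene/rna/protein under a
# gene-symbol namespace) in an assembly.
gene_like_symbols <- function(assembly,
                              symbol_namespaces = DEFAULT_SYMBOL_NAMESPACES) {
  e <- assembly$entities
  keep <- e$func %in% GENE_LIKE_FUNCTIONS &
    toupper(e$namespace) %in% toupper(symbol_namespaces)
  sort(unique(toupper(e$name[keep])))
}

#' Map seed genes onto mechanism subgraphs
#'
#' A seed maps to a subgraph iff some gene, RNA or protein entity of the
#' induced subgraph has that symbol as its name under a gene-symbol
#' namespace; matching is case-insensitive.
#'
#' @param assembly a [knowledge_assembly()].
#' @param seeds a [seed_set()] or character vector of symbols.
#' @param symbol_namespaces namespaces treated as carrying gene symbols.
#' @return named list: subgraph label -> character vector of mapped seeds.
#' @export
map_seed_genes <- function(assembly, seeds,
                           symbol_namespaces = DEFAULT_SYMBOL_NAMESPACES) {
  stopifnot(inherits(assembly, "knowledge_assembly"))
  genes <- as_seed_genes(seeds)
  out <- lapply(assembly$subgraph_inventory, function(lb) {
    intersect(genes, gene_like_symbols(induce_subgraph(assembly, lb), symbol_namespaces))
  })
  setNames(out, assembly$subgraph_inventory)
}

#' Score one mechanism subgraph against a seed set
#'
#' The score is the geometric mean of coverage (mapped seeds over seeds
#' present anywhere in the assembly) and specificity (mapped seeds over
#' gene-like entities of the subgraph), in `[0, 1]`; it is 0 exactly when no
#' seed maps. `hypergeom_p` is the upper-tail hypergeometric probability of
#' observing at least as many seed hits when drawing the subgraph's gene-like
#' entities from the assembly's gene-like universe.
#'
#' @inheritParams map_seed_genes
#' @param label subgraph label.
#' @return object of class `subgraph_score` with fields `label`,
#'   `mapped_genes`, `n_mapped`, `coverage`, `specificity`, `score`,
#'   `hypergeom_p`.
#' @export
score_subgraph <- function(assembly, label, seeds,
                           symbol_namespaces = DEFAULT_SYMBOL_NAMESPACES) {
  stopifnot(inherits(assembly, "knowledge_assembly"))
  genes <- as_seed_genes(seeds)
  universe <- gene_like_symbols(assembly, symbol_namespaces)
  seeds_present <- intersect(genes, universe)
  sub_genes <- gene_like_symbols(induce_subgraph(assembly, label), symbol_namespaces)
  mapped <- intersect(genes, sub_genes)
  coverage <- if (length(seeds_present)) length(mapped) / length(seeds_present) else 0
  specificity <- if (length(sub_genes)) length(mapped) / length(sub_genes) else 0
  p <- if (length(sub_genes) && length(seeds_present)) {
    phyper(length(mapped) - 1L, length(seeds_present),
           length(universe) - length(seeds_present), length(sub_genes),
           lower.tail = FALSE)
  } else {
    1
  }
  structure(
    list(
      label = label, mapped_genes = mapped, n_mapped = length(mapped),
      coverage = coverage, specificity = specificity,
      score = sqrt(coverage * specificity), hypergeom_p = p
    ),
    class = "subgraph_score"
  )
}

#' @export
print.subgraph_score <- function(x, ...) {
  cat(sprintf("<subgraph_score> %s: %d mapped, score %.3f (p=%.3g)\n",
              x$label, x$n_mapped, x$score, x$hypergeom_p))
  invisible(x)
}

#' Score every mechanism subgraph against a seed set
#'
#' @inheritParams map_seed_genes
#' @return data.frame with one row per inventory label: `label`, `n_mapped`,
#'   `coverage`, `specificity`, `score`, `hypergeom_p`, plus a list column
#'   `mapped_genes`.
#' @export
score_subgraphs <- function(assembly, seeds,
                            symbol_namespaces = DEFAULT_SYMBOL_NAMESPACES) {
  scores <- lapply(assembly$subgraph_inventory, function(lb) {
    score_subgraph(assembly, lb, seeds, symbol_namespaces)
  })
  out <- data.frame(
    label = vapply(scores, `[[`, character(1), "label"),
    n_mapped = vapply(scores, `[[`, integer(1), "n_mapped"),
    coverage = vapply(scores, `[[`, numeric(1), "coverage"),
    specificity = vapply(scores, `[[`, numeric(1), "specificity"),
    score = vapply(scores, `[[`, numeric(1), "score"),
    hypergeom_p = vapply(scores, `[[`, numeric(1), "hypergeom_p"),
    stringsAsFactors = FALSE
  )
  out$mapped_genes <- I(lapply(scores, `[[`, "mapped_genes"))
  out
}

#' Select the top score percentile among candidate subgraphs
#'
#' Candidates are subgraphs with at least one mapped seed. The selection
#' keeps candidates whose score is at least the empirical `1 - fraction`
#' quantile (linear interpolation) of candidate scores; ties at the threshold
#' are included, so the selection is never empty when candidates exist.
#' With twelve distinctly scored candidates and the default fraction, two are
#' selected.
#'
#' @param scores data.frame from [score_subgraphs()] (or any data.frame with
#'   columns `label`, `n_mapped`, `score`).
#' @param fraction top fraction kept, in (0, 1); default 0.10.
#' @return character vector of selected labels (empty, with a warning, when
#'   no subgraph has a mapped seed).
#' @export
select_top_percentile <- function(scores, fraction = 0.10) {
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1) {
    cn_stop("comorbnet_invalid_input", "fraction must lie strictly between 0 and 1")
  }
  need <- c("label", "n_mapped", "score")
  if (!is.data.frame(scores) || !all(need %in% names(scores))) {
    cn_stop("comorbnet_invalid_input", "scores must have columns %s",
            paste(need, collapse = ", "))
  }
  cand <- scores[scores$n_mapped >= 1L, , drop = FALSE]
  if (!nrow(cand)) {
    warning("no subgraph has a mapped seed gene; empty selection")
    return(character(0))
  }
  thr <- quantile(cand$score, probs = 1 - fraction, type = 7, names = FALSE)
  sort(cand$label[cand$score >= thr])
}

#' Normalize a mechanism subgraph label for cross-context matching
#'
#' Lowercases, trims, and strips a trailing "subgraph"/"sub-graph" suffix so
#' that differently styled labels of the same mechanism compare equal.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalize_subgraph_label <- function(x) {
  trimws(gsub("[-_ ]*sub[-_ ]?graphs?$", "", tolower(trimws(x))))
}

#' Comparative mechanism enrichment across two disease contexts
#'
#' Runs scoring and top-percentile selection independently in each context
#' and intersects the selections after label normalization (lowercasing and
#' stripping a trailing "subgraph"/"sub-graph" suffix), so that, e.g.,
#' `"Gaba sub-graph"` in one assembly matches `"GABA subgraph"` in the other.
#'
#' @param assembly_a,assembly_b the two context [knowledge_assembly()]s.
#' @param seeds a [seed_set()] or character vector of symbols.
#' @param fraction top fraction kept per context (see
#'   [select_top_percentile()]).
#' @param context_labels length-2 character vector naming the contexts.
#' @inheritParams map_seed_genes
#' @return object of class `comparative_result`: list with `contexts`,
#'   per-context `scores` and `selected`, `shared` (normalized labels), and
#'   `shared_scores` (data.frame of per-label score pairs).
#' @export
comparative_enrichment <- function(assembly_a, assembly_b, seeds, fraction = 0.10,
                                   context_labels = c("A", "B"),
                                   symbol_namespaces = DEFAULT_SYMBOL_NAMESPACES) {
  stopifnot(inherits(assembly_a, "knowledge_assembly"),
            inherits(assembly_b, "knowledge_assembly"),
            length(context_labels) == 2L)
  sa <- score_subgraphs(assembly_a, seeds, symbol_namespaces)
  sb <- score_subgraphs(assembly_b, seeds, symbol_namespaces)
  sel_a <- select_top_percentile(sa, fraction)
  sel_b <- select_top_percentile(sb, fraction)
  na <- normalize_subgraph_label(sel_a)
  nb <- normalize_subgraph_label(sel_b)
  shared <- sort(intersect(na, nb))
  shared_scores <- do.call(rbind, lapply(shared, function(s) {
    la <- sel_a[match(s, na)]
    lb <- sel_b[match(s, nb)]
    data.frame(
      shared_label = s,
      label_a = la, score_a = sa$score[match(la, sa$label)],
      label_b = lb, score_b = sb$score[match(lb, sb$label)],
      stringsAsFactors = FALSE
    )
  })) %||% data.frame(shared_label = character(0), label_a = character(0),
                      score_a = numeric(0), label_b = character(0),
                      score_b = numeric(0), stringsAsFactors = FALSE)
  structure(
    list(
      contexts = context_labels,
      scores = setNames(list(sa, sb), context_labels),
      selected = setNames(list(sel_a, sel_b), context_labels),
      shared = shared,
      shared_scores = shared_scores
    ),
    class = "comparative_result"
  )
}

#' @export
print.comparative_result <- function(x, ...) {
  cat(sprintf("<comparative_result> %s: %d selected; %s: %d selected; %d shared\n",
              x$contexts[1], length(x$selected[[1]]),
              x$contexts[2], length(x$selected[[2]]), length(x$shared)))
  invisible(x)
}
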