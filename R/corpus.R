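# Document-level co-occurrence index over a literature corpus: each document
# carries a set of tagged disease terms and a set of mentioned gene symbols.
# Emulates the query layer of a literature search engine indexed over MEDLINE.

#' Construct a literature co-occurrence index
#'
#' A corpus index records, per document, the disease terms it is tagged with
#' and the gene symbols it mentions. Presence/absence is at document level;
#' mention counts are deliberately not modelled.
#'
#' @param documents character vector of unique document identifiers.
#' @param doc_diseases named list mapping document id -> character vector of
#'   disease-term identifiers. Documents absent from the list carry no terms.
#' @param doc_genes named list mapping document id -> character vector of gene
#'   symbols (uppercased on input).
#' @return an object of class `corpus_index`.
#' @examples
#' ci <- corpus_index(c("d1", "d2"),
#'                    doc_diseases = list(d1 = "epilepsy", d2 = c("epilepsy", "diabetes")),
#'                    doc_genes = list(d1 = "SCN1A", d2 = c("SCN1A", "GABRA1")))
#' @export
corpus_index <- function(documents, doc_diseases = list(), doc_genes = list()) {
  documents <- as.character(documents)
  if (anyDuplicated(documents)) {
    cn_stop("comorbnet_validation_error", "duplicate document identifiers")
  }
  if (length(documents) && any(!nzchar(documents) | is.na(documents))) {
    cn_stop("comorbnet_validation_error", "document identifiers must be non-empty")
  }
  check_map <- function(m, what) {
    if (is.null(m)) m <- list()
    if (!is.list(m)) cn_stop("comorbnet_validation_error", "%s must be a named list", what)
    if (length(m) && (is.null(names(m)) || !all(names(m) %in% documents))) {
      cn_stop("comorbnet_validation_error",
              "every key of %s must be a known document identifier", what)
    }
    m
  }
  doc_diseases <- check_map(doc_diseases, "doc_diseases")
  doc_genes <- check_map(doc_genes, "doc_genes")

  norm <- function(m, upper) {
    full <- setNames(vector("list", length(documents)), documents)
    for (d in documents) {
      v <- as.character(m[[d]] %||% character(0))
      v <- v[!is.na(v)]
      if (upper) v <- toupper(v)
      if (any(!nzchar(v))) {
        cn_stop("comorbnet_validation_error", "empty identifier in document '%s'", d)
      }
      full[[d]] <- unique(v)
    }
    full
  }
  structure(
    list(
      documents = documents,
      doc_diseases = norm(doc_diseases, upper = FALSE),
      doc_genes = norm(doc_genes, upper = TRUE)
    ),
    class = "corpus_index"
  )
}

#' @export
print.corpus_index <- function(x, ...) {
  cat(sprintf(
    "<corpus_index> %d documents, %d disease terms, %d gene symbols\n",
    length(x$documents),
    length(unique(unlist(x$doc_diseases, use.names = FALSE))),
    length(unique(unlist(x$doc_genes, use.names = FALSE)))
  ))
  invisible(x)
}

#' Construct a disease query
#'
#' A query is one disease term, or several joined with AND semantics
#' (documents must carry every term), mirroring how comorbidity gene sets are
#' retrieved by joining a comorbidity term with the index-disease term.
#'
#' @param terms non-empty character vector of disease-term identifiers.
#' @return an object of class `disease_query` with fields `terms` and
#'   `combinator` (`"single"` iff exactly one term, else `"and"`).
#' @export
disease_query <- function(terms) {
  terms <- unique(as.character(terms))
  if (!length(terms) || any(!nzchar(terms) | is.na(terms))) {
    cn_stop("comorbnet_invalid_query", "query terms must be a non-empty set of identifiers")
  }
  structure(
    list(terms = terms, combinator = if (length(terms) == 1L) "single" else "and"),
    class = "disease_query"
  )
}

#' Run a disease query against a corpus index
#'
#' @param index a [corpus_index()].
#' @param query a [disease_query()] (a bare character vector is promoted).
#' @return character vector of document identifiers whose disease-term set
#'   contains every query term.
#' @examples
#' ci <- corpus_index(c("d1", "d2"),
#'                    doc_diseases = list(d1 = "epilepsy", d2 = c("epilepsy", "diabetes")))
#' run_query(ci, disease_query(c("epilepsy", "diabetes")))  # "d2"
#' @export
run_query <- function(index, query) {
  stopifnot(inherits(index, "corpus_index"))
  if (!inherits(query, "disease_query")) query <- disease_query(query)
  hit <- vapply(index$doc_diseases, function(terms) all(query$terms %in% terms), logical(1))
  index$documents[hit[index$documents]]
}

# Per-gene document counts inside a document set.
gene_doc_counts <- function(index, docs) {
  genes <- unlist(index$doc_genes[docs], use.names = FALSE)
  if (!length(genes)) return(integer(0))
  tab <- table(genes)
  setNames(as.integer(tab), names(tab))
}

check_background <- function(index, query_docs) {
  query_docs <- unique(as.character(query_docs))
  if (!all(query_docs %in% index$documents)) {
    cn_stop("comorbnet_invalid_query", "query_docs contains unknown document identifiers")
  }
  if (!length(query_docs)) {
    cn_stop("comorbnet_undefined_background", "empty query document set: background undefined")
  }
  complement <- setdiff(index$documents, query_docs)
  if (!length(complement)) {
    cn_stop("comorbnet_undefined_background",
            "query matches the whole corpus: background undefined")
  }
  list(query_docs = query_docs, complement = complement)
}

# Vectorized relative-entropy machinery shared by the scalar scorer and
# associated_genes(). Smoothed document frequencies:
#   p = (k_q + pc) / (n_q + 2 pc),  b likewise over the complement,
#   RE = p * ln(p / b)   (positive iff p > b, since p > 0).
relative_entropy_table <- function(index, query_docs, genes, pseudocount = 0.5) {
  sets <- check_background(index, query_docs)
  if (!is_scalar_number(pseudocount) || pseudocount <= 0) {
    cn_stop("comorbnet_invalid_input", "pseudocount must be a positive number")
  }
  nq <- length(sets$query_docs)
  nb <- length(sets$complement)
  cq <- gene_doc_counts(index, sets$query_docs)
  cb <- gene_doc_counts(index, sets$complement)
  kq <- ifelse(genes %in% names(cq), cq[genes], 0L)
  kb <- ifelse(genes %in% names(cb), cb[genes], 0L)
  p <- (kq + pseudocount) / (nq + 2 * pseudocount)
  b <- (kb + pseudocount) / (nb + 2 * pseudocount)
  data.frame(
    gene = genes,
    n_query_docs = as.integer(kq),
    n_background_docs = as.integer(kb),
    in_query_freq = as.numeric(p),
    background_freq = as.numeric(b),
    relative_entropy = as.numeric(p * log(p / b)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Relative-entropy association score of one gene for a query
#'
#' Compares the smoothed document frequency of a gene inside a query's
#' document set against its frequency in the rest of the corpus, via the
#' single-gene Kullback-Leibler term `p * ln(p/b)` (in nats). The score is
#' positive exactly when the gene is more frequent inside the query results,
#' which is the criterion used to call a gene "associated".
#'
#' @param index a [corpus_index()].
#' @param query_docs documents returned by [run_query()]; must be a proper
#'   non-empty subset of the corpus.
#' @param gene gene symbol (case-insensitive).
#' @param pseudocount symmetric smoothing pseudocount added to both mention
#'   and non-mention counts (default 0.5).
#' @return an object of class `gene_association_score` with fields `gene`,
#'   `in_query_freq`, `background_freq`, `relative_entropy`.
#' @export
relative_entropy_score <- function(index, query_docs, gene, pseudocount = 0.5) {
  stopifnot(inherits(index, "corpus_index"))
  if (!is_nonempty_string(gene)) cn_stop("comorbnet_invalid_input", "gene must be one symbol")
  row <- relative_entropy_table(index, query_docs, toupper(gene), pseudocount)
  structure(as.list(row[1, c("gene", "in_query_freq", "background_freq", "relative_entropy")]),
            class = "gene_association_score")
}

#' @export
print.gene_association_score <- function(x, ...) {
  cat(sprintf("<gene_association_score> %s: p=%.4g b=%.4g RE=%.4g nats\n",
              x$gene, x$in_query_freq, x$background_freq, x$relative_entropy))
  invisible(x)
}

#' Genes associated with a disease query
#'
#' Returns the genes mentioned in at least one query document whose
#' relative-entropy score is strictly positive (more frequent inside the
#' query's documents than in the rest of the corpus). Note that a sign-only
#' rule has no multiplicity control: under a null corpus roughly half of the
#' mentioned genes land on the positive side. Pass `alpha` to additionally
#' require a one-sided hypergeometric enrichment p-value at most `alpha`.
#'
#' @inheritParams relative_entropy_score
#' @param query a [disease_query()] or character vector of terms.
#' @param alpha optional significance level for the hypergeometric filter;
#'   `NULL` (default) applies the sign criterion alone.
#' @return sorted character vector of associated gene symbols.
#' @export
associated_genes <- function(index, query, pseudocount = 0.5, alpha = NULL) {
  stopifnot(inherits(index, "corpus_index"))
  if (!inherits(query, "disease_query")) query <- disease_query(query)
  qd <- run_query(index, query)
  sets <- check_background(index, qd)
  mentioned <- sort(unique(unlist(index$doc_genes[sets$query_docs], use.names = FALSE)))
  if (!length(mentioned)) return(character(0))
  tab <- relative_entropy_table(index, qd, mentioned, pseudocount)
  keep <- tab$relative_entropy > 0
  if (!is.null(alpha)) {
    nq <- length(sets$query_docs)
    n_tot <- length(index$documents)
    k_tot <- tab$n_query_docs + tab$n_background_docs
    pval <- phyper(tab$n_query_docs - 1L, k_tot, n_tot - k_tot, nq, lower.tail = FALSE)
    keep <- keep & pval <= alpha
  }
  sort(tab$gene[keep])
}

#' Read/write a corpus index as TSV
#'
#' Columns: `document_id`, `disease_terms` (semicolon-separated),
#' `gene_symbols` (semicolon-separated). Empty cells mean no annotation.
#'
#' @param path file path.
#' @return [read_corpus_tsv()] returns a [corpus_index()];
#'   [write_corpus_tsv()] returns `path` invisibly.
#' @export
read_corpus_tsv <- function(path) {
  if (!file.exists(path)) cn_stop("comorbnet_io_error", "cannot read corpus file '%s'", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character", comment.char = "#")
  need <- c("document_id", "disease_terms", "gene_symbols")
  if (!all(need %in% names(df))) {
    cn_stop("comorbnet_validation_error", "corpus TSV must have columns %s",
            paste(need, collapse = ", "))
  }
  split_cell <- function(x) {
    v <- strsplit(x %||% "", ";", fixed = TRUE)[[1]]
    v[nzchar(v)]
  }
  corpus_index(
    documents = df$document_id,
    doc_diseases = setNames(lapply(df$disease_terms, split_cell), df$document_id),
    doc_genes = setNames(lapply(df$gene_symbols, split_cell), df$document_id)
  )
}

#' @param index a [corpus_index()].
#' @rdname read_corpus_tsv
#' @export
write_corpus_tsv <- function(index, path) {
  stopifnot(inherits(index, "corpus_index"))
  df <- data.frame(
    document_id = index$documents,
    disease_terms = vapply(index$doc_diseases[index$documents],
                           paste, character(1), collapse = ";"),
    gene_symbols = vapply(index$doc_genes[index$documents],
                          paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_corpus_tsv
#' @export
read_corpus_json <- function(path) {
  if (!file.exists(path)) cn_stop("comorbnet_io_error", "cannot read corpus file '%s'", path)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("documents", "doc_diseases", "doc_genes")) {
    if (is.null(x[[field]])) {
      cn_stop("comorbnet_validation_error", "corpus JSON is missing field '%s'", field)
    }
  }
  corpus_index(
    documents = unlist(x$documents, use.names = FALSE),
    doc_diseases = lapply(x$doc_diseases, function(v) unlist(v, use.names = FALSE)),
    doc_genes = lapply(x$doc_genes, function(v) unlist(v, use.names = FALSE))
  )
}

#' @rdname read_corpus_tsv
#' @export
write_corpus_json <- function(index, path) {
  stopifnot(inherits(index, "corpus_index"))
  payload <- list(
    documents = index$documents,
    doc_diseases = lapply(index$doc_diseases, function(v) I(v)),
    doc_genes = lapply(index$doc_genes, function(v) I(v))
  )
  jsonlite::write_json(payload, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
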