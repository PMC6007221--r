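# Pleiotropy rates, prevalence ratios, and their rank correlation.

#' Epilepsy pleiotropy rate
#'
#' The pleiotropy rate of a comorbidity is the percentage of genes associated
#' with the joint comorbidity-AND-index-disease query among all genes
#' associated with the index disease. Reported rates are truncated (not
#' rounded) at two decimals; the raw value is retained.
#'
#' @param n_comorbidity_genes non-negative integer count of genes associated
#'   with the joint query.
#' @param n_index_genes positive integer count of genes associated with the
#'   index disease alone (the denominator, e.g. 2901 for epilepsy).
#' @param comorbidity optional disease-term identifier carried through.
#' @return object of class `pleiotropy_result` with fields `comorbidity`,
#'   `n_comorbidity_genes`, `n_index_genes`, `rate_percent` (truncated) and
#'   `rate_raw`.
#' @examples
#' pleiotropy_rate(184, 2901)$rate_percent  # 6.34
#' pleiotropy_rate(306, 2901)$rate_percent  # 10.54 (10.5481 truncates)
#' @export
pleiotropy_rate <- function(n_comorbidity_genes, n_index_genes, comorbidity = NA_character_) {
  if (!is_scalar_number(n_index_genes) || n_index_genes <= 0) {
    cn_stop("comorbnet_invalid_input", "n_index_genes must be a positive integer")
  }
  if (!is_scalar_number(n_comorbidity_genes) || n_comorbidity_genes < 0) {
    cn_stop("comorbnet_invalid_input", "n_comorbidity_genes must be a non-negative integer")
  }
  raw <- 100 * n_comorbidity_genes / n_index_genes
  structure(
    list(
      comorbidity = comorbidity,
      n_comorbidity_genes = as.integer(n_comorbidity_genes),
      n_index_genes = as.integer(n_index_genes),
      rate_percent = trunc_decimals(raw, 2),
      rate_raw = raw
    ),
    class = "pleiotropy_result"
  )
}

#' @export
print.pleiotropy_result <- function(x, ...) {
  cat(sprintf("<pleiotropy_result> %s: %d / %d = %.2f%%\n",
              x$comorbidity %||% "?", x$n_comorbidity_genes, x$n_index_genes,
              x$rate_percent))
  invisible(x)
}

#' Prevalence ratio of a condition in an index-disease population
#'
#' Ratio of the prevalence of a condition among patients with the index
#' disease to its prevalence in the general population, from epidemiological
#' studies. Values above 1 indicate the condition is over-represented among
#' index-disease patients.
#'
#' @param prevalence_epilepsy prevalence (percent, > 0) among index-disease
#'   patients.
#' @param prevalence_general prevalence (percent, > 0) in the general
#'   population.
#' @param condition optional disease-term identifier.
#' @return object of class `prevalence_record`.
#' @examples
#' prevalence_ratio(5.71, 3.47)$prevalence_ratio  # migraine, ~1.65
#' @export
prevalence_ratio <- function(prevalence_epilepsy, prevalence_general,
                             condition = NA_character_) {
  if (!is_scalar_number(prevalence_epilepsy) || prevalence_epilepsy <= 0 ||
      !is_scalar_number(prevalence_general) || prevalence_general <= 0) {
    cn_stop("comorbnet_invalid_input", "prevalences must be positive numbers")
  }
  structure(
    list(
      condition = condition,
      prevalence_epilepsy = prevalence_epilepsy,
      prevalence_general = prevalence_general,
      prevalence_ratio = prevalence_epilepsy / prevalence_general
    ),
    class = "prevalence_record"
  )
}

as_condition_df <- function(x, value_field, cls) {
  if (is.data.frame(x)) return(x)
  if (is.list(x) && all(vapply(x, inherits, logical(1), cls))) {
    key <- if (cls == "pleiotropy_result") "comorbidity" else "condition"
    return(data.frame(
      condition = vapply(x, function(r) as.character(r[[key]]), character(1)),
      value = vapply(x, function(r) r[[value_field]], numeric(1)),
      stringsAsFactors = FALSE
    ))
  }
  cn_stop("comorbnet_invalid_input", "expected a data.frame or a list of %s objects", cls)
}

#' Rank correlation of pleiotropy rates against prevalence ratios
#'
#' Matches prevalence records and pleiotropy results by condition identifier
#' and computes Spearman's rank correlation over the matched pairs. Unmatched
#' conditions are excluded and reported via a message.
#'
#' @param records list of [prevalence_ratio()] objects, or a data.frame with
#'   columns `condition` and `value` (the prevalence ratio).
#' @param rates list of [pleiotropy_rate()] objects, or a data.frame with
#'   columns `condition` and `value` (the rate).
#' @return list with `estimate` (rho), `p_value`, `n` matched pairs, and
#'   `excluded` (unmatched condition identifiers).
#' @export
correlate_rates <- function(records, rates) {
  a <- as_condition_df(records, "prevalence_ratio", "prevalence_record")
  b <- as_condition_df(rates, "rate_raw", "pleiotropy_result")
  shared <- intersect(a$condition, b$condition)
  excluded <- setdiff(union(a$condition, b$condition), shared)
  if (length(excluded)) {
    message("correlate_rates: excluding unmatched conditions: ",
            paste(sort(excluded), collapse = ", "))
  }
  if (length(shared) < 3) {
    cn_stop("comorbnet_insufficient_data",
            "need at least 3 matched condition pairs, got %d", length(shared))
  }
  x <- a$value[match(shared, a$condition)]
  y <- b$value[match(shared, b$condition)]
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(
    estimate = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(shared),
    excluded = sort(excluded)
  )
}

#' Published comorbidity co-occurrence counts for epilepsy
#'
#' Packaged plain-text table of the published epilepsy comorbidity analysis:
#' per disease, the MeSH identifier, the number of retrieved documents, the
#' number of disease-associated genes, the number of genes associated with
#' the joint disease-AND-epilepsy query, and the reported pleiotropy rate in
#' percent. The epilepsy row carries the denominator (2901 associated genes)
#' and has no comorbidity columns. The stroke row's reported rate is
#' inconsistent with the stated formula (633/2901 would give 21.82, not
#' 17.78) and is flagged by `consistent = FALSE` in [pleiotropy_table()].
#'
#' @return data.frame with columns `disease`, `mesh_id`, `n_documents`,
#'   `n_disease_genes`, `n_comorbidity_genes`, `reported_rate_percent`.
#' @export
epilepsy_comorbidity_counts <- function() {
  path <- system.file("extdata", "epilepsy_comorbidity_counts.tsv",
                      package = "comorbnet", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Recompute pleiotropy rates from a counts table
#'
#' Applies [pleiotropy_rate()] to each comorbidity row of a counts table (as
#' returned by [epilepsy_comorbidity_counts()]), using the index-disease row
#' (the one with missing comorbidity count) as the denominator, and compares
#' against the reported rate when present.
#'
#' @param counts data.frame as returned by [epilepsy_comorbidity_counts()].
#' @return data.frame ordered by recomputed rate (descending) with columns
#'   `disease`, `n_comorbidity_genes`, `n_index_genes`, `rate_percent`,
#'   `rate_raw`, `reported_rate_percent`, `consistent`.
#' @export
pleiotropy_table <- function(counts = epilepsy_comorbidity_counts()) {
  idx <- which(is.na(counts$n_comorbidity_genes))
  if (length(idx) != 1) {
    cn_stop("comorbnet_invalid_input",
            "counts must contain exactly one index-disease row (NA comorbidity count)")
  }
  denom <- counts$n_disease_genes[idx]
  rows <- counts[-idx, , drop = FALSE]
  res <- lapply(seq_len(nrow(rows)), function(i) {
    pleiotropy_rate(rows$n_comorbidity_genes[i], denom, rows$disease[i])
  })
  out <- data.frame(
    disease = rows$disease,
    n_comorbidity_genes = rows$n_comorbidity_genes,
    n_index_genes = denom,
    rate_percent = vapply(res, `[[`, numeric(1), "rate_percent"),
    rate_raw = vapply(res, `[[`, numeric(1), "rate_raw"),
    reported_rate_percent = rows$reported_rate_percent,
    stringsAsFactors = FALSE
  )
  out$consistent <- !is.na(out$reported_rate_percent) &
    abs(out$rate_percent - out$reported_rate_percent) < 1e-9
  out[order(-out$rate_percent, out$disease), , drop = FALSE]
}
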