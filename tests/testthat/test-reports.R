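# Hand-built corpus small enough to verify the pleiotropy report against an
# independent per-gene frequency computation.
report_corpus <- function() {
  corpus_index(
    c("e1", "e2", "em", "ed", "m1", "d1", "b1", "b2"),
    doc_diseases = list(
      e1 = "epilepsy", e2 = "epilepsy",
      em = c("epilepsy", "migraine"), ed = c("epilepsy", "diabetes"),
      m1 = "migraine", d1 = "diabetes"
    ),
    doc_genes = list(
      e1 = c("SCN1A", "GABRA1"), e2 = c("SCN1A", "KCNQ2"),
      em = c("SCN1A", "CACNA1A"), ed = c("INS", "SCN1A"),
      m1 = "CACNA1A", d1 = "INS",
      b1 = "ACTB", b2 = "ACTB"
    )
  )
}

# independent oracle: smoothed document-frequency comparison done inline
oracle_associated <- function(index, terms, pc = 0.5) {
  qd <- index$documents[vapply(index$doc_diseases,
                               function(v) all(terms %in% v), logical(1))[index$documents]]
  cd <- setdiff(index$documents, qd)
  genes <- unique(unlist(index$doc_genes[qd]))
  pos <- character(0)
  for (g in genes) {
    kq <- sum(vapply(index$doc_genes[qd], function(v) g %in% v, logical(1)))
    kb <- sum(vapply(index$doc_genes[cd], function(v) g %in% v, logical(1)))
    p <- (kq + pc) / (length(qd) + 2 * pc)
    b <- (kb + pc) / (length(cd) + 2 * pc)
    if (p * log(p / b) > 0) pos <- c(pos, g)
  }
  sort(pos)
}

test_that("the pleiotropy report matches an independent frequency computation", {
  ci <- report_corpus()
  df <- cmd_pleiotropy(ci, "epilepsy", c("migraine", "diabetes"))
  expect_equal(nrow(df), 2L)
  n_index <- length(oracle_associated(ci, "epilepsy"))
  for (term in c("migraine", "diabetes")) {
    row <- df[df$disease == term, ]
    expect_equal(row$n_documents,
                 sum(vapply(ci$doc_diseases, function(v) term %in% v, logical(1))))
    joint <- oracle_associated(ci, c("epilepsy", term))
    expect_equal(row$n_comorbidity_genes, length(joint))
    expect_equal(row$pleiotropy_rate,
                 trunc(round(100 * length(joint) / n_index * 100, 6)) / 100)
  }
  expect_true(all(diff(df$pleiotropy_rate) <= 0))
})

test_that("report files carry metadata headers and empty queries give header-only tables", {
  ci <- report_corpus()
  out <- withr::local_tempfile(fileext = ".tsv")
  cmd_pleiotropy(ci, "epilepsy", character(0), out = out)
  lines <- readLines(out)
  expect_true(any(startsWith(lines, "# comorbnet")))
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1L)  # column header only
  expect_match(body, "^disease\t")
})

test_that("a known counts row renders its truncated rate in the report table", {
  tab <- pleiotropy_table()
  expect_equal(tab$rate_percent[tab$n_comorbidity_genes == 184], 6.34)
  out <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  reread <- read.delim(out)
  expect_equal(reread$rate_percent[reread$n_comorbidity_genes == 184], 6.34)
})

test_that("enrichment and comparison commands mirror the underlying modules", {
  sim <- simulate_assembly(graph_sim_config(seed = 44))
  out <- withr::local_tempfile(fileext = ".tsv")
  df <- cmd_enrich(sim$assembly, sim$truth$seed_genes, out = out)
  expect_setequal(df$label[df$selected], sim$truth$planted_labels)
  expect_true(file.exists(out))

  cmp <- cmd_compare(list(sim$assembly, sim$assembly), sim$truth$seed_genes,
                     context_labels = c("ctx1", "ctx2"))
  expect_setequal(cmp$label_ctx1[cmp$shared & cmp$selected_ctx1],
                  sim$truth$planted_labels)
  expect_error(cmd_compare(list(sim$assembly), sim$truth$seed_genes),
               class = "comorbnet_usage_error")

  empty_seeds <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("", "# only comments"), empty_seeds)
  expect_error(cmd_enrich(sim$assembly, empty_seeds),
               class = "comorbnet_usage_error")
})

test_that("the paths command writes subnetwork JSON, GraphML and listings", {
  sim <- simulate_assembly(graph_sim_config(seed = 45))
  dir <- withr::local_tempdir()
  sn <- cmd_paths(sim$assembly, sim$truth$pairs$source, sim$truth$pairs$sink,
                  out_dir = dir)
  expect_true(all(file.exists(file.path(dir, c("subnetwork.json",
                                               "subnetwork.graphml",
                                               "paths.tsv", "nodes.tsv")))))
  back <- read_nodelink(file.path(dir, "subnetwork.json"))
  expect_setequal(back$entities$key, sn$nodes)
})

test_that("summarize consumes node-link JSON and lenient BEL input", {
  fx <- test_path("fixtures", "toy_assembly.json")
  df <- cmd_summarize(fx)
  expect_equal(df$n_relationships[df$label == "Total"], 5L)
  bel <- system.file("extdata", "synthetic_epilepsy_sample.bel", package = "comorbnet")
  expect_message(df2 <- cmd_summarize(bel, lenient = TRUE), "skipped")
  expect_equal(df2$n_relationships[df2$label == "Total"], 8L)
})

test_that("identical command inputs give checksum-identical report files", {
  sim <- simulate_assembly(graph_sim_config(seed = 46))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  cmd_enrich(sim$assembly, sim$truth$seed_genes, out = f1, seed = 46)
  cmd_enrich(sim$assembly, sim$truth$seed_genes, out = f2, seed = 46)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("the umbrella script runs a subcommand end to end with exit code 0", {
  script <- system.file("scripts", "comorbnet.R", package = "comorbnet")
  expect_true(nzchar(script))
  dir <- withr::local_tempdir()
  out <- file.path(dir, "summary.tsv")
  fx <- normalizePath(test_path("fixtures", "toy_assembly.json"))
  res <- system2("Rscript", c(script, "summarize", "--assembly", shQuote(fx),
                              "--out", shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  expect_identical(attr(res, "status") %||% 0L, 0L)
  expect_true(file.exists(out))
  # usage errors exit with status 2
  res2 <- suppressWarnings(system2("Rscript", c(script, "compare"),
                                   stdout = TRUE, stderr = TRUE))
  expect_identical(attr(res2, "status"), 2L)
})
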