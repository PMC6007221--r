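Package: comorbnet
Title: Literature Co-Occurrence Pleiotropy and Knowledge-Graph Mechanism
    Enrichment for Disease Comorbidities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for hypothesizing mechanisms shared between a disease and
    its comorbidities. Implements document-level literature co-occurrence
    queries with relative-entropy gene association and pleiotropy rates, a
    minimal Biological Expression Language (BEL) subset for causal knowledge
    assemblies with per-mechanism summary statistics, seed-gene (drug-target)
    mechanism enrichment with top-percentile selection and two-context
    comparison, shortest-path mechanism-subnetwork extraction with common
    upstream controllers, and a synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
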