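---
title: "From literature co-occurrence to mechanism subnetworks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From literature co-occurrence to mechanism subnetworks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

comorbnet implements a two-stage strategy for hypothesizing mechanisms shared
between an index disease (the motivating case is epilepsy) and its
comorbidities. The first stage is gene-centric: literature co-occurrence is
used as a proxy for shared genetic architecture (pleiotropy). The second is
mechanism-centric: a curated causal knowledge graph, annotated with candidate
pathophysiological mechanisms, is queried with a drug's target genes to rank
mechanisms, compare them across two disease contexts, and extract an
interpretable subnetwork of causal paths from targets to phenotype-level
processes. This vignette explains the models behind each stage, the tunable
parameters and why they default where they do, what the synthetic-data
generator does and does not emulate, and the design decisions that were
genuinely open.

## Stage 1: co-occurrence pleiotropy

### The corpus model

A `corpus_index` is a set of documents, each tagged with disease terms and
mentioning gene symbols. Mentions are document-level presence/absence — the
simplest model consistent with "co-occurring in the literature". Counting
repeated mentions within an abstract would mostly reward verbose writing
styles, and the downstream criterion (below) only compares frequencies of
documents, so multiplicity is deliberately not modelled.

Disease queries have AND semantics: `disease_query(c("epilepsy",
"diabetes"))` returns documents tagged with *both* terms. This is how
comorbidity gene sets are built — a comorbidity term joined with the index
disease term — and it guarantees the monotonicity the tests assert: adding a
term can only shrink the result set.

### Relative-entropy association

A gene is called *associated* with a query when it occurs more frequently in
the query's documents than in the rest of the corpus. comorbnet quantifies
this with the single-gene Kullback–Leibler term on smoothed document
frequencies,

$$\mathrm{RE} = p \,\ln\!\frac{p}{b}, \qquad
p = \frac{k_q + c}{n_q + 2c}, \quad b = \frac{k_b + c}{n_b + 2c},$$

where $k_q$ of $n_q$ query documents mention the gene, $k_b$ of $n_b$
complement documents do, and $c$ is a symmetric pseudocount (default 0.5, a
Jeffreys-style half-count that keeps both frequencies strictly positive).
Because $p > 0$ always, $\mathrm{RE} > 0$ exactly when $p > b$: the sign of
the score *is* the association criterion, which is the property the original
two-stage filter relies on (genes mentioned in the query documents, then
restricted to those scoring positive). Only the sign and the relative
ordering of scores are ever used downstream, so the choice of the single KL
term over alternatives (full binary KL, log-odds) is immaterial to results
but guarantees the sign property by construction.

The background is the *complement of the query result*, not the whole
corpus. Using the whole corpus would contaminate the background with the
query documents themselves and shrink every contrast toward zero.

**Null calibration.** A sign-only rule has no multiplicity control. If a
gene's mention rate is identical inside and outside the query, the estimated
frequencies still differ by sampling noise, and the gene lands on the
positive side roughly half the time (just under one half, because exact ties
score zero). This is a structural property of any sign test, not an
implementation artifact, and the package's null simulations measure it at
around 45–55% of mentioned genes. Where a calibrated false-positive rate
matters, `associated_genes(..., alpha = 0.05)` additionally requires a
one-sided hypergeometric enrichment p-value, which brings the null call rate
down to the nominal few percent. The default remains the bare sign rule
because that is the published criterion the package reproduces.

### Pleiotropy rates and reporting

The pleiotropy rate of a comorbidity is
$100 \cdot n_{\text{joint}} / n_{\text{index}}$: the percentage of
joint-query-associated genes among all index-disease-associated genes
(denominator 2901 in the packaged epilepsy table). Reported rates are
**truncated** at two decimals, never rounded — the packaged table is only
reproducible under truncation (10.5481 prints as 10.54, 0.0689 as 0.06);
`pleiotropy_rate()` retains the raw float alongside. One row of the packaged
table (stroke: 633 genes, printed rate 17.78) is arithmetically inconsistent
with its own counts under any rounding convention; it is preserved verbatim,
flagged `consistent = FALSE`, and excluded from automated agreement checks.

`correlate_rates()` relates pleiotropy rates to epidemiological prevalence
ratios (condition prevalence among index-disease patients divided by
general-population prevalence) by Spearman rank correlation — chosen because
no distributional form is plausible for either quantity and only
monotonicity is scientifically meaningful. Pairs are matched by condition
identifier; unmatched conditions are excluded and reported, and fewer than
three matched pairs is an error rather than a meaningless coefficient.

## Stage 2: knowledge assemblies and mechanism enrichment

### The BEL-subset model

Causal knowledge is represented as a `knowledge_assembly`: typed entities
(abundance, protein, gene, RNA, biological process, pathology, complex)
identified by (function, namespace, name), connected by a multiset of
relations from the eight-relation vocabulary (five causal: increases,
directly_increases, decreases, directly_decreases, regulates; three
associative). Every relation carries a citation and an optional set of
mechanism subgraph labels. Parallel edges from different citations are kept
separate — curation happens at the statement level, and collapsing them
would silently discard evidence counts.

The parser covers a deliberately minimal dialect of BEL Script: simple
`f(NS:Name)` terms, the eight relations, and `SET`/`UNSET` of Citation,
Evidence and Subgraph. Modified or nested terms (protein modifications,
variants, translocations, composite complexes) raise parse errors rather
than degrading silently, because a half-parsed modification changes the
identity of a node. For third-party files, lenient mode counts and reports
out-of-dialect lines instead of failing, so the in-dialect fraction of a
full BEL document can still be summarized. Per-mechanism summaries report
entities, relationships, weakly connected components (on the undirected
projection — "connected groups of nodes" regardless of edge direction), and
distinct citations; the Total row uses distinct unions, so total citations
can be below the per-label sum when one article supports several mechanisms.

### Seed-gene enrichment scoring

Mechanism enrichment asks which labelled subgraphs a drug-target gene set
concentrates in. A seed maps to a subgraph when a gene/RNA/protein entity of
the induced subgraph bears its symbol under a gene-symbol namespace (HGNC by
default; configurable). Each subgraph is scored by the geometric mean

$$s = \sqrt{\text{coverage} \times \text{specificity}}, \qquad
\text{coverage} = \frac{|\text{mapped}|}{|\text{seeds in assembly}|}, \quad
\text{specificity} = \frac{|\text{mapped}|}{|\text{gene-like entities in
subgraph}|}.$$

The reference workflow's server-side scoring formula is not public; what is
documented is that its scores are *relative* and feed a top-percentile rule.
The geometric mean is adopted because it is the simplest score that (a) is 1
exactly when a subgraph contains all seeds and nothing else, (b) is 0 exactly
when nothing maps, and (c) penalizes both diluted mechanisms (huge subgraphs
with one target) and fragmentary ones. Since only ranks enter the selection,
any monotone recombination of coverage and specificity would select
identically. An upper-tail hypergeometric probability (seed hits when
drawing the subgraph's gene-like entities from the assembly's gene-like
universe) is reported alongside as a calibrated companion; it is
cross-checked against exhaustive enumeration in the tests.

Selection keeps the top decile by default: among *candidates* — subgraphs
with at least one mapped seed — those scoring at or above the empirical
90th percentile (linear interpolation, ties inclusive) are selected. The
candidate-restricted base set is one of two defensible readings of the
original description; it is the one that reproduces the documented behavior
of twelve candidate networks yielding two selections, and it keeps the rule
meaningful when most subgraphs map nothing. Ties at the threshold are
included, so a selection is never empty when candidates exist, and raising
the fraction never shrinks it.

Comparative enrichment runs the same seed set against two context
assemblies independently and intersects the selections after label
normalization (lowercasing, stripping a trailing "subgraph"/"sub-graph"),
since independently curated assemblies style the same mechanism name
differently.

### Mechanism subnetworks

`shortest_path_union()` extracts, for every (source, sink) pair — typically
drug targets and phenotype-level biological processes — **all** tied
shortest directed paths over causal edges, and unions them into one graph.
All tied paths, not an arbitrary one, because the construction merges paths
into a graph for interpretation, which presupposes multiplicity; a
single-path mode exists behind a flag. Edges are unweighted and polarity
(increases/decreases) rides along as metadata: no principled weighting
scheme is available, and a wrong weighting is worse than none.
Associative edges are excluded by default since the object of interest is a
causal chain from intervention to phenotype. Pairs unreachable in the
directed graph are recorded; an optional undirected fallback retries them on
the undirected projection and flags them as such rather than mixing them
silently with directed results.

"Common upstream controllers" are operationalized minimally: a node outside
the subnetwork is added when it has *direct* (1-hop) causal out-edges onto
on-path nodes of at least two distinct source–sink pairs. The 1-hop reading
is the weakest assumption that makes "common" and "upstream" precise;
augmentation only ever adds nodes and edges and provably never changes
registered path lengths (asserted in tests). The package stops at the merged
path-plus-controller graph — the manual interpretation step that produces a
simplified narrative figure is out of scope by design.

## The synthetic-data generator

Both generators exist to make every stage testable against planted ground
truth, with no external services.

`simulate_corpus()` draws each document's gene mentions as independent
Bernoulli variables: baseline probability 0.02 per gene, multiplied by an
enrichment factor (default 10) for genes planted in the document's disease
context. The default configuration — 400 background documents, 200
joint-context documents, a 300-gene vocabulary, 20 planted genes — is sized
so that a planted gene appears in roughly 40 query documents against a 2%
background, comfortably recoverable, while the corpus stays small enough for
hundreds of replicates in seconds. What the generator does *not* emulate:
correlated mentions (real genes co-occur in families), heavy-tailed document
lengths, mention-level counts, and MEDLINE-scale corpus sizes. Passing
recovery tests therefore demonstrate the scoring logic, not robustness to
the dependence structure of real literature.

`simulate_assembly()` builds labelled mechanism blocks (10 protein + 3
bioprocess entities each; within-block causal edge probability 0.12,
cross-block 0.01, cross-block edges deliberately unlabelled — connections
*between* mechanisms are not members of either). Seed genes enter every
planted block with probability `min(1, factor × baseline)` — 1 under the
defaults (factor 10, baseline 0.1). That choice is scientific, not
statistical: a drug target known to belong to a mechanism is a member of it,
not a probabilistic visitor; the baseline probability (0.1) governs stray
appearances elsewhere. A corollary is that planted blocks of equal size earn
exactly tied top scores, which the ties-inclusive percentile rule selects
jointly — so planted-mechanism recovery is sharp rather than borderline.
Planted source→sink chains and the shared controller are protected by
constraint-based rejection: candidate noise edges pointing *into* any
planted-path node or the controller are discarded during sampling. This
simultaneously guarantees (and the generator asserts post hoc via graph
distances) that planted paths stay uniquely shortest, and that the planted
controller is the only node causally feeding two pairs. Real knowledge
graphs offer no such protection; the guarantee is what makes exact-recovery
assertions meaningful, not a claim about curated data.

Identical configurations and seeds give byte-identical serialized output,
which the tests verify by checksum.

## Numerical choices and degenerate inputs

* Truncation at two decimals is implemented as truncation after a guard
  rounding at the sixth decimal, so binary floating-point noise immediately
  below an exact boundary cannot flip the reported digit.
* Quantiles use R's default type-7 (linear interpolation); with twelve
  distinct candidate scores the 90th percentile falls between the 10th and
  11th order statistics, which is what yields exactly two selections.
* Empty query results and queries matching the whole corpus are errors
  (the background frequency is undefined), as are seed sets with no symbols,
  fewer than three matched correlation pairs, and subgraph labels absent
  from the inventory (the error lists valid labels).
* A subgraph with no gene-like entities has specificity defined as 0 and
  score 0; it can never be selected.
* Tie-breaking everywhere is lexicographic (sorted labels, sorted node
  keys, paths ordered by their node sequence), so every report is
  deterministic and checksum-stable.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run: 200 random graphs (4–10
nodes) against an exhaustive path-enumeration oracle; hypergeometric tails
against exhaustive draw enumeration on universes up to 12; and 100 seeded
replicates each for corpus recovery (factor 10), corpus null calibration
(factor 1), mechanism-selection recovery, and controller recovery. These
sizes give stable rates (binomial standard error below 3 percentage points
at 100 replicates) while keeping the whole suite in well under five minutes
on a single core.

## Known limitations

* Document-level co-occurrence is a weak proxy for genetic pleiotropy; the
  package reproduces the published workflow and its published caveat (rates
  need not correlate with epidemiological prevalence ratios) rather than
  claiming validity of the proxy.
* The sign-only association rule is uncalibrated under the null (see
  above); use the `alpha` filter when false-positive control matters.
* The enrichment score is relative; absolute score values are not
  comparable across assemblies with different annotation densities, which
  is why comparative enrichment intersects *selections*, not scores.
* The BEL dialect is intentionally small; rich BEL documents lose their
  modified-term statements (counted, in lenient mode) and any entity that
  participates only in such statements.
* Controllers are 1-hop by definition here; multi-hop regulatory
  convergence is invisible to the current operationalization.
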