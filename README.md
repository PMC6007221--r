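# comorbnet

Tools for hypothesizing **mechanisms shared between a disease and its
comorbidities**, for computational biologists working at the interface of
literature mining and causal knowledge graphs. The motivating application is
epilepsy and its comorbid conditions (Alzheimer disease, migraine, Parkinson
disease, ...), but every component is generic.

The package implements a two-stage workflow:

1. **Co-occurrence pleiotropy.** Over a document–disease–gene index, a gene
   is *associated* with a disease query when its smoothed document frequency
   is higher inside the query's results than in the rest of the corpus —
   positive relative entropy, the single-gene KL term
   *RE = p·ln(p/b)* with *p = (k_q + c)/(n_q + 2c)* and *b* computed
   identically over the complement. The **pleiotropy rate** of a comorbidity
   is *100·n_joint/n_index*: the percentage of genes associated with the
   comorbidity-AND-index-disease query among all index-disease genes,
   reported truncated (not rounded) at two decimals. Spearman rank
   correlation relates these rates to epidemiological prevalence ratios.

2. **Mechanism enrichment and subnetworks.** Causal knowledge curated in a
   minimal subset of Biological Expression Language (BEL) is compiled into a
   typed knowledge assembly whose relations carry citations and mechanism
   subgraph labels. A drug-target seed set is mapped onto each mechanism and
   scored by *s = sqrt(coverage × specificity)* (with an upper-tail
   hypergeometric p-value as calibrated companion); the top decile of
   candidate mechanisms is selected, optionally compared across two disease
   contexts. Finally, the union of **all tied shortest causal paths** from
   targets to biological processes of interest is extracted and augmented
   with **common upstream controllers** (nodes with direct causal edges onto
   paths of at least two source–sink pairs).

A synthetic-data generator with planted ground truth (associated genes,
enriched mechanisms, shortest paths, controllers) makes the full pipeline
testable offline.

## Worked example

Recompute pleiotropy rates from the packaged co-occurrence counts table
(one row per comorbidity, 2901-gene denominator):

```r
library(comorbnet)
head(pleiotropy_table()[, c("disease", "n_comorbidity_genes", "rate_percent",
                            "reported_rate_percent", "consistent")], 5)
#>            disease n_comorbidity_genes rate_percent reported_rate_percent consistent
#>             Stroke                 633        21.82                 17.78      FALSE
#>  Alzheimer disease                 396        13.65                 13.65       TRUE
#>           Migraine                 306        10.54                 10.54       TRUE
#>  Parkinson disease                 258         8.89                  8.89       TRUE
#>       Hypertension                 252         8.68                  8.68       TRUE
```

396 of 2901 epilepsy-associated genes also associate with the joint
Alzheimer query: a 13.65% pleiotropy rate. The stroke row of the source
table is arithmetically inconsistent with its own counts (633/2901 = 21.82,
not 17.78) and is flagged rather than silently corrected.

Mechanism enrichment and subnetwork extraction on a simulated assembly with
two planted mechanisms, planted target→process chains and one planted shared
controller:

```r
sim <- simulate_assembly(graph_sim_config(seed = 7))
head(cmd_enrich(sim$assembly, sim$truth$seed_genes), 4)
#>         label n_mapped coverage specificity    score selected
#>  Mechanism 01        5      1.0    0.277778 0.527046     TRUE
#>  Mechanism 02        5      1.0    0.277778 0.527046     TRUE
#>  Mechanism 04        2      0.4    0.166667 0.258199    FALSE
#>  Mechanism 03        1      0.2    0.090909 0.134840    FALSE

sn <- cmd_paths(sim$assembly, sim$truth$pairs$source, sim$truth$pairs$sink)
sn
#> <mechanism_subnetwork> 9 nodes, 8 edges, 2 path(s) over 2 pair(s), 1 controller(s), 2 unreachable pair(s)
```

All five seed genes map into both planted mechanisms (coverage 1), which tie
at the top score and are jointly selected by the top-decile rule; the two
planted three-edge paths are recovered and the planted controller
(`p(HGNC:CTRL1)`) is the single added upstream node. The two cross pairs
(target of one mechanism to process of the other) are correctly reported
unreachable.

BEL-subset scripts and node-link JSON round-trip losslessly:

```r
a <- parse_bel_subset(c(
  'SET Citation = {"PubMed", "123"}',
  'SET Subgraph = "Gaba subgraph"',
  'p(HGNC:GABRA1) increases bp(GO:"inhibitory synaptic transmission")'
))
summarize_subgraphs(a)
#>           label n_entities n_relationships n_connected_components n_citations
#> 1 Gaba subgraph          2               1                      1           1
#> 2         Total          2               1                      1           1
```

A thin umbrella script exposes the same operations as subcommands
(`pleiotropy`, `enrich`, `compare`, `paths`, `summarize`, `simulate`):

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "comorbnet.R", package = "comorbnet"))')" \
  summarize --assembly assembly.json --out summary.tsv
```

See the vignette (`vignettes/comorbidity-mechanisms.Rmd`) for the models,
parameter defaults, generator design and known limitations.

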