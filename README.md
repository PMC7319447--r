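# seednet

Rule-defined microRNA networks, score overlays and hit-enrichment
statistics.

## What problem this solves

High-throughput miRNA experiments end in a long table: one mature miRNA
per row, one or more numeric scores per column (log2 fold change,
expression, a survival P-value, a screening phenotype). The biological
question is rarely about single rows — mature miRNAs sharing a **seed**
(nucleotides 2–7) repress overlapping target sets, miRNAs transcribed
from **neighboring genomic loci** are co-expressed as polycistrons, and
miRNAs with **overlapping predicted targets** act redundantly. `seednet`
builds these three relation graphs from miRBase-style annotation,
overlays the user's scores on the nodes, and quantifies whether the
high-scoring miRNAs ("hits") aggregate where biology predicts.

It is aimed at computational biologists who want the network
construction and the statistics scriptable and reproducible offline —
every input is a plain FASTA/GFF3/TSV file and every output is GraphML,
JSON, TSV or SVG.

## The statistics

* **Local binomial test** — with `p = n_hits / n_nodes` over the
  *measured* network nodes, a cluster/family with `n_c` measured nodes
  and `k` hits gets the upper-tail P-value `P(X ≥ k)`,
  `X ~ Binomial(n_c, p)`, summed exactly in log space. With a
  background of 44 hits among 241 measured miRNAs, a 48-node cluster
  holding 24 hits gives P = 6.1 × 10⁻⁷; a 7-node cluster with 2 hits
  gives P = 0.37.
* **Global permutation test** — counts *hit pairs* (edges whose both
  endpoints are hits) and compares against uniform reassignment of hit
  labels among measured nodes (hit total fixed). Strict tail plus an
  add-one corrected estimate, seed recorded.
* **Exact paired Wilcoxon signed-rank** — for family export designs
  (vesicle minus parental cell, per member and preparation). Exact
  enumeration (dynamic program) for ≤ 25 tie-free pairs: 10 same-sign
  differences give the minimal two-sided P = 2/2¹⁰ ≈ 0.002; 15 give
  2/2¹⁵ ≈ 6 × 10⁻⁵.
* **Hypergeometric target-set enrichment** per miRNA.

See `vignettes/mirna-networks.Rmd` for models, assumptions, parameter
defaults and numerical choices.

## Worked example

Everything below runs offline on the package's deterministic synthetic
fixtures (species code `syn`), which plant one enriched family against
a 10% hit background:

```r
library(seednet)

spec <- fixture_spec(rng_seed = 42,
                     planted_groups = list(list(group = "family_001",
                                                hit_probability = 0.9)))
ann    <- generate_annotation(spec)       # writes matures.fa + loci.gff3
net    <- build_seed_network(ann$matures)
net
#> miRNA network [Seed2_7]
#>   200 nodes, 900 edges, 20 components

scores <- generate_scores(spec, ann$truth)
hits   <- define_hits(scores, "score",
                      hit_rule(1, "greater", expression_column = "expression"))
#> 34 hit(s) of 200 measured [score > 1 AND expression > 10]

head(run_local_tests_all_groups(net, hits), 3)
#>      group_id n_nodes n_hits n_cluster k_hits background_p       pvalue    pvalue_BH
#> 1  syn-miR-1a     200     34        10     10         0.17 2.015994e-08 4.031988e-07
#> 2  syn-miR-7a     200     34        10      4         0.17 7.414725e-02 7.414725e-01
#> 3 syn-miR-15a     200     34        10      3         0.17 2.341305e-01 1.000000e+00

global_permutation_test(net, hits, n_trials = 1e5, rng_seed = 42)
#> global permutation test: 62 hit pairs observed (34 hits / 200 measured)
#>   P(strict) = 0, P(add-one) = 1e-05  [100000 trials, seed 42]
```

Reading the output: the planted family (all ten members of
`syn-miR-1a`'s component are hits against a 17% background) tops the
local-test table at P ≈ 2 × 10⁻⁸, the other families are flat, and the
global test confirms that hits aggregate on family edges far beyond
chance (no random hit assignment among the 100 000 trials reached the
observed 62 hit pairs).

The same pipeline from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "seednet", package = "seednet"))')
Rscript $CLI simulate       --seed 42 --out-dir fx
Rscript $CLI build-network  --rule Seed2_7 --fasta fx/matures.fa --out-dir net
Rscript $CLI test-local     --network net/network.json --scores fx/scores.tsv \
                            --value-column score --out-dir res
Rscript $CLI test-global    --network net/network.json --scores fx/scores.tsv \
                            --value-column score --n-trials 100000 --seed 42 \
                            --out-dir res
```

Subcommands: `build-network`, `list-clusters`, `overlay`, `test-local`,
`test-global`, `test-family-export`, `render`, `simulate`. Rules:
`Seed2_7`, `Genomic_Distance_2k`, `Genomic_Distance_50k`,
`Genomic_Distance_50k_clusters_3+`, `Diana50`, `TargetScan54`,
`DianaTarBase50`, `TargetScan54_degree_10+`, `custom`. Every run writes
its effective configuration (`run_config.json`) next to its outputs;
options can also come from a JSON config file (`--config`) with flags
taking precedence.

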