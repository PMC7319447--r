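---
title: "Rule-defined miRNA networks and hit-enrichment statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-defined miRNA networks and hit-enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seednet)
```

## The model

A mature microRNA acts by near-perfect pairing of its *seed* — the six
nucleotides at positions 2–7 — with mRNA targets. Three biological
relations therefore induce networks over mature miRNAs, and `seednet`
builds all three from standard annotation files:

* **Seed families** (`build_seed_network()`): an edge whenever two
  matures carry an identical seed. Components are by construction
  cliques, one per seed — the classical miRNA families.
* **Genomic clusters** (`build_genomic_network()`): an edge whenever
  precursor loci of two matures lie on the same chromosome closer than a
  threshold (strictly). 2 kb targets polycistrons (co-transcribed
  neighbors); 50 kb targets the larger reorganizations seen in tumors.
  The gap is measured between interval ends; overlapping or book-ended
  loci, and matures cut from the same hairpin, have gap 0 and always
  connect. A mature transcribed from several genomic copies is one node
  and uses the *minimum* gap over its loci ("any co-location
  connects").
* **Target co-regulation** (`build_target_overlap_network()`): an edge
  whenever predicted target sets overlap by strictly more than a
  fraction. The default measure is the overlap coefficient
  $|A \cap B| / \min(|A|,|B|)$, which matches the reading "miRNA pairs
  sharing more than X% of (the smaller one's) targets"; Jaccard is
  available because the exact published formula for those thresholds is
  not stated in accessible form. The conventional thresholds are 0.50
  and 0.54 depending on the prediction source.

Two single-pass simplifications mirror the published network variants:
`filter_clusters_min_size()` (keep components of ≥ 3 nodes) and
`filter_min_degree()` (drop nodes with input-network degree < 10 —
deliberately *not* an iterated k-core, so surviving nodes keep the
semantics they had in the full graph).

## Scores, hits and overlays

User measurements arrive as one row per mature miRNA
(`parse_score_table()`); ids are matched case-insensitively and
originals preserved. A *hit* is a measured miRNA passing a rule
(`hit_rule()` + `define_hits()`): a threshold, a direction (`greater`,
`less`, or `absolute`), and an optional expression filter (default
"> 10 reads") that decides who counts as *measured* at all. Directions
matter: prognosis-style analyses restrict hits to one sign.
`style_nodes()` maps a score column onto a diverging green–white–red
scale with clamping; unmeasured or unexpressed nodes get a neutral grey
at alpha 0.25 (the published figures name the behavior, not the values;
both are configurable).

## The statistics

**Local binomial test.** With $p = n_\mathrm{hits}/n_\mathrm{nodes}$
the hit proportion among *measured* network nodes, a family or cluster
containing $n_c$ measured nodes and $k$ hits has upper-tail P-value
$P(X \ge k)$, $X \sim \mathrm{Binomial}(n_c, p)$. The tail is summed in
log space (`logsumexp` over `dbinom(log = TRUE)` terms), keeping
$10^{-30}$-scale tails exact; the tests verify agreement with a naive
PMF summation to $10^{-10}$ relative error on a grid up to $n = 60$.
Unmeasured nodes never enter any count.

**Global permutation test.** The statistic is the number of *hit pairs*
(edges with both endpoints hits). The null reassigns hit labels
uniformly among measured nodes, keeping the hit total fixed. Following
the strict "observed below randomized" rule, ties count as *not*
exceeding, so the strict estimate can be exactly 0; the add-one
corrected $(m+1)/(n+1)$ estimate is always reported alongside, with the
seed and trial count recorded in the result. Default 100 000 trials
(the source description does not state a count).

**Exact paired Wilcoxon signed-rank** (`exact_wilcoxon_signed_rank()`,
used by `family_export_test()`): zeros dropped, midranks on ties,
two-sided P as twice the smaller tail, capped at 1. With $\le 25$
tie-free differences the null distribution of $W^+$ is computed exactly
by dynamic programming (equivalent to enumerating all $2^n$ sign
vectors — the tests check this equivalence literally up to $n = 12$);
with ties or larger $n$, a normal approximation with continuity and tie
corrections is used and flagged in the result. For a family of 5
members measured in 2 vesicle preparations, all exported, the exact
two-sided P is $2/2^{10} \approx 0.002$ — the minimum attainable at
$n = 10$; across 3 preparations, $2/2^{15} \approx 6\times10^{-5}$.

**Target-set enrichment** (`target_set_enrichment()`): per miRNA, the
upper-tail hypergeometric probability of the observed overlap between
its targets (restricted to the universe) and a gene set.

`run_local_tests_all_groups()` batches the local test over components
or explicit groups and appends Benjamini–Hochberg adjusted values — an
addition of this package; raw values remain the primary readout.

## The synthetic world

The fixture generator emits miRBase-like files with planted truth so
the whole pipeline is testable offline. Defaults state the reference
world used by the test suite: 20 families of 10 matures (200 measured
nodes), species code `syn`, genomic clusters of 5 loci with 500 bp
internal gaps separated by > 100 kb, a 2000-gene universe with 40
targets per miRNA, and a background hit probability of 0.1; planted
groups get hit probability 0.9. Scores are drawn so that
`score > 1` recovers the planted labels exactly, which separates
generator correctness from test correctness. Family target pools are
deterministic subsets (each member carries its whole family pool), so
within-family overlap is *guaranteed* to reach the shared fraction
rather than only in expectation. The universe default is 2000 (not
smaller) because 20 disjoint pools of 32 genes must fit inside it.

What the generator does **not** emulate: real sequence composition,
chromosome counts, expression distributions, or correlated
measurement noise. A green planted-recovery test therefore establishes
that the statistics detect the planted structure at the stated effect
sizes — not that they would rank real biological families identically.

## Numerical choices and degenerate inputs

* Internal genomic coordinates are 0-based half-open; GFF3's 1-based
  inclusive convention is converted exactly once at parse/write time.
* All thresholds are strict inequalities ("closer than", "more than");
  book-ended loci connect.
* `k = 0` hits gives local P-value exactly 1; an all-zero difference
  vector, an empty measured set, or an empty gene universe are errors,
  not silent results.
* Fewer than 2 hits makes the permutation test degenerate: observed 0,
  P-value 1, with a warning.
* Component ordering is deterministic (size descending, then smallest
  member), and every builder is a pure function of its inputs, so
  identical inputs produce identical files byte for byte.

## Calibration and its limits

The local test is an *exact discrete* test whose background proportion
is estimated from the same network. Two consequences, verified
numerically in the test suite:

1. Its achieved size never exceeds the nominal level — on null
   fixtures the rejection rate at $\alpha = 0.05$ stays at or below
   $\alpha$ (asserted within 3 binomial SE above $\alpha$).
2. It is *conservative*: with families of 10 nodes and a background
   near 0.1 the achieved size is ≈ 0.013–0.024, and no configuration
   of cluster size and background brings it within 3 SE of the nominal
   0.05 at large replicate counts, because the discrete tail jumps
   over $\alpha$ and the estimated background correlates negatively
   with each group's own hit count. The acceptance suite keeps the
   literal "matches $\alpha$ within 3 SE" check, which accordingly
   fails and is documented as unattainable rather than weakened.

Practically: significant local P-values can be trusted at face value;
non-significant ones are, if anything, understated.

## Known limitations

* Published network sizes (e.g. the 820-node filtered genomic network)
  depend on a specific annotation release and are out of scope;
  properties (clique structure, threshold monotonicity) replace them.
* No ID history resolution across annotation releases; matching is
  case normalization only.
* The SVG renderer is a static, deterministic force-directed sketch for
  sharing results, not a reproduction of any published layout.
* Survival modeling, normalization and differential expression are
  upstream of this package: P-values and fold changes enter as scores.
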