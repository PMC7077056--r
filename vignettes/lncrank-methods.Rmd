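---
title: "Multi-network lncRNA prioritization: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-network lncRNA prioritization: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncrank)
```

## The problem and the model

Known cancer lncRNAs cluster together in molecular networks: they
co-express, share miRNA sponges, bind the same proteins, and sit in
hub positions. `lncrank` exploits this guilt-by-association signal across
*several* networks simultaneously, because any single network is incomplete
and partly wrong.

The pipeline has three stages.

**1. Per-network propagation.** On each network the walk
`p[q+1] = (1 − alpha) W p[q] + alpha p0` is iterated from the seed
distribution (`p0`: total mass 1, uniform over the seeds present in that
network) to its stationary point; `W` is the column-normalized adjacency.
Candidates in the network are ranked by stationary probability with
average ties. A network that contains no seed carries no information for
the walk: its candidates all tie at rank `(n + 1) / 2`.

**2. Topology profiling.** Per network we record the rank ratio
`r = R / n` (1 when absent), and the min–max normalized betweenness and
degree over that network's nodes (0 when absent, and 0 for the degenerate
all-equal case — no topological evidence). Coverage `T` counts the member
networks; `t = T / N`; `bs` and `ds` are the sums of the normalized
statistics over all `N` networks divided by `T` (absent layers contribute
zero to the sums but not to the denominator).

**3. Fusion.** The overall score is

$$S = \frac{\prod_{j=1}^{N} \ln(r_j + 1)}{t \, e^{bs + ds}},$$

smaller is stronger. Each factor `ln(r + 1)` lies in `(0, ln 2]`, so a top
rank in any layer pulls the score down multiplicatively, an absent layer
contributes the neutral worst-case factor `ln 2`, and coverage/topology act
through the denominator.

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `alpha` | 0.7 | Restart probability per step (dimensionless). The canonical value in network-propagation prioritization; larger values localize the walk around the seeds. Convergence is geometric at rate ≤ `1 − alpha`, so results are insensitive across 0.5–0.9 while the *relative* ranking of near-seed candidates changes little. Exposed in `rwr_params()`. |
| `tol` | 1e-10 (L1) | Iteration stopping rule; also the bound on the fixed-point residual. Far below any rank-changing scale. |
| `max_iter` | 1000 | With `alpha = 0.7`, convergence needs < 100 iterations even on 1000-node scale-free graphs. |
| `min_coverage` | 4 | Candidates in fewer than 4 networks are unscorable with any confidence; filtering at 4 of 9 layers is the best-performing setting and is exposed as an argument everywhere. |
| `pcc_min`, `fdr_max` | 0.8, 0.01 | Co-expression edge thresholds (strict inequalities, Benjamini–Hochberg over all pairs tested in the call). |
| BLAST cutoffs | e-value < 1e-5, bit score > 80 | Strict on both, applied to outfmt-6 hits; self-hits dropped. |

## Numerical and convention choices

These were genuinely open design points; the package commits to the
following and documents why.

* **Score orientation.** Whether `e^{bs+ds}` divides or multiplies the
  product is ambiguous on its face. We divide, making hub-like topology
  *strengthen* (shrink) the score, for two reasons: known cancer lncRNAs
  demonstrably have higher degree and betweenness than other candidates,
  so topology must push in the favourable direction; and downstream
  displays of `−log10(S)` treat large values as significant. The other
  reading is available via `orientation = "multiply"`.
* **Log base.** Natural log. The base rescales every factor by the same
  positive power and cannot reorder candidates with equal membership
  patterns; `ln` keeps the closed forms clean (`ln(e − 1 + 1) = 1`).
* **Betweenness convention.** Unnormalized Brandes betweenness, each
  unordered pair counted once, fractional credit for tied shortest paths.
  The per-network min–max rescaling absorbs any global constant, so any
  consistent convention gives identical scores; this one is what a
  brute-force shortest-path enumeration reproduces directly, which is how
  it is tested.
* **Dangling nodes.** Zero-degree nodes get all-zero columns in `W`.
  Walker mass reaching them leaks and is *not* renormalized per step: the
  direct linear solve `p = alpha (I − (1 − alpha) W)^{-1} p0` defines the
  semantics and the iteration matches it exactly, which keeps the
  iterative/direct oracle equivalence clean.
* **Seed mass.** Total restart mass 1 split uniformly over the seeds
  present in each network. Auxiliary seeds (cancer genes/miRNAs/proteins)
  that exist as nodes simply join that uniform pool in the networks that
  contain them.
* **Ties.** Average ranks throughout (within networks and in the final
  ranking), so exchangeable candidates receive identical scores.
* **Degenerate min–max.** A network whose nodes all share one betweenness
  (or degree) value contributes 0 — "no topological evidence" — rather
  than an arbitrary 0/0.
* **Hypergeometric tails.** The functional-similarity and ceRNA tests are
  upper tails `P(X ≥ k)`; `FDR` always means Benjamini–Hochberg over the
  pairs tested in the same call. In the ceRNA test the miRNA universe
  defaults to the miRNAs observed in the interaction input, overridable
  via `universe_size`.
* **Coordinates.** All intervals are 0-based half-open; CLIP support
  requires full containment with closed boundaries (`cs ≤ s`, `e ≤ ce`).
* **LOOCV protocol.** The held-out known is scored as an ordinary
  candidate with the remaining knowns as seeds; ROC negatives are all
  non-gold candidates (no decoy sampling); AUC uses trapezoids, which for
  this step construction equals the Mann–Whitney statistic with 0.5 tie
  credit. Held-out knowns that fail the coverage filter are excluded from
  the ROC and counted.
* **Robustness removal.** The 20% removal pool is *all* lncRNA nodes of
  the perturbed network, seeds included. Losing known lncRNAs from one
  evidence layer is precisely the incompleteness a multi-network method
  should absorb — and excluding seeds would remove the very mechanism
  (seed loss in one layer) that makes single networks fragile. Each
  repetition resamples independently.

## What the synthetic generator emulates

`simulate_collection()` builds nine layers over shared node pools
(300 lncRNAs, 200 mRNAs, 100 miRNAs, 60 proteins, 30 TFs by default) with
a planted 15-member module standing in for the known cancer lncRNAs:

* module members connect to each other (unipartite layers) or to a common
  set of partner molecules (bipartite layers) with probability
  `p_in = 0.5`, against a background density of `p_out = 0.02`;
* module members get a mild degree boost (`topology_boost = 1.5`) over the
  background, reproducing the hub-like excess degree and betweenness of
  known cancer lncRNAs;
* every node is missing from each layer with probability
  `missing_frac = 0.15`, except that module members are never dropped from
  the four lncRNA-lncRNA layers — so planted knowns always meet the
  coverage-4 filter;
* each layer "sees" only a random 70% of the module
  (`informative_frac = 0.7`): real evidence types are complementary, and
  this is exactly what makes the fused ranking beat every single layer.

Sizes are kept at a few hundred nodes per network so that a full
evaluation (LOOCV, coverage sweep, 10-repetition robustness) completes in
minutes on one CPU; the problem sizes used by the tests and the acceptance
script are these defaults.

What the generator does **not** emulate: the heavy-tailed size spread of
real curated networks (hundreds to millions of edges), correlated
membership across layers, annotation biases (well-studied lncRNAs appear
in more databases *because* they are studied), and measurement artefacts
in expression or CLIP data. Passing the planted-module benchmarks
therefore shows the machinery is correct and that fusion works when
evidence is complementary — not that any particular real-data AUC will be
matched.

The companion generators mirror the raw inputs: `simulate_expression()`
(one latent factor per planted edge; a degree-1 pair has population
correlation `1 / (1 + noise_sd^2)`, ≈ 0.92 at the default `noise_sd = 0.3`,
comfortably above the 0.8 edge threshold), `simulate_intervals()`
(constructed-contained vs partially overlapping CLIP clusters), and
`simulate_blast_hits()` (planted pairs pass both thresholds, decoys fail
exactly one).

## Degenerate inputs

Empty edge files parse to empty networks; self-loops are dropped with a
count; duplicate and reversed duplicate edges collapse. Zero-variance
expression features are skipped (not errors). lncRNAs with no annotated
co-expression partner get empty term sets. Candidates present in no
network are dropped (coverage 0 would divide by zero); a coverage filter
that removes everything returns an empty result with a warning rather than
an error, except in LOOCV where an evaluation without positives is
meaningless and aborts.

## Known limitations

* Scores are comparable within one run, not across cancer types or
  collections with different `N`.
* The walk treats all edges as equally reliable; edge weights are
  supported (`weighted = TRUE`) but the default binary treatment matches
  thresholded input networks.
* Prioritization is impossible for cancer types with very few known
  lncRNAs — the walk needs seeds, and LOOCV needs at least two.
* GO terms are used as flat labels (no ontology graph propagation), which
  overstates the independence of related terms in the similarity test.
* The functional-similarity `k` counts shared *assigned* terms; with very
  small assigned sets the hypergeometric tail is conservative.
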