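---
title: "Learning categorical Bayesian networks from cytokine-hormone panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning categorical Bayesian networks from cytokine-hormone panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytobn)
```

## The model

`cytobn` analyses serum analyte panels — cytokines and hormones measured
across an in vivo timecourse — as a categorical Bayesian network. A network
is a pair (G, Θ): G is a directed acyclic graph whose vertices are the
analytes, and Θ holds, for each node, a conditional probability table (CPT)
giving the distribution of the node's concentration bin for every joint
configuration of its parents' bins. Concentrations enter the model only
through relative bins: each analyte is z-score normalized and then cut into
`n_bins = 3` equal-frequency categories (low / medium / high), so a third of
the samples lands in each bin and the analysis is invariant to any monotone
rescaling of a given analyte.

The package covers five stages, each usable on its own:

1. **Preprocessing** — z-scoring, equal-frequency discretization, Pearson
   correlation matrices, and a weighted-mean trend heterogeneity test with
   Benjamini–Hochberg FDR control.
2. **Structure learning** — Tabu search over the BDe score with an optional
   literature-seed structure prior, and bootstrap model averaging.
3. **Inference and perturbation** — exact marginals by variable elimination
   and point-mass in-silico interventions.
4. **Network comparison** — directed-edge confusion counts, specificity /
   sensitivity / F-score, and parent-category complexity.
5. **Synthetic data** — planted-DAG generators that make every stage
   testable without access to animal data.

## The trend test

For each analyte with per-timepoint means $m_t$ and standard errors
$SE_t$ ($t = 1..T$), the null hypothesis is that the mean is constant at
the inverse-variance weighted mean. With weights $w_t = SE_t^{-2}$,

$$\bar m = \frac{\sum_t w_t m_t}{\sum_t w_t}, \qquad
  Q = \sum_t w_t (m_t - \bar m)^2 \sim \chi^2_{T-1}
  \ \text{under the null},$$

with per-timepoint scores $z_t = (m_t - \bar m)\sqrt{w_t}$ reported
alongside. P-values are Benjamini–Hochberg adjusted across the analyte
family at $\alpha = 0.05$. The choice of a single heterogeneity statistic
per analyte (rather than some aggregation of per-timepoint scores) is a
documented design decision: it is the standard statistic that matches a
constancy null with inverse-squared-standard-error weights. Its calibration
is verified in the test suite: over 10,000 simulated null analytes the
rejection rate at $\alpha = 0.05$ is within $\pm 0.01$ of nominal.

## Scoring and search

Structure learning maximizes the BDe marginal likelihood under a Dirichlet
prior in its BDeu parameterization: a family with $r$ child states and $q$
parent configurations gets per-cell pseudo-count $ESS/(rq)$. This keeps
every prior cell strictly positive and makes Markov-equivalent structures
score identically (asserted to $10^{-9}$ in the tests). Defaults, all
exposed through `score_config()` / `pipeline_config()`:

| parameter | default | meaning |
|---|---|---|
| `ess` | 1 | Dirichlet prior strength, in pseudo-observations |
| `kappa` | 0.5 | prior factor per edge differing from the seed |
| `max_parents` | 3 | in-degree cap during search |
| `tabu_length` | 10 | recent moves whose inverses are forbidden |
| `max_iterations` / `patience` | 1000 / 100 | step cap / early stop |
| `n_bootstrap` | 100 | bootstrap replicates |
| `threshold` | 0.9 | bootstrap confidence cut |

The seed network is a soft bias: the score is multiplied by
$\kappa^{\delta}$ where $\delta$ counts the directed edges in the symmetric
difference between a candidate structure and the seed DAG, so seed edges
are judged by the data like any other edge. Undirected literature edges are
oriented by a deterministic depth-first traversal (`orient_seed_edges()`),
and edges that close feedback cycles are removed as the back-edges of a
lexicographic DFS (`remove_cycles()`) — Bayesian networks cannot represent
structural loops.

Tabu search proposes single-edge additions, deletions and reversals,
applies the best admissible move even when it worsens the score, forbids
recent inverse moves, and breaks all ties lexicographically so that runs
are bit-reproducible. The returned structure never scores below the seed,
and on every labelled three-node hypothesis space (25 DAGs) the search
attains the exhaustively enumerated optimum. The in-degree cap applies
during search but is deliberately not re-imposed on the model-averaged
thresholded network, whose per-edge confidences come from independently
learned bootstrap replicates.

## Interventions

`exact_marginals()` computes node marginals by variable elimination with a
greedy min-degree elimination order, and is checked against a brute-force
joint-enumeration oracle. Interventions are point masses. The default
`surgical` mode implements graph surgery: the intervened node's incoming
edges are cut and its distribution is replaced by the point mass, while
every CPT stays untouched, so only descendants can change (a property
asserted over random networks). `observational` mode instead conditions on
the forced states as evidence. The two coincide on parentless nodes, and
multi-node interventions clamp jointly — under graph surgery order cannot
matter. Qualitative labels take the dominant bin, prefixed with
"moderately" when its probability is below 0.5; ties resolve toward the
medium bin, which never carries the modifier.

## Comparing networks

`edge_confusion()` classifies every slot of an explicit edge universe —
directed without self-loops ($n(n-1)$, the default), directed with
self-loops ($n^2$), or undirected ($n(n-1)/2$) — into TP/FP/FN/TN against
a reference network taken as the standard of truth. The universe is a
parameter because published totals mix conventions; making it explicit
lets any of them be reproduced. Metrics follow

$$\text{specificity} = \frac{TN}{TN+FP}, \quad
  \text{sensitivity} = \frac{TP}{TP+FN}, \quad
  F = \frac{2 \cdot \text{spec} \cdot \text{sens}}{\text{spec} + \text{sens}},$$

computed on unrounded ratios and rounded only for display. Network
complexity sums, over nodes, the product of the parents' category counts
(an orphan contributes 1); the node's own category count does not enter,
exactly as the measure is defined in print.

## The synthetic generator

Because the study's per-animal measurements are not deposited, the
generator plants known ground truth and emulates the study's shape: 26
analytes, 53 samples over 7 timepoints (days 1, 2, 4, 10, 16, 21, 24 with
n = 8, 8, 8, 7, 8, 7, 7), and three temporal profile clusters (an early
peak near day 5 for the hormone-associated cluster, a saturating rise, and
a broad peak centred on day 10). Choices that the data could not fix were
made once, for testability:

- **Emission model.** Bin b of an analyte emits a Gaussian at location
  $\mu_b$ with scale $\sigma_b$, truncated at zero, drawn by inverse CDF so
  a zero scale is exactly degenerate. Defaults are a geometric ladder
  (25, 100, 400 concentration units) with 15 % CV — separated enough that
  re-discretization is approximately label-preserving.
- **Strong-CPT preset.** For recovery benchmarks, each child row peaks at
  0.9 on the state `clamp(sum(parent states) - (k - 1), 0, n_bins - 1)` —
  additive activation with saturation. Every parent shifts the child both
  marginally and conditionally (a parity-style rule would be invisible to
  greedy search), and child marginals stay near-uniform so the
  equal-frequency quota relabels few samples. Orphans are uniform for the
  same reason.
- **Replicate noise.** 0.1 of the profile dynamic range; the study reports
  no quantitative noise level, so this is calibrated for testability, not
  biological realism.
- **Seeding.** A master integer seed fans out to per-consumer sub-seeds
  drawn up front (`sample.int(2^31 - 2)`), so bootstrap replicates are
  order-independent and every generator is bit-reproducible.

## What the benchmarks show — and what they do not

The acceptance-level benchmark plants an 8-node DAG (in-degree at most 2),
samples n = 500 records, emits concentrations, and runs the full
normalize → discretize → learn → bootstrap pipeline: every planted
adjacency then reaches bootstrap confidence at least 0.9 and non-adjacent
pairs stay at or below 0.3, mirroring the high-stringency threshold used
in the study. Problem sizes (8 nodes, 500 records, 100 replicates;
10,000 simulated analytes for the trend calibration; 5-node spaces for the
inference oracle) were chosen so the whole suite runs comfortably on a
laptop while keeping binomial noise far from the asserted margins.

Known limitations, observed while validating the generator:

- **Three-parent families at n = 500 are marginal.** A 3-parent family has
  27 table rows; after the equal-frequency quota relabels a few percent of
  states, its per-parent incremental BDe signal can drop below the
  complexity penalty, so round-trip recovery of 3-parent nodes is not
  guaranteed at this sample size. Learning from the sampled categorical
  records directly (no emission round trip) recovers such families.
- **Discretization weakens screening.** Binning a common parent leaves
  residual dependence between its children, so a sibling pair can
  accumulate non-trivial bootstrap support split across both directions at
  some generator seeds; the 0.9-threshold network remains correct because
  neither single direction reaches the cut.
- The generator does not model immunoassay error, plate effects or
  detection limits beyond zero-truncation, so passing benchmarks
  demonstrate correctness of the machinery, not robustness to assay
  artifacts.

## End-to-end example

```{r pipeline, eval = FALSE}
truth <- sample_random_dag(8, max_parents = 2, edge_density = 0.3, seed = 11)
model <- ground_truth_model(truth, strong_cpts(truth))
records <- sample_discrete_records(model, 500, seed = 12)
panel <- emit_continuous_panel(records, model, seed = 13)

fit <- run_pipeline(panel, config = pipeline_config(seed = 42),
                    out_dir = "results")
fit$network                      # thresholded high-confidence DAG
edge_confusion(fit$network, truth)

marg <- exact_marginals(fit$network, fit$cpts,
                        intervention_spec(c(X1 = 0L)))
attr(marg, "labels")
```
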