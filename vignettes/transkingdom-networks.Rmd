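---
title: "Transkingdom correlation networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transkingdom correlation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tknet)
```

## The problem

Replicated diet- or treatment-intervention studies in mice commonly produce
two coupled data sets per animal: a 16S amplicon profile (ASV counts) and a
panel of continuous host phenotypes such as flow-cytometry population
frequencies. The question `tknet` addresses is which microbes and which host
parameters sit at the interface between the two kingdoms — not merely which
features shift under treatment, but which ones mediate the covariation
between microbiota and host physiology. The package reconstructs a
*transkingdom network* whose nodes are microbes and host parameters and whose
edges are treatment-coherent correlations, then ranks nodes by how often they
sit on shortest paths connecting the two kingdoms (bipartite betweenness
centrality, BiBC), and finally asks how unusual the top-ranked nodes are
relative to size-matched random graphs.

The design assumes two independent experiments, each with a control and a
treatment group (four analysis groups in total), each group with roughly 7–9
animals, and animals nested in birth cohorts (litters).

## Normalization

Microbial counts go through a fixed chain, in this order, recorded in the
feature table's provenance flags:

1. **Singleton removal** — ASVs whose total count across *all* samples of
   both experiments equals exactly 1 are discarded as likely artifacts.
2. **Cumulative-abundance filter** — ASVs are ranked by grand total and the
   minimal prefix reaching 99.5% of all counts is kept (the ASV crossing the
   threshold is included). This keeps the abundant community and drops the
   sparse tail that cannot support rank correlations at n = 8.
3. **Relativization per million** — counts become counts-per-million within
   each sample.
4. **Quantile normalization (per experiment)** — every sample's value vector
   is replaced by the mean order statistics across that experiment's samples,
   forcing a common distribution. Ties receive the mean of the reference
   values over the tied ranks. With this convention, exact multiset equality
   across samples holds for tie-free data; tied blocks (typically zeros in
   sparse ASV columns) share one averaged value, so samples with different
   zero counts agree only up to those blocks. Applying the transform twice is
   idempotent.
5. **log2 transform** — `log2(x + 1)`. The pseudocount 1 is negligible on
   the counts-per-million scale and maps zeros to zero.

Host parameters are normalized in two stages: each value is divided by its
birth-cohort mean (removing litter effects; the median is available via
`cohort_center = "median"`), and parameters measured in both experiments are
then z-scored per experiment so the two studies are comparable. Parameters
present in a single experiment skip the second stage and are flagged.
Quantile normalization is applied to microbes only: host panels are
heterogeneous in scale and meaning, and forcing a common distribution across
flow-cytometry frequencies has no analogue of the "same sequencing process"
argument that justifies it for counts.

Fold changes (used by the edge filters and as node attributes) are median
treatment / median control per experiment, computed on positive ratio
scales: back-transformed normalized abundances (`2^x - 1`) for microbes and
the stage-1 cohort-normalized values for hosts — z-scores can be negative
and have no meaningful ratio.

## Edge selection

For every feature pair and every analysis group (experiment x diet group),
the Spearman rank correlation is computed with average-rank ties, and a
two-sided p-value from the t approximation on n − 2 degrees of freedom
(appropriate at the study's group sizes; `cor.test`'s approximation agrees).
A candidate edge then has four (rho, p, n) triples and passes through:

1. **Sign consistency** — all four rhos strictly share one sign. A zero rho
   has no sign and fails: a value that cannot vote for a direction should not
   rescue an edge.
2. **Causality coherence** — sign(average rho) must equal the product of the
   two endpoints' fold-change directions. If the treatment raises A and
   lowers B, a positive A–B correlation is incoherent with the intervention
   and is treated as noise. Exactly 4 of the 8 sign combinations pass.
3. **Fold-change consistency** — both endpoints must shift in the same
   direction in both experiments; a fold change of exactly 1 has no
   direction and fails.
4. **Individual-p prefilter** (microbe–host edges only) — every per-group p
   must fall below 0.6, a deliberately permissive screen that removes edges
   with essentially no evidence in some group before FDR correction. Named
   edges can be *rescued* past this screen (and past the FDR gate) and are
   flagged, mirroring the practice of retaining biologically prioritized
   edges; rescued edges still must pass filters 1–3.
5. **Meta-analysis and FDR** — per-group correlations are pooled by a
   fixed-effect model on Fisher's Z scale: `z_i = atanh(rho_i)` with weight
   `n_i - 3` (the inverse of the Fisher-transform variance), pooled mean
   `zbar`, standard error `1/sqrt(sum(w))`, and a two-sided normal p-value.
   Benjamini–Hochberg adjustment is computed *within* each edge class over
   the edges surviving the earlier filters, and gated at class-specific
   thresholds: microbe–microbe 0.05, microbe–host 0.15, host–host 0.10.
   The FDR is computed on the meta-analysis p-values (the per-group
   p-values feed only the prefilter); Benjamini–Yekutieli is available via
   `fdr_method = "BY"`.

The output table is audit-complete: removed edges stay in it with the first
failing predicate recorded in the order sign → causality → fold-change →
prefilter → FDR (the predicates are pure, so the outcome is
order-independent; only the recorded reason follows this convention).

## Network topology

Kept edges form an undirected simple graph; only endpoints of kept edges
become nodes. For disjoint node sets A (microbes) and B (hosts), the BiBC of
a node v is

$$\mathrm{BiBC}(v) \;=\; \sum_{s \in A,\; t \in B,\; s \neq v \neq t}
\frac{\sigma_{st}(v)}{\sigma_{st}},$$

the sum over cross-kingdom pairs of the fraction of shortest s–t paths
passing through v. Each unordered pair is counted once, endpoints earn no
credit for their own pair, disconnected pairs contribute zero, and edges are
unweighted — the statistic counts paths; correlation magnitude stays an edge
attribute. Scores are normalized by `|A| x |B|` (the number of pairs) into
[0, 1]. The implementation is a Brandes-style accumulation in C++ restricted
to A-sources and B-targets; the test suite checks it against an exhaustive
all-shortest-paths enumeration on small graphs and against classical
betweenness in the degenerate A = B = V case (where it equals twice the
classical score, since each pair is seen from both sides).

Candidates are ranked by (normalized BiBC desc, degree desc, node id asc) —
a fully deterministic order so reruns agree; the id tie-break matters in
sparse networks where many nodes tie at BiBC 0 and degree 1.

## Null calibration

The observed (degree, BiBC) pairs are calibrated against an Erdős–Rényi
G(n, m) ensemble with n and m taken from the actual network. Each sampled
graph gets a uniformly random bipartition of the real partition sizes — the
real microbe/host labels have no meaning in an unlabeled random graph — and
every node's degree and normalized BiBC are pooled. The pooled samples are
binned into a 2D probability density (degree at integer bins; BiBC in 50
equal-width bins up to 1.05x the pooled maximum), and the tail probability
of a query node is the empirical fraction of pooled samples at least as
large in *both* coordinates. A query beyond every pooled sample is reported
at the resolution bound 1/(pool size) and flagged censored. Pooling **all**
nodes (rather than only each network's top node) is the default: it is the
richer null and conservative for extreme queries; `mode = "top"` gives the
per-network-maximum variant for comparison.

## The synthetic study generator

Because real paired host/microbe tables are rarely public, `generate_dataset()`
plants a known ground truth at the study's design point: 2 experiments x 2
groups x 8 samples, 100 ASVs, 12 treatment-shifted ASVs, one bottleneck, 4
linked host parameters among 10, sequencing depth 50,000.

* **Abundances.** A log-normal baseline (log2 sd 1.5) shared across
  experiments produces a realistic heavy-tailed rank-abundance curve, so the
  99.5% filter is exercised non-trivially. All latent quantities — baseline,
  batch offsets (sd 0.3), cohort offsets (sd 0.15), per-sample noise
  (sd 0.5) and the treatment shift — live on the log2 scale, so the effect
  size (default 1.0, i.e. a 2x shift) shares units with the noise terms.
  Counts are multinomial at the configured depth, so each sample's counts
  sum to the depth exactly and compositional closure is present by
  construction.
* **Shift placement.** Shifted ASVs are drawn from the abundant-but-not-
  dominant ranks (skipping the top 3): abundant enough that counts are
  rarely zero, but below the community's dominant members so that closure
  (the community total moving with the shifts) cannot cancel a planted
  direction. Directions are identical in both experiments — the consistency
  filters assume exactly this.
* **Host parameters.** Each linked parameter is
  `base + coupling x sign x z + noise + cohort offset`, where z is the
  standardized log2 observed abundance of its bottleneck. The construction
  is monotone in the bottleneck's abundance, so the planted rank correlation
  survives any monotone normalization, and the planted edge sign equals the
  product of the endpoint shift directions — planted edges satisfy the
  causality filter by construction. With coupling 1 and all noise terms at
  0, within-group Spearman correlations are exactly ±1.
* **What it does not emulate.** Real 16S reads and denoising, longitudinal
  dynamics, taxon–taxon ecological interactions (microbe–microbe
  correlations arise only incidentally through closure and shared offsets
  and are not scored), overdispersion beyond log-normal noise, and
  batch-by-treatment interactions. Passing recovery tests therefore shows
  the pipeline's statistical machinery is sound at the study's design point,
  not that any particular real network is correct.

At these defaults the full pipeline places the planted bottleneck in the
microbe top 3 (by normalized BiBC, with the documented tie-breaks) in about
85–95% of seeds; batches of 20 seeds are used in the test suite and the
acceptance script. The dominant failure mode is informative: when at most
one planted edge survives the four-group cascade, the bottleneck enters the
network at degree 1 and BiBC 0 and must win ties on node id alone. With
coupling 0 the kept microbe–host edge fraction stays near 0.2–0.6% — far
below the 15% FDR ceiling, because the sign-consistency and causality
screens already remove most null edges.

## Numerical and degenerate-input choices

* Spearman p-values use the t approximation; `|rho| = 1` is clamped to
  `1 - 1e-7` before the Fisher transform, with a warning.
* Constant features within a group give undefined correlations; such edges
  are excluded and recorded as `constant_feature`.
* A zero control median makes a fold change undefined; the node's edges are
  removed by the fold-change filter rather than propagating infinities.
* An experiment with a single sample passes quantile normalization
  unchanged, with a warning; a cohort with fewer than two samples falls back
  to the overall mean, with a warning; a zero cohort mean is an error.
* The cumulative-abundance ranking breaks total-count ties by ASV id, and
  the threshold comparison tolerates `1e-12` of floating-point slack.
* G(n, m) sampling and the ensemble are deterministic given a seed and
  restore the caller's RNG state.

## Problem sizes

The shipped tests run the generator's default design point (32 samples, 100
ASVs, 10 host parameters; ~5,500 candidate edges per run) over 20 seeds for
recovery and 50 seeds for the no-coupling floor; null-model checks use
500–1,000 graphs at n = 109, m = 221 plus a 10,000-graph run in the
acceptance script. A full pipeline run at this size takes well under a
second; the 10,000-graph ensemble with per-node BiBC takes a few seconds.

## Known limitations

* The causality filter is a sign-coherence heuristic, not causal discovery;
  it is togglable by omitting the filter column from downstream gating.
* Fixed-effect pooling assumes a common underlying correlation across the
  four groups; no heterogeneity statistic is computed at n = 7–9 per group.
* FDR tiers are class-specific but the classes are adjusted independently;
  no hierarchy across classes is enforced.
* BiBC treats all edges as unit length; correlation-weighted path lengths
  are deliberately out of scope.
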