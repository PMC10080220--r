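---
title: "Knockout-aware benchmarking of pathway enrichment: models and design choices"
author: "knockpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockout-aware benchmarking of pathway enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The benchmarking model

A knockout experiment gives pathway analysis something it normally lacks:
a ground truth. If gene g is knocked out, every pathway whose gene set
contains g is a *true KO pathway*; all others are negatives. A method
that assigns each pathway a p-value then induces, at any significance
level, a confusion table (TPKO/FPKO/TNKO/FNKO), and across all levels an
ROC curve. The label depends only on pathway membership — deliberately
not on whether the knockout "really" perturbed the pathway, which no
external arbiter could certify — so the ground truth is cheap, objective
and method-independent. The price is label noise in both directions: a
pathway can contain the KO gene in a biologically inert role, and a
pathway without the gene can sit directly downstream of it. AUC values
from this benchmark are therefore comparative instruments, not absolute
effect sizes.

## DEG selection on the interaction graph

Differential expression is decided on *edges*, not genes. With
`fitGeneStats()` each gene gets a log2 fold-change (KO minus control
means) and a two-sided p from a moderated t-test — limma's
empirical-Bayes variance shrinkage, s2_post = (d0 s0^2 + d s^2)/(d0 + d),
with the prior estimated by moment matching on the cross-gene variance
distribution. `moderation = "off"` gives the textbook pooled t and is the
oracle route in the tests; an explicit `d0` (including `Inf`) exposes the
shrinkage limit for verification.

Every undirected global-graph edge (X, Y) with measured endpoints scores

    |FC_X| (1 - p_X) + |FC_Y| (1 - p_Y),

a quantity in [0, |FC_X| + |FC_Y|] that is large only when both endpoints
move and do so credibly. Scores are symmetric in the edge direction, so
scoring runs over unordered pairs; direction is kept for perturbation
only. On the descending-sorted score curve, `detectChangepoint()` fits an
at-most-one-change mean shift by exact minimization of the within-segment
sum of squares (cumulative-sum identities; ties resolve to the smallest
split). The three thresholds are HES1 (last elevated score), HES2 (score
at rank ceiling(0.75 k) of the k elevated scores) and HES3 (maximal
score). HES3 structurally selects exactly two genes whenever the top edge
is unique — the endpoints of that edge — which the acceptance script
recomputes from scratch.

Two readings of the HES2 wording were possible: a rank-based exclusion of
the lowest quartile of elevated edges, or a 25% multiplicative markup of
HES1. We implement the rank-based rule as the default (`rule = "rank"`)
because it is the one that actually keeps "the top 75% of the remaining
scores"; the multiplicative variant stays available as `rule = "scaled"`.
Similarly, change-point detection operates on the sorted score sequence
rather than a histogram; the sorted form is what makes "the curve becomes
flat" a mean-shift statement.

## Enrichment methods

* **ORA** — upper-tail hypergeometric P(X ≥ overlap) on the measured
  universe (`stats::phyper`).
* **GSEA (gene permutation)** — weighted Kolmogorov–Smirnov running sum
  with weight exponent 1 on the signed moderated t ranking; the null
  permutes gene labels; p uses add-one smoothing, so 0 is unreachable.
* **SPIA-style topology method** — ΔE holds the log2 fold-changes of the
  pathway's DEGs; the signed weight matrix B (activating subtypes +1,
  inhibitory −1, binding/association and indirect effects weight 0 —
  retained in the graph for edge scoring, excluded from propagation;
  the mapping is data, see `defaultRelationConfig()`) is column-normalized
  by the number of weighted targets; PF solves (I − B) PF = ΔE, tA is the
  net accumulation sum(PF − ΔE); the bootstrap null re-assigns NDE
  fold-changes from the dataset-wide DEG pool to random measured pathway
  genes; pG = c − c ln c with c = pNDE · pPERT (χ²₄ survival), BH and
  Bonferroni adjusted. Singular (I − B) marks the pathway NA and is
  logged, mirroring how such pathways are skipped upstream.

`pSize` reports *measured* pathway genes (the quantity entering the
hypergeometric); the all-genes count is kept alongside as `pSizeAll`
since a printed table cannot disambiguate the two. External methods join
through `EXTERNAL:<name>` tables (pathway_id, p) rather than
re-implementation.

## ROC layer: conventions that matter

The ROC predictor is the method-native primary p (pG for the topology
method, the single p otherwise) — "every possible p-value" describes the
raw trade-off; FDR-adjusted values enter only the fixed-alpha TPKO calls.
Pathways missing from a result table count as p = 1 (never reported
significant). Curve points are evaluated at every distinct p with
sentinels, so trapezoidal AUC equals pair-counting concordance with ties
at half weight — an identity the tests assert up to n = 500 and
cross-check against pROC. Partial areas restrict to 90–100% specificity
(or sensitivity, via curve inversion using the best specificity attained
at each sensitivity); the McClish correction maps [chance, perfect] =
[0.005, 0.1] onto [0.5, 1] and is clamped below at 0.5 so a curve that
never enters the region reports the chance value. Youden's threshold
maximizes specificity + sensitivity; ties prefer the higher-specificity
point, then the smaller p; the returned cutoff is the midpoint of the
separating gap so it is usable as an operating threshold. Bootstrap CIs
resample positives and negatives separately (percentile, 2.5/97.5).
Curve comparisons are paired: a bootstrap z on the statistic difference,
and a permutation test that rank-transforms each method's p-values,
swaps the two methods per pathway with probability 1/2 and measures the
integrated absolute curve difference. Zero-difference Wilcoxon pairs are
dropped per the signed-rank convention; an all-zero comparison reports NA.

## What the synthetic fixtures emulate

`fixtureSpec(seed)` pins the study conditions: 30 pathways of 8–25 genes,
70% containing the KO gene, a balanced 5 vs 5 design, KO effect −2.0
log2 units, propagation decay 0.5 per hop, noise sd 0.5. The generator
writes real KGML files (parsed back through the same parser as any other
collection) with these structural choices:

* **Rooted cascades.** Each pathway is a random spanning tree directed
  away from its first gene plus random crosstalk edges; in KO-containing
  pathways the KO gene is that root. Knocked-out genes in real benchmark
  sets are upstream regulators whose pathways cascade from them; an
  unrooted graph with random orientations produces no coherent
  perturbation signal at all and makes the topology evidence vacuous.
* **A shared signaling core.** About half of each pathway's genes come
  from a 60-gene core subpool (the rest from a 600-gene periphery), so
  unrelated pathways still contain knockout-neighborhood genes — the
  feature that actually stresses count-based methods. The pool sizes were
  set so the KO gene's effective (2-hop) neighborhood is a minority of
  the measured genome; with a much smaller pool the propagated signal
  blankets the genome and every statistic saturates.
* **Propagation.** KO samples shift the KO gene by −effect and every gene
  at hop distance d (deterministic BFS on the undirected global graph,
  edge signs multiplied along the discovered path) by
  −effect · decay^d · signproduct. The sign convention applies the
  knockout's own −effect consistently at d = 0 and downstream, so an
  activation chain is driven down and an odd-inhibition chain up.
  Expression is baseline Normal(8, 1) per gene plus iid Normal(0, noise).

Not emulated: probe-level noise, batch structure, unbalanced designs,
correlated noise between co-pathway genes, and any gene not in the
pathway universe. Passing tests on these fixtures show the machinery is
correct and the statistics behave as derived — they do not certify
performance on microarray data.

All randomness flows from the single mandatory seed (collection and
expression draws use fixed derived offsets), so every file the generator
writes is byte-reproducible; run outputs embed the seed and a sanitized
copy of the run configuration, and `summary.json` is path-free so a
re-run under one seed is byte-identical.

## Problem sizes

The test suite runs the default 30-pathway fixture across 20 seeds
(bootstrap 500 replicates) for the recovery study, 7 null datasets (210
pathway-level p-values, 300 replicates) for calibration, and scales every
oracle comparison to the sizes where exhaustive computation is exact
(n ≤ 500 for AUC pair counting, N ≤ 30 for hypergeometric enumeration,
n ≤ 200 for the change point, length ≤ 12 for BH). These sizes were
chosen as the smallest at which each property is informative.

## Known limitations — measured, not hidden

Two findings from our own simulation studies are worth stating plainly,
because the test suite asserts the opposite expectations and reports them
as failures by design:

1. **The topology route does not dominate ORA on these fixtures.** Across
   20 seeds the topology method's mean AUC is ≈ 0.8 but exceeds ORA's in
   well under half the seeds. Under the generator's propagation rule the
   signal travels along global-graph edges, so any pathway containing DE
   genes usually also contains the very edges that produced them; DEG
   counts then carry nearly all the discriminative information, the
   perturbation p adds Monte-Carlo noise (its stand-alone AUC is
   0.5–0.65), and the Fisher product of a strong and a weak ranker trails
   the strong one. Separating the two routes would require negatives rich
   in *orphan* DE genes (present without their generating edges) far
   beyond what realistic gene sharing produces at 30-pathway scale.
2. **pG is anti-conservative under a global null.** With a null effect
   the change point still returns a split (a monotone noise curve has no
   elbow, but the minimizer exists), selecting roughly half the genome as
   DEGs, and edge-endpoint selection favors high-degree genes. Core
   genes have both high degree and high pathway membership, so pathways
   receive more DEGs than a uniform draw — the classic hub bias — and
   the hypergeometric component rejects at ≈ 3× nominal. The
   perturbation component itself is conservative. Users applying the
   framework to collections with heavily reused hub genes should read
   pNDE-driven significance accordingly.

Both are properties of the benchmarked framework at this scale, measured
by this package's own seeded studies; neither is patched over by tuning
the fixtures.
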