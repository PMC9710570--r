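---
title: "Dynamic aging-specific subnetworks: model, assumptions and design"
author: "DynAgeNet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic aging-specific subnetworks: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DynAgeNet)
```

# The model

DynAgeNet asks which genes are aging-related, given (i) a context-unspecific
protein-protein interaction network and (ii) gene expression measured in
donors of known age. Because the interaction network itself is static, age
specificity is injected by *network propagation*: expression at each age is
propagated over the network, and it is the *change* of the resulting edge
activity across ages — not expression itself — that serves as the predictive
signal.

## Expression-biased random walk and edge flux

For one age (or age group), let $g_v \ge 0$ be the aggregated expression of
gene $v$ (the mean over that age's samples). The walk on the network uses

* transition probabilities biased by the destination's expression,
  $P_{uv} = g_v / \sum_{w \in N(u)} g_w$ for neighbours $v$ of $u$;
* a restart distribution proportional to expression, $q_v = g_v / \sum_w g_w$;
* a restart probability $r \in (0, 1)$.

The stationary distribution solves $\pi = (1 - r)\,P^{\top}\pi + r\,q$ and is
found by power iteration started from $q$. The *flux* through the directed
edge $(u, v)$ is $\mathrm{EF}(u \to v) = \pi_u P_{uv}$; fluxes over all
directed edges sum to one. Every quantity is a ratio of expression scores, so
the walk is invariant to rescaling the expression column — normalization
*between* samples matters (see TMM below), global scale does not.

Each undirected interaction receives two directed fluxes; the snapshot weight
is the *smaller* of the two, a conservative choice that requires an
interaction to carry flux in both directions to score highly.

## From snapshots to the dynamic subnetwork

With $x$ ages there are $x$ weighted snapshots. Weights are first made
comparable across snapshots; the default scheme divides each snapshot by its
weight total (`per_snapshot_sum`), removing the per-age nuisance scale that
remains after taking edge-wise minima. A pooled affine min-max alternative is
provided and tagged in all outputs. The relative-change formula below is
itself scale-free per edge pair, so the scheme mainly affects the
*comparability* of magnitudes across edges.

Consecutive normalized snapshots $i, i+1$ yield a *differential* snapshot
with edge weights

$$ w_{i,i+1} = \frac{(w_{i+1} - w_i) \cdot 100}{w_{i+1} + w_i} \in [-100, 100], $$

with the convention $w_{i,i+1} = 0$ when $w_i = w_{i+1} = 0$ (no evidence of
change; the count of such pairs is logged). The ordered collection of the
$x - 1$ differential snapshots is the weighted dynamic aging-specific
subnetwork.

## Features and classifier

Nine per-gene feature definitions are registered (`featureRegistry()`),
spanning the families used in prioritization work of this kind: signed,
positive-channel and negative-channel weighted degree sequences; clustering
coefficient, harmonic closeness (edge distance $1/|w|$) and $k$-core
sequences on graphs sparsified to the top `theta` percent of absolute
differential weight; eigenvector centrality on absolute weights; graphlet
orbit counts (2-4-node graphlets, 15 orbits) on the union of the sparsified
graphs; and a (slope, mean, variance) trend summary of the signed weighted
degree. The exact feature set of the original line of work lives in its
supplementary material and is not reproduced here; the registry is pluggable
so alternative definitions can be dropped in, and conclusions should be read
as statements about this registry.

Each feature matrix feeds an L2-regularized logistic regression (one
"predictive model" per feature), evaluated by stratified 5-fold
cross-validation with folds shared across all models and subnetworks.
Per fold, coordinates are standardized by training-fold mean and standard
deviation (zero-variance coordinates are dropped for that fold). The best
model per subnetwork is the one with the highest fold-averaged AUPR, ties
broken by F-score and then model id.

## Significance, overlaps and enrichment

Significance against chance uses label permutations within the labeled set,
re-running the identical fold/standardize/fit/score pipeline per permutation;
the empirical p-value is $(1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$.
Overlap and enrichment tests are one-sided hypergeometric (upper tail), the
field-standard reading of "statistically significantly high overlap", with
Benjamini-Hochberg adjustment within each test family (the pair family for
overlaps, the full group-by-set family for enrichment). The enrichment
universe is the set of ground-truth labeled genes, and the four gene groups
(Predicted/NotPredicted crossed with Aging/NonAging) are taken as the strict
partition of that universe.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `restart` | 0.5 | restart probability $r$; the original propagation method's value is not published, so it is exposed and recorded in every manifest |
| `tolerance` | 1e-10 | L1 convergence tolerance of the power iteration |
| `zeroFloorFactor` | 1e-3 | zero expression scores are floored at this factor times the smallest positive score, keeping the chain irreducible on a connected network |
| `scheme` | `per_snapshot_sum` | snapshot weight normalization |
| `theta` | 25 | percentage of nonzero-weight edges kept by sparsification (top quartile of absolute differential weight) |
| `trimM`, `trimA` | 0.30, 0.05 | TMM double-trim fractions (canonical defaults) |
| `regStrength` | 1.0 | inverse ridge strength $C$; the fitted penalty is $\lambda = 1/(C\,n_{\mathrm{train}})$ |
| `classWeight` | balanced | each class contributes equal total weight; with ~6% positives an unweighted fit at threshold 0.5 predicts almost nothing |
| `threshold` | 0.5 | probability cut-off for the predicted-aging set |
| `k` | 5 | cross-validation folds |

# Preprocessing decisions

*Counts are TMM-normalized before per-age averaging.* TMM reference
selection (upper-quartile closest to the mean), precision weights and trim
fractions follow the canonical trimmed-mean-of-M-values algorithm; factors
are rescaled to geometric mean one. Whether propagation should consume
normalized values before or after averaging is not settled by the source
material; this pipeline normalizes per sample first, then averages — the
order is a documented configuration point of `runAll()`'s combination
handling rather than a claim.

*Missing network genes.* Genes present in the network but absent from the
expression data receive either zero (default) or, under `background_mean`,
the mean of the lowest-quartile expressed genes at that age. The latter is a
deliberate proxy for "average expression of non-active genes": presence
calls of the original microarray processing chain are proprietary and out of
scope, but the intent — missing genes get background-level rather than zero
expression — is preserved.

*Probe mapping.* Probes mapping to more than one gene symbol are discarded;
multiple probes per gene are averaged per sample. Age binning uses half-open
decade intervals (`[20, 30)` ... `[70, 80)`) by default, dropping samples
outside all bins.

*Labels.* Positives are the curated list intersected with the gene universe
(the intersection of all subnetworks' node sets); negatives are the
remaining genes minus the union of five additional curated aging datasets,
since genes appearing in any of them are too suspect to be confident
negatives.

# The synthetic study generator

Real studies of this design require four external data products (microarray
and RNA-seq expression, two interaction databases) plus curated labels and
pathways. The generator replaces them with a fully specified study whose
ground truth is known:

* a connected preferential-attachment network (500 genes, $m = 3$ by
  default) — degree-heterogeneous like real interaction networks;
* a planted aging module: 6% of genes, grown by breadth-first expansion
  around high-degree seeds in clusters of ~10 so that propagation fluxes
  around them change coherently (an independent `uniformPlacement` option
  exists for null experiments, where labels must not correlate with
  topology);
* expression at six ages (decade midpoints 25-75, 10 samples each):
  log-normal baselines, planted genes drifting linearly to $\pm 100\%$ of
  baseline across the age range (direction $\pm 1$ equiprobable, floored at
  zero), multiplicative log-normal noise (sdlog 0.3); a counts mode draws
  negative-binomial reads with per-sample log-normal depth to exercise TMM;
* incomplete curation: 30% of planted genes are withheld from the visible
  positive list ("hidden" genes, which therefore sit among the labeled
  negatives, as an incomplete database would put them);
* five exclusion lists of random non-planted genes, and five gene sets: the
  planted module plus `ceiling(0.2 n)` random contaminants, and four
  size-matched random sets.

What the generator does *not* emulate: probe-level microarray artifacts,
tissue structure, batch effects beyond per-sample depth, and — importantly —
the network proximity of real pathway members. In curated pathway databases,
members interact densely, so false-positive predictions adjacent to true
aging genes often still lie in aging pathways; here the contamination of the
planted pathway is uniform at random, so such neighbours never do. Passing
tests therefore demonstrate that the pipeline recovers planted dynamic
signal and hidden positives, not that real-data enrichment magnitudes are
reproduced; the enrichment power of the synthetic design is structurally
lower than the real study's.

# Numerical choices and degenerate inputs

* Power iterations (stationary distribution, eigenvector centrality) are
  deterministic: fixed start vectors ($q$, uniform), L1 respectively
  max-norm tolerances (1e-10), iteration caps that raise errors carrying
  the final residual. Eigenvector centrality iterates on $A + cI$ with $c$
  the maximum weighted degree, which preserves eigenvectors and prevents
  oscillation on bipartite-like graphs.
* Scale invariance of the walk and of the differential formula is exact in
  exact arithmetic and holds to ~1e-13 in floating point (rescaling inputs
  perturbs sums by one ulp).
* Degenerate cases have stated conventions: 0/0 differential weights are 0;
  all-equal weights under pooled min-max map to 0 with a warning; an empty
  predicted set has precision 0 with a `no_predictions` flag; test folds
  lacking one class are excluded from the AUPR average (all-excluded is an
  error); constant-feature folds fall back to chance-level scores.
* AUPR uses the average-precision formulation with tied scores processed as
  one threshold, making it invariant under strictly monotone score
  transforms.
* Fold assignment shuffles within each class under the seed and deals
  round-robin, positives first and negatives continuing from the next fold,
  so per-fold positive counts and total sizes each differ by at most one.
* Master seeds derive per-stage streams by a stable string hash
  (`stableSeed`), so adding a data combination never perturbs the
  randomness of the others.

# Problem sizes

The shipped tests and the acceptance script run the reference study at 500
genes, six ages, ten samples per age; propagation oracles use dense linear
solves on graphs of up to 50 nodes; graphlet counts are cross-checked by
exhaustive subset enumeration on 12-node graphs; permutation significance
uses B = 199. These sizes were chosen so a full run completes in minutes on
one core while keeping every statistical check non-trivial.

# Known limitations

* The nine feature definitions are a functional substitute for the original
  (unpublished here) feature set; rankings among models should be read
  accordingly.
* The restart probability of the original propagation runs is unknown; all
  results are conditional on the configured $r$ (default 0.5, recorded in
  manifests).
* Enrichment of predicted-but-unlabeled genes in the planted pathway is
  power-limited by the generator's uniform pathway contamination (see
  above): across seeds, a noticeable minority of runs yields an adjusted
  p-value above 0.05 even though hidden positives are recovered.
* The pipeline treats every expression column as an independent sample;
  repeated donors or regions are not modelled.
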