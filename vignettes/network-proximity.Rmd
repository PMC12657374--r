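---
title: "Network proximity for herbal combination inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network proximity for herbal combination inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The model

`herbnet` treats every pharmacological entity — an ingredient, a herb, a
disease — as a set of protein nodes on an undirected protein–protein
interactome, and quantifies interaction strength as a distance between those
sets. All distances are unweighted shortest-path hop counts: the interactome
carries no edge weights in this framework, and confidence- or
degree-weighting is out of scope by design.

Four metrics cover the four interaction types:

* **Closest distance** `closest_distance()` — for target sets $A$ and $B$,
  $$d^C(A,B) = \frac{\sum_{a\in A}\min_{b\in B} d(a,b) + \sum_{b\in B}\min_{a\in A} d(a,b)}{|A|+|B|}.$$
  Every target contributes its *nearest* counterpart in the other set, so two
  ingredients whose targets interleave on the network score near zero even
  when no target is shared. This is the ingredient–ingredient synergy score.

* **Shortest distance** `shortest_distance()` — the average hop count over all
  $|a|\cdot|b|$ cross pairs of targets. It is deliberately blunter than the
  closest distance (one remote target pulls the average up), which makes it
  suitable as a stable pairwise edge weight between ingredients.

* **Center distance** `center_distance()` — the herb–herb score. Each herb is
  represented by its *center ingredient*, the ingredient minimising the
  summed shortest distance to the herb's other ingredients
  (`center_ingredient()`); the herb–herb distance is then the shortest
  distance between the two centers' target sets. The center acts as a
  medoid of the herb's ingredient cloud on the interactome.

* **Disease proximity** `disease_proximity()` — directed: the mean, over the
  disease genes $Y$, of the distance from each gene to its nearest drug
  target in $X$. The direction matters: the measure asks "how well does the
  drug's target set cover the disease module?", not the converse, and it is
  zero exactly when every disease gene is itself a target. Herbs enter
  through the union of their ingredients' targets (`herb_target_union()`).

Two printed forms of these definitions in the surrounding literature are
internally inconsistent, and the package resolves both in favour of the form
that makes the quantity a well-defined average: the closest distance keeps
the min operator (without it the formula is just a grand sum), and the
shortest distance divides by the number of cross pairs $|a|\cdot|b|$ rather
than $|a|+|b|$. The literal sum-normalised variant remains available via
`shortest_distance(..., norm = "sum")` for comparison.

## Significance: three regimes

A distance is only interpretable against what random pairing would produce.
Three regimes are implemented, mirroring how the analysis is used at three
scales:

1. **Random-pair null + Fisher Z** (`sample_null()`, `z_test()`): for
   within-formula synergy scans and custom combination queries, a null of
   1000 pairs drawn uniformly (with replacement, seeded) from the relevant
   pair universe. The observed distance is standardised,
   $Z = (x-\mu_{null})/\sigma_{null}$, and the p-value is the **left tail**
   of the standard normal: small distances are the interesting ones, so
   significance means "closer than random". $\sigma_{null}$ is the sample
   standard deviation (denominator $n-1$). Pairs with $p < 0.05$ are flagged;
   no multiple-testing correction is applied, matching the raw-threshold
   practice this engine reproduces (p-values are returned, so users can apply
   `p.adjust` downstream).

2. **Per-screen disease nulls**: a repositioning screen
   (`reposition_for_disease()`, `reposition_for_entity()`) samples one null
   of 1000 random entity–disease pairs and shares it across all entities of
   that screen. A per-entity null would make screens quadratic in catalog
   size for no statistical gain, since the null describes the same pair
   universe either way. The null's strategy, size and seed travel with the
   result as provenance.

3. **Empirical 5% tail of the co-occurrence pool**
   (`cooccurrence_pool()`, `empirical_threshold()`): for browse-scale
   screening over very many candidate pairs, per-pair Z-tests are replaced by
   one exhaustive null — every unordered pair co-occurring in at least one
   formula, each scored once — and a nearest-rank 5% quantile of that pool
   serves as a distance cutoff. Co-occurring (hence often similar) pairs are
   intentionally *kept* in the pool: combining similar herbs is standard
   practice in the tradition these formulas come from, and excluding them
   would bias the null against exactly the clinically relevant region.

The nearest-rank rule is rank $\lceil qn \rceil$ on the ascending sort; the
implementation subtracts $10^{-9}$ before the ceiling because $q \cdot n$
can land a floating-point epsilon above an integer (0.05 × 100 evaluates to
5.000000000000001 in doubles, which would otherwise shift the threshold a
whole rank).

## Combination queries and disease modules

`recommend()` implements five query patterns — herb+herb,
ingredient+ingredient, their +disease variants, and
prescription+prescription+disease — each returning a *combination landscape*:
a typed node list plus scored, significance-flagged edges. Prescription
queries expand each formula to its herbs and ingredients and score
cross-prescription pairs (within-prescription pairs via
`include_within = TRUE`).

`build_combination_graph()` converts a landscape to a weighted graph with
$w = e^{-d}$. The exponential transform is monotone decreasing and finite at
$d = 0$; a $1/d$ transform would blow up on shared-target pairs, which are
common. By default only significant edges are kept in the exported graph.

`detect_modules()` runs Louvain modularity maximisation (resolution 1.0 by
default, exposed) with a fixed seed and canonical sorted vertex order, so a
given seed always yields the same partition. `disease_module_members()`
returns the entities sharing the disease node's community — the candidates
most likely to act synergistically on that disease.

**A design decision that ran the other way in practice.** The natural first
choice is to detect modules on the significant-edge subgraph, since that is
the network one would visualise. It does not work: after thresholding, what
survives on a benchmark scenario is essentially one dense component (the
proximal block plus its borderline neighbours), and the modularity-optimal
partition of a single dense component *fragments* it — on the default planted
scenario the "all proximal pairs in one community" partition has modularity
−0.015 while Louvain finds +0.09 by splitting, scattering the planted
ingredients across communities and recovering only about half of them.
Modularity compares observed edge weight to the weight expected from the
whole network, so it needs the non-significant edges as background.
`extract_disease_module()` therefore runs Louvain on the **complete**
weighted ingredient–disease network (relations `ing-ing` and `ing-disease`;
the herb layer is excluded because herb target unions duplicate their
ingredients' signal as hub nodes). With $e^{-d}$ weights the non-significant
edges form exactly the diffuse background against which a disease-proximal
module stands out; on the default scenario this recovers 85–100% of planted
ingredients across seeds.

## ADMET filtering

`admet_filter()` consumes a per-ingredient property table (categorical
`+`/`-` values and numerics) and a conjunctive filter spec such as
`HIA eq +`, `OB ge 30`, `BBB eq +` — the "absorbs well, bioavailable above
30%, crosses the blood–brain barrier" style of post-hoc pharmacokinetic
screen. Properties are never predicted here; the table is an input.
Candidates missing a referenced value are excluded and reported rather than
silently passed, and adding a conjunct can only shrink the surviving set.

## The synthetic-scenario generator

`generate_scenario()` emulates the *shapes* of a curated catalog so that the
whole pipeline is testable without external data:

* an interactome from a random-graph model — Barabási–Albert with $m = 3$ by
  default, since protein interactomes are approximately scale-free; nodes are
  relabelled `P0001`… and the graph is regenerated until connected;
* a disease module: a breadth-first ball of 30 nodes around a random center,
  the simplest connected structure under which proximity signal is
  well-defined; the single disease's gene set is the module itself;
* 20 *planted* ingredients drawing `round(bias × 8)` of their 8 targets from
  inside the module (remainder uniform) and 80 *background* ingredients
  drawing all targets uniformly — `proximity_bias` is the effect size, 0.8 by
  default;
* ingredients grouped five to a herb, herbs ten to a formula, with at least
  one formula guaranteed to contain a planted pair so within-formula scans
  can find one;
* truth labels (planted/background IDs, planted co-occurring pairs, module
  genes) for benchmarking, and `generate_admet_table()` for a toy property
  table whose marginal rates mirror the reported landscape of herbal
  ingredients (~86% HIA+, ~67% BBB+, ~37% hepatotoxicity alerts, skewed-low
  bioavailability).

The defaults — 1000 nodes, module 30, 20 + 80 ingredients, 8 targets, bias
0.8 — are the package's benchmark conditions; they were chosen once as a
realistic desk-scale miniature (a module and target sets small relative to
the network, an 80/20 background/signal split, a strong but not degenerate
effect) and the whole suite runs in minutes on one CPU at these sizes.

What the generator does **not** emulate: real interactome topology beyond
scale-freeness, correlated target annotations (real ingredients of one herb
share chemistry and targets), noisy or predicted targets, multiple diseases
with overlapping modules, and any chemistry in the ADMET table. Passing the
recovery benchmarks therefore shows the inference machinery is correct and
well-calibrated under its own assumptions — not that it will rank real
ingredients correctly, which depends on catalog quality in ways no synthetic
benchmark can certify.

## Numerical and determinism choices

* Unreachable pairs: every metric assumes finite distances, so interactomes
  are restricted to their largest connected component at load time (ties
  broken by the component holding the lexicographically smallest node). With
  `restrict_lcc = FALSE`, hitting an unreachable pair is an error, never a
  silent infinity.
* Unmapped targets are dropped with a count (`n_dropped`), erroring only when
  an entity loses *all* targets; skipped entities in screens are reported,
  not dropped.
* Ties: the center ingredient and screen ranks break ties by
  lexicographically smallest ID; iteration everywhere is over sorted IDs, so
  catalog row order never affects results.
* Batch distance computations go through a hop-count cache keyed by the node
  universe (one multi-source BFS sweep via `igraph::distances`), so each
  target set's single-source distances are computed once per screen.
* All sampling is seeded through a save/restore wrapper, so library calls
  never perturb the caller's RNG state; seeds are embedded in every
  stochastic output's provenance sidecar.
* IDs are opaque, case-sensitive strings; no identifier normalisation is
  attempted (that belongs to catalog curation, not inference).

## Benchmark problem sizes

The test suite and the acceptance script verify, at the sizes stated: exact
agreement of all four metrics with a hand-written BFS reference on 200 random
connected graphs (n ≤ 40); Z-test equality with the closed-form normal CDF to
1e−12; on-null flagged fraction within 0.05 ± 0.02 over 2000 draws (the
calibration universe uses 16-target ingredients so the closest-distance null
averages enough terms to be approximately normal, which the Z approximation
presumes); repositioning AUC ≥ 0.9 and disease-module recall ≥ 80% on the
default planted scenario; and monotone growth of the planted-background
distance gap in the proximity bias over 10 seeds, with a null gap at bias 0.

## Known limitations

* Hop-count distances ignore interaction confidence and direction; a
  literature-biased interactome biases every downstream score toward
  well-studied proteins.
* The normal approximation in the Z-test regimes is only as good as the
  null's normality; for small or oddly shaped pair universes the empirical
  threshold regime is the safer tool.
* Proximity cannot distinguish synergy from additivity, nor detect
  antagonism; it flags closeness, which is a necessary but not sufficient
  signature of functional interplay.
* Modularity-based module extraction inherits Louvain's resolution limit;
  very small disease modules can be absorbed into larger communities at
  resolution 1.
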