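---
title: "Phylogeny-guided ortholog sampling and phenotype-distance association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-guided ortholog sampling and phenotype-distance association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosample)
```

## The procedure and its assumptions

`orthosample` operates on a branch-length-annotated phylogeny of an enzyme
family (an ML protein tree, branch lengths in expected substitutions per
site) and treats the patristic distance — the sum of branch lengths along
the unique path between two leaves — as the working measure of evolutionary
divergence. Everything downstream assumes that distance is meaningful:
branch lengths must be non-negative (a negative length is a hard error;
a missing length is taken as 0 with a warning), and leaf labels must be
unique, because they serve as join keys between the tree and tabular
screen data. Patristic distances are invariant to rooting; of the two
clustering modes, only `max_clade` depends on where the tree is rooted,
since its clusters are clades of the tree as written. Unrooted trees
(basal multifurcation) are accepted.

The selection pipeline is three deterministic stages:

1. `threshold_clusters()` partitions the leaves under a maximum
   within-cluster patristic diameter `threshold`.
2. `plan_subclusters()` cuts each cluster into
   `k = max(1, ceiling(fraction * n))` subclusters by agglomerative
   hierarchical clustering on the patristic sub-matrix.
3. `pick_representatives()` selects one leaf per subcluster.

Given identical inputs the composed `sample_tree()` output is
byte-identical across runs — there is no randomness anywhere in selection.

## Tunable parameters

* `threshold` (branch-length units, i.e. substitutions/site; default
  **1.75**). The maximum patristic diameter tolerated inside one cluster.
  The default reproduces the published screen design for the NadA/IspG
  families; for other families it should scale with the tree's depth, since
  the number of clusters grows as the threshold shrinks.
* `mode` (`"max_clade"` default, or `"max"`). The cited clustering tool's
  default mode is clade-restricted, and the published analysis does not
  state which mode was used, so the clade-restricted variant is the
  default here; `max` gives the minimum cluster count achievable by cutting
  branches, dropping the clade restriction. Both enforce the same diameter
  constraint.
* `fraction` (unitless, in (0, 1]; default **0.2**). Subcluster count as a
  share of cluster size — the "20% rule". Rounding is `ceiling` with a
  floor of one subcluster per cluster, which guarantees every cluster
  contributes at least one representative; on many small clusters this
  inflates the selected share above 20% (47 selected from 192 is ~24%),
  which matches the published set sizes.
* `linkage` (`"average"` default, `"complete"`, `"single"`). The published
  analysis used hierarchical subclustering without stating the linkage;
  average linkage is the conventional choice for taxon sub-grouping on
  distance matrices and is the default, with the others selectable.
* `priorities`: a `(leaf, rank)` table, higher rank preferred; the
  convention used in the reference screen is reference strain = 2,
  previously tested sequence = 1, everything else 0. Whether those two
  classes carry distinct ranks or one pooled rank is the caller's choice —
  the published description does not resolve it.

## Statistics

**Representativeness.** `representativeness_report()` compares the
patristic-distance-from-focal distribution of the selected subset against
that of the *full* set (focal excluded from both; a 192-leaf tree yields
191 host distances). The selected set is a subset of the full set, so the
two samples overlap; this mirrors exactly the published validation (191 vs
47, not 144 vs 47). A consequence worth knowing: with overlapping samples
the rank-sum test is conservative — under honest random subsampling its
p-values concentrate above 0.5 rather than being uniform. The test suite
checks uniformity on the disjoint subset-vs-complement form (where it
holds) and conservativeness on the overlapping form. A small p therefore
remains strong evidence of biased sampling, and the calibration checks
show the deliberate most-distant-leaves subsample is rejected essentially
always while the pipeline's own selections are not.

**Rank-sum test.** `rank_sum_test()` is two-sided. For pooled samples of
at most 25 values (`exact_limit`) the exact null distribution of the rank
sum over all `choose(N, n1)` assignments is computed by subset-sum
convolution on doubled mid-ranks, handling ties exactly; two-sided p is
twice the smaller tail, capped at 1. Above the cutoff — exact enumeration
at the published sample sizes (191 + 47) is infeasible, so the published
p-values were necessarily asymptotic — a normal approximation with
tie-corrected variance and a 0.5 continuity correction is used; the
continuity correction can be disabled (`continuity = FALSE`), since
whether the original analysis applied one is not stated.

**Correlation ratio.** `correlation_ratio()` computes
η² = SS_between / SS_total for a categorical outcome against a continuous
covariate, and η as its positive root. For binary outcomes η² equals the
R² of the one-way least-squares decomposition (cross-checked in the test
suite), and η is invariant to affine rescaling of the distances. η is
undefined — and an error — when only one category is present or the
covariate has zero variance. `outcome_distance_association()` applies it
to a screen table joined to the tree: outcomes are binarized with
`partial` counted positive by default (that convention reproduces the
published "only 8" IspG aerobic count, which includes the `+/-` entry),
`NT`/`?` rows dropped, and the focal host's own row (distance 0, positive)
included by default since it appears as a row of the published tables;
both conventions are flags, because the exact rows entering the published
η values are not stated.

**Kruskal–Wallis.** `kruskal_wallis()` wraps the standard tie-corrected H
test (used in the reference work to show predicted translation-initiation
rates do not differ between outcome groups), with the degenerate
all-values-identical case reported as H = 0, p = 1.

## What the simulators emulate — and what they do not

`simulate_yule_tree()` grows a pure-birth tree: at *k* extant lineages the
waiting time to the next speciation is exponential with rate
`k * birth_rate`, a uniformly chosen lineage splits, and a final interval
at *n* lineages is appended, so the expected root-to-tip depth is
`sum(1/(2:n))` (about 4.88 at n = 200, rate 1) — an analytic anchor the
test suite checks. Pure birth was chosen over birth–death precisely for
that checkability. Its trees are ultrametric (all tips equidistant from
the root), which real ML protein trees are not: rate heterogeneity across
lineages, and hence much of the spread in distances from a focal leaf, is
under-represented. Distances from a focal tip on an ultrametric tree take
few distinct values (twice the depth of each shared ancestor), so ties are
far more common than in real data — a stress test for the tie handling in
the rank statistics, but a reason not to read the simulated cluster counts
as predictions for real trees.

`simulate_trait()` draws binary outcomes under three regimes:
`clade_gain` picks the internal node containing the focal leaf whose leaf
count is closest to `clade_fraction * n` (ties to the smaller clade) and
assigns positives with probability `p_in` inside and `p_out` outside —
coupling clade membership to distance from the focal leaf, as in a screen
where complementation concentrates around the host's clade; `distance_decay`
uses a logistic curve in distance with midpoint `d0` and scale `s`;
`random` is iid Bernoulli. Defaults (`p_in = 0.95`, `p_out = 0.05`,
`clade_fraction = 0.5`) put the clade regime's mean η in the 0.6–0.7 range
on 150-leaf trees — the strength of association the NadA screen shows —
while the random regime sits near 0.05–0.1, the IspG regime. Passing these
calibration tests shows the statistics separate the two regimes on
clade-generated data; it does not certify power against subtler signals
(e.g. weak distance decay) or against non-phylogenetic confounding present
in real screens (expression failures, oxygen sensitivity of the assay).

`eta_null_distribution()` permutes outcome labels across leaves to give an
empirical null for η; under the random regime the observed-η percentile is
uniform across seeds (checked by a KS test in the suite), and under strong
clade signal the observed η exceeds the 99th null percentile.

## Numerical choices and tie-breaking

* Cluster ids are numbered by the first member's position in the tree's
  tip order; subclusters follow `stats::cutree` numbering on
  lexicographically sorted labels, so merge ties in `stats::hclust`
  resolve toward the smaller label pair deterministically.
* In `max` mode the greedy cut compares depth sums against
  `threshold + 1e-9 * max(1, threshold)`: branch-length sums accumulated
  down the tree and matrix entries can disagree in the last float bits,
  and without the guard a threshold lying exactly on a pairwise distance
  (common on ultrametric trees) flips cuts arbitrarily. Ties between
  equally deep children cut the lower-postorder child.
* Representative selection order is: unique highest priority rank
  (`reason = "priority"`); else subcluster medoid, the member with minimum
  summed patristic distance to the others (`"medoid"`); else smallest
  label (`"lexicographic"`). Singleton subclusters report `"medoid"`.
* The exact rank-sum cutoff `n1 + n2 <= 25` keeps the convolution table
  small; at the cutoff the exact and normal p agree within 0.02 on
  tie-free data (checked over random instances at n1 = n2 = 12).
* Degenerate inputs: fully tied rank-sum samples give p = 1; η on a single
  category or zero-variance distances is an error rather than a silent 0;
  empty clusters and out-of-range fractions are errors.

## Problem sizes used in the checks

The test suite and `scripts/acceptance.R` run entirely on synthetic data
plus the shipped screen tables: exhaustive clustering oracles on trees of
6–12 leaves (subset-DP partition minimum, edge-cut enumeration, clade
enumeration), rank-test enumeration up to 12 pooled values, η calibration
over 60–100 seeds on 100–150-leaf trees, and representativeness
calibration over 100–200 replicates of 100-leaf trees. These sizes keep
the full suite within a few minutes on one CPU while leaving every
statistic's sampling noise well inside the asserted margins.

## Known limitations

* The deposited ML trees for the NadA/IspG families are consumed as
  inputs, not redistributed; the three checks that need them (η = 0.61 /
  0.03, the 191-vs-47 rank-sum p, the 15-cluster count at threshold 1.75)
  fail with instructions until the files are placed under
  `inst/extdata/deposited/`. All other results are self-contained.
* Tree inference, alignment, homolog search, and support values are out of
  scope; internal-node labels are carried as strings and never used.
* The association statistic is the plain correlation ratio, as in the
  reference analysis — not a phylogenetic comparative method; it ignores
  the non-independence of related taxa, and a significant η should be read
  as descriptive structure, not as a test calibrated under a trait
  evolution model.
* `max` mode minimizes cluster count among branch-cut partitions (as the
  cited tool does). Across ~900 random small-tree instances the test
  oracles found no case where an unrestricted leaf partition beat the best
  branch-cut partition, but no proof of equivalence is claimed.
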