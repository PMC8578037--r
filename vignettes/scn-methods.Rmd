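---
title: "Structural covariance networks from subcortical morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance networks from subcortical morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scovnet)
```

## The analysis in one paragraph

A structural covariance network (SCN) is a group-level graph: nodes are
brain regions, and an edge links two regions whose gray-matter volumes
covary across the participants of a group. `scovnet` implements this
analysis for a catalog of 100 subcortical regions (bilateral basal ganglia
structures plus amygdaloid, hippocampal, and thalamic subfields): volumes
are adjusted for age and intracranial volume (ICV) by per-region ordinary
least squares; the residuals of each group are correlated (Pearson) into a
100 x 100 association matrix; the matrix is binarized by keeping the
top-`k` correlations at each network density of a sweep (0.17 to 0.45 in
steps of 0.02); every network's global topology (clustering coefficient C,
characteristic path length L, global efficiency, the normalized small-world
indices gamma, lambda, sigma, and modularity Q) and nodal topology (degree,
clustering, betweenness) is measured; and groups are compared by a
permutation test whose across-density summary is a functional
(area-between-curves) statistic. A volumetric arm (MANCOVA, per-region
ANCOVA with FDR and pairwise post-hoc contrasts, demographic tests,
region-psychometric correlations) covers the non-network statistics, and a
synthetic-cohort generator provides data with known structure for testing
and calibration.

## Covariate adjustment

Each region's volume is regressed on `[1, age, ICV]` and replaced by the
residual. Covariates are mean-centered first — this changes only the
intercept, never the residuals, and improves conditioning. The default
fitting sample for a two-group comparison is the *pooled pair*
(`scope = "pooled_pair"`): one regression over both groups, fitted once,
before any permutation. The permutation test relabels *adjusted* volumes,
so adjustment must not depend on the labels — pooled fitting keeps the two
groups exchangeable under the null hypothesis. Per-group and pooled-over-
all-groups fits are available for sensitivity analysis
(`scope = "per_group"`, `"pooled_all"`); per-group adjustment makes each
group's residuals mean-zero within the group but breaks exchangeability,
so the test refuses nothing but the user should know what they are asking.

The residual operator is a projection, which gives two invariants the test
suite checks: residualizing twice changes nothing, and any affine rescaling
of a covariate (age in months instead of years) leaves the residuals
untouched.

## Network construction

Edges are defined by ranking the N(N-1)/2 region pairs by their
correlation, signed, largest first — positive covariance is what structural
covariance studies threshold — and keeping the top `floor(density *
N(N-1)/2)`. An `absolute`-value ranking is available as a flag. Ties are
broken by lexicographic pair order so that results are bit-reproducible;
ties have probability zero for continuous data but occur in constructed
test cases. Because thresholding is rank-based, the resulting network is
invariant under any strictly monotone transform of the correlations, and
the edge set at a lower density is nested inside that at any higher
density.

The sweep runs from density 0.17 to 0.45 in increments of 0.02 (15
networks per group). The lower end is tied to the minimum-connected-density
rule: the analysis assumes every analyzed network is a single connected
component, and `minimum_connected_density()` reports the smallest grid
density at which that holds (by binary search over the nested edge sets).
Networks that fragment inside the sweep are flagged; path-length-based
metrics refuse flagged networks rather than silently switching convention.

## Topological properties

* **C** — Watts-Strogatz local clustering (triangles over possible
  triangles at each node; degree < 2 contributes 0), averaged over nodes.
* **L** — mean shortest-path length over ordered pairs; defined only on
  connected graphs.
* **E_global** — mean inverse shortest-path length, with 1/Inf = 0, so it
  tolerates disconnection.
* **gamma, lambda, sigma** — C and L normalized by their means over
  `n_random` degree-preserving rewirings of the same graph (double-edge
  swaps, connectivity re-checked with retry; 20 references and 10·E swap
  attempts for observed networks). sigma = gamma/lambda > 1 is the
  conventional small-world criterion.
* **Q** — Newman modularity maximized by greedy agglomerative merging
  restarted from 1000 random vertex orders, keeping the best partition;
  never reported below the single-community baseline Q = 0.
* **Degree distribution** — the empirical cumulative distribution
  P(K >= k) is fitted by Levenberg-Marquardt nonlinear least squares to the
  exponentially truncated power law k^(a-1) exp(-k/b), with start values
  from the log-linear form; R^2 is reported on the cumulative curve. The
  fit is evaluated at the lowest analyzed density by default (the sweep's
  most sparse, most informative network); the density is a flag because a
  single published (a, b, R^2) per group does not determine the choice.
* **Resilience** — random failure: remove a fraction of nodes uniformly at
  random, record the relative size of the largest connected component,
  average over repetitions.

Graph primitives (shortest paths, betweenness, rewiring, greedy merging)
are delegated to igraph; a compiled (Rcpp) implementation of the
correlation-to-metrics sweep carries the permutation loops. The test suite
checks both against brute-force enumeration oracles (Floyd-Warshall
distances, triple counting, path enumeration, exhaustive partition search)
on every connected labeled graph with up to 5 nodes and on random graphs
with 6, 7, and 20 nodes.

## Permutation inference and the FDA statistic

For two groups with sizes n1 and n2, each of `n_perm` (default 1000)
repetitions partitions the pooled, already-adjusted participants uniformly
at random into sizes n1 and n2 and recomputes every metric curve for both
pseudo-groups. One relabeling schedule drives all metrics, preserving their
joint dependence. Per density, the two-tailed p-value is the add-one
percentile rule p = (1 + #{|null| >= |observed|}) / (n_perm + 1), which
cannot return 0 and is valid for finite permutation counts. Across
densities, the functional statistic is the signed area between the two
curves (the sum of per-density differences); its p-value uses the same
percentile rule. Two-tailed is the default (a one-tailed flag exists).

Estimator noise: sigma and Q are themselves Monte-Carlo estimates. Inside
the test, both the observed statistic and every permutation replicate use
the same scaled estimator settings (`n_random_perm`, default 6 references
with 3·E swap attempts; `modularity_restarts_perm`, default 20), so the
observed value and the null draws are exchangeable under the null
hypothesis and the test stays calibrated; the separately reported
descriptive curves use the full-quality settings. If a permutation
replicate fragments at some density, that density is recorded as missing
for that replicate and the functional statistic is computed from the
available densities, rescaled to the full grid length (complete-pairs
counting); fragmented replicates are counted and reported.

Nodal inference repeats the same machinery per node (degree, clustering,
betweenness curves), yielding 100 FDA p-values per metric, corrected by
Benjamini-Hochberg across nodes at q = 0.05; raw and corrected decisions
are both reported, because "significant before, empty after correction" is
itself a result worth seeing.

## Volumetric statistics

The omnibus MANCOVA treats all regional volumes as dependent variables
with group as predictor and age and ICV as covariates; Wilks' lambda is
computed with the group term entered after the covariates, with Rao's F
approximation. The multivariate effect size is 1 - lambda^(1/s) (s from
Rao's formula); the convention is recorded in the result because more than
one is in circulation. With 100 dependent variables the MANCOVA needs more
than 103 participants; smaller cohorts are refused with a message pointing
at the per-region arm, which runs one ANCOVA per region, corrects the 100
F-test p-values by Benjamini-Hochberg, and computes unadjusted pairwise
covariate-adjusted t contrasts (cMDD-HC, RD-HC, cMDD-RD) only for regions
that survive FDR — correction lives at the region level, where the
multiplicity is.

Demographics use the standard battery: Pearson chi-square without
continuity correction for gender-by-group, one-way ANOVA for age,
education, and rumination (RRS), Kruskal-Wallis for the skewed HAMD-17,
Mann-Whitney U for illness duration between the patient groups.
Region-psychometric correlations are Pearson for RRS and illness remission
and Spearman for HAMD-17 and illness duration, two-tailed, with pairwise
deletion of missing clinical values.

## The synthetic cohort generator

No participant-level data are distributed with this kind of study, so the
package ships a generator that produces cohorts with the statistical
structure the analysis assumes:

volume = base mean + marker shift(group) + beta_age·(age - age_ref) +
beta_icv·(ICV - ICV_ref) + (Lambda_g f)_i + noise,

with standard-normal factors f and independent Gaussian noise. Group
differences enter through two independent channels. *Marker effects* are
additive mean shifts in designated regions; they move group means without
touching covariance, so the volumetric arm can be tested in isolation.
*Covariance geometry* is carried by the group's loading matrix Lambda_g,
which is what the SCN topology sees; mean shifts are invisible to it.

The shipped `cohort_spec_paperlike()` uses the study's group sizes
(131 currently depressed, 67 remitted, 235 controls) over the 100-region
catalog. Controls combine five strongly clustered modules with 30 strong
long-range shortcut correlations — a small-world covariance geometry with
high clustering and short paths. Currently depressed patients carry a
smooth distance-decay ring (Gaussian loading profiles of width tau = 8
regions): correlation falls off with ring distance, so the thresholded
network is a thick ring band at every analyzed density — an elongated
geometry with markedly longer characteristic paths, higher normalized path
length, and a weaker small-world index. Remitted patients sit between the
two (the decay ring plus a reduced shortcut set). The marker shifts mirror
the published volumetric findings: bilateral pallidum and thalamic
PuA/VLa/VLp reductions, trait-like on the left (both patient groups),
state-like on the right (remitted only). Ages, ICV, and the clinical
instruments (HAMD-17, RRS, education, durations) are drawn from the
published per-group means and dispersions; durations use a lognormal
matched to mean and SD because they are non-negative and right-skewed.

Why these geometries: binarization is rank-based, so at a fixed density a
"weaker" version of the same covariance pattern produces the *same* binary
network — only the *arrangement* of the strong correlations matters. At a
fixed edge budget, removing clustering frees edges that reappear as random
cross-connections, which also shorten paths; clustering and path length
therefore move together under most constructions, and the published
patient pattern (longer paths with reduced small-worldness) is a
constrained corner. The decay ring reaches it by keeping nearly *every*
region pair on a planted correlation gradient, so almost no edge budget is
left for random shortcuts and path length stays high across the sweep,
while the small-world deficit is carried by the normalized path length
(clustering itself is approximately matched between the planted groups).
The loading strengths put the planted correlation levels (about 0.1-0.5)
clear of sampling noise at the study's group sizes (sd(r) ~ 0.09 at
n = 131).

What the generator does not emulate: segmentation error, site or scanner
effects, non-Gaussian or heavy-tailed volume distributions, age-by-group
interactions, and spatial autocorrelation of adjacent structures beyond
what the factor blocks induce. Passing tests on these cohorts demonstrates
that the pipeline recovers structure it was designed to detect under its
own assumptions — not that real cohorts satisfy those assumptions.

`cohort_spec_tiny()` (20 regions, 30 per group) is the same design scaled
down for fast tests; `cohort_spec_paperlike_tiny()` keeps the 20-region
catalog but the study's group sizes; `cohort_spec_null_tiny()` shares one
factor model between groups for type-I-error calibration; and
`cohort_spec_markers()` plants pure mean-shift markers (0.5 SD trait in
both patient groups on the left pallidum, 0.6 SD state in the remitted
group on the right pallidum) with no covariance differences, at the
study's group sizes — effect sizes chosen a priori by standard power
arithmetic so the post-hoc signature is detectable at those n.

## Numerical and reproducibility choices

* Exact edge count `floor(density · N(N-1)/2)`, ties broken
  lexicographically: bit-reproducible thresholding.
* All stochastic stages (rewiring, permutation schedules, modularity
  restarts, resilience) draw sub-seeds derived deterministically from one
  master seed per run, hashed per stage and index, so adding a stage never
  shifts another stage's stream.
* The orientation of a comparison is canonicalized internally
  (alphabetical); swapping the order of the two groups negates observed
  differences and leaves every p-value identical.
* Degenerate inputs fail loudly with typed errors: zero-variance regions
  (correlation undefined), constant covariates (rank-deficient design),
  regular graphs (degree distribution degenerate), disconnected graphs
  passed to path-length.

## Problem sizes used by the shipped checks

The calibration suite runs 200 null datasets (two groups of 40 over 20
regions) at 200 permutations against the clustering-coefficient curve; the
effect-recovery suite runs 30 paperlike datasets at 100 permutations with 6
reference graphs per network; the marker suite runs 50 datasets at the full
group sizes over the 20-region catalog. These sizes are the package's
standing choices for its own regression checks; analyses of real data
should use the defaults (1000 permutations, 20 references, 1000 restarts).

## Known limitations

* Pearson edges only; no partial-correlation or sparse-inverse-covariance
  networks (undefined when regions outnumber the smaller group, as here).
* Group-level networks mean there is one network per group; individual
  variability enters only through the permutation null.
* The FDA statistic is the signed area between curves — the simplest
  across-threshold functional; curve differences that cancel across
  densities (sign flips) can escape it, though the per-density p-values
  remain visible.
* Weighted, directed, and targeted-attack analyses are out of scope.
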