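---
title: "Morphological brain networks for gyri and sulci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological brain networks for gyri and sulci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphnet)
```

## The problem

Convex ridges (gyri) and concave grooves (sulci) of the folded cortex
differ in their microstructure, connectivity and development, which
motivates asking whether *networks* built over gyral regions organize
differently from networks built over sulcal regions. `morphnet`
implements a complete single-subject morphological network analysis for
this question: each cortical region is summarized by the distribution of
a morphological feature (cortical thickness, fractal dimension,
gyrification index, sulcal depth) over its surface vertices, and an edge
between two regions measures how similar those two distributions are.
Everything downstream — thresholding, small-world topology, test-retest
reliability, behavioural variance decomposition, group contrasts — runs
on these similarity matrices and their gyral/sulcal blocks.

No imaging data ship with the package. A synthetic-cohort generator with
recorded ground truth stands in for vertex-wise feature maps, so that
every stage of the pipeline is testable end to end.

## Similarity model

For one subject and one feature, each retained region contributes a
vector of vertex values. For a region pair (i, j):

1. a shared support grid of 256 (2^8) equally spaced points spans the
   pooled range of both samples, padded by 10% of the range on each side
   so kernel tails are not clipped;
2. each sample gets a Gaussian kernel density estimate with Silverman's
   rule-of-thumb bandwidth, evaluated on the grid and renormalized to sum
   to one — the sampled density is treated as a discrete probability
   distribution, which is what the divergence formulas consume;
3. the Jensen-Shannon divergence
   `JSD(P||Q) = 0.5 KLD(P||M) + 0.5 KLD(Q||M)` with `M = (P+Q)/2` is
   computed with base-2 logarithms, so `JSD` is bounded by 1;
4. the edge weight is `1 - sqrt(JSD)`, a similarity in [0, 1].

Identical distributions give similarity 1; distributions with disjoint
support give 0. The diagonal is 1 by definition (self-JSD is
analytically zero). With the default bilateral parcellation — 29 gyral,
31 sulcal and 14 ambiguous regions per hemisphere, ambiguous regions
excluded — the result is a 120 x 120 matrix over 58 gyral + 62 sulcal
nodes, decomposing into G-G (58 x 58), S-S (62 x 62) and G-S (58 x 62)
blocks. Nodes are ordered canonically (gyral first, ascending region id,
then sulcal) so the block layout is deterministic.

Three numerical choices deserve flagging. *Log base:* base 2 throughout;
the similarity transform requires `JSD <= 1`, which only holds in bits.
*Support:* the grid is chosen per region pair rather than globally —
this mirrors the pairwise nature of the comparison and avoids resolution
loss for narrow distributions, at the cost that different edges use
different grids. *Evaluation:* the default engine evaluates each KDE by
linear binning plus truncated-kernel convolution in compiled code
(the same discretization `stats::density()` uses, kernel cut at 6
bandwidths); `engine = "reference"` runs the plain-R path through
`estimate_density()` and `jsd()`. The two agree to well below 1e-3 in
similarity, and the package tests enforce that.

## Graph topology

Weighted blocks are binarized by proportional (sparsity) thresholding:
the `round(s * N(N-1)/2)` strongest unique edges are kept. Ties at the
cutoff break by ascending (row, column) index, which makes thresholding
deterministic and edge sets nested across sparsities. The analysis range
is s = 0.08 to 0.40 in steps of 0.02 (17 thresholds). The lower end is
anchored by an estimability criterion: the average degree `s (N-1)` must
reach `ln N`, giving minimal sparsities of 0.071 for 58 nodes and 0.068
for 62 nodes — both below the 0.08 floor, so every evaluated threshold
is estimable.

At each sparsity the package computes the clustering coefficient Cp
(mean nodal clustering; nodes of degree < 2 contribute 0) and the
characteristic path length Lp (mean shortest path over reachable pairs;
if the graph is disconnected the value is computed over reachable pairs
only and flagged, which keeps curves finite instead of infinite or
silently restricted to the largest component). Both are normalized by
the mean of 100 degree-preserving rewired null networks (double edge
swaps, 10 x |E| swap attempts per null): gamma = Cp/Cp_null,
lambda = Lp/Lp_null. A small-world network has gamma > 1 with
lambda near 1. Curves are summarized by the trapezoidal area under the
curve over the sparsity range.

## Test-retest reliability

For cohorts scanned in repeated sessions, each edge's reliability is the
one-way random-effects intraclass correlation
`ICC = (MS_b - MS_w) / (MS_b + (k-1) MS_w)`, with MS_b and MS_w the
between- and within-subject *mean* squares of a one-way ANOVA and k the
number of sessions. (Some descriptions of this formula say "sum of
squares", but the formula's scale only works with mean squares; the
standard ICC(1,1) reading is implemented, and the package tests pin it
to R's ANOVA machinery to 1e-10.) ICCs can be negative; they are
reported unclamped but classified into the conventional bins at
0.25/0.4/0.6/0.75 using half-open intervals `[lo, hi)` — strict
inequalities would leave boundary values unassigned, and everything at
or below 0 is "poor". Gyral-vs-sulcal reliability is compared by a
two-sample permutation test that pools edges and re-splits them at the
original sizes, treating edges as exchangeable units.

## Behavioural variance component model

Behavioural items are z-scored across subjects and averaged within
domains. Between-subject network similarity M is the correlation matrix
of subjects' vectorized network blocks, with each edge z-scored across
subjects first so high-variance edges do not dominate. The model for a
domain score vector y is `Y = B + E`, `B ~ N(0, sigma_b^2 M)`,
`E ~ N(0, sigma_e^2 I)`; the variance explained by network similarity is
`V = tr(Sigma_B) / (tr(Sigma_B) + tr(Sigma_E))`, components summed over
phenotypes.

The fitting algorithm is a deliberate design choice: a method-of-moments
(Haseman-Elston-type) estimator solving the 2 x 2 trace system

```
[ tr(M^2)  tr(M) ] [ sigma_b^2 ]   [ y' M y ]
[ tr(M)    n     ] [ sigma_e^2 ] = [ y' y   ]
```

per phenotype. It is deterministic, closed-form, testable, and unbiased
in the package's recovery suite (mean error < 0.02 across
V in {0, 0.2, 0.5, 0.8} at n = 300); REML would be a noted alternative
but is not implemented. Only the traces of Sigma_B and Sigma_E are
estimated — V depends on nothing else. Negative component estimates are
clamped to zero (with a count of clamps reported); `M = I` makes the
system singular and raises a non-identifiability error rather than
returning arbitrary numbers. Significance of V comes from shuffling
subject rows of Y jointly across phenotypes, 1000 times by default, with
the add-one convention `p = (1 + #{V_perm >= V_obs}) / (1 + n_perm)`
(one-sided, since V is nonnegative by construction). FDR control across
domains is Benjamini-Hochberg at q = 0.05. Significant domains can be
localized by edgewise Pearson correlations with BH-FDR across edges and
per-node counts of incident significant edges.

## Group comparisons

Patient-control contrasts residualize the per-subject summary on age and
sex by OLS, then permute group labels (residualize-then-permute; valid
under exchangeability of residuals, with Freedman-Lane as the noted
alternative). Within-subject contrasts — G-G vs S-S mean similarity, or
each region's intra-class vs inter-class mean similarity — use paired
sign-flip permutations, because the compared quantities belong to the
same subjects and an unpaired shuffle would be mis-specified. Nodal
contrasts apply BH-FDR within each class. All permutation tests are
two-tailed with the add-one convention and exactly reproducible under a
fixed seed; location tests default to 10,000 permutations (the
variance-component null keeps its stated 1000).

## The synthetic cohort generator

`simulate_cohort()` draws, for region r, subject s, session t:

```
x ~ Normal(mu_r + delta_sr + eps_srt, sigma_r)
```

- `mu_r`: region mean = class mean (defaults 2.7 gyral / 2.3 sulcal,
  thickness-like, in mm) + Normal(0, tau_class) dispersion
  (tau = 0.15), drawn once per cohort so inter-regional similarity is a
  cohort-level property, as in real anatomy;
- `sigma_r`: region-level within-region SD, lognormal around 0.5 mm with
  log-SD 0.25. This second dispersion dimension matters: real regions
  differ in how heterogeneous their feature values are, and
  broad-distribution regions overlap many others, acting as hubs. With a
  single common SD the similarity structure is a function of
  |mu_i - mu_j| alone and thresholded graphs degenerate into 1-D
  proximity lattices (inflated path lengths, isolated extreme regions);
  with SD heterogeneity the thresholded blocks sit in the small-world
  regime the analysis assumes (gamma > 1 at every threshold, mean lambda
  ~ 1.3 — approaching 1 from above as sparsity grows, as in empirical
  networks);
- `delta_sr ~ Normal(0, sigma_subject^2)`: stable subject-by-region
  effect (default 0.1);
- `eps_srt ~ Normal(0, sigma_session^2)`: session noise (default 0.05).
  The vertex-wise pattern itself is drawn once per subject and carried
  across sessions — it is the subject's anatomy — so sessions differ
  only through eps. The generative edgewise reliability ratio is exactly
  `sigma_subject^2 / (sigma_subject^2 + sigma_session^2)`, and
  sigma_session = 0 yields edgewise ICC = 1 identically.

Group effects perturb the sulcal region means of the patient group by
Normal(0, group_effect^2), drawn once per cohort: patient sulcal means
are more dispersed, so patient S-S similarity drops, monotonically in
`group_effect`. Age and sex are generated independent of group unless an
explicit `group_age_shift` is set, so covariate-adjusted tests are not
confounded by construction. Behaviour is generated from the same
variance-component model the estimator assumes, with
`sigma_b^2 = V_true` and `sigma_e^2 = 1 - V_true`, after clipping
negative eigenvalues of M and renormalizing its diagonal (finite-sample
correlation matrices can be indefinite).

What the generator does *not* emulate: cortical geometry and spatial
smoothing, site/scanner effects, non-Gaussian or multimodal vertex
distributions, and hemispheric asymmetries. Passing tests therefore
demonstrate the correctness and calibration of the estimators on data
satisfying their assumptions — not robustness to the full complexity of
real imaging data.

## Problem sizes and tolerances

The test-suite simulations are sized for quick, repeated runs: cohorts
of 10-60 subjects on reduced bilateral atlases (3-8 regions per class
per hemisphere), 100 rewired nulls for small-world normalization, 500
null replicates for type-I calibration (empirical rejection required to
fall in [2%, 9%] at nominal 5%), 20 replicates for variance-component
recovery at n = 300 subjects (required within 0.1 of truth), and 3
cohort seeds for the reliability band (mean edgewise ICC required in
[0.3, 0.7] when the generative ratio is 0.5 — the band is wide because
the similarity transform is nonlinear and folding of location
differences attenuates the edge-level ratio below the vertex-level
one). Oracle comparisons are exact: discrete JSD to 1e-12 against
direct summation, Cp/Lp to 1e-12 against brute-force triangle counting
and Floyd-Warshall over *all* labelled graphs on up to 6 nodes, ICC to
1e-10 against R's ANOVA tables, and BH-FDR identical to a hand-written
step-up on random p-vectors.

## Interfaces

The package's surface is its functions; `load_config()` (YAML over
documented defaults, unknown keys rejected) and `run_pipeline()`
(simulate, build networks, subcomponent contrasts, topology,
reliability, association, group comparison, with one master seed
spawning per-stage seeds and a manifest of parameters and output
hashes) orchestrate full runs. A worked example with printed output is
in the README; `scripts/acceptance.R` recomputes the headline constants.

## Known limitations

- Correlation- or distance-based similarity variants are not
  implemented; the similarity is the JSD-based one throughout.
- Weighted-graph topology, the small-worldness scalar, modularity and
  hub metrics are out of scope.
- The bandwidth rule, grid placement and padding are declared choices;
  other reasonable choices shift similarity values slightly (the
  package's invariance and equivalence tests quantify the binning
  effect at < 1e-3).
- Edgewise multiple-comparison correction is BH-FDR; cluster-based
  edge statistics are not provided.
- The reliability permutation treats edges as exchangeable, ignoring
  their dependence through shared nodes.
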