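# morphnet

Single-subject morphological brain networks for gyri and sulci.

Cortical gyri (ridges) and sulci (grooves) differ in microstructure,
connectivity and development. `morphnet` asks the network-level version of
that question: if each cortical region is represented by the distribution
of a morphological feature (cortical thickness, fractal dimension,
gyrification index, sulcal depth) over its surface vertices, and edges
measure distributional similarity between regions, do gyral networks and
sulcal networks organize differently? The package implements the full
analysis as a tested, reusable pipeline, and ships a synthetic-cohort
generator with known ground truth so every stage is verifiable without
access to imaging data.

## The model

For regions *i*, *j* with vertex-value distributions *P*, *Q* (kernel
density estimates on a shared 256-point grid, renormalized to sum to 1):

```
JSD(P||Q) = ½ KLD(P || (P+Q)/2) + ½ KLD(Q || (P+Q)/2),
KLD(P||Q) = Σᵢ P(i) log₂ P(i)/Q(i),
similarity = 1 − √JSD   ∈ [0, 1]
```

With the default bilateral parcellation (29 gyral + 31 sulcal + 14
ambiguous regions per hemisphere; ambiguous excluded) this yields a
120 × 120 network over 58 gyral + 62 sulcal nodes with G-G (58 × 58),
S-S (62 × 62) and G-S (58 × 62) blocks. Downstream analyses:

- **Topology** — proportional thresholding over sparsities 0.08–0.40
  (step 0.02), clustering coefficient Cp and characteristic path length
  Lp normalized by 100 degree-preserving rewired nulls
  (γ = Cp/Cp_rand, λ = Lp/Lp_rand), curves summarized by trapezoidal AUC.
- **Reliability** — edgewise one-way random-effects
  ICC = (MS_b − MS_w)/(MS_b + (k−1) MS_w) across repeat sessions, binned
  poor/low/fair/good/excellent at 0.25/0.4/0.6/0.75.
- **Behavioural associations** — variance-component model Y = B + E,
  B ~ N(0, σ_b² M), E ~ N(0, σ_e² I) with M the between-subject network
  correlation matrix; variance explained
  V = tr(Σ_B)/(tr(Σ_B) + tr(Σ_E)), fitted by a method-of-moments trace
  system, with a 1000-shuffle permutation p and BH-FDR across domains.
- **Group comparisons** — age/sex-adjusted two-sample permutation tests,
  paired sign-flip contrasts between network blocks, nodal
  intra-vs-inter-class contrasts with FDR, clinical correlations.

## Worked example

```r
library(morphnet)

cohort   <- simulate_cohort(
  simulation_config(n_subjects = 20, n_sessions = 2, seed = 1))
networks <- build_cohort_networks(cohort)

net <- networks[[1]][[1]]
print(net)
#> morph_network (CT): 120 nodes (58 gyral, 62 sulcal)
#>   mean off-diagonal similarity: 0.668

blocks <- extract_subcomponents(net)
mean_similarity(blocks$gg)                  # 0.720
mean_similarity(blocks$ss)                  # 0.728
mean_similarity(blocks$gs, square = FALSE)  # 0.613

# paired contrast of per-subject G-G vs S-S mean similarity
session1 <- lapply(networks, `[[`, 1)
gg <- sapply(session1, function(n) mean_similarity(extract_subcomponents(n)$gg))
ss <- sapply(session1, function(n) mean_similarity(extract_subcomponents(n)$ss))
paired_subcomponent_test(gg, ss, n_perm = 10000, seed = 2)
#> $statistic : -0.0108   $p : 2e-04

# small-world topology of this subject's gyral block
sparsity_sweep(blocks$gg, n_null = 100, seed = 3)
#> small_world_result over 17 sparsities [0.08, 0.40]
#>   AUC: Cp 0.197 | Lp 0.782 | gamma 0.725 | lambda 0.395

# test-retest reliability of the 1,653 G-G edges across the two sessions
r <- edgewise_icc(networks, "gg")
table(r$bin)
#>      poor  low  fair  good  excellent
#>         3   14   103   362       1171
mean(r$icc)
#> 0.792
```

Reading the output: the subject's gyral block is small-world over the
whole sparsity range (γ AUC 0.725 over a 0.32-wide range means γ ≈ 2.3 on
average, with λ ≈ 1.2); the paired test shows a small but consistent
G-G/S-S difference in mean similarity for this synthetic cohort; and with
the default generator settings (stable subject effects, ratio
σ²_subj/(σ²_subj+σ²_sess) = 0.8) most edges show good-to-excellent
test-retest reliability, mean ICC 0.79.

Full runs (simulate → networks → topology → reliability → association →
group comparison, with a reproducibility manifest) go through
`load_config()` / `run_pipeline()`.

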