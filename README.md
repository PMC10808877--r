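# envcorridors

Tools for asking whether environmental barriers shape the spread of
culture between societies — and whether any continent's corridors are
systematically more permeable than others'. The package is aimed at
cultural-evolution and ecological-biogeography researchers who work with
gridded climate data, society point locations, discrete trait codes and
language phylogenies.

## What it computes

**Environmental axes.** Per-cell monthly climate series are summarized by
mean, variability and Colwell's predictability *P* = *C* + *M* (constancy
plus seasonal contingency, from the 12 × s month-by-state entropy
decomposition) for temperature and precipitation, then reduced by a
global PCA over land cells to two axes: temperature harshness (TH) and an
aridity index (AI), sign-anchored so harsh/arid conditions score high.

**Start-relative least-cost paths.** Land cells form an 8-connected
graph whose edges carry great-circle step lengths (haversine,
R = 6371.0088 km), so no projection distortion enters. Traversing cell
*v* on a path started at *a* costs |e(v) − e(a)|; edge weight is
step × mean endpoint cost (+ a 1e-9 × step tie-breaker). Because the cost
surface is start-relative, A→B and B→A differ; the pair record keeps the
mean directional accumulated cost and length for TH and AI surfaces, a
slope-based topographic path (weight = step × (1 + |rise|/run)), local
|ΔTH|, |ΔAI|, and the geodesic distance — all costs/lengths log(1+x).

**Sharing models.** Per trait, the 11 raw pair predictors (collinear by
construction, VIF ≫ 5) are reduced to 5 varimax components
(temperature turnover, aridity turnover, travel cost, ancestry,
neighbourhood transmission) and the sharing flag is fit with

    logit P(share) = β0 + Σ βk·PCk + u[id_A] + u[id_B],  u ~ N(0, σ²)

a crossed *multimembership* random intercept (one shared variance, built
through lme4's modular interface). Models with sharing outside 10–90%,
fewer than 50 pairs, or failed convergence are excluded; p-values are
Benjamini–Yekutieli adjusted; fit quality is rank-based AUC; residuals are
screened with permutation Moran's I correlograms on pair midpoints.

**Origin corridors.** For societies inside centres of agricultural
origin, the nine barrier metrics are averaged over the 100 nearest
neighbours (close range) and the 100 nearest at ≥ 2500 km (long range);
varimax PCAs give 3 close-range / 4 long-range components, each compared
across the 16 areas with variance-weighted linear models, semi-parametric
spatial eigenvector filtering (greedy Moran's-I reduction on MWM
eigenvectors) and Tukey HSD contrasts. Paleo reruns swap in reconstructed
climates while reusing the climate-independent topographic and geodesic
columns.

**Synthetic worlds.** `world_config()` + `simulate_world()` generate
latitudinally structured climate, smooth terrain, society placements, a
Yule language tree and trait histories (vertical inheritance with
branch-length switch probability 1 − exp(−μb), plus one horizontal
copying pass whose log-odds decay with distance and TH dissimilarity), so
the whole pipeline is testable end to end with known effect sizes.

## Worked example

```r
library(envcorridors)

cfg <- world_config(n_societies = 150, seed = 20260923,
                    beta_env = -2, beta_dist = -1,
                    alpha_horizontal = -0.5, mu_vertical = 0.6)
run <- run_pipeline(cfg, out_dir = "run1", n_traits = 10,
                    k_neighbors = 20, origin_k = 20)

glance(run$sharing)
#> # A tibble: 10 × 8
#>    trait       n share_fraction   auc converged included reason max_vif
#>    <chr>   <int>          <dbl> <dbl> <lgl>     <lgl>    <chr>    <dbl>
#>  1 trait01  1731          0.315 0.776 TRUE      TRUE     <NA>   374564.
#>  2 trait02  1731          0.445 0.919 TRUE      TRUE     <NA>   378706.
#>  3 trait03  1731          0.555 0.972 TRUE      TRUE     <NA>   376442.
#>  # … one row per trait; share_fraction inside (0.1, 0.9) and converged
#>  #   models are flagged included

dplyr::filter(tidy(run$sharing), label == "tempTurnover")[1:3, 1:6]
#> # A tibble: 3 × 6
#>   trait   label        term  estimate std_error statistic
#>   <chr>   <chr>        <chr>    <dbl>     <dbl>     <dbl>
#> 1 trait01 tempTurnover RC2     0.0243    0.0653     0.372
#> 2 trait02 tempTurnover RC2    -0.170     0.0875    -1.94
#> 3 trait03 tempTurnover RC3    -0.0380    0.110     -0.347
```

The raw predictors are near-degenerate (`max_vif` in the 1e5 range),
which is exactly why the models run on varimax components. With the
injected negative environmental slope (`beta_env = -2`), turnover
coefficients lean negative (60% of turnover terms in this run) —
environmental dissimilarity lowers the odds of sharing — while `auc`
summarizes each model's discrimination. `run1/` holds the per-trait
results table, the area mean/SD and Tukey tables for the origin
comparison, the barrier table, and a manifest logging every filter count
(pairs dropped, traits dropped, models excluded with reasons).

Column conventions: every user-facing function takes a data frame first
and returns a tibble; fitted objects support `tidy()` / `glance()`;
`plot_forest()`, `plot_correlogram()`, `plot_origin_means()` and
`plot_env_axes()` give the standard displays.

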