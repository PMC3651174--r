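# scnmod — modular organization of structural covariance networks

`scnmod` analyzes how the cortex organizes into modules when brain regions
are linked by the across-subject correlation of their mean cortical
thickness, and how that organization differs between two groups (e.g.
autistic and typically developing children). It is aimed at researchers who
have a subjects × regions thickness table (68 Desikan–Killiany regions by
default) and want the full chain: covariate removal, group-level weighted
correlation networks, maximum-modularity partitions, module/node connectivity
metrics, and nonparametric group inference — plus a planted-partition
synthetic cohort generator so every stage can be validated without access to
restricted imaging data.

## The model

For each group, regional thickness is residualized per region on intercept,
subject global mean thickness, age, sex and age×sex; Pearson correlation of
the residuals across subjects gives a fully weighted network with N = 68
nodes and K = N(N−1)/2 = 2278 edges, normalized to total weight L = 1
(negative correlations are zeroed for modularity computations; the signed
matrix is kept). Modular organization maximizes Newman's weighted modularity

    Q = Σ_s [ l_s / L − ( d_s / 2L )² ]

over partitions (l_s: weight inside module s; d_s: summed node strength of
module s), via a seeded multi-restart Louvain-style optimizer. Under a
reference partition — the control group's optimum, imposed on the case
network — the package computes intra-/inter-module connectivity (MC, IMC)
and per-node intra-module degree (MD, a within-module strength z-score) and
participation coefficient (PC = 1 − Σ_s (κ_is/k_i)²). Group differences are
tested three ways: an edge-weight permutation null for Q, subject-relabeling
permutation tests (group sizes preserved, whole pipeline recomputed per
permutation) for any network measure, and edge-wise Fisher r-to-z
comparisons, Z = (z_control − z_case)/√(1/(n₁−3) + 1/(n₂−3)), with
Benjamini–Hochberg FDR at q = 0.01.

See `vignettes/scnmod-methods.Rmd` for assumptions, parameter defaults and
design choices.

## Worked example

Simulate a matched pair of cohorts in which, relative to controls, the case
group's within-module correlation is lowered by 0.3 in planted modules 1–2
and raised by 0.3 in module 3, then run the full comparison:

```r
library(scnmod)

spec <- cohort_spec(n_autism = 60, n_control = 60, seed = 42)
pair <- make_autism_like_pair(spec)
fit  <- scn_compare(combine_cohorts(pair$case, pair$control),
                    n_restarts = 20, n_perm = 999, n_random = 1000, seed = 42)
fit
#> Structural covariance network comparison (case - control)
#>   groups: autism (n = 60) vs control (n = 60); policy truncate_negative
#>   modules: 2 (case), 3 (control); baseline = control
#>   Q under baseline partition: case 0.3843, control 0.5874 (diff -0.2032, perm p = 0.001)
#>   edges altered at FDR q = 0.01: 19 of 2278 (5 decreased, 14 increased in case)

summary(fit)$modules
#>  module size MC_case MC_control   diff p_perm
#>       1   13  0.0395      0.147 -0.108  0.001
#>       2   28  0.1902      0.454 -0.263  0.001
#>       3   27  0.6736      0.368  0.306  0.001
```

The printout reads: the control network splits into the 3 planted modules;
imposing that organization on the case network yields substantially lower
modularity (difference −0.20, permutation p = 0.001 at 999 permutations);
intra-module connectivity drops in modules 1–2 and rises in module 3 — the
injected pattern, recovered with correct signs and significance. Edge-wise
Fisher comparison flags 19 of 2278 edges at FDR q = 0.01.

Desk-scale arithmetic on published inputs is also available: the package
ships the altered-correlation pairs reported for a 49 + 51 children study,
and recomputing the Fisher statistic from the printed correlations

```r
pub <- published_edge_correlations()
(atanh(0.43) - atanh(-0.45)) / sqrt(1/46 + 1/48)   # POPE.R–PSTC.R pair
#> [1] 4.578067
```

reproduces the published |Z| = 4.61 within the rounding of the two-decimal
r values.

A thin CLI (`inst/cli/scn`) wraps the same functions:
`scn simulate`, `scn analyze --config config.yaml`, `scn compare-edges`,
`scn report`.

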