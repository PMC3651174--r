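---
title: "Modular organization of structural covariance networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular organization of structural covariance networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnmod)
```

## The problem

A structural covariance network treats brain regions as nodes and the
across-subject correlation of a regional morphometric measure -- here, mean
cortical thickness in millimetres -- as edge weights. Because the correlation
is computed across subjects, each *group* (e.g. an autism group and a
typically developing control group) yields one network, and group comparisons
are comparisons of two weighted graphs, not of per-subject values. `scnmod`
implements the full chain from a subjects-by-regions thickness table to
group-level networks, their modular organization, module- and node-level
connectivity metrics, and three inferential procedures, together with a
synthetic cohort generator that makes every stage testable without access to
restricted imaging repositories.

Nodes are the 68 regions of the Desikan-Killiany gyral parcellation
(34 per hemisphere, `dk_atlas()`); all matrices, partitions and cohort
columns use this atlas order, with odd indices on the left. A fully weighted
network over 68 nodes has K = 68 x 67 / 2 = 2278 distinct edges; no
thresholding or binarization is applied anywhere, which avoids the
arbitrariness of sparsity selection.

## From thickness to networks

**Residualization.** Before correlating, each region's thickness is replaced
by the residuals of an OLS regression on an intercept, the subject's global
mean thickness (mean over the 68 regions), age, sex (M = 1, F = 0) and the
age-by-sex interaction. Two points deserve emphasis:

* *Global mean thickness* is interpreted as each subject's mean over the
  atlas regions, the convention of the structural covariance literature. Note
  that this covariate removes shared signal in the manner of global signal
  regression: it necessarily reshapes the correlation structure (correlations
  shrink toward, and partly below, zero). This is intentional --- the
  networks describe covariance *beyond* global thickness --- but it means
  planted correlations in synthetic data are only preserved exactly when the
  global-mean covariate is omitted, and our structure-preservation tests are
  formulated accordingly.
* Regression is fitted *within each group* by default, since networks are
  per group; a pooled fit is available (`per_group = FALSE`) because the
  choice is a genuine ambiguity in the field's descriptions of the procedure.

Rank-deficient designs (a single-sex group makes the interaction collinear;
residualizing already-residualized data makes the global mean an all-zero
column) drop the offending columns with a warning rather than failing. The
near-zero-column check is explicit because base `qr()`'s rank test is
column-relative and would otherwise project onto numerical noise.

**Correlation and normalization.** Pearson correlation across subjects for
every region pair gives the signed 68 x 68 matrix, which is always retained
(the Fisher edge comparison needs it). Modularity-facing weights are derived
by a *weight policy*: `truncate_negative` (default; zero out negative
correlations), `absolute`, or `keep_signed` (which the modularity code
refuses, since Newman's Q is ill-behaved with negative strengths). After the
policy, edge weights are divided by the total network weight L so both
groups' networks carry L = 1 and module-level weight sums are directly
comparable; Q itself is scale-invariant, so this affects MC/IMC but not
modularity.

## Modularity and module metrics

For a partition of the nodes into modules, with `l_s` the summed edge weight
inside module s, `d_s` the summed node strength of module s and L the total
edge weight,

$$Q = \sum_s \left[ \frac{l_s}{L} - \left( \frac{d_s}{2L} \right)^2 \right].$$

The optimal partition is sought by a Louvain-style greedy algorithm (local
node moving followed by community aggregation) written in-package, restarted
`n_restarts` times (default 100) under a fixed seed. Roughly half the
restarts begin from singleton communities and half from a random coarse
partition: greedy local moving can only merge, never split, so varied
starting points are required to escape merge-order traps; on small graphs
this scheme reproduces exhaustive search (the test suite verifies equality
with enumeration over all set partitions for networks up to 8 nodes). Equal-Q
ties are resolved by canonical labeling: modules are numbered by the lowest
node index they contain, which makes repeated runs and cross-group
comparisons stable. The number and size of modules are never specified in
advance.

Module- and node-level metrics under a partition:

* **MC_s** -- intra-module connectivity, the sum of edge weights within
  module s; **IMC_st** -- inter-module connectivity, the sum of weights
  between modules s and t. Together they conserve the total weight.
* **MD_i** -- intra-module degree, the z-score of node i's within-module
  strength relative to the other nodes of its module. The *population*
  standard deviation is used (the sample/population choice is not decidable
  from the field's standard formulations; the population form is the
  convention of the original participation-coefficient literature). If a
  module's spread is zero -- including singleton modules -- MD is 0, the
  symmetric choice for an otherwise undefined z-score.
* **PC_i** -- participation coefficient, `1 - sum_s (kappa_is / k_i)^2`,
  where `kappa_is` is node i's weight into module s and `k_i` its strength:
  0 for purely intra-modular nodes, at most `1 - 1/N_m`. Isolated nodes
  (k = 0) get PC = 0 by convention, with a message.

## Group inference

**Baseline-partition strategy.** The control group's optimal partition is
taken as the reference modular organization and imposed on the case network;
all Q/MC/IMC/MD/PC comparisons are made under this common partition. This
mirrors the practice of treating the typically developing organization as the
baseline against which reorganization is measured, and avoids comparing
metrics across different partitions.

**Random-network null for Q.** Null networks are built by uniformly
permuting the multiset of upper-triangle edge weights over node pairs --
same nodes, same number of edges, same weight multiset, so L is conserved
exactly while any modular arrangement is destroyed. By default each
replicate re-scores the fixed reference partition; re-optimizing inside
every replicate is available (`reoptimize = TRUE`) since descriptions of
this null vary on that point, but it is roughly `n_restarts` times more
expensive and is more conservative. The observed Q is compared to the null
sample with a one-sample t-test (two-sided p reported alongside the
one-sided "observed exceeds null" p; sidedness is another point left open in
common usage). A degenerate null (all weights equal, every permutation
identical) reports p = 1.

**Subject-relabeling permutation test.** Any deterministic function
cohort -> network measure(s) can be tested: subjects are randomly reassigned
to the two groups preserving the original group sizes, the entire pipeline
(residualize, correlate, policy, normalize, measure) is recomputed for each
permuted group, and the observed case-minus-control difference is referred
to the permutation distribution, two-tailed. The statistic may be
vector-valued so that Q, all MC/IMC terms and all node roles share one set
of permutations. The default p-value uses the add-one convention
`(1 + #{|null| >= |obs|}) / (n_perm + 1)`, the standard bias correction that
keeps Monte-Carlo p-values positive; the plain `u / n_perm` proportion is
available via `include_observed = FALSE`. The default of 10,000 replicates
for both this test and the random null matches published practice; tests and
examples pass ~1,000 to stay interactive at desk scale.

**Edge-wise Fisher comparison.** Each region pair's correlations are
compared with `z = atanh(r)` and
`Z = (z_control - z_case) / sqrt(1/(n_case - 3) + 1/(n_control - 3))`, so a
correlation *reduced* in the case group gives positive Z. Two-tailed normal
p-values over all 2278 edges form one family corrected by Benjamini-Hochberg
at q = 0.01 (per-node MD/PC tests form a second family). Edges with |r| = 1
have infinite z; they are flagged, excluded from the FDR family and warned
about rather than silently propagated. `bh_fdr()` delegates to
`stats::p.adjust(method = "BH")` and is tested against the step-up
definition directly.

## The synthetic cohort generator

`cohort_spec()` defines the generative model the tests and examples rely on.
It emulates the statistical shape of a two-group pediatric thickness study:

| parameter | default | meaning |
|---|---|---|
| `n_autism`, `n_control` | 49, 51 | subjects per group |
| `n_rois` | 68 | regions (atlas order) |
| `planted_partition` | 3 blocks: 13/28/27 | ground-truth modules |
| `r_within`, `r_between` | 0.5, 0.1 | planted block correlations |
| `age_mean`, `age_sd`, `age_range` | 9.65, 2.15, 6--15 y | truncated-normal ages |
| `age_slope` | -0.03 mm/y | linear cortical thinning with age |
| `sex_effect` | 0.02 mm | male--female offset |
| `p_male` | 0.8 | male share (exercises imbalanced designs) |
| `noise_sd` | 0.35 mm | idiosyncratic regional noise |
| `base_thickness` | 2.5 mm | thickness at the mean age |
| `clip_range` | 0--5 mm | physiological clipping |

Thickness is `base + age_slope (age - mean age) + sex_effect male` plus a
zero-mean Gaussian vector whose correlation matrix is the planted block
structure; the total stochastic SD is `noise_sd / sqrt(1 - r_within)`
(about 0.5 mm at the defaults, matching the regional variability reported
for pediatric cohorts), of which `noise_sd` is the region-specific part.
Group-specific block perturbations (`group_effects`) add deltas to
within-block or between-block target correlations for one group;
`make_autism_like_pair()` packages the headline configuration (modules 1-2
weakened by 0.3, module 3 strengthened by 0.3 in the case group). Sampling
draws i.i.d. normals and maps them through the eigendecomposition of the
target correlation matrix: this realizes *any* admissible block pattern --
including module-pair perturbations that a one-factor-per-module
construction cannot represent -- and the implied matrix is verified positive
semi-definite (minimum eigenvalue above -1e-8) with an explicit error
otherwise. Identical spec and seed give bit-identical cohorts; clipping is
logged and stays below 1% at the defaults.

What the generator does *not* emulate: MRI acquisition and segmentation
error, site/scanner effects, non-linear age trajectories, spatially graded
(non-block) covariance, heavy-tailed or skewed thickness distributions, and
region-specific variances. Passing tests therefore demonstrate correctness
of the pipeline's statistics under a clean planted-structure model, not that
real cortical data carry such structure.

## Numerical and design choices

* **Weight policy default** is `truncate_negative`: Newman's Q assumes
  non-negative strengths, and the thickness-covariance literature analyzes
  positive covariance. The signed matrix is always retained, so the Fisher
  edge comparison is unaffected by the policy. `keep_signed` exists to make
  the choice explicit rather than silent.
* **Normalization after the policy**, so L is the total of exactly the
  weights Q/MC/IMC consume.
* **Dense 68 x 68 storage**; at this size sparse structures buy nothing.
* **Orthogonality tolerances**: residual columns are orthogonal to design
  covariates to 1e-8 relative; residualization is idempotent to 1e-10;
  Q identities hold to 1e-12.
* **Determinism**: every stochastic stage takes a seed; `scn_compare()`
  derives independent sub-seeds from one master seed, and repeated runs with
  the same config and seed produce byte-identical output tables. RNG state
  of the caller is always restored.
* **Error style**: schema problems name the offending column/row; partition
  files must cover every node exactly once with contiguous module ids;
  pipeline errors are prefixed with the failing stage.
* **Problem sizes in the test suite** (chosen as desk-scale defaults):
  exhaustive-search equivalence on networks up to 8 nodes (enumeration over
  all set partitions, up to 4140); planted-partition recovery and
  directional-recovery fixtures at n = 100 subjects per group with 1,000
  permutations over 20 seeds; permutation-test calibration over 200 null
  simulations of a 20-region system at 199 permutations; FDR calibration
  over 500 replicates of 2278 uniform p-values. Group-level findings from
  real cohorts are *not* reproducible from synthetic data; the suite instead
  verifies the machinery that would produce them.

## Known limitations

* Modularity optimization is heuristic; equality with exhaustive search is
  only verifiable at small n, and on 68-node networks the returned partition
  is the best of the seeded restarts.
* The Fisher Z comparison assumes approximate normality of `atanh(r)`, which
  degrades at very small n (hence the hard requirement n > 3, and caution
  below n of about 20).
* The permutation test assumes exchangeability of subjects across groups
  under the null; strong covariate imbalance between groups weakens that
  premise (the generator draws matched covariate distributions).
* Negative correlations are either discarded or folded in by magnitude;
  signed-modularity variants are out of scope.
* No hierarchical or overlapping community structure, and no small-world or
  path-based metrics.
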