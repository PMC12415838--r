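---
title: "Statistical methods for paired dried-versus-frozen microbiome comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for paired dried-versus-frozen microbiome comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dryfreeze)
```

## The design and why permutation nulls

The package targets a paired preservation experiment: several source
materials (faecal and soil samples are the motivating case), each split into
two arms — desiccated then stored at room temperature, versus frozen at
−80 °C — with an equal number of replicates per arm. Materials differ from
each other far more than treatments do, and replicate-to-replicate spread
within an arm (material heterogeneity, DNA extraction, PCR and sequencing
stochasticity) is substantial. Every test in the package therefore
conditions on material: the permutation null models shuffle *within* a
material's samples, breaking value–treatment associations while keeping
value–material associations intact. No distributional form (normality,
equal variances) is assumed anywhere; significance always comes from the
empirical permutation distribution of the observed statistic.

## Ratio-of-means location test

For a scalar success metric, `ratio_statistic()` forms the per-material
ratio of dried-arm mean to frozen-arm mean, and averages these ratios with
equal weight across materials (each material is one independent realisation
of the treatment contrast, regardless of its absolute scale — the ratio is
scale-free). `location_test()` compares the observed average ratio
$\rho$ against ratios from random within-material value shuffles, two-sided
around 1: the p-value is the fraction of permuted $\rho^*$ with
$|\rho^* - 1| \ge |\rho - 1|$.

Two estimator conventions are offered. The default (`"fraction"`) is the
plain fraction of at-least-as-extreme permutations; the identity permutation
is not force-included and no smoothing is applied, so p can be exactly 0.
The `"add_one"` option returns $(b+1)/(N+1)$, which is a guaranteed-valid
p-value at the cost of never reaching 0. Tests with fewer than 100
permutations record a warning in the result rather than failing.

Samples with a missing metric value are excluded from that metric's test in
every permutation, and the reported `n` reflects the exclusion. A
frozen-arm mean of exactly zero is an error naming the material — silently
dropping a stratum would change the estimand.

## Compositional agreement (coefficient of determination)

For one material, `treatment_mean_proportions()` averages each feature's
per-sample proportions within each arm, giving dried means $X_i$ and frozen
means $Y_i$. After an abundance filter (feature kept iff
$X_i \ge t$ **and** $Y_i \ge t$; boundary kept; no renormalisation after
filtering), the agreement statistic is

$$R^2 = 1 - \frac{\sum_i (Y_i - X_i)^2}{\sum_i (Y_i - \bar{Y})^2}.$$

This is a fixed-prediction coefficient of determination: $X$ is taken as-is
(no fitted slope or intercept), so $R^2 = 1$ iff $X = Y$ elementwise and
$R^2 < 0$ whenever disagreement exceeds the spread of the frozen means. The
frozen means are the denominator reference; the statistic is deliberately
not symmetrised, and swapping the roles of the arms changes the value. The
default thresholds are $t = 10^{-4}$ (0.01%, taxa) and $t = 10^{-5}$
(0.001%, genes); they exist to exclude features whose means are dominated by
sampling shot noise.

`agreement_test()` permutes the treatment labels of the material's samples
(group sizes preserved) and recomputes the *entire* pipeline — means, filter,
$R^2$ — in every permutation. Recomputing the filter keeps the null
exchangeable with the observed pipeline; a `refilter = FALSE` switch freezes
the observed feature set instead, since either reading of the procedure is
defensible. The p-value is one-sided on the lower tail (low $R^2$ =
disagreement), counting strictly lower permuted values; `include_ties =
TRUE` switches to tie-inclusive counting, which is the conservative variant
(with heavily tied data the strict count can be much smaller — both
behaviours are exercised in the test suite). Permutations that come out
degenerate (fewer than two retained features, or constant frozen means) are
excluded from the null; the test errors only if every permutation is
degenerate.

### Within-OTU decomposition

`within_otu_asv_table()` renormalises conspecific ASVs to sum 1 within each
(OTU, sample) block. Agreement tests on the result are blind to whole-OTU
abundance shifts and detect only changes in strain representation within
species. Blocks with zero total are flagged missing (`NA`), never zero: a
species absent from a sample carries no information about its internal
strain composition. Treatment means then average over the non-missing
replicates only, and features missing in an entire arm drop out pairwise.

Two inclusion rules circulate for which ASVs enter the renormalisation: a
per-sample rule (the ASV must represent ≥ 0.01% of that sample's reads) and
a treatment-mean rule (the filter used in the main agreement analysis). The
constructor binds the per-sample rule via `min_sample_proportion = 1e-4`
(set 0 to disable) because it is the rule stated for the upstream inclusion
of ASVs; the treatment-mean rule remains available through
`agreement_test(threshold = )` on the resulting table. The choice is a
configuration, not a guess about which is "right".

## Beta diversity, ordination, PERMANOVA

`bray_curtis()` computes $\sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, which on
unit-sum rows is half the L1 distance; `weighted_jaccard()` computes the
Ružička form $1 - \sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)$. Ružička
was chosen as the abundance-weighted Jaccard because it is the standard
quantitative generalisation of the Jaccard index (it is also what `vegan`'s
quantitative `"jaccard"` computes, which the test suite uses as an
independent cross-check); the Chao abundance-based estimator is a known
alternative that corrects for unseen species but estimates a different
quantity, and is deliberately not the default.

`mmds()` embeds a dissimilarity matrix by minimising Kruskal stress-1,
$\sqrt{\sum_{i<j} (d_{ij} - \delta_{ij})^2 / \sum_{i<j} \delta_{ij}^2}$,
using SMACOF majorisation: the Guttman transform guarantees the raw stress
never increases across iterations, making the descent monotone and
deterministic. Initialisation is the classical-scaling (PCoA) configuration
— usually already close to the optimum and fully deterministic — with
optional seeded random restarts (`n_restarts`) for rugged instances; the
best configuration wins. Convergence is declared at a relative raw-stress
change below `tol = 1e-10`, capped at `max_iter = 10000`; hitting the cap
flags the result (`converged = FALSE`) rather than erroring, since a
near-converged embedding is still usable for plotting. Note that majorisation
finds a local optimum; the restart mechanism exists precisely because
different starts can land a few parts in $10^5$ apart in stress.

`pcoa()` is classical scaling (double-centred $-\tfrac12 D^2$,
eigendecomposition), delegated to `stats::cmdscale` with the full eigenvalue
spectrum retained: negative eigenvalues — the signature of non-Euclidean
dissimilarities like Bray-Curtis — are reported, never clipped, and a
`deficient` flag marks requests for more axes than positive eigenvalues
exist.

`permanova()` implements the one-factor distance-based decomposition:
$SS_\text{total} = \frac1N \sum_{i<j} \delta_{ij}^2$, $SS_\text{within}$
summing within-group pairs with group-size normalisation, and pseudo-$F =
(SS_\text{between}/(a-1)) / (SS_\text{within}/(N-a))$ with $a = 2$
treatment groups. Labels are permuted freely within the material (the
per-material restriction *is* the stratification; there is no finer
structure to preserve), and $R^2 = SS_\text{between}/SS_\text{total}$ is
reported alongside p. The decomposition is checked in the tests against
`vegan::adonis2` to 1e-10 and against exhaustive label enumeration.

## Per-group Welch permutation tests

For grouped functional profiles (e.g. KEGG level-C groups),
`welch_group_test()` compares each group's proportions between arms with the
Welch statistic $t = (\bar{x}_d - \bar{x}_f) / \sqrt{s_d^2/n_d +
s_f^2/n_f}$, permuting treatment labels within the material. Two-sided
counting on $|t|$ was chosen (the direction of a preservation artefact is
not known a priori) and Bonferroni correction is applied across the groups
tested within one material — each material is analysed, reported and
interpreted separately, so the material is the natural family. Degenerate
groups follow fixed conventions: zero variance and zero mean difference
gives $t = 0$, $p = 1$; zero variance with a nonzero difference is flagged
infinite and receives the smallest p the permutation distribution can
attain (only splits reproducing an infinite statistic count as extreme).

## The synthetic-data generator

`simulate_metric_table()` and `simulate_feature_table()` emulate the paired
design so every statistical module can be tested for calibration (uniform
p-values under the null) and recovery (known effects found) without any
external data. Defaults mirror the motivating study design: 6 materials ×
2 treatments × 5 replicates, sequencing depths log-normal around 70,000
reads (floored at 1,000).

Scalar metrics: material baseline $B_{mg}$ is log-normal
($e^{\mathcal{N}(\log 100,\, 1)}$ — materials differ by orders of
magnitude); frozen replicates are $B_{mg} e^\varepsilon$ and dried
replicates $B_{mg}\, r_g\, e^\varepsilon$ with
$\varepsilon \sim \mathcal{N}(0, \log(1 + \mathrm{CV}^2))$, so the
multiplicative noise has exactly the configured coefficient of variation
(default 0.2, a plausible replicate-level spread for extraction-scale
metrics) and $r_g$ is the true dried/frozen ratio.

Communities: each material draws a base composition from a symmetric
Dirichlet with total concentration `base_concentration` (default 50 over
1,000 features — sparse and uneven, as amplicon communities are); the dried
condition multiplies it by $e^{\delta_i}$, $\delta_i \sim \mathcal{N}(0,
\sigma^2)$ with $\sigma$ = `treatment_effect_sd` (default 0.3, a moderate
perturbation; 0 is the exact null); each replicate draws its own
composition from a Dirichlet centred on the condition composition with
concentration `within_material_overdispersion` (default 200) and counts
from a multinomial at its sampled depth. The Dirichlet-multinomial family
was chosen because within-arm spread in such experiments is attributed to
sample heterogeneity and PCR/sequencing stochasticity without a stated
model; a single overdispersion knob makes that heterogeneity tunable. None
of these defaults are fitted to real data — they are plausible magnitudes,
and the recovery/calibration tests state their own parameter choices
explicitly.

Ground truth (baselines, true ratios, base compositions, per-feature
log-folds, depths) is always returned and serialisable
(`write_ground_truth()`) so recovery tests never re-derive truth from the
generator's internals. What the generator does **not** emulate: taxonomic
structure, chimeras and sequencing error profiles, compositional
correlations between features, batch effects, and depth–composition
dependence. Passing calibration on synthetic data therefore shows the tests
are valid under exchangeable nulls with realistic sparsity and
overdispersion — not that any particular real dataset satisfies those
assumptions.

## Determinism and seeds

Every stochastic operation takes an explicit integer seed, runs under a
locally scoped RNG (the caller's random state is untouched), and is
bit-reproducible. Rarefaction draws each sample's without-replacement
subsample (sequential conditional hypergeometric via `rhyper`, so
million-read samples cost time proportional to features, not reads) from a
single seeded stream, processing samples in lexicographic id order —
results are independent of input row order. The pipeline derives child
seeds as a polynomial byte-hash of the master seed with the stage and
material labels (`derive_seed()`), so adding or reordering stages never
perturbs other stages' draws. One consequence, shared by any
single-stream design: Monte-Carlo p-values are exactly invariant only under
transformations that preserve the draw sequence (e.g. metric rescaling, or
material renamings that preserve lexicographic order); arbitrary renamings
are equivalent in distribution only.

## Numerical conventions

* Proportions are validated to sum to 1 within 1e-6 on input (published
  tables carry rounded values) and renormalised to exact unit sums
  internally; all-zero rows are an error naming the sample.
* Abundance filters use ≥ (boundary kept).
* Group aggregation removes omitted groups *before* renormalising
  proportions, so omitted mass is redistributed, not silently kept.
* Vectorised Welch variances clamp relative cancellation error below 1e-10
  to exact zero so constant groups hit the degenerate conventions exactly.
* Distance matrices are symmetrised to machine precision on construction
  and must have an exactly zero diagonal.

## Problem sizes in the test suite

The suite verifies Monte-Carlo tests against exhaustive enumeration on
instances small enough to enumerate (≤ 8 samples; $\binom{4}{2}$ to
$\binom{6}{3}$ label splits), calibration on 1,000 null simulations per test
at 199 permutations each, recovery of a 1.5× metric ratio over 300
simulated designs against a direct brute-force expectation, and
dose–response monotonicity over a 3-point perturbation grid with 60
simulations per point. These sizes give binomial/KS resolution well below
the tolerances asserted while keeping the default run in tens of seconds;
they are choices of the package, and all of them scale up by editing the
constants in the tests.

## Limitations

* The agreement statistic is asymmetric by construction; reporting both
  orientations requires two calls.
* PERMANOVA here is strictly one-factor, two-group, per material — no
  interaction or multi-factor designs.
* No phylogenetic (UniFrac-type) dissimilarities: no tree is in scope.
* The permutation p-value of the default estimator can be exactly 0; use
  `estimator = "add_one"` when downstream procedures require strictly
  positive p-values.
* Reproduction of the motivating study's deposited per-sample metric tables
  is wired into the acceptance tests but requires those journal supplements
  to be placed under `inst/extdata/deposited/`; they are not redistributed
  with the package.
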