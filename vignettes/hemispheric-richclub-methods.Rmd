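---
title: "Rich-club organization and hemispheric asymmetry of white-matter networks: methods"
author: "hemirc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rich-club organization and hemispheric asymmetry of white-matter networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemirc)
```

## The analysis in one paragraph

Diffusion-MRI tractography yields, for each subject, a symmetric 90×90
matrix of mean fractional anisotropy (FA) between atlas regions (45 per
hemisphere), together with an integer streamline-count matrix. `hemirc`
keeps an edge only when its fiber number strictly exceeds 3, discards
inter-hemispheric connections, and analyses the two homologue-aligned
45×45 hemispheric networks per subject: weighted rich-club curves
normalized against degree- and weight-preserving null ensembles, a
degree-based hub partition on the pooled group-average network, the
classification of every edge as rich-club (hub–hub), feeder
(hub–peripheral) or local (peripheral–peripheral), per-class connectivity
density and strength, hemispheric asymmetry scores, and
group-by-hemisphere repeated-measures inference with covariates.

## The weighted rich-club coefficient

For a degree level $k$, let $S_{>k}$ be the set of nodes with nodal degree
greater than $k$ (degree is a binary edge count; weights are ignored for
ranking). With $W_{>k}$ the total weight among $S_{>k}$ and $E_{>k}$ the
number of those edges,

$$\varphi^w(k) = \frac{W_{>k}}{\sum_{l=1}^{E_{>k}} w_l^{\mathrm{ranked}}},$$

where the denominator sums the $E_{>k}$ strongest edge weights anywhere in
the network. The ratio lies in $[0,1]$. Levels where $|S_{>k}| < 2$ or
$E_{>k} = 0$ are *masked*, never imputed as zero: a masked level carries
no information, whereas a zero would claim the club exists and is
maximally weak. The strict `> k` membership rule follows the van den
Heuvel–Sporns convention for weighted rich clubs.

Because $\varphi^w(k)$ rises mechanically with $k$ in any weighted graph,
it is normalized by its mean over an ensemble of rewired networks:
$\varphi_{\mathrm{norm}}(k) = \varphi^w(k) / \langle
\varphi^w_{\mathrm{rand}}(k) \rangle$. Values above 1 over a range of
degrees indicate rich-club organization. The package default is 1000
nulls per subject and hemisphere, the conventional choice for per-subject
normalization; the examples and acceptance run in this package use 100,
which changes $\varphi_{\mathrm{norm}}$ estimates by well under the
group-level differences of interest (the Monte-Carlo standard error is
tracked per level and exposed as `attr(curve, "phiNullSd")`).

## The null model

`maslovRewire()` randomizes topology by double-edge swaps
$(a,b),(c,d) \to (a,d),(c,b)$, rejecting self-loops and duplicate edges.
Each weight travels with its edge through every swap, so two properties
hold *exactly*, not approximately: the degree sequence of every node, and
the multiset of edge weights (hence total strength). These are the two
preservation properties the normalization requires. Per-node strength is
only approximately preserved — an acknowledged property of
weights-ride-with-edges rewiring; callers who need to quantify the
deviation can compare `nodalStrength()` before and after. The swap count
is 10 per edge by default, with an attempt cap so that swap-free graphs
(stars, near-cliques) terminate; rewiring is deterministic given its
seed, and ensemble replicate $r$ derives its seed by stable hashing of
(master seed, "null", $r$).

## Hubs, edge classes, and the two connectivity measures

Hub selection ranks nodes by nodal degree on a *group-average* network —
by default the zero-inclusive elementwise mean over all subjects and both
(homologue-aligned) hemispheres, so a single hub set serves the whole
cohort. The hub count is $\lfloor 0.16\,n \rfloor$: for $n = 45$ regions,
exactly 7 hubs and 38 peripheral regions. Ties at the cut are broken by
higher nodal strength, then node order, making the partition
deterministic. Zero-inclusive averaging is the default because averaging
only over subjects possessing an edge would erase density differences
between groups; `average_mode = "nonzero_only"` is available for
sensitivity analysis, as is per-group or per-hemisphere averaging by
passing a subset of networks to `groupAverage()`.

Each existing edge is classified once: rich-club (both endpoints hubs),
feeder (one hub), local (none). Connectivity *density* of a class is its
edge count divided by the total possible edges of the hemispheric network
($n(n-1)/2 = 990$ for 45 nodes) — deliberately not the per-class
possible-edge count, so the three densities sum to the overall network
density. Connectivity *strength* is the summed FA weight of the class's
edges. Both measures are therefore additive across classes, which the
test suite asserts to machine precision.

## Asymmetry and inference

The asymmetry score of a metric $X$ is
$AS(X) = 100\,[X(R) - X(L)]/[X(R) + X(L)]$: negative means leftward
advantage, positive rightward, bounded in $[-100, 100]$ for nonnegative
metrics, undefined (NA with a warning) when both hemispheres are zero.

Group-by-hemisphere inference uses the classical two-level
repeated-measures decomposition in ANCOVA form. With $m_i = (L_i+R_i)/2$
and $d_i = R_i - L_i$:

* the **group** effect is the sum-coded group term of
  $m \sim \text{covariates} + \text{group}$;
* the **hemisphere** effect is the intercept of
  $d \sim \text{covariates} + \text{group}$ with centered covariates and
  sum-coded group (i.e. the adjusted grand mean of $d$);
* the **interaction** is the group term of the same difference model.

Each is an exact $F(1, N - 2 - c)$ test with $c$ covariates — denominator
df 99 for 104 subjects and the default covariates (age, sex coded 0/1,
handedness score). The handedness score is consumed as an opaque
covariate; the package does not attempt to reconstruct how it is derived
from hand-preference items. Post hoc tests are paired $t$-tests for
hemisphere differences within each group (subject-level covariates cancel
from within-subject differences) and covariate-adjusted independent
$t$-tests for group differences within each hemisphere, implemented as
the group coefficient of `lm(value ~ covariates + group)` — equivalent to
residualizing both the response and the group indicator, but with the
correct residual df. Asymmetry scores get per-group one-sample $t$-tests
against zero (df $n-1$) plus the same adjusted group contrast. Nodal
degree, tested per region, is Bonferroni-corrected with $m = 45$;
connectivity measures are reported uncorrected; significance is starred
at 0.05/0.01/0.001.

Clinical correlations use a covariate-adjusted Spearman coefficient: rank
both variables, residualize the ranks on the covariate design, correlate
the residuals, with a $t$ approximation on $n - 2 - c$ df. Both the
adjusted and the plain coefficient are reported, since it is genuinely
ambiguous which clinical-score scale (raw or adjusted) such analyses
should correlate against.

The edge-wise census tests every classified edge three ways: group
difference (independent $t$ on the per-subject mean of the edge's left
and right weights, absent edges entering as true zeros rather than
missing data), hemisphere difference (paired $t$ on homologue-aligned
weights), and group difference in the edge's asymmetry score. Per-edge
significance is uncorrected $\alpha = 0.05$, matching the exploratory
framing of such censuses; an edge-level FDR option would be a
straightforward extension but is off by default. Counts and percentages
are reported per class.

## What the synthetic cohort emulates — and what it does not

`generateCohort()` exists so that the entire pipeline, including
parameter-recovery tests, runs without imaging data. It emulates:

* symmetric, nonnegative FA-like weight matrices (clipped normal, mean
  0.45, sd 0.10 — a plausible white-matter FA range; the true FA
  distribution is not identifiable from published group statistics and
  the choice is config-exposed);
* core–periphery topology: 7 designated hub regions per hemisphere with
  hub–hub connection probability 0.90, hub–peripheral probability 1.8×
  the peripheral–peripheral baseline (solved so the overall density hits
  its target, default 0.30), and a 1.5× hub–hub weight boost — so a
  rich-club effect exists by construction;
* mirrored homologous edges, with hemispheric asymmetry injected as a
  multiplicative left/right scale on class-specific weights. For a pure
  scale factor $f$ on one side, the strength asymmetry is exactly
  $AS = 100(f-1)/(f+1)$, so the factor achieving a target AS has the
  closed form $f = (100+AS)/(100-AS)$ — no iterative calibration needed.
  Defaults: +5 rightward on local connections in the shared template, −5
  (leftward) on patients' right-hemisphere feeder connections;
* patient-group deficits concentrated in feeder (−10% FA) and local
  (−15% FA) edges, leaving rich-club edges untouched;
* fiber counts with mean 20 on adopted edges and a 5% fraction seeded
  below the adoption threshold, assigned on the hemisphere template and
  mirrored so that a fully null configuration keeps the hemispheres
  statistically identical after thresholding;
* per-subject multiplicative lognormal edge noise (sd 0.10) plus a global
  per-subject scale (sd 0.05), which cancels from asymmetry ratios;
* a latent severity per patient that drives both dropout of
  right-hemisphere connections at three designated peripheral "symptom"
  regions (injecting regional-degree asymmetry) and
  negative-binomially distributed symptom scores within the usual ranges
  of the mania (0–41) and depression (0–32) scales, via a logistic mean
  link — so rank correlations between degree asymmetry and symptoms have
  recoverable sign;
* demographics in realistic ranges (age 21–50, handedness 0.75–1).

It does **not** simulate tractography, distance-dependent connection
probabilities, realistic atlas geometry, inter-regional FA covariance, or
the variance structure of any real cohort: no published subject-level
variances exist for these measures, so effect sizes are chosen for
testability. Passing recovery tests therefore demonstrates that the
pipeline's inference machinery is correct and directionally faithful —
not that a real cohort of this size would show these effect magnitudes.
Synthetic effects are also considerably cleaner (larger $F$) than
published values from real cohorts, where between-subject anatomical
variability dominates.

## Numerical and design choices

* **Symmetry tolerance** 1e-10 on input matrices: genuine asymmetry is an
  error, numerical asymmetry is averaged away.
* **Strict FN > 3**: a count of exactly 3 is discarded; the rule is
  idempotent and monotone in the threshold.
* **Masked curve levels** propagate: a degree level enters group
  statistics only if $\varphi$ is defined for *every* subject and
  hemisphere.
* **Degenerate fits**: metrics constant across subjects (e.g. rich-club
  density in a saturated core) yield $F = 0, p = 1$ when the effect
  estimate is zero rather than NaN.
* **Seeds**: one master seed; every stochastic sub-task (template,
  subject, phenotype draw, null replicate) derives its own 31-bit seed by
  stable string hashing, so results are reproducible and independent of
  evaluation order.
* **Hub-selection pooling**: the single hub set pools both groups and
  both hemispheres (after homologue alignment). Whether hemispheres are
  pooled before or after splitting is not externally constrained; pooling
  is the default because a common hub set is what makes per-class
  measures comparable across hemispheres, and the alternatives remain
  available through `groupAverage()` on any subset.
* **Problem sizes** used in this package's own tests and acceptance run:
  null ensembles of 100–200 where curves are normalized, 100-replicate
  recovery studies at 50 subjects per group, 2000-replicate type-I
  calibrations on 20-per-group metric tables. These sizes give
  Monte-Carlo standard errors comfortably below the tolerances asserted.

## Known limitations

* The repeated-measures factor has exactly two levels (hemispheres), so
  sphericity is not an issue; the implementation does not generalize to
  more within-subject levels.
* The census treats edges independently; no network-based statistic or
  permutation clustering is provided.
* Per-node strength preservation in the null model is approximate; if a
  strength-exact null is required, annealing-based rewiring would be
  needed.
* The generator's degree separation between designated hubs and
  peripheral nodes is stochastic; in small cohorts a boundary region can
  swap between the estimated and designed hub sets. Effect recovery is
  robust to this (deficits are injected per true class, measured per
  estimated class), but exact hub-set recovery is not guaranteed.
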