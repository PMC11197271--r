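---
title: "Network-restricted strength analysis of pre/post-stressor resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-restricted strength analysis of pre/post-stressor resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question and the outcome variable

Resting-state functional connectivity studies of stress-related disorders
ask whether the coupling of the default mode network (DMN) — the intrinsic
connectivity network most active during self-referential, task-free thought
— is altered in posttraumatic stress disorder (PTSD) relative to major
depressive disorder (MDD), and whether such alterations are trait-like or
are pushed around by an acute stressor. The design this package supports is
a 2 (group: PTSD vs MDD) x 2 (scan: immediately before vs immediately after
an in-scanner affective stressor) repeated-measures comparison of a single
scalar outcome per scan: the **network-restricted strength** (NRS) of the
DMN.

NRS is deliberately simple. Given a cortical parcellation into nodes and a
consensus assignment of nodes to six intrinsic connectivity networks
(default mode DMN, central executive CE, dorsal salience DS, ventral
salience VS, somatomotor SM, visual VI), one scan's processing is:

1. average the cleaned BOLD series within each parcel (this package starts
   from the parcel-averaged series);
2. compute all pairwise Pearson correlations `r_ij` across frames;
3. variance-stabilize with the Fisher transform `z_ij = atanh(r_ij)`;
4. average `z_ij` over the `k(k-1)/2` unordered pairs of the `k` nodes of
   the network of interest.

`network_strength()` implements step 4; `scan_strength()` composes steps
2–4. Two conventions are worth making explicit because the verbal
definition ("mean connectivity between all nodes within the network") does
not fix them:

* **Self-pairs are excluded.** `z(1) = atanh(1)` is infinite; including the
  diagonal would be degenerate, so the diagonal is stored as zero and never
  read.
* **Pair-mean equals node-mean.** Averaging the upper triangle of the
  within-network block is identical to averaging the per-node mean
  connectivity (`nodal_strength()`); the package computes both and the test
  suite asserts their equality to 1e-12, which also guards the indexing.

Correlations are clipped to `|r| <= 1 - 1e-7` before `atanh` so that a
duplicated or degenerate pair of series yields a large finite z (about 8.4)
rather than poisoning the network mean with an infinity.

# Timeseries cleanup

The package's entry point is a parcel-by-frame matrix that has already been
through standard volume/surface preprocessing and denoising. Three cleanup
steps that commonly remain at this level are provided:

* `drop_initial_frames()` — removal of initial pre-steady-state volumes
  (five, in the design this package models: 650 acquired frames at
  TR = 0.7 s, 645 retained).
* `expand_motion_confounds()` + `regress_confounds()` — the standard
  24-parameter motion model: the six rigid-body parameters, their first
  differences, and the squares of both. The derivative convention is a
  **backward difference with the first frame backfilled with zero**; this
  keeps the frame count constant and is the common convention in motion
  regression. (A central difference would be equally defensible; nothing
  downstream depends on the choice.) Regression is ordinary least squares
  with an intercept always included; exactly collinear columns are dropped
  with a warning rather than an error, because expanded motion sets often
  contain near-duplicates.
* `mgtr()` — mean-timeseries regression, the parcel-level analogue of mean
  grayordinate timeseries regression: each node is residualized on the
  across-node mean series (plus intercept). The contract is orthogonality
  of every residual series to the *input* mean series, not a zero output
  mean. A zero-variance mean series (e.g. two exactly anti-correlated
  nodes) is an error, since the regressor carries no information.

`clean_timeseries()` applies them in the order drop frames, then motion
regression, then MGTR — the order in which these steps are conventionally
run.

# The 2x2 mixed GLM as exact t reductions

With one two-level between factor and one two-level within factor, the
repeated-measures GLM collapses algebraically onto three t contrasts, and
`mixed_anova_2x2()` is implemented as exactly that reduction:

* **group**: independent-samples pooled t on the subject means
  `(pre + post)/2`; `F = t^2`, df = (1, N-2);
* **interaction**: independent-samples pooled t on the difference scores
  `post - pre`; `F = t^2`, df = (1, N-2);
* **stress**: one-sample t on the *unweighted* average of the two group
  mean differences, using the pooled difference variance; df = (1, N-2).

The reduction doubles as its own oracle: the test suite checks `F = t^2`
against `t.test()` on 100 random cohorts to 1e-10, and checks all three F
statistics against `aov()` with an `Error(subject/scan)` stratum on
balanced cohorts. With unequal group sizes the group and interaction F are
identical to any standard implementation; the stress main effect depends on
whether the grand mean weights groups equally (Type-III style, used here)
or by size. The unweighted-means convention is reported in every result
object (`convention` field) because the choice is invisible in output
otherwise.

`simple_effect()` (paired t within one group) and `group_contrast()`
(pooled t between groups at one condition) report a signed difference
alongside a magnitude plus direction, because the natural prose for this
design reports "a 10% reduction" as a positive number. Percent differences
use the comparison condition's mean as denominator: the group's own
pre-stress mean for within-group stress effects, and the second (reference)
group's mean at the same condition for between-group effects. These
denominators reproduce the natural pairing of differences with percentages
and are an explicit convention, not a statistical necessity.

A useful arithmetic identity follows from the reductions and is asserted in
the tests: the difference of the two within-group deltas equals the
difference of the two between-group contrasts,
`(delta_PTSD - delta_MDD) = (groupdiff_post - groupdiff_pre)`, exactly.

`ancova_interaction()` re-tests the interaction with mean-centered
between-subject covariates added to the difference-score submodel. Centered
covariates leave the group contrast interpretable; each retained covariate
costs one error df, giving df2 = N - 2 - k (e.g. 39 with N = 52 and k = 11).
Constant covariates are dropped silently from k; exactly collinear pairs
are an error naming the pair.

Supporting tests delegate to the base R implementations a practitioner
would use: Pearson chi-square **without** continuity correction
(`chisq.test(correct = FALSE)`) for 2x2 demographics — the uncorrected
statistic is what standard social-science software reports by default for
these tables; Mann-Whitney via `wilcox.test` (exact enumeration when both
n <= 8 and untied, otherwise the tie-corrected normal approximation);
Benjamini-Hochberg via `p.adjust` for the nodal exploration (with
Bonferroni behind a flag). Correlation p-values come from
`t = r sqrt(n-2)/sqrt(1-r^2)` on n-2 df; `|r| = 1` returns p = 0 with a
degeneracy flag rather than erroring, because tiny simulated cohorts can
produce it.

# Power analysis

The power module answers "what is the smallest standardized effect this
design detects at a given power?" for the three effects, by mapping each
onto a two-tailed t test and evaluating the noncentral t distribution:

| effect | design | noncentrality | df |
|---|---|---|---|
| stress | paired t on all N difference scores | `d sqrt(N)` | N-1 |
| group | two-sample t on two-scan subject averages | `d sqrt(2) sqrt(n1 n2/N)` | N-2 |
| interaction | two-sample t on difference scores | `d sqrt(n1 n2/N)` | N-2 |

The group mapping treats the two scans as uncorrelated, so averaging them
halves the variance and a single-scan-scale d gains a factor `sqrt(2)`;
that zero between-scan correlation assumption is explicit and is the reason
`mdes("between_on_averages") * sqrt(2) = mdes("between_on_differences")` at
equal n (asserted to 1e-6 in the tests). `mdes()` inverts `power_of()` by
monotone bisection on [1e-6, 10] to 1e-8, which is safe because power is
strictly increasing in d.

Both an exact noncentral-t mode and a normal-approximation mode ship. At
n = 28/24 they differ by about 0.01–0.02 in the minimum detectable d, and
published tables of this kind are frequently computed with approximations
(the interaction cell at 80% power is 0.795 exactly and 0.779 under the
approximation). Since the evaluation mode behind any given published table
is usually undocumented, comparisons in the acceptance tests accept either
mode's value per cell. Simulated rejection rates (strength-mode cohorts,
2000 replicates) match the analytic power within the Monte-Carlo error, and
that agreement is itself a test.

# What the synthetic cohorts emulate — and what they do not

The generator exists because the motivating study's subject-level data are
available only on request; every quantitative claim in this package is
therefore exercised on synthetic cohorts with *known* injected effects.

Two modes:

* **Strength mode** (`simulate_strengths()`): draws the outcome directly.
  `pre ~ N(mu, subject_sd^2)`, `post = pre + shift + N(0, diff_sd^2)`, with
  the PTSD post shift set to `-d * diff_sd` so the standardized interaction
  effect is exact by construction. This is the fast path for type-I-error
  and power experiments (thousands of replicates in seconds).
* **Timeseries mode** (`simulate_cohort()`): draws every scan as
  multivariate Gaussian frames whose correlation matrix is block-structured
  by a six-network atlas (`rho_within` on the diagonal blocks, default 0.3,
  a typical within-network parcel correlation; `rho_between` elsewhere).
  Each subject carries a random within-DMN Fisher-z level
  (`mu + N(0, subject_sd)`) and each scan an independent jitter
  (`N(0, scan_sd)`); group, stress, interaction and within-run drift
  effects are added *in z space* and back-transformed, so injected
  decrements are exact on the analysis scale, which averages z rather
  than r.

Default cohort parameters are the modelled study's conditions: 28 + 24
subjects, two scans, TR 0.7 s; strength-scale defaults
(`mu_strength = 0.146`, `subject_sd = 0.032`, `diff_sd = 0.026`) are chosen
so that group means, their standard errors, and difference-score standard
errors sit at the magnitudes typical for within-DMN strength in a ~360-node
parcellation (strengths near 0.13–0.15, group-difference SEMs near 0.01,
within-group difference SEMs near 0.005 at these n). The spatial defaults
are reduced scale — a 60-node atlas with the DMN keeping its ~21% share
(75/360), 200 frames — so that replicated experiments run in seconds; the
test suite and the analysis scripts state their sizes explicitly, and full
scale (`n_nodes = 360, frames = 645`) is one argument away.

A standardized interaction effect in timeseries mode must be expressed
relative to the variability of the *measured* NRS difference, which
combines the subject-by-scan jitter with the sampling noise of an NRS
estimate at the configured frame count. The sampling-noise term has no
convenient closed form (within-network pair correlations share nodes, so
the pair z's are cross-correlated); `calibrate_diff_sd()` estimates it by a
seeded Monte-Carlo over independent null scans and is deterministic given
the config seed. Calibration accuracy (a few percent) is well inside the
±0.05 recovery tolerance the tests enforce.

Determinism is a contract: all randomness flows from `cfg$seed` through a
private RNG scope that saves and restores the global `.Random.seed`, so
identical configs are bit-identical, generators with different seeds can be
interleaved without interaction, and the simulator neither reads nor
disturbs the ambient RNG state.

What the generator does **not** emulate, deliberately: BOLD temporal
autocorrelation (frames are white so that `NRS -> atanh(rho)` is exact and
calibration targets are closed-form), hemodynamics, physiological noise,
scanner drift, motion spikes, and per-node heterogeneity of the true
consensus atlas (the packaged 360-node atlas file is a synthetic stand-in
partition, not the study's membership list, which is not public). Passing
tests therefore demonstrate the *procedures'* correctness and calibration
under the stated model — not that real resting-state data satisfy that
model.

If a configured effect pushes the block correlation matrix outside the
positive-definite cone, the generator fails loudly with the offending
eigenvalue rather than projecting back silently; silent repair would
invalidate the calibration claims.

# Numerical choices and degenerate inputs

* Fisher clipping margin `1e-7`; symmetry tolerance for connectivity
  matrices `1e-12`; orthogonality of residuals asserted at
  `1e-8 x frames`.
* `split_halves()` takes contiguous halves and **drops the single middle
  frame when the count is odd** (645 -> 322 + 322) so both halves have
  identical duration — unequal halves would introduce a duration confound
  into what is precisely a duration analysis.
* Zero-variance nodes are an error naming the node (a correlation with a
  constant series is undefined); a zero-variance across-node mean is an
  error in `mgtr()`; zero pooled variance and all-identical difference
  scores are errors in the contrasts.
* Atlas nodes missing from a matrix are an error listing the nodes, never
  silently dropped — silent intersection is how node-ordering bugs hide.
* `cohort_table()` refuses missing strengths and duplicate subject ids;
  symptom scores may be missing (scales administered to one group only are
  the normal case) and correlations use complete pairs.

# Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes, from scratch:
the nine minimum-detectable-d cells at 80/85/90% power; the correlation and
chi-square p-values implied by the published summary statistics; the
interaction-contrast identity; the type-I error of the full
simulate-to-ANOVA pipeline over 5000 null cohorts; empirical power at the
d = 0.79 interaction effect over 2000 cohorts; NRS consistency against
`atanh(0.3)`; and the nodal localization rate of a three-node injected
decrement over 200 replicates. The numbered scripts under `analysis/` walk
the same pipeline narratively on one simulated cohort (simulate, build
connectomes, primary GLM, nodal + split-half follow-ups, power table).

# Known limitations

* The stress main effect under unbalanced groups is convention-dependent
  (unweighted vs weighted means); only the unweighted version is computed.
* The ANCOVA enters covariates in both submodels but reports only the
  adjusted interaction; per-covariate inference is out of scope.
* No linear mixed-effects machinery: the design is exactly 2x2, and the
  algebraic reduction is both faster and self-verifying. Designs with more
  levels need a different tool.
* CIFTI parcellated-timeseries input is not supported; the TSV interchange
  format is canonical.
* Power calculations cover the three design effects only, not the
  mass-univariate nodal analysis or covariate-adjusted models.
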