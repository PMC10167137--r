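---
title: "Distributional regression trees and multiverse analysis of visual search data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional regression trees and multiverse analysis of visual search data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsmulti)
```

## The scientific problem

Feature visual search — finding an ellipse among circle distractors —
produces reaction times (RTs) that grow with the number of items on
screen (the set size) and accuracy rates that fall with it. In
case-control studies of children with a vision impairment, many factors
besides group membership plausibly shape performance: age, gender,
nystagmus, binocular acuity. Classical slope-and-intercept analyses of
the RT/set-size relationship compare only means. `vsmulti` implements a
different analysis: the whole *distribution* of the response is modelled
at every step, so effects on spread and skew are visible, not just
effects on location.

The pipeline has four steps:

1. **Screening** — Boruta shadow-feature selection and the One Rule
   baseline rank the candidate covariates: group `G`, set size `S`,
   target presence `T`, nystagmus `n`, age `a`, gender `g`.
2. **Multiverse regression** — the full model
   `DV ~ G * S * T + n + a + g` is fitted under three defensible lenses
   (median quantile regression, Huber robust regression, distributional
   regression) on one byte-identical design matrix, and per-term
   agreement across the universes is summarized.
3. **Reduction and testing** — a reduced, explainable model is proposed
   from Steps 1–2 and tested with the rank-based ANOVA-type statistic
   (when all retained covariates are categorical) or a median quantile
   model (otherwise).
4. **Distributional regression trees** — the response is recursively
   partitioned; every node carries a full maximum-likelihood
   distribution fit (Ex-Gaussian for RTs, generalized beta type 1 for
   accuracy rates), and splits occur where the fitted parameters are
   most unstable along a covariate.

## Trial-level preprocessing

Each participant contributes 80 presentations: 8 practice trials
(dropped) and 72 test trials spread over the six set-size × target
conditions (8–15 presentations each, 12 on average). Within each
participant × condition:

* RTs above 10 s are excluded (strictly above: a trial at exactly 10 s
  is kept);
* only the first eight *correct*, cutoff-surviving RTs are retained, in
  presentation order;
* accuracy is the proportion of correct responses among all test
  presentations of the condition. A printed worked example (10 correct
  of 12 presentations = 83%) anchors this rule; the alternative
  historically stated form — 8 divided by the number of presentations
  needed to reach the eighth correct response — is inconsistent with
  that example and is provided only behind
  `summarize_condition(accuracy_rule = "eight_over_trials")`.
* a condition observation with accuracy at or below chance (50%) is
  excluded. Exclusion is per participant × condition observation, not
  per participant: the source analysis reports six excluded
  *observations*, which only makes sense at that granularity.

## Distribution families

**Ex-Gaussian** (RTs, seconds): convolution of a Normal(mu, sigma) and
an exponential with mean nu; links identity/log/log. The log-density is
evaluated entirely on the log scale; for extremely negative values of
the standardized argument the code switches to a Mills-ratio asymptotic
expansion in which the two numerically huge terms cancel symbolically —
without this branch, catastrophic cancellation at absurd parameter
values (reachable by a line search) can fabricate a spurious optimum.

**Generalized beta type 1** (accuracy rates on (0,1)): the
location–scale–shape parameterization with `mu`, `sigma` in (0,1)
(logit links) and shapes `nu`, `tau` positive (log links). At
`nu = tau = 1` it reduces exactly to a Beta with `a = mu(1-s²)/s²`,
`b = (1-mu)(1-s²)/s²`; this nesting is the definitional test of the
parameterization. Accuracies of exactly 100% occur routinely, so
responses are first squeezed by `squeeze_unit()` (affine compression
with margin 0.005). The four GB1 parameters are only weakly identified
on samples that a Beta already fits well; the fitted log-likelihood is
then trustworthy even where individual shape estimates are not.

Fits use BFGS on the link scale with analytic per-observation scores
(Ex-Gaussian, Normal, GB1 all have closed-form scores here),
method-of-moments starts — for the Ex-Gaussian, a skewness-based split
of the variance between sigma and nu, floored at small positive values
— and up to three jittered restarts. Convergence requires the optimizer
to at least match its own start (reltol 1e-10 internally, declared at
1e-8); any link-scale parameter beyond ±15 flags a boundary fit, which
is never reported as converged.

## Score-based instability splitting

At a fitted node the per-observation score contributions (derivatives
of the log-density in each parameter) have mean zero. If the fitted
parameters are wrong for an identifiable subgroup, the scores drift
systematically along the covariate that defines it. `instability_test()`
decorrelates the score columns with the inverse square root of their
empirical covariance and then:

* **categorical covariates** (nominal and ordinal): a Pearson-type
  chi-square over level-wise score sums, df = p(k−1);
* **numeric covariates**: the supLM statistic — the maximum of the
  squared cumulative score process, scaled by t(1−t), over cutpoints
  with t in [0.1, 0.9]. Its asymptotic null is the supremum of a
  squared, tied-down Bessel process over the trimmed interval; the
  package evaluates p-values against a simulated null distribution of
  that functional (40,000 replicates of a Brownian bridge on a grid of
  1,000, fixed internal seed, cached per dimension and trim, so
  p-values are deterministic), with an exponential tail extension
  beyond the simulated range. Simulated type-I error at alpha = .05 is
  0.03–0.07 in the acceptance suite for both covariate kinds.

`select_split()` Bonferroni-adjusts the minimum p-value across the
covariates that vary in the node (not across cutpoints — the supLM
functional already accounts for scanning) and abstains unless the
adjusted p-value is below alpha (default .05). `find_partition()` then
maximizes the children's joint log-likelihood over admissible
bipartitions: observed-value midpoints for numerics, contiguous level
blocks for ordinals (set size can split {4} | {16,24} but not
{4,24} | {16}), all level bipartitions for nominals. Node models are
intercept-only: covariates act only through splits, which is what makes
each node a plain, plottable distribution. Defaults: alpha .05,
minimum node 20 (at least 5× the parameter count), maximum depth 5.
Each node reports n, the median and an approximate 95% CI from the
binomial order-statistic ranks ⌊(n − 1.96√n)/2⌋ and symmetric
counterpart, clamped to the sample range (the sample range itself,
flagged wide, below n = 6).

## Screening and the multiverse

Boruta is implemented on `ranger` forests (500 trees, permutation
importance — impurity importance cannot be compared against shadows) as
the reference algorithm prescribes: per iteration, every covariate gets
a within-column permuted shadow copy; a covariate scores a hit when its
importance exceeds the *maximum* shadow importance; two-sided binomial
tests at level .01, Bonferroni-corrected across the candidate set,
confirm or reject; anything undecided after `max_iter` stays tentative.
One Rule discretizes numeric variables (and a numeric response) by
quartiles and scores each covariate's single-variable majority rule by
training accuracy.

The three regression universes consume one design matrix with fixed
treatment coding (references: control, set size 4, target absent,
female). Quantile regression is IRLS on the epsilon-smoothed check loss
with bootstrap standard errors (200 resamples, warm-started); robust
regression is Huber M-estimation (k = 1.345) via `MASS::rlm`;
distributional regression is joint ML with the full predictor on the
location parameter and intercepts on scale/shape by default
(`full_for = "mu"`). Putting all 15 design columns on all four GB1
parameters makes the observed information numerically singular at these
sample sizes, which silently destroys that universe's standard errors —
the restricted default is the standard distributional-regression
compromise and keeps the information well conditioned. Covariates can
be put on any subset of parameters via `full_for`.

**Reduction rule.** The default rule retains a variable when the screen
confirms it *and* the multiverse corroborates it (some design-matrix
term involving the variable is significant with a consistent sign in at
least 2 of the 3 universes). The pure union of the two criteria is
available as `rule = "or"`, but it cannot veto screen hits that are
mere proxies: with 82% nystagmus prevalence inside the impaired group,
nystagmus is marginally predictive of RT and an all-relevant screen
*must* confirm it — textbook Boruta behaviour — while every regression,
conditioning on group, correctly finds it inert. Step 2 exists
precisely to rectify Step 1, so the conjunction is the default.

Step 3 dispatches on the measurement level of the retained set: the
ANOVA-type statistic (Box-approximated numerator df, Brunner
denominator df, both exposed, plus an F(df1, ∞) variant) when all
retained covariates are categorical; otherwise a median quantile model
— discretizing age would be the alternative and is deliberately not
done.

## The synthetic experiment generator

`simulate_experiment()` emulates the reference study's structure so the
whole pipeline is testable without the archived raw data: 39 impaired
participants (82% nystagmus, acuity ~ Normal(0.63, 0.31) LogMAR
truncated to [0.2, 1.5] — the SD reconstructs the reported SEM, 0.05,
times √39) and 33 controls (acuity near 0); ages Normal(11.6, 3.1) and
Normal(13.0, 2.9) truncated to [5, 18]; male proportions 0.56 and 0.61;
8 practice + 72 test trials with per-condition counts in [8, 15].

Reaction times are Ex-Gaussian per group × set-size × target × gender
cell. Cell medians are the published node medians (seconds): impaired
1.59 at set size 4; controls 0.91 (present) / 1.08 (absent) at set
size 4; at set sizes 16/24: controls 2.43 absent, impaired females
4.37 vs males 3.10 absent, impaired 2.15 present, control males 1.51 vs
females 1.38 present. Within the 16/24 band, 16 is scaled by 0.95 and
24 by 1.05 — search time should still grow with display size — keeping
the pooled band median on target. Scale and tail are set to
sigma = 0.12 × median and nu = 0.35 × median (right-skew typical of RT
data), and the location is then *solved* so the implied Ex-Gaussian
median matches the map exactly; medians are calibration targets, never
hard-coded outputs. Draws above 10 s occur naturally in the slow cells,
exercising the cutoff rule. Trial correctness is Bernoulli from an
accuracy map reproducing the reported age pattern: ~0.97 at set size 4;
at 16/24 target-present 0.88 under age 14 and 0.98 at 14+; target
absent slightly easier (0.93 / 0.99). `effect_scale` and
`accuracy_effect_scale` interpolate all effects toward a null
experiment (log/logit scale), and `acuity_slope` optionally couples the
RT location linearly to acuity within group. A participant-level random
intercept is available (`participant_sd`) but defaults to zero — the
reference models carry none, and retained RTs are otherwise independent
given the cell.

What the generator deliberately does **not** emulate: within-participant
dependence (fatigue, learning), lapse trials, acuity psychophysics
beyond a monotone link, diagnosis subgroups. Passing tests therefore
demonstrate that the *methods* recover the structure the generator
encodes at realistic sizes and noise — not that real search data meet
these independence assumptions.

## Analysis units and problem sizes

Steps 1 and 3 run on the condition table (one row per participant ×
set-size × target, ~432 rows; this matches a rank test with a few
hundred denominator df). Step 2 runs on every retained reaction time
(~3,400 rows) for the RT response — gender effects of ~0.1–0.2 s are
resolvable there and not reliably at the condition level — and on the
condition table for accuracy, its only possible unit. The RT tree uses
retained trials; the accuracy tree uses squeezed condition accuracies.
The acceptance suite sizes its simulations accordingly: 50 seeds for
tree topology, 30 for null trees, 20 for end-to-end reduction, 1,000
replicates for test calibration, 200 for parameter-recovery bias.

## Known limitations

* The end-to-end recovery of the reference *accuracy* variable set
  {S, T, a} is power-limited: with per-trial correctness probabilities
  pinned to the published percentages and ~12 trials per condition, the
  set-size and target effects on condition accuracy are ~0.02–0.05
  against a binomial standard deviation of ~0.08, and their
  corroboration by two of three regression universes is unstable across
  simulated experiments. The acceptance suite reports the observed
  rates rather than masking them.
* GB1 node fits on near-ceiling accuracy data can fail to converge;
  such nodes become leaves with a warning rather than reporting an
  unconverged fit as a model.
* supLM p-values below ~2.5e-5 come from the exponential tail
  extension, not simulation, and are best read as "very small".
* The ATS implementation is the between-subjects form; repeated
  measures within participant are not modelled (consistent with the
  full-model regressions, which also treat rows as independent).
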