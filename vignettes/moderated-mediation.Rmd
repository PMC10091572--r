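---
title: "Mediation and moderated mediation with bias-corrected bootstrap inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediation and moderated mediation with bias-corrected bootstrap inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modmedr)
```

# The model

modmedr estimates observed-variable path models of the form

$$
M = i_M + a X + g_M' C + \varepsilon_M, \qquad
Y = i_Y + c' X + b M + g_Y' C + \varepsilon_Y,
$$

where $X$ is an exposure (here: childhood-trauma total), $M$ a mediator
(self-esteem), $Y$ an outcome (depression or anxiety symptom total), and
$C$ a common covariate vector (age, sex) entered in *every* equation.
The total effect $c$ comes from the reduced model $Y = i + cX + g'C$.
Because all three equations are least squares with the same covariate
set, the decomposition

$$ c = c' + a\,b $$

is an algebraic identity, not an approximation — the package's tests
assert it to $10^{-12}$ on the point fit and to $10^{-10}$ on every
bootstrap resample. The indirect effect is $a\,b$ and the proportion
mediated is $100\,ab/c$, reported only when $|c| > 10^{-8}$ (a ratio to a
vanishing total is meaningless; the floor is far below any effect the
scales can express).

The moderated analysis adds one moderator $W$ per run and asks whether
either stage depends on it:

* first stage: $M \sim C \mid {+}\,X, W \mid {+}\,XW$
* second stage: $Y \sim C \mid {+}\,X, W, M \mid {+}\,MW$

with $\mid$ separating hierarchically entered blocks. Each block reports
$\Delta R^2$ and the incremental
$F = (\Delta R^2/q) / \big((1-R^2_\text{step})/(n-p_\text{step}-1)\big)$,
which equals the nested-model ANOVA $F$ (tested against `anova()`).

All moderated fits are run on z-scored variables (the $n-1$ SD, matching
the sample descriptives), with interaction products formed *from the
standardized components* and not re-standardized. That convention is what
makes moderator values $-1/0/+1$ exactly one SD below/at/above the mean,
so the simple-effect protocol needs no re-estimated SDs: the first-stage
simple effect at level $w$ is $a + w\,a_{XW}$, the second-stage effect is
$b + w\,b_{MW}$, the conditional indirect effect is their product, and
high-minus-low differences equal $2\times$ the interaction coefficient by
construction (asserted to $10^{-12}$).

# Bootstrap inference

Intervals come from a nonparametric bootstrap: whole respondent rows are
resampled with replacement at the original $n$, the full procedure —
including re-standardization, for standardized fits — is recomputed on
each resample, and bounds are read from the replicate distribution.

Two interval types are offered:

* **percentile**: the $\alpha/2$ and $1-\alpha/2$ empirical quantiles;
* **bias-corrected percentile** (default): quantile positions shifted to
  $\Phi(2z_0 + z_{\alpha/2})$ and $\Phi(2z_0 + z_{1-\alpha/2})$, with
  $z_0 = \Phi^{-1}\!\big(\Pr(\hat\theta^* < \hat\theta)\big)$.

Numerical choices that matter at the second decimal:

* Empirical quantiles use order statistics with linear interpolation
  (R's type 7). Published bounds rounded to two decimals are sensitive to
  the quantile convention, so it is fixed and documented rather than
  left to chance.
* Replicates exactly equal to the point estimate count one half toward
  $z_0$ — a continuity correction that keeps the probit finite under
  heavy ties; additionally the tail proportion is clamped to
  $[1/2B,\, 1-1/2B]$ so a pathological replicate set cannot produce
  $z_0 = \pm\infty$. With $z_0 = 0$ the bias-corrected bounds reduce
  *exactly* to the percentile bounds (tested).
* A rank-deficient resample (possible in tiny samples) is redrawn and
  counted in the `n_redrawn` attribute rather than silently propagating
  `NA`s.
* Acceleration (BCa) is deliberately not implemented: the analysis this
  package operationalizes specifies the bias-corrected percentile
  method, and adding an acceleration constant would change the bounds it
  is validated against.
* The reported $z$ is point estimate / bootstrap SE; a first-order delta
  (Sobel) SE for the indirect effect is available via
  `se_method = "delta"` because published tables do not always say which
  was used.

Defaults are 5000 resamples at the 95% level — the settings of the
reference analysis — and every function takes an integer `seed` that
makes results byte-reproducible without touching the caller's RNG
stream.

# The synthetic-data generator

The generator exists because raw survey data of this kind are typically
not shareable. It emulates three layers:

**Scale level.** `generate_scale_level()` draws multivariate-normal data
whose population means, SDs and correlations equal a `moment_spec()` —
for the worked examples, `adult_survey_moments()`: the printed moment
structure of a 6057-respondent adult survey (e.g. CTQ mean 38.46, SD
11.67; CTQ–SES $r=-0.41$; PHQ-9–GAD-7 $r=0.80$). Because printed
correlation tables are rounded and get augmented with partially known
rows (age), the assembled matrix can be indefinite;
`repair_correlation_matrix()` restores positive definiteness by
eigenvalue clipping at a floor of $10^{-6}$ followed by rescaling to a
unit diagonal, iterated to convergence — the smallest perturbation that
yields a usable covariance, with the max elementwise change reported.
(The shipped matrix happens to be definite even with the age column, so
the repair is a verified no-op there.)

**Demographics.** Only quantiles of age are typically printed, so age is
a monotone transform of a standard normal: piecewise-linear in $z$ with
separate scales below and above the median, calibrated so the median
(34) and both quartiles (30, 40) are matched exactly, truncated at 18
and rounded to whole years. The right tail is heavier than the left
(IQR 30–40 around a median of 34), which this two-sided construction
captures without committing to a parametric family. Age correlations are
wired only where values are known (−0.13 with depression, −0.10 with
anxiety; all others 0), and sex is drawn independently of the scales —
the reference sample showed no sex differences — either by exact quota
(2422 of 6057 women, reproducing the printed split) or Bernoulli.

**Item level.** `generate_item_level()` draws compound-symmetric latent
batteries: one common factor plus unique parts giving every item pair
the same correlation $\rho$, which implies
$\alpha = k\rho/(1+(k-1)\rho)$. Published reliabilities invert to, e.g.,
$\rho = 0.222$ for a 28-item battery with $\alpha = 0.889$. Likert
discretization at equal-probability thresholds attenuates the realized
$\alpha$ by a few points; a `rho_inflation` argument can compensate, and
is off by default because the target publications report item-level
distributions too sparsely to calibrate it against anything.

**Structural level.** `generate_structural()` draws from the path model
itself with known coefficients (including $XW$ and $MW$ interactions)
and attaches them to the data, which is what the recovery, coverage and
type-I-error studies run on.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: item- and scale-level non-normality and
skew (symptom scales are right-skewed in practice; the ERQ subscales of
the reference survey were explicitly non-normal, and the generator's
Gaussian margins are a documented idealization with the monotone age
transform as the template for adding skewed margins), floor effects,
response styles (acquiescence, careless responding), and missingness
mechanisms (`validate_input()` drops incomplete rows; nothing is
imputed). Conclusions about estimator behaviour under those features
need purpose-built simulations.

# Scale scoring choices

Built-in definitions encode the standard instruments, with two
documented judgment calls:

* **PHQ-9 / GAD-7 coding.** Survey write-ups sometimes describe 1–4
  response anchors and per-item means, yet report scale-level
  descriptives (mean ≈ 4.19, SD ≈ 4.90 for nine depression items) that
  are only arithmetically consistent with the standard 0–3 coding summed
  to a 0–27 total. The default is therefore sum-on-0–3; `coding = "1-4"`
  and `scoring = "mean"` are available for datasets that genuinely use
  the alternative.
* **Reverse-keyed sets.** The Rosenberg SES uses the canonical 5-of-10
  reverse set by default and accepts any other set, since published uses
  vary; the CTQ-28 uses the canonical 7 reverse items and treats the 3
  minimization/denial items as administered-but-unscored.

`cronbach_alpha()` is the plain variance-ratio formula
$\frac{k}{k-1}\big(1 - \sum_j s_j^2 / s_\text{total}^2\big)$, verified in
tests against a hand-computed fixture and against the two-way
mean-square (Hoyt) decomposition it is algebraically equal to.

# Design decisions on genuinely open points

* **Full-sample interaction fit vs subgroup approach.** Both appear in
  applied work and can disagree (dichotomizing a moderator discards
  information and biases subgroup estimates). The interaction fit is the
  default everywhere; `subgroup_effects()` implements the mean/median
  split so the disagreement itself can be reproduced and inspected.
* **Published simple-effect tables need not be affine in $w$.** Under a
  single linear-interaction model, effects at $w=-1,0,+1$ are exactly
  collinear and the high-minus-low difference is twice the interaction
  coefficient. Published cell values that violate this cannot be
  produced by the stated model on any dataset, so the package implements
  the protocol (linear combinations of the fitted coefficients) rather
  than chasing any particular table's cells; its correctness checks are
  algebraic identities and parameter-recovery studies, not cell
  matching.
* **Covariates everywhere, with a sensitivity switch.** Age and sex
  enter every equation by default; `sensitivity = TRUE` in the pipeline
  repeats all analyses without them. On moment-faithful synthetic data
  the adjusted and unadjusted indirect effects agree to well under 0.01
  — the generator's age/sex structure is nearly orthogonal to the
  mediation triangle by construction, mirroring the robustness the
  reference analysis reported.
* **One master seed, forked per stage.** The pipeline draws a named seed
  pool once, in a fixed stage order, so toggling a later stage (e.g.
  sensitivity) never changes an earlier stage's draws, and two runs of
  the same config are `identical()`. The run log records every substream
  seed; run timings are deliberately *not* part of the bundle so that
  reproducibility can be asserted bitwise.

# Validation scale

The shipped checks run at the following problem sizes, chosen to keep
Monte-Carlo error well inside the asserted tolerances: moment fidelity
at $n = 10^5$ against the $4/\sqrt{n}$ Fisher-z bound; reliability and
mediation replication at the survey's own $n = 6057$ with 5000
resamples; parameter recovery at $n = 50{,}000$ within 3 Monte-Carlo
SEs; interval coverage (93–97% band) and type-I error of the
indirect-difference test (3σ binomial band around 5%) over 500
replicates at $n = 500$ with 1000 resamples each; power monotonicity of
the second-stage difference test over $b_{MW} \in \{0, .05, .1, .2\}$
at 120 replicates per point.

# Known limitations

* Observed-variable path models only: no latent variables, no
  measurement-error correction, no serial or parallel multiple
  mediators, no Johnson–Neyman regions.
* OLS standard errors are classical (no robust/sandwich option); the
  bootstrap is the intended inference route.
* Cross-sectional estimands: "effect" language describes model
  coefficients, not causal identification, which these designs cannot
  deliver on their own.
* The generator's Gaussian margins understate tail behaviour of skewed
  symptom scales; bootstrap coverage verified here is for the Gaussian
  regime.

```{r example, eval = FALSE}
# end-to-end, at full scale
cfg <- analysis_config(n = 6057, n_boot = 5000, seed = 1)
bundle <- run_full_analysis(cfg)
write_report_bundle(bundle, "report")
```
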