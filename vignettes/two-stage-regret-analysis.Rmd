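---
title: "Two-stage analysis of regret-guided risky choice: models, simulator and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage analysis of regret-guided risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regretwheel)
```

## The task and its calculus

The Wheel-of-Fortune paradigm presents two lotteries per trial. Each
lottery has a better outcome $x$, a worse outcome $y$ ($x > y$) and a win
probability $p$; both wheels are spun after the choice, so the subject
sees the factual *and* the counterfactual outcome. The experiment crosses
two social factors: *beneficiary* (the outcome accrues to the chooser or
to a familiar partner) and *audience* (the partner watches or is absent),
giving a 2x2 within-subject design.

Three trial-level statistics drive choice:

$$\mathrm{dEV} = EV_L - EV_R, \qquad EV = p\,x + (1-p)\,y$$
$$\mathrm{dSD} = SD_R - SD_L, \qquad SD = \sqrt{p\,(x-EV)^2 + (1-p)\,(y-EV)^2}$$
$$\mathrm{AR} = |y_R - x_L| - |y_L - x_R|$$

dEV is the expected-value advantage of the left option; dSD the risk
difference (note its reversed orientation, exactly as the statistic is
conventionally defined in this paradigm); AR the anticipated-regret
factor: the difference between the two options' maximum possible
experienced regret. AR is a signed difference of absolute gaps and is
deliberately *not* rectified at zero, so it also encodes anticipated
rejoicing.

After the outcome, two experienced-emotion factors are defined:
experienced regret (counterfactual minus obtained outcome, across wheels)
and experienced disappointment (unobtained minus obtained branch of the
chosen wheel). On the worked example trial — chosen wheel (50, −200)
landing on −200, unchosen wheel landing on 200 — these are 400 and 250
points:

```{r}
experienced_regret(obtained = -200, counterfactual = 200)
experienced_disappointment(lottery(50, -200, 0.5), obtained = -200)
```

Payment converts points to money through four printed anchors (200, 50,
−50, −200 points = 2.5, 1.5, 1.0, 0 GBP). The anchors are *not*
collinear, so "linear conversion" cannot mean a single line through all
four; `points_to_gbp()` interpolates piecewise-linearly between adjacent
anchors, which is exact at every anchor and monotone. Since task outcomes
only ever take the four anchor values, the interpolation rule is
unobservable in practice and matters only for off-alphabet inputs.

## The two-stage inference

**Stage 1.** Within each design cell, choice (1 = left) is modelled by a
mixed-effects logistic regression

$$\mathrm{logit}\,P(y_{it}=1) = x_t\beta + z_t b_i, \qquad
  b_i \sim \mathcal N(0, \mathrm{diag}(\tau^2))$$

with $x_t = z_t = (1, \mathrm{dEV}, \mathrm{dSD}, \mathrm{AR})$ and a
diagonal random-effect covariance (independent random effects). Fitting
uses `lme4::glmer` (Laplace approximation, nloptwrap optimizer) — the
standard tool for exactly this model. Fixed effects are the
population-level estimates; per-subject composite coefficients are fixed
effect plus the subject's BLUP, shrunken toward the population value.
Emotional ratings get the mirror-image linear mixed model
(`lmerTest::lmer`, REML) with experienced regret and disappointment as
regressors; fixed-effect tests there use Satterthwaite degrees of
freedom, which is why the df are fractional.

Two estimation notes. The model formula includes fixed and random
intercepts even though the regressor set is usually written without one:
the logistic intercept absorbs any side bias, and removing it is a
one-switch change in `choice_model_spec()`. And the occasionally-seen
residual term in the logistic model specification is treated as
notation — a Bernoulli response has no separate observation-level
Gaussian residual to estimate.

**Stage 2.** Per-subject composite coefficients (for dEV, dSD, AR, and
for the two rating slopes) enter a 2x2 repeated-measures ANOVA across
cells. With two levels per factor each F equals the squared paired t of
the corresponding within-subject contrast (so no sphericity issue
arises); effect size is partial eta-squared $SS_n/(SS_n+SS_d)$, with a
confidence interval from noncentral-F inversion: the bounds are the
noncentralities placing the observed F at the $\alpha/2$ tail
quantiles, mapped through $\lambda/(\lambda + DF_n + DF_d + 1)$. This
reproduces the published intervals of the reference analysis to ~0.01,
which is also how the partial (rather than classical) eta-squared reading
of the published table was verified.

## The generative simulator

`simulate_dataset()` replaces human participants: 50 subjects x 4 cells
x 48 trials by default, outcomes drawn from {−200, −50, 50, 200}, win
probabilities from multiples of 0.05 in [0.2, 0.8] (the task's
probability list is not published; this grid gives visibly distinct wheel
segments and non-degenerate SDs). One stimulus list is generated per
dataset and shared by all subjects and cells, as in the task. The list is
resampled until dEV, dSD and AR each span both signs and no regressor
pair exceeds |r| = 0.95, so stage-1 fits are identifiable.

Population defaults (`population_spec()`): control cell
$\beta = (0,\ 0.010,\ -0.002,\ 0.010)$ logit/point, with additive
condition offsets chosen once to reproduce the qualitative published
pattern — audience presence raises the regret weight (+0.005) and damps
the expected-value weight (−0.003); partner beneficiary lowers the regret
weight (−0.004). These keep simulated choice probabilities mostly inside
[0.1, 0.9] for the default gamble ranges. Between-subject SDs are half
each coefficient's magnitude ($\tau = |\beta|/2$). Rating coefficients
default to the published baseline-condition estimates
($b_{reg} = -0.25$, $b_{dis} = -0.59$ rating units/point) with residual
SD 12 — chosen so trial ratings use most of the [−50, 50] axis without
being pure noise.

Random effects are redrawn independently per design cell, matching the
per-condition independent fits of the analysis;
`subject_constant_effects = TRUE` shares a subject's draws across cells
instead. Ratings are rounded to integer cursor positions and clamped to
[−50, 50]; with the published slope magnitudes the linear predictor
frequently exceeds the axis, so clamping-induced censoring is a real
feature of the simulated data (and of the task). It attenuates fitted
rating slopes and is deliberately not modelled; exact-recovery
diagnostics switch rounding and clamping off. Missing responses are not
simulated, but the reader drops and counts missing-choice rows so
external data with omissions flow through.

What the simulator does *not* emulate: reaction times, trial-order and
fatigue effects, the facial-expression channel, subject-specific lapse
rates, and any nonlinearity of the regret-to-choice mapping (a sigmoid
transform of AR has been suggested in the literature). Tests passing on
simulated data therefore certify the pipeline's statistical machinery,
not these aspects of real behaviour.

## Numerical choices and degenerate inputs

* Stage-1 fits use nloptwrap; on a convergence failure the fit restarts
  from zero variance components with tightened tolerances, and a fit
  whose *fixed-effect* linear predictor exceeds |25| logits is treated as
  (quasi-)separated and ridge-stabilised (penalty 1e−3) with a warning
  and a flag. Subject-level saturation through large BLUPs is not
  separation and is left alone.
* The simulation harnesses (`type1_simulation()`, `power_simulation()`)
  default to the `nAGQ = 0` (PIRLS) approximation, trading a little
  fixed-effect accuracy for a ~5x speedup across hundreds of replicate
  fits; single-dataset analyses default to the full Laplace fit.
* A model spec with no random terms drops to ordinary pooled logistic
  regression; at zero random-effect variance the mixed fit and the
  pooled MLE coincide, which the test suite verifies against an
  independently coded Newton-Raphson fitter (`logistic_mle()`).
* `rm_anova_2x2()` snaps sums of squares below 1e−12 of the response's
  total square to zero, so constant input gives F = 0 rather than a
  ratio of floating-point noise; a zero error term with a nonzero effect
  is reported as F = Inf with p = 0 rather than an error.
* BIC counts fixed effects plus variance components. The
  anticipated-disappointment regressor used for model comparison is
  dAD = (x_L − y_L) − (x_R − y_R), the within-lottery analogue of AR;
  under the default alphabet it is strongly collinear with dSD
  (r ~ −0.98), which is precisely why the reference analysis found no
  BIC support for it — the risk term already carries the information.

## Calibration of the two-stage shortcut, honestly

Treating per-subject BLUPs as observed data in stage 2 understates
uncertainty: composite coefficients are shrunken toward the cell's fixed
effect (compressing the ANOVA's error term) while the cell-level
fixed-effect estimation noise — common to every subject in the cell —
survives in the effect term. Writing $\sigma^2$ for the squared
standard error of one subject's coefficient and $s =
\tau^2/(\tau^2+\sigma^2)$ for the shrinkage factor, the paired-t
variance ratio is inflated by $1/s^2$; the procedure is calibrated only
when between-subject heterogeneity dominates estimation noise
($\tau \gg \sigma$).

The package's calibration harness measures this directly. Under the
default population ($\tau = |\beta|/2$) at the reduced scale of 20
subjects x 24 trials, $\sigma \approx \tau/2$ for the regret weight and
the empirical type-I error of the stage-2 main effects is far above the
nominal 5% (0.51–0.54 per effect over 500 replicates, driven
additionally by replicates whose variance components hit the boundary,
which collapses the error term entirely). With heterogeneity three times
larger the same harness drops to roughly 0.15 — closer to, but still
above, the nominal level at this design size. This is a real property of the two-stage
shortcut at low heterogeneity, not an implementation artefact — the
pooled-MLE and recovery checks pass under the same settings — and it is
reported as measured rather than tuned away. Published applications of
the method operate in the favourable regime: there, between-subject
spread is comparable to the coefficient means themselves and trials are
twice as many. The harness exists exactly so users can check which
regime their design is in before trusting stage-2 p-values.

Power, by contrast, is generous in either regime:
`power_simulation()` with the default audience offset on the regret
weight (+0.005 logit/point) exceeds 80% at 50 subjects and is monotone
over 10 → 25 → 50, mirroring the sample-size rationale of the reference
study — with the caveat that part of that sensitivity is the same
anticonservatism measured above.

## Problem sizes used by the test suite

The suite favours a few deep checks over many shallow ones: oracle
equivalence uses 20 datasets at 50 x 48 (study scale); fixed-effect
recovery uses 100 replicates at study scale (Monte-Carlo SE of the bias
estimates ~1e−4 logit/point); the type-I harness uses the reduced
20 x 24 scale with 500 replicates and the power curve 100 replicates per
sample size. These sizes keep the full suite within tens of minutes on
one CPU while leaving Monte-Carlo error well below the margins being
asserted.

## Known limitations

* The exact 48-item published gamble table is not reproduced (it is not
  printed in the source); the generator emulates its statistical role.
* External deposits are ingested through a user-supplied column mapping
  (`read_dataset(..., dialect = "mapped")`); no schema is hard-coded.
* Ratings are modelled as continuous despite being bounded integers;
  censoring at ±50 attenuates slopes, most visibly at the published
  slope magnitudes.
* The degrees-of-freedom method for the rating model's fixed effects is
  Satterthwaite; other software may print slightly different fractional
  df for the same fit.
* No Bayesian fitting, no non-diagonal random-effect covariance, no
  time-on-task regressor.
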