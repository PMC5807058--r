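---
title: "Models and methods behind mindwandr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mindwandr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindwandr)
```

mindwandr simulates and analyses a three-task individual-differences study
of mind wandering, metacognition and cognitive control. This vignette
documents the generative models, the estimators, the numerical choices, and
the places where the design was genuinely open — together with what the
package's own simulations can and cannot show about real data.

## The trait layer

Every simulated subject is a draw from a Gaussian copula over six latent
traits (`gen_population()`): mind-wandering propensity, detection ability,
metacognitive noise, control strength, base speed, and lapse rate. The
copula separates two modelling decisions that are often conflated: the
*marginal* distribution of each trait on its native scale, and the
*correlation structure* tying traits together. Marginals are fixed quantile
maps (Beta for probabilities, truncated normal for the noise and speed
parameters, Normal for control strength in ms); correlations are specified
on the latent Gaussian scale, where the metacognition axis is oriented as
*efficiency* so that a positive entry means "better metacognition goes with
more control".

Default correlations: efficiency-control +0.29 (the structural path of
interest), efficiency-detection +0.15, efficiency-propensity -0.15,
control-propensity -0.15, everything else 0. The +/-0.15 entries encode the
predicted directions of the study's hypothesis diagram at a deliberately
modest magnitude; 0.29 matches the structural estimate the analysis is
meant to recover.

Marginal choices worth knowing about, with the cohort-level summaries they
were calibrated against (published descriptives of these paradigms, not any
acceptance quantity):

* `mw_propensity ~ Beta(4, 16)` with a per-trial Markov return rate of 0.10
  gives roughly two-thirds off-task occupancy and ~45% overall No-Go
  commission rates, typical for a 225-trial SART.
* `metacog_noise ~ TruncNormal(0.80, 0.30)` in evidence-SD units; see the
  metacognition section for what this implies.
* `control_strength ~ Normal(20, 40)` ms: a 20 ms mean congruency sequence
  effect with broad individual differences.
* `detection_ability ~ Beta(2, 2)`: a broad, unimodal spread; detection is
  the least-constrained construct in the literature.
* `base_speed ~ TruncNormal(370, 45)` ms, `lapse_rate ~ Beta(2, 98)`.

## The SART simulator

Attention follows a three-state Markov chain - on-task, weakly decoupled,
deeply decoupled - honoring the graded view of perceptual decoupling: the
chain leaves the on-task state with per-trial probability equal to the
subject's propensity (split 2:1 into weak and deep), and returns with rate
0.10. Emissions degrade with depth: No-Go commissions rise from .15 to .55
to .85, Go omissions from .005 to .30, anticipations (< 100 ms presses)
scale the lapse rate by 0.1x / 1.5x / 6x, and lognormal RT dispersion
roughly quadruples. These constants are the package's design (the source
paradigm specifies no process model); they sit at the generous end of the
SART literature because the downstream detection index needs contrast to
have any chance of working from 12 four-trial segments.

Probe answers use a two-part model: an off-task answer occurs with
probability `b0 * (1 - da) + da * gain(state)` with `b0 = 0.15` and gains
(0, .85, 1.0) by state depth, where `da` is detection ability. Two limiting
cases motivated the form: a perfect detector (`da = 1`) makes no false
off-task reports, and a zero-ability subject answers at a flat rate
independent of state - which makes the expected detection index exactly
zero, the behavior the index's validity argument requires. These two limits
cannot be combined with "a never-wandering subject always answers
'focused'" in one smooth model; the package resolves the tension in favor
of the zero-ability limit, and the degenerate-chain test uses a perfect
detector.

Self-caught reports fire while off-task with per-trial hazard
`0.25 * detection_ability`. The 0.25 scale keeps the expected number of "B"
presses per 240-trial session in the single digits, as observed in this
paradigm; a unit hazard would catch nearly every episode within a trial or
two and produce ~30 reports per session. After any report the chain resets
to on-task, mirroring the instruction to refocus.

Probe scheduling draws inter-probe gaps uniformly from the 30-90 s interval
converted at 2.5 s/trial (12-36 trials), truncating each draw so the
remaining probes still fit before the session ends; 12 probes in 225 trials
require a mean gap under 19 trials, so the schedule is necessarily denser
than an unconstrained uniform draw. Every probe-mode session contains
exactly 12 probes.

## The dot task and meta-d'

Each trial presents a reference cloud of 50 dots against 50 + delta; the
difficulty delta follows the unequal-step staircase (+2 dots after an
error, -1 after a correct answer, doubled to +4/-2 after four consecutive
reversals, reset after eight, floored at one dot, starting at 20). With
sensory noise `sigma_s = 6` dots the staircase tracks the ~2/3-correct
equilibrium of the (2,1) rule; because the reflected random walk spends
time above its equilibrium and early trials are easy, realized session
accuracy sits near 0.72-0.75, inside the [0.60, 0.82] band the tests
assert.

The observer model: signed evidence `x ~ N(s * delta / sigma_s, 1)` drives
the choice by its sign. Confidence is formed from a second read-out
`x2 = x + N(0, sigma_m^2)` - the metacognitive-noise mechanism by which
first-order information is lost - as the observer's posterior probability
of being correct. The observer does not know the trial's delta, so the
posterior is evaluated at the staircase-tracked sensitivity
(`qnorm(2/3)`); confidence is therefore a fixed monotone map of the
choice-signed metacognitive evidence, and with per-subject quantile
binning any such monotone map yields identical type-2 counts. (An observer
who used the true per-trial delta would rate easy trials more extremely,
and under the staircase's difficulty mixture that inflates fitted
meta-d'/d' by ~40% - an artifact, not metacognition.)

`fit_meta_d()` implements the response-conditional maximum-likelihood
measure: meta-d' is the type-1 sensitivity an ideal SDT observer would
need to produce the observed confidence data, with its type-1 criterion
pinned at the empirical relative position c' = c/d'. The multinomial
likelihood of the stimulus x response x bin counts is maximized over
meta-d' and 2(K-1) monotone type-2 criteria (log-spacing parameterization,
`nlminb`, objective tolerance 1e-10, start at meta-d' = d'). K = 4
quantile bins is the default and is exposed as configuration; zero cells
are padded by 1/(2K), and extreme type-1 rates by 1/(2N).

One calibration subtlety deserves emphasis. The naive mapping
`meta-d'/d' = 1/sqrt(1 + sigma_m^2)` - which suggests `sigma_m = 0.80`
should give a ratio of 0.78 - ignores that the *choice* is made from `x`
while confidence comes from `x2`. Conditioning the type-2 distributions on
a response made from a correlated-but-different variable lowers the fitted
ratio further: simulated cohorts at a fixed `sigma_m = 0.80` yield a
grand-mean ratio near 0.70, not 0.78. Under the package's default
*heterogeneous* population (mean 0.80, SD 0.30) and 200-trial sessions the
grand-mean fitted ratio lands near 0.78-0.80, because the ratio is convex
in the noise and short sessions add upward dispersion. The package keeps
the stated noise defaults rather than re-tuning them to force any
particular fitted value.

## The conflict task and the Gratton index

Cell medians (450, 540, 460, 530 ms for the previous-congruency x
congruency cells) imply congruency effects of 90 ms after congruent and
70 ms after incongruent trials; per-cell error rates (1.75, 3.98, 3.47,
3.72%) imply error congruency effects of 2.23 and 0.25 points. A subject's
`control_strength` enters through the interaction contrast
`d = (cs - 20)/4` added as `(-d, +d, +d, -d)`, which sets the subject's
congruency sequence effect to `cs` exactly while leaving the mean
congruency effect and both main effects untouched; `base_speed` shifts all
cells additively. RTs are lognormal with `sdlog = 0.20` around the cell
median, so the median is the natural location summary.

The analysis applies, in order: first-of-block removal, error removal (RT
analysis only), and post-error removal (both analyses, no cross-block
spillover); previous congruency is read from the immediately preceding
*presented* trial even when that trial was itself excluded. Note
4/160 = 2.5% of trials fall to the first-of-block rule. Even-sized cells
use the mean-of-middle median. The 2 x 2 within-subject ANOVA is the
textbook decomposition (each effect tested against its effect-by-subject
interaction); the implementation is closed-form sums of squares, checked in
the tests against `stats::aov` and the paired-t-squared identity for the
interaction.

## Robust outlier reporting

Subject-level tables are screened with squared robust Mahalanobis
distances from an MCD scatter (`MASS::cov.rob`, fixed search seed,
rescaled so the median distance matches the chi-square median) and an
adjusted-quantile threshold: the larger of `qchisq(.975, p)` and the
sample quantile where the empirical tail departs from the chi-square
reference by more than `(0.24 - 0.003 p)/sqrt(n)` (scaled by
`alpha/0.05`; the tail comparison starts at `qchisq(1 - delta, p)`).
Outliers are *reported, never removed*: downstream model fitting keeps all
subjects, which is why the path model uses robust (sandwich) standard
errors instead.

## The path model

`fit_ml_sem()` fits, by plain maximum likelihood (RAM parameterization,
analytic-gradient `nlminb`), the structural model in which a latent
behavioral mind-wandering factor is measured by the four SART indicators
(first loading fixed to 1), control is regressed on metacognitive
efficiency, detection on efficiency, the latent factor on efficiency and
control, and the factor's residual covaries with detection: 16 free
parameters against 28 moments, df = 12. The chi-square is `(n-1) F_ML`;
CFI uses the independence baseline fit by the same estimator (whose MLE is
the diagonal of S); RMSEA uses `sqrt(max(chi2 - df, 0)/(df * n))` - with
`n`, not `n - 1`, which is the arithmetic consistent with the fit
statistics this model family reports. Standard errors are sandwich
estimates (inverse Hessian of the casewise log-likelihood, bread; summed
outer products of casewise scores, butter); naive inverse-Hessian SEs are
returned alongside. No Satorra-Bentler scaling of the test statistic is
applied: point estimates equal those of a robust-ML run, and the fit
indices are computed from the unscaled statistic. Heywood cases are
flagged, not hidden. Missing detection indices lead to listwise deletion.

A robustness note verified in the tests: with iid heavy-tailed errors the
sandwich and naive SEs of *regression paths* coincide asymptotically
(normal-theory SEs for paths are robust to excess kurtosis when errors are
independent of predictors); the inflation shows up on *variance*
parameters, and on paths only under heteroskedasticity. Claims that
"robust SEs are larger" should be read with that in mind.

## What the simulations do and do not show

The package's tests demonstrate internal validity: the estimators recover
what the generators put in, at the study's actual design sizes. Two
negative results are as informative as the recoveries, and both are
properties of the *design*, not bugs:

* **The probe-caught detection index is noisy by construction.** Twelve
  probes yield ~4-6 off-task segments of four trials; a pool of ~20 trials
  contains two or three No-Go trials, so the commission indicator swings
  between 0 and 100%. Simulated cohorts of 200 subjects show a
  detection-index/ground-truth correlation of only ~0.2-0.3 even under
  generous emission contrasts, and ~a quarter of subjects have undefined
  indices (no No-Go trial in the off pool). Real studies using this index
  at n ~ 60 should expect severe attenuation and missingness.
* **Single-indicator paths attenuate.** The efficiency estimate from 200
  trials correlates ~0.5 with true efficiency; the Gratton index from 160
  trials correlates ~0.7 with true control strength. A true
  efficiency-control correlation of 0.29 therefore surfaces as an observed
  standardized path of ~0.10-0.15 in the fitted model, which treats both
  as error-free. Nothing in the Fig-4-style model can disattenuate this;
  a latent formulation with split-half indicators could, and is the
  natural next step.

The generators emulate trial-level structure (staircases, sequential
congruency, Markov attention) but not everything real data contain: no
practice or fatigue trends, no RT autocorrelation beyond the attention
chain, no intentional mind wandering, no motivation differences, and
error RTs are only crudely faster. Passing tests show estimator
correctness under the stated models, not that those models exhaust human
behavior.

## Problem sizes used in the tests

Simulation-based checks run at the sizes that make their claims sharp while
keeping the suite quick: cohorts of 63 for the study-scale checks, 200 for
recovery correlations, 2000 for the path-model recovery, 1000 replicates
for type-I-error and chi-square calibration, and 10^4-10^5 trials for
distributional properties of single generators.
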