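---
title: "Methods: from raw acceleration to fitness-mediated paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw acceleration to fitness-mediated paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the assumptions behind them, the parameters that matter, and
the places where the design was genuinely open and a choice had to be made.

## The problem

Time spent at different physical-activity (PA) intensities, measured by a
hip-worn accelerometer, is associated with cardiometabolic health; so is
cardiorespiratory fitness (CRF). The two are entangled: activity of
sufficient intensity raises fitness, and fitness itself tracks
cardiometabolic risk. The analysis implemented here treats CRF as a
*mediator*: it decomposes the PA–health association into a direct part and
an indirect part flowing through CRF, and it does so while representing PA
not as a single number but as a full intensity spectrum.

Two statistical obstacles shape the design. First, the spectrum variables
(min/day in 22 narrow acceleration bins plus non-wear) are compositional —
they sum to 1440 min — and neighbouring bins are strongly correlated, so
ordinary regression on them is ill-posed. Second, mediation requires a path
model, not a single regression. The package combines partial least squares
(PLS), which handles collinear blocks by extracting a few
covariance-maximising components, with structural path modelling over
standardised construct scores (PLS-SEM in composite form).

## Signal processing

Raw tri-axial acceleration (g) is processed per axis with a 0.29–4 Hz
band-pass before anything else; this removes the gravitational component
(DC) and high-frequency vibration while keeping the frequency content of
human movement. Design choices, since a filter family is a free parameter:

* **Butterworth, total order 4, applied forward–backward**
  (`signal::filtfilt`), i.e. zero phase. Zero-phase filtering avoids
  time-shifting the signal relative to its epoch boundaries; the
  forward–backward pass squares the magnitude response, so corner-frequency
  gain is 0.5 and stop-band attenuation is doubled. `bandpass_gain()`
  evaluates the response analytically and is used both in tests and to
  back-compute amplitudes in the signal simulator.
* **Filter first, then vector magnitude** `sqrt(x² + y² + z²)`, then epoch
  means. Filtering is linear, the magnitude is not, so the order matters;
  filtering each axis first is the standard sequence for this kind of
  processing.
* **Epoch statistic**: mean of the filtered magnitude over 1-s windows,
  reported in mg. Trailing partial epochs are dropped.

Non-wear is detected on 1-minute means of the epoch series because the rule
is stated in minutes: a maximal run of at least 60 min of zero output, where
interruptions totalling at most 2 min below the sedentary threshold do not
break the run, and runs must start and end on a zero minute. Two numerical
tolerances are configurable:

* `zero_tolerance` (default 1 mg): filtered real signals are never exactly
  zero, so "zero output" means a minute mean below this bound.
* `sedentary_threshold` (default 25 mg): the bound for allowance minutes,
  defaulting to the lowest spectrum edge above zero activity. Calibrated
  device-specific values can be substituted via `cutpoint_config()` /
  `signal_config()`.

Days are calendar days (local midnight boundary); partial first/last days
are judged by the same 10-h wear rule as complete days. A person's spectrum
is the mean over valid days (≥ 10 h wear), and a measurement is valid with
≥ 4 valid days — invalid persons are carried with `valid = FALSE` rather
than silently dropped. On complete days the 22 bins plus non-wear partition
1440 min exactly; the test suite asserts this closure to 1e-6.

The coarse cut-point summary (SED/LPA/MPA/VPA/VVPA) is provided for
reference. The calibrated cut-point values belong to a specific device
study and are not hard-coded; the defaults (50, 150, 500, 1000 mg) sit on
spectrum edges so that the coarse classes partition exactly into sums of
spectrum bins, which the tests exploit as a consistency property.

## The composite score

The five risk factors — waist circumference (cm), systolic blood pressure
(mmHg), HbA1c (mmol/mol), TC:HDL ratio and triglycerides (mmol/L) — are
Z-scored over the analysed sample (sample SD, n−1). The two lipid variables
are averaged first so that dyslipidaemia carries the same weight as the
other three components; the final score is the mean of four terms,
reversed, so positive values mean better health. Consequences worth
keeping in mind:

* the score is **sample-specific**: Z-scores are taken on the analysis
  sample after exclusions, so scores are not comparable across cohorts;
* the construction is linear in the component Z-scores: a one-SD
  perturbation of waist moves the score by −1/4, of TC:HDL by −1/8 (the
  lipid halving);
* analysis is complete-case; subjects with any missing component are
  excluded with a message.

Blood pressure is consumed as a single `sbp` number; if multiple readings
exist, average them before building the panel (the package takes the mean
of whatever is supplied).

## The PLS-SEM engine

Constructs are **composites**, not reflective factors: each construct score
is a weighted sum of its indicators, standardised to mean 0, SD 1. The
engine is deliberately small and closed-form — no iterative inner/outer
weighting scheme is needed for the model class it supports:

1. **Stage 1 (measurement).** For the spectrum block, `k` PLS components
   are extracted against the model's ultimate outcome (the unique sink
   construct downstream of the block — CS in the health models, CRF in the
   fitness models). Component 1 weights are proportional to the
   covariances of the standardised indicators with the target; later
   components repeat the construction on the deflated block, so scores are
   orthogonal. The higher-order PA score is the regression-weighted
   combination of the component scores (two-stage approach; the
   repeated-indicators alternative is not implemented). `k = 2` by
   default: one component captures the dominant activity gradient, the
   second the curvature that distinguishes mid-range from extreme
   intensities; additional components mostly fit noise in data of this
   shape. Single-indicator constructs (CRF, CS, sex, age) are the
   standardised indicator itself.
2. **Stage 2 (structural).** Every endogenous construct is regressed by
   OLS on its parents' scores. Because all scores are standardised, path
   coefficients are standardised regression coefficients, and R² per
   endogenous construct is the usual coefficient of determination. The
   test suite checks stage-2 output against hand-written normal-equations
   oracles at 1e-10.
3. **Orientation.** A composite is oriented so it correlates
   non-negatively with its stage-1 target; with regression weighting this
   holds automatically, and bootstrap replicates inherit the convention,
   keeping path signs comparable across replicates.
4. **Interactions.** A moderation term `A:B` is the element-wise product
   of the two standardised scores, re-standardised, entered as an extra
   predictor (product-of-scores approach). A constant factor makes the
   product collinear and is rejected.

Degenerate inputs are handled explicitly: zero-variance indicators are
dropped from blocks with a warning (and reported as 0 in pattern
profiles); a block whose covariance with the target is below 1e-10 in norm
is flagged degenerate and falls back to its dominant variance direction so
downstream code still receives a score; collinear single-indicator
constructs abort with the offending names.

**Bootstrap.** Subject-level resampling with replacement, percentile
intervals (default B = 1000 in `bootstrap_pls()`, 95%). Every derived
quantity — paths, weights, R², pattern values, and the mediation
decomposition — is recomputed per replicate, so intervals for products and
ratios come from the replicate distribution of the product or ratio
itself, not from a delta approximation. Replicates that fail to fit are
dropped and counted; more than 5% failures aborts. Fixed seeds give
byte-identical intervals.

**Pattern diagnostics.** For each spectrum bin, the square-root selectivity
fraction is the absolute correlation between the standardised bin variable
and the PA composite score (its square is the bin's variance fraction
explained by the construct); the multivariate covariance coefficient is the
covariance of the *raw* bin (min/day) with the standardised score, giving
the pattern in original units. The figure-level reading: the pattern is a
joint object — with this collinearity a minute of vigorous activity in the
pattern is always accompanied by several moderate minutes, and bins cannot
be interpreted independently.

## The seven models and the mediation decomposition

`study_model(1..7)` encodes: (1) PA→CS; (2) PA→CS with sex and age into
CS; (3) PA→CRF; (4) PA→CRF with covariates; (5) CRF→CS with covariates,
no PA; (6) the mediation model PA→CRF→CS plus direct PA→CS, covariates
into both CRF and CS; (7) model 6 plus a sex×CRF interaction into CS.
Covariates are wired only into endogenous outcomes, not into PA — the
covariate adjustment controls the outcomes, and the composite itself is
defined by its covariance with the outcome. Sex enters as a 0/1 indicator
(female = 0, male = 1) standardised like any other score; age in years,
standardised.

The decomposition is the product-of-coefficients identity: indirect =
`a·b`, total = `c' + a·b`, proportion mediated = indirect/total. These
identities hold exactly (1e-12) on point estimates by construction, and the
bootstrap recomputes them per replicate. When the total is zero the
proportion is undefined and reported as `NA`; when indirect and total
disagree in sign the proportion leaves [0, 1] and a consistency warning is
raised. The proportion's interval is reported even though it is rarely
printed in applied work, with the caveat that it becomes unstable whenever
the total is near zero.

## The synthetic cohort: what it emulates, what it does not

`simulate_cohort()` generates the *joint* structure the analysis assumes,
with every ground-truth quantity known:

* A standard-normal latent activity score drives CRF
  (`CRF = a·PA + sex/age terms + noise`) and, together with CRF, the
  target composite score (`CS = b·CRF + c'·PA + sex/age terms + noise`),
  all on standardised scales. Default paths are a = 0.387, b = 0.563,
  c' = 0.047 with covariate paths (sex→CRF 0.43, age→CRF −0.20,
  sex→CS −0.30, age→CS −0.12) on the scale the motivating cohort
  reports; residual variances are solved so every latent is unit-variance,
  and infeasible path configurations are rejected at validation.
* The spectrum allocates 1440 min/day across the 22 bins plus non-wear by
  a softmax over baseline log-weights anchored to realistic class means
  (non-wear ≈ 556, sedentary ≈ 690, light ≈ 106, moderate ≈ 86,
  vigorous ≈ 2 min/day), plus a loading profile rising with intensity
  (−0.3 to 1.2 across bins; non-wear −0.1) so higher-intensity bins
  respond more strongly to the latent score, plus smooth AR(1) bin noise
  (ρ = 0.7, SD = 0.08 on the log-weight scale). This produces exact
  compositional closure, lognormal-like sparsity in the vigorous range,
  and the neighbour-versus-distant correlation structure the PLS
  machinery exists to handle. The noise SD reflects that the spectrum is
  a 7-day average, where within-person allocation noise is small relative
  to between-person differences; at this level the bin block retains
  roughly 95% of the latent variance, which is what makes near-unbiased
  path recovery possible at all.
* Risk factors are assigned Z-scores consistent with the target score
  plus idiosyncratic noise (SD 0.4 z-units), then un-standardised with
  realistic means/SDs, so rebuilding the score with `composite_score()`
  is part of the tested path. The structural residual of CS is shrunk by
  exactly the variance of the averaged idiosyncratic noise, so the
  population paths onto the rebuilt score equal the nominal ones rather
  than being attenuated.
* Sex is Bernoulli(0.5), age uniform on 50–64 — the design range of the
  motivating cohort.

What it does **not** emulate: bout structure and circadian patterning of
real activity, device noise and calibration error, skewed or missing
clinical values, non-random non-wear. Passing recovery tests on these
cohorts therefore demonstrates that the estimator chain is consistent and
unbiased *under the assumed structure*, not that the published
dataset-specific values (R² levels, the 0.59 CRF–CS path) would be
reproduced — those depend on the restricted cohort itself.

`simulate_recording()` covers the raw layer: plan segments become tri-axial
sinusoids whose post-filter epoch magnitude equals a prescribed mg level
exactly, because the amplitude is back-computed from the analytic filter
gain and the discrete rectified-sine mean at the chosen sample rate.
Carriers with an integer number of half-cycles per second make every epoch
mean identical; others draw a warning. Zero segments are exact zeros, and a
1 g gravity term rides on the z axis to prove the filter removes it.

## Validation sizes and known limitations

The test suite validates parameter recovery at n = 4000 over 100 seeds
(bias on a, b, c' each bounded by 0.02) and bootstrap behaviour at n = 300
with B = 150 over 150 null datasets; these sizes were chosen so the whole
suite runs comfortably on a single CPU while keeping Monte-Carlo error
well below the asserted bounds.

One limitation deserves emphasis because the test suite deliberately
exposes it. Under a *true null* (activity unrelated to anything), the
stage-1 weights are still chosen to maximise in-sample covariance with the
outcome, so the fitted composite correlates positively with the outcome by
selection alone — an overfitting bias on the order of sqrt(p/n) — and the
percentile bootstrap, which re-centres on the biased estimate, does not
repair it. Coverage of zero for the composite's *direct path into its own
stage-1 target* is therefore far below nominal, and the composite's other
paths are also pulled below nominal to the extent their endpoint correlates
with the target (PA→CRF, with CRF→CS strong, sits noticeably under 95%).
Single-indicator paths, by contrast, show calibrated ~95% coverage,
confirming the bootstrap machinery itself. This is a property of supervised-composite
path modelling in general, not of this implementation; practically, weak
direct paths of a supervised composite should be interpreted with caution,
which is also why the mediation literature treats a small direct path as
"potentially full mediation" rather than evidence of a real direct effect.

Other limitations: the proportion mediated is reported on point estimates
whose ratio form is unstable near zero totals; cross-sectional data cannot
establish temporal precedence, so "mediation" is an associational
decomposition; and the composite score's sample-specific standardisation
means absolute score values carry no meaning across cohorts.
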