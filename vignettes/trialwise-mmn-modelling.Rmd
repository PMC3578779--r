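---
title: "Modelling trial-by-trial MMN amplitudes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling trial-by-trial MMN amplitudes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnlearn)
```

## The problem

The mismatch negativity (MMN) is a negative event-related potential evoked
when a tone violates a learned auditory regularity. In a roving oddball
paradigm the "standard" changes over time: trains of identical tones are
followed by a train of a different frequency, so the first tone of each
train is a *deviant* and the sixth presentation of the same tone is the
*standard* — physically identical stimuli in different contexts. Because
the listener keeps learning the statistics of the sequence, the amplitude
of the MMN changes from deviant to deviant, and those trial-wise changes
carry information about the underlying learning process.

`mmnlearn` treats competing explanations of the MMN as trial-indexed
state-space models: an evolution function updates an internal state from
the sensory input (the tone's log-frequency), and a response function maps
the state to the predicted neural response at each deviant. Thirteen
response models in five families are implemented:

* **Change detection** (M1–M3): a one-trial memory trace; the MMN indexes
  the occurrence (M1, a constant null model), the unsigned size (M2) or
  the signed size (M3) of the change in log-frequency.
* **Adaptation** (M4): seven frequency-selective neural populations whose
  responsiveness decays exponentially with presentations of the preferred
  tone (time constant `tau_a`) and recovers toward 1 otherwise
  (`tau_r`); the MMN tracks the responsiveness of the deviant-driven
  population at stimulus arrival.
* **Prediction error** (M5–M6), **novelty** (M7–M8) and **model
  adjustment** (M9–M13): readouts of a shared free-energy Bayesian
  observer, described next.

## The Bayesian observer

The observer holds a probabilistic mental model of the tone sequence: an
extension of a hidden Markov model in which the hidden state is the tone's
category and the transition probabilities depend on how long the current
tone has been repeated. Its beliefs comprise:

* `nu[j]` — the characteristic log-frequency of each of 10 tone
  categories. The category grid is the minimal contiguous run of
  equal-tempered semitones (A4 = 440 Hz) covering the 500–800 Hz stimulus
  range: B4 (493.88 Hz) up to Ab5 (830.61 Hz).
* `lambda_hat` — the expected train length in tones.
* `B` — the change-conditional transition matrix (zero diagonal; row
  `k` gives the distribution of the next category given a change away
  from `k`).

Each belief carries an effective observation count; the prior strength
`kappa` sets the initial counts (virtual prior observations). Perceptual
uncertainty `sigma2_u` — the variance of the log-frequency representation
— is a fixed property of the observer, never learned.

With point-mass (delta) approximate posteriors, free-energy minimization
reduces to maximum-a-posteriori inference on the expected internal
energy. On each trial the observer:

1. forms a predictive distribution over categories: stay with probability
   `1 - h(r)`, or change with hazard `h(r)` and land according to row
   `B[c_prev, ]`;
2. assigns the tone to the category maximizing
   `log p_pred(j) - (u - nu[j])^2 / (2 sigma2_u)` (ties to the lower
   index);
3. updates the conjugate sufficient statistics: the MAP category's mean
   moves toward the input with weight `1 / (count + 1)`; if a change was
   inferred, the transition row is incremented, `lambda_hat` is updated
   as the count-weighted running mean of the completed train's length,
   and the run length resets.

The response models read, per deviant, quantities computed from the
pre-update prediction and the same-trial update: the precision-weighted
sensory prediction error (M5) and category prediction error (M6, using
the predictive mean and variance of the category means), the surprisal of
the input (M7) and of the category (M8), and signed/absolute belief
adjustments (M9/M12 for `nu`, M10/M13 for `lambda_hat`, M11 for the L1
change in `B`).

### Run-length hazard

The printed account constrains the transition structure — the hazard must
depend on the current run length and on the expected train length — but
not the distributional family. We default to train lengths distributed as
`1 + Poisson(lambda - 1)` (mean `lambda`, hazard increasing with run
length, matching the intuition that a change becomes more likely the
longer a train lasts); a geometric option (`hazard = "geometric"`,
constant hazard `1/lambda`) is provided for sensitivity analyses. The
hazard is clamped to `[1e-12, 1 - 1e-12]` for numerical safety.

### Other observer conventions

* The first tone of a session starts a run but is neither a deviant nor a
  change event: it contributes to category learning only.
* `lambda_hat` learns from completed runs only, since a run's length is
  observable exactly when a change is inferred.
* Categorization ties break toward the lower category index, making
  trajectories fully deterministic.

## Hyperparameters and grids

Subject-level hyperparameters are estimated by evidence-maximizing grid
search; the evidence reported for a model is the maximum over its grid.

* Free-energy models: `sigma2_u` in {5e-4, 2e-3, 8e-3} log-Hz² (SDs of
  roughly 0.4–1.5 semitones; the semitone spacing is ln(2)/12 ≈ 0.058
  log-Hz), `kappa` in {1, 5, 20} virtual observations, `lambda0` in
  {3, 7, 11} tones, bracketing the design's mean train length of 7.3375.
* Adaptation: `tau_a`, `tau_r` on the doubling grid {1, 2, 4, 8, 16,
  32, 50} trials, spanning the plausible range of auditory adaptation
  time scales.

Grid search (rather than continuous optimization) keeps the estimator
deterministic and directly yields the maximized evidence used downstream;
one observer run per grid point serves all nine free-energy models.

## Evidence and model selection

Per electrode, trial-wise amplitudes are modelled by Bayesian linear
regression on the model's z-scored predictor (sample SD, intercept added
for every model except the constant-only M1) with a conjugate
Normal–Inverse-Gamma prior: `beta | sigma^2 ~ N(0, sigma^2 tau^2 I)` and
`1/sigma^2 ~ Gamma(a0, b0)`, defaults `tau = 10`, `a0 = b0 = 1e-3`
(weakly informative on microvolt scales). The coefficient prior scales
with the residual variance so that the marginal likelihood has an exact
multivariate-t closed form; this closed form is the default evidence path,
with prior-sampling Monte-Carlo integration (`log_evidence_mc`,
log-sum-exp stabilized, seeded) retained as the sampling-based
cross-check. Electrodes are conditionally independent given the design,
so subject evidence is the sum of per-electrode evidences.

Group-level inference treats the generating model as a random effect with
Dirichlet-distributed population frequencies, fitted by the standard
variational scheme (responsibilities weighted by `exp(l + digamma(alpha_k)
- digamma(sum(alpha)))`; convergence at `max |delta alpha| < 1e-6`, cap
500 iterations). Exceedance probabilities are Monte-Carlo estimates from
the Dirichlet posterior (default 1e6 draws, seeded). Family-level
inference sets each model's prior count to 1 over its family size — so
the implied prior over families is flat — and aggregates sampled model
frequencies within families. We use direct Dirichlet sampling with
within-family summation rather than Gibbs sampling; both target the same
posterior, and the sampler identity is an implementation detail.

A known property worth stating: for near-equivocal evidence (differences
below about 2 nats at 8 subjects) the variational posterior is
overconfident in the favored model relative to exact integration (we
verified deviations of 0.05–0.09 in expected probability at 0.5–1 nat
differences against both numerical integration and a Gibbs sampler, but
under 0.02 from about 2 nats up). Conclusions that hinge on small
evidence differences should therefore lean on the family-level
comparison, which pools evidence and sharpens differences.

## Synthetic data

The generator produces cohorts with the statistical structure the
analysis assumes, so every stage is testable without EEG recordings.
Defaults mirror the modelled study's conditions: 8 subjects, 1600-tone
sequences, 7 log-spaced frequencies from 500 to 800 Hz, train repetition
counts 0–10 with probabilities 2.5, 2.5, 3.75, 3.75 and then seven times
12.5 percent, and 10 electrodes (standing in for the fronto-central
selection). Amplitudes follow the evidence model exactly: `y_k = X w_k +
eps_k` with the generating model's z-scored design, per-electrode weights
(default intercept −2 µV and slope −1 µV scaled by distinct electrode
gains 0.6–1.4 — negative, encoding the MMN's polarity) and i.i.d.
Gaussian noise (default SD 2 µV). Generating-model defaults are mid-grid
values: observer hyperparameters (2e-3, 5, 7) for free-energy models and
`tau_a = 8`, `tau_r = 16` for adaptation.

Epoch-level simulation adds a deterministic per-frequency standard
template (zero over the baseline), a deviance-specific bump at a
configurable latency (default: Gaussian, center 150 ms, SD 20 ms — the
middle of the 100–200 ms search band) scaled by the trial's amplitude,
and optional white sensor noise. A flat-topped bump option makes the
windowed-mean extraction exactly invertible, which the fidelity tests
exploit. What the generator does *not* emulate: realistic head geometry
and volume conduction, temporally correlated or non-Gaussian EEG noise,
eye-blink and movement artifacts, and overlapping responses from
consecutive tones. Passing tests therefore demonstrate correctness of the
algorithms under the model's own assumptions, not robustness to real EEG
noise.

## Amplitude extraction

The four-step estimation: (1) per deviant, subtract the standard ERP of
the same tone (the average over its sixth-in-a-row presentations); (2)
subtract the mean potential over the 100 ms before tone onset; (3) set
the subject's MMN peak latency to the minimum of the average difference
wave between 100 and 200 ms (ties to the earlier sample); (4) average
each deviance-specific potential over a window centered at that latency.
The window width is configurable with a 50 ms default chosen to match the
duration of a typical MMN deflection. Electrodes are screened by paired
one-sided t-tests of the MMN-window mean against the immediately
preceding and following windows of equal width, at the Šidák-corrected
per-test level `1 - (1 - 0.05)^(1/m)`; the placement of the comparison
windows (immediately adjacent, equal width) is our concrete choice where
only "before and after" is specified. Subjects with no surviving
electrode are flagged rather than dropped. In the full pipeline the
latency is estimated provisionally over all candidates, electrodes are
selected around it, and the final latency and amplitudes use the selected
subset.

## Problem sizes and runtime choices

The test-suite and acceptance runs use the study-sized conditions where
they matter (8 subjects, 1600 tones, 10 electrodes for model and family
recovery; 200,000 trains for the stimulus distribution; 1e6 draws for
Monte-Carlo evidence and exceedance estimates) and smaller sequences
(200–800 tones) for unit-level properties, which keeps the full suite in
the low minutes on a single core while leaving every statistical check at
a scale where its tolerance is meaningful.

## Known limitations

* The observer's update equations are one concrete MAP/conjugate-count
  realization of the free-energy scheme: the hazard family, the precision
  weighting of the category prediction error (we use the predictive
  variance of the category means), and the hyperparameter estimator
  (grid search) are this package's own documented choices, isolated
  behind the trajectory interface so alternatives can be dropped in.
* Evidence assumes independent Gaussian trial noise per electrode;
  spatial correlation between electrodes is not modelled (it inflates
  the effective evidence of all models alike).
* The regression links each model's single computational variable
  linearly to amplitude; waveform-resolved or multivariate response
  models are out of scope.
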