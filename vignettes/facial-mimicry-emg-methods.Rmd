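---
title: "Facial-mimicry EMG: models, preprocessing, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facial-mimicry EMG: models, preprocessing, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the generative model behind the synthetic data, the
preprocessing conventions, the two statistical analyses (frequentist
mixed models and the hierarchical Bayesian asymptotic regression), the
model-comparison machinery, and the design decisions that were
genuinely open.

## The experiment being emulated

Participants in three between-subject arms (amisulpride 400 mg,
naltrexone 50 mg, placebo) watch 5-s videos of faces morphing from
happy to angry or vice versa — 24 videos built from 10 face identities,
each repeated four times, 96 trials in two blocks of 48, with at most
three consecutive trials of the same morph direction. Facial EMG is
recorded at 1200 Hz from the zygomaticus major (ZM) and corrugator
supercilii (CS). Mimicry appears as ZM activation and CS relaxation
while happiness grows on screen, and the reverse for anger. Participants
also press a key when they perceive the expression change, giving one
response time per trial. The pharmacological question is whether either
receptor blockade dampens mimicry; the design's expected outcome under
the motor-copy account is a null.

## Synthetic-data generator

The generator is first-class, tested code: every downstream stage is
validated against its known ground truth.

**Window-level model.** For each trial, muscle and 1-s window
$t = 1..5$, the generating mean of log proportion-of-baseline is the
asymptotic curve
$\mu(t) = a_i - (a_i - b_i)e^{-e^{c_i}(t-1)}$
with per-subject coefficients $a_i, b_i, c_i$ drawn around the
muscle-by-emotion cell values of a `ground_truth()` object, plus a
per-face stimulus intercept and a window-level residual
$\varepsilon \sim N(0, \sigma_{\text{resid}})$.

**Raw-signal construction.** The signal is band-limited Gaussian noise
(passband inside the analysis band-pass) amplitude-modulated by
$\text{baseline}_{\text{RMS}} \cdot e^{\mu(t)}$, where $\mu(t)$
interpolates the window values piecewise-linearly across the five
window centres and the residual is applied as a per-window step so that
window means recover $\mu + \varepsilon$ exactly. Amplitude modulation
(not additive sinusoids) is deliberate: full-wave rectification and
smoothing of modulated noise recovers the envelope up to a common
rectified-noise constant, and that constant cancels in baseline
normalisation — making the preprocessing output analytically
predictable. A 50 Hz sinusoid models line interference; the
pre-stimulus envelope is flat at the tonic baseline RMS; a configurable
fraction of trials (default 2%) has its whole amplitude multiplied by 8,
emulating gross artefacts that the 2-SD rules should catch with
near-certainty.

**Default effect sizes.** Drug effects default to zero — the study's
null. Mimicry asymptotes default to roughly ±0.1 log units (ZM positive
for AngryToHappy, negative for HappyToAngry; CS mirrored), log rates to
−0.5, residual SD to 0.2, baseline RMS to 8 µV and line noise to 1 µV —
magnitudes a facial-EMG practitioner would call typical, chosen once;
the published per-window slopes (≈ ±0.02 log units/window) emerge from
these values. Random-effect SDs default to 0.05 (asymptote), 0.03
(starting value) and 0.10 (log rate). The rate heterogeneity is kept
within the scale of the analysis model's own Half-Normal(0, 0.1)
random-effect prior: a generator emulating this study should draw
subject effects on a scale the study's model deems plausible, otherwise
unabsorbed subject variation leaks into the group-level (drug)
coefficients and biases the nested-model comparison even under the
null. Random-effect correlations are zero in the generator; they are
not a recovery target.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: electrode placement and impedance effects,
cross-talk between muscles, non-stationary baselines (drift, swallowing,
eye-blinks), heavy-tailed artefact distributions, and any correlation
structure among a subject's curve parameters. Recovery results here
demonstrate internal consistency of the pipeline, not robustness to
every physiological nuisance.

## Preprocessing conventions

The chain is band-pass → notch → full-wave rectification → low-pass,
then epoching, baseline normalisation, outlier rejection, and log
binning. Decisions that were open:

* **Filter family/order:** 4th-order Butterworth sections, applied
  zero-phase (forward–backward), standard surface-EMG practice; the
  notch is a 2nd-order IIR biquad with Q = 30 (≈1.7 Hz width at 50 Hz).
* **Sampling-rate profiles:** the full design samples at 1200 Hz with a
  20–400 Hz band-pass. The desk profile (600 Hz) cannot carry a 400 Hz
  edge below Nyquist, so `desk_filter_spec()` moves the upper edge to
  250 Hz and the generator's noise band sits inside it; every other
  stage is unchanged.
* **Outlier rules:** a trial is excluded if its epoch mean or epoch
  peak lies more than 2 SDs from that subject-and-muscle's mean of
  means/peaks, or if the same rules flag its baseline segment. The
  mean and peak rules are combined by union by default; a conjunctive
  reading is available (`rule = "intersection"`) since the verbal
  description of such rules is ambiguous. SDs are computed in a single
  pass including the candidate trial; comparisons are strict
  inequalities. At the desk scale these rules exclude ~18% of epochs,
  close to the study's reported ~20%.
* **Binning:** half-open windows $[w-1, w)$ s after onset, natural log
  of the window-mean proportion, floored at $10^{-4}$ of baseline so a
  silent window cannot produce $-\infty$.

## Frequentist mixed models

Per muscle: `log_emg ~ emotion * drug * time_c` with
`(1 + emotion * time_c | subject) + (1 | stimulus)`; REML, Type-III F
tests with Satterthwaite denominator degrees of freedom (the fractional
df in the study's reporting identify this family). Time is numeric over
windows 1–5 (centred by default): the study's 1-df time tests imply a
linear covariate, not a categorical factor. If the maximal structure
fails to converge, random terms are dropped in a fixed, recorded order:
correlations first, then the interaction slope, then the time slope;
singular fits count as converged, as is standard for these designs.
Simple slopes are per-emotion refits (`log_emg ~ time_c` with
by-subject time slopes), matching the study's follow-up of fitting a
smaller model on one emotion's trials; $z = b/\mathrm{SE}$. The
by-stimulus structure is intercept-only for the EMG models, with an
emotion slope available as a switch; the RT model uses by-subject and
by-stimulus intercepts and emotion slopes.

## Hierarchical Bayesian asymptotic regression

The likelihood unit is the trial × window row (not subject-condition
means). The curve
$y = a - (a-b)e^{-e^{c}(t-1)}$
is parameterised so that $y(1) = b$ exactly — the printed form of the
exponent in the source material is typographically ambiguous, and the
stated property "b is the value at t = 1" resolves the grouping to
$e^{-e^{c}(t-1)}$. The rate is $e^{c}$ (log link), hence always
positive: an approach toward the asymptote from the starting value, in
either direction. Fixed effects: one coefficient of $a$ and $c$ per
drug × muscle × emotion cell, no global intercept; $b$'s fixed effect
is pinned to 0 because the data are proportion of baseline. Random
effects: non-centred per-subject coefficients of $a$, $b$, $c$ for each
muscle × emotion cell, independent across cells and parameters. The
study specifies an LKJ-style maximal structure with correlations; the
correlations are omitted here as a deliberate simplification — the
generator's truth has none, desk-scale data cannot inform a 66-entry
correlation matrix, and the nested-model comparison is unaffected.
Priors follow the study: Normal(0, 0.2) on $a$ cells, Normal(−1, 1) on
$c$ cells, Half-Normal(0, 0.1) on random-effect SDs, Half-Normal(0,
0.5) on the residual SD (priors stated on the SD scale). 4 chains ×
5000 iterations; the stated count is read as including warmup, and the
first 50% is discarded (`warmup_frac` is a switch for the other
reading).

**Sampler.** `sample_posterior()` uses a purpose-built blocked Gibbs
sampler. Given the rate side, the curve is linear in $a$ and $b$, so
the asymptote-side fixed effects, non-centred subject effects, and
their SDs have exact Gaussian or truncated-Gaussian full conditionals.
The rate side uses vectorised Metropolis updates in which the
conditionally Gaussian partner block is analytically marginalised
(rank-1 Sherman–Morrison marginal likelihoods) and then redrawn — a
partially collapsed step that decouples the strong $a$–$c$ posterior
correlation within each cell. Two interweaving move families handle the
remaining slow directions of the hierarchy: exact Gibbs draws along the
likelihood-invariant translation directions (a fixed effect against the
mean of its group's non-centred effects), and Metropolis scale moves on
$(\mathrm{sd}, z)$ columns with the group-move Jacobian
$e^{\eta(1 - J)}$. Metropolis step sizes adapt toward ~0.44 acceptance
during warmup only and are frozen afterwards, so the post-warmup kernel
is fixed and valid. The residual SD is slice-sampled on the log scale.
An independent JAGS backend (`backend = "jags"`) implements the same
model and serves as a cross-check: the test suite compares the two
posteriors parameter by parameter, verifies the joint density against a
term-by-term oracle, and runs a small simulation-based calibration
(rank-uniformity of prior-drawn truths in their posteriors).
Convergence is summarised by classic split-R-hat (each chain halved,
between/within variance ratio) for every parameter, with a pass
threshold of 1.01; a failed threshold warns and attaches the report
rather than erroring. Zero-variance chains yield NaN by construction.

## WAIC, PSIS-LOO, and model weights

The nested family drops the drug factor from $a$, from $c$, or from
both; priors and random structures are untouched. WAIC uses
$\widehat{\mathrm{elpd}} = \sum_i \left[\log \tfrac1S \sum_s
e^{\ell_{is}} - \mathrm{Var}_s(\ell_{is})\right]$ with the log-mean-exp
computed stably and the variance on the $n-1$ denominator; the
criterion is $-2\,\widehat{\mathrm{elpd}}$. PSIS-LOO forms importance
ratios $e^{-\ell_{is}}$, fits a generalised Pareto distribution to the
largest 20% per observation by the Zhang–Stephens profile-likelihood
quantile method, replaces that tail with expected order statistics
(truncated at the raw maximum), and reports the tail-shape $k$ per
observation with a warning above 0.7. Weights are
$w_m = e^{-\Delta_m/2} / \sum_k e^{-\Delta_k/2}$ — the simplest reading
that reproduces a two-column (WAIC, LOO) weight table; stacking or
pseudo-BMA weights are out of scope. The comparison table is emitted in
a fixed row order: Full, asymptote-only, rate-only, no-drug.

## Problem sizes and numerical choices

Simulations run at a desk profile — 12 subjects per arm, 24 trials,
600 Hz — chosen so a complete simulate-to-comparison pass finishes in
minutes on one CPU while keeping every structural feature of the full
design; the full-scale profile (43/96/1200) is available via
`design_config()`. Calibration suites (type-I error of the omnibus drug
test; null RT models) use direct window-level simulation
(`simulate_binned()`) rather than raw-signal synthesis, since filtering
fidelity is established separately by the closure tests; the
nested-model smoke comparison runs at 10 subjects per arm and 16
trials, the smallest size at which the information criteria reliably
separate the null model from the full one. Degenerate inputs are
guarded explicitly: zero-variance subjects error in z-scoring, silent
baselines error in normalisation, fewer than three trials error in
outlier rejection, out-of-support SDs give a log density of $-\infty$,
and the HPDI requires an interior mass.

## Known limitations

Desk-scale posteriors are wide; the asymptote–rate trade-off is only
weakly identified from five windows, so asymptote posterior means can
sit noticeably beyond the generating values while intervals remain
calibrated. The sampler's split-R-hat clears 1.01 at the fixed 4 × 5000
budget, but slowly mixing tails remain in the rate-side SDs. PSIS-LOO
at trial-window granularity treats rows as exchangeable given the
hierarchy — grouped (leave-one-subject-out) cross-validation is not
implemented. Random-effect correlations, artefact-specific preprocessing
(eye-blink, ECG), and alternative link functions are out of scope.
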