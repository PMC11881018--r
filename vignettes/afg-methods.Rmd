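---
title: "Models and methods behind afgtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind afgtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afgtools)
```

This vignette documents the scientific models, the tunable parameters and
the numerical choices in `afgtools`, and states what the synthetic
generators do and do not emulate.

## Stimulus model

All stimuli are sequences of 50 ms *chords*: sets of simultaneous pure
tones, each gated with a 10 ms raised-cosine onset/offset ramp. The *ground*
is a stochastic tone cloud — per chord, an integer number of tones (drawn
uniformly from 9–21, independently per chord) with frequencies i.i.d.
log-uniform over the band (180–7246 Hz for the fixed and dynamic-high
variants, 90–3623 Hz for dynamic-low). The *figure* is either a fixed set of
3 frequencies repeated over 42 chords (temporal coherence), or a harmonic
complex tracking a speech F0 contour (multiples {2,3,4} or {5,10,20,30} of
the per-chord F0, 15–29 chords).

Choices the design left open, and how they were fixed:

* **SNR definition.** SNR in dB is the per-tone amplitude ratio of figure to
  ground components, `20·log10(a_fig / a_ground)`. This is the convention of
  the stochastic figure-ground literature and makes the commanded SNR
  independent of ground density. The mixture is peak-normalized to 0.95
  after summation, so the commanded SNR is a relative quantity.
* **Ground density.** Not fixed by the battery description; 9–21 tones per
  chord is typical of published stochastic figure-ground stimuli and is
  configurable in `stim_config()`.
* **Fixed-figure frequencies.** Drawn log-uniformly from the ground band
  (distinct components), matching the logarithmic scale of the ground.
* **Gap placement.** Uniform over all positions leaving at least 5 figure
  chords on each side, so the gap never truncates the figure onset/offset
  and is always detectable. The ground continues through the gap.
* **Harmonic set of the low variant.** The components are exactly
  {2,3,4}·F0, without the fundamental itself — the literal construction
  rule. Including F0 would change the lowest component from ~150 Hz to
  ~75 Hz and is left to the caller via the `multipliers` argument.
* **Ground "tailoring".** Each interval of a trial receives an independent
  ground draw; no exclusion zone around figure frequencies is applied (none
  is described in the battery design).
* **Sample rate / levels.** 44.1 kHz, 16-bit PCM on disk; no dB HL
  presentation-level modelling (headphone calibration is out of scope).

## Pitch-contour processing

Raw pitch-tracker output is cleaned in four linear steps, mirroring how
sentence contours are prepared for the dynamic figures:

1. `strip_artifacts()` removes frames outside (10, 300) Hz — tracker noise
   below 10 Hz and octave-error spikes above 300 Hz become unvoiced gaps.
2. `conjoin_voiced()` deletes unvoiced gaps and concatenates voiced runs.
   Gaps shorter than `gap_bridge_ms = 50` ms are linearly interpolated
   instead of deleted: isolated dropped frames inside a voiced run are
   tracker misses, not speech pauses. The 50 ms boundary equals one chord.
3. `smooth_contour()` demeans, removes a least-squares linear trend
   (declination), low-pass filters, and restores trend and mean. The
   nominal 2000 Hz cutoff is only meaningful above a 4 kHz sampling rate,
   while contours are sampled at 100 frames/s; the contour is therefore
   upsampled to 44.1 kHz by linear interpolation first, filtered with a
   minimum-order Kaiser FIR (60 dB stopband, zero-phase application with
   odd-reflection padding), and decimated back. At these rates the filter's
   practical effect is confined to the sharp corners introduced by gap
   conjoining — contour-scale features pass unchanged, which the test suite
   verifies against the filter's independently evaluated frequency
   response. After filtering the residual is re-centred so the output mean
   equals the input mean exactly.
4. `chunk_to_chords()` averages consecutive 50 ms windows into per-chord F0
   values. A trailing partial window is dropped below 25 ms (half a chord)
   and averaged otherwise.

`synth_contour()` generates speech-like contours where real ones are not
available: three random-phase sinusoids with modulation rates drawn from
0.5–3 Hz, a downward declination of 10% of the mean over the sentence, a
per-sentence mean spread of 6 Hz s.d., clipped to 74.94–295.44 Hz. The
amplitude budget is solved so the population mean and s.d. match the corpus
statistics (131.59 ± 15.61 Hz); the suite checks the grand mean to ±5 Hz.
These contours emulate the spectral scale and declination of read matrix
sentences, **not** their microprosody, jitter or voicing structure.

## Adaptive tracks and observers

`staircase_step()` implements the transformed up-down rules. Conventions
that the battery description leaves implicit:

* A *reversal* is logged when the direction of SNR movement flips; the first
  movement defines the direction and is not a reversal (standard
  convention). The reversal is recorded at the SNR of the just-completed
  trial.
* The step size drops from 2 to 0.5 dB once the reversal count reaches the
  configured threshold (3 for the gap task, 7 for the pattern task).
* SNR is clamped to [−40, +20] dB; clamping never logs a spurious reversal.
* The stability screen reads "differences of the last six reversals smaller
  than ±5 dB" as *range* (max − min) < 5 dB — the only reading that uses
  all six values symmetrically.

Simulated observers follow a logistic psychometric function
`p = guess + (1 − guess − lapse)·logistic((snr − threshold)/slope)` with
2AFC guess 0.5 and lapse 0.02 by default. Observer difficulty is modelled on
SNR only; the working-memory load of the pattern task is not modelled. The
suite verifies the textbook convergence points: 2-down-1-up tracks average
within 1 dB of the observer's 70.7%-correct SNR, and 1-up-1-down within
1 dB of the 50% point (checked with a `guess = 0` observer, for which that
point exists).

## The synthetic cohort

`simulate_cohort()` draws participants from a linear Gaussian structural
model: a Gaussian copula for uniform age (18–79), age → PTA, age and PTA →
latent AFG ability, and AFG/PTA/age → latent SIN ability, with observed
task scores as noisy indicators on the published scales. Two structural
details matter:

* the two dynamic AFG tasks share a *dynamic-specific* component beyond the
  common AFG factor (they covary by construction), and that component also
  carries a weak path into SIN;
* age has a direct path into WiN in addition to its latent-mediated effects.

Both are needed for the generator to reproduce the published 7-variable
Spearman matrix within ±0.08 at n = 10⁴ — a single-factor mediation cannot
simultaneously match the dynamic tasks' weak age/PTA correlations and their
stronger speech correlations. The path coefficients were calibrated once,
analytically (Gaussian path tracing plus the Pearson-to-Spearman map
ρ_s = (6/π)·asin(ρ/2)), and frozen as `cohort_defaults()`.

WiN is mapped to proportion correct by a monotone logistic squash matched
to the published mean and s.d. (0.673, 0.107); rank statistics are
unaffected. SSQ is generated independently of everything, matching the
observed absence of correlation with the speech scores. A configurable
6.5% of participants are flagged unstable to exercise the exclusion screen.

Because model 3 contains neither the dynamic-specific → SIN path nor the
direct age → WiN path, fitting it to the *default* cohort is mildly
misspecified — deliberately so, since the real data also fit model 3
imperfectly. Parameter-recovery checks therefore use model-consistent
variants (`b_dyn_sin = 0`, and for model 3 also `b_age_win = 0`), where all
generating paths are recovered within ±0.05 at n = 10⁴.

What the cohort does **not** emulate: non-Gaussian score distributions
(the real thresholds are skewed — the analysis pipeline's rank statistics
are insensitive to this, but the SEM operates on covariances), per-frequency
audiograms (PTA is a scalar), floor/ceiling effects in WiN beyond the
logistic squash, and any relationship between the stability flag and the
scores.

## The SEM engine

Models are specified in a small lavaan-like syntax and compiled to a RAM
parameterization: `v = A·v + u`, `u ~ N(0, S)`, implied covariance
`Σ = F(I−A)⁻¹S(I−A)⁻ᵀFᵀ`. Latents are identified by fixing the first
indicator's loading to 1 (fixed-marker scaling); the suite verifies that χ²
is invariant to which indicator is chosen.

Numerical choices:

* **Estimation.** Normal-theory ML discrepancy, minimized by `nlminb`
  (relative tolerance 1e−14) with a BFGS polish; up to five jittered
  restarts if the gradient norm exceeds the convergence flag threshold
  (1e−3; the optimizers themselves run to machine-level tolerance, the flag
  only guards against plateau stops). Start values: loadings from
  regressions on the scaling indicator, paths at 0, residual variances at
  half the sample variances, exogenous moments at their sample values, and
  residual covariances at 0 — the latter keeps the starting Σ positive
  definite.
* **Test statistic.** χ² = (n−1)·F_min with the unbiased sample covariance
  (classic Jöreskog convention); RMSEA uses (n−1). The Satorra–Bentler
  robust correction is not implemented: the synthetic cohorts are
  multivariate normal, where the correction is asymptotically inert.
* **Baseline model.** The independence model's ML solution is the diagonal
  of S (closed form), giving the baseline χ² for CFI/TLI.
* **SRMR** is the root mean square of the standardized covariance residuals
  `(s_ij − σ_ij)/√(s_ii s_jj)` over all p(p+1)/2 unique moments, diagonal
  included.
* **Degenerate cases.** A saturated model (df = 0) reports RMSEA 0 and TLI
  `NA`. Negative variance estimates raise a Heywood warning but are not
  constrained away. Standard errors come from the inverse observed
  information ((n−1)/2 times the numerical Hessian of F).
* **Scale harmonization.** WiN, the only proportion-scored measure, is
  z-scored and multiplied by −1 before fitting so that higher always means
  worse; flipping a variable flips its standardized paths and changes no
  fit index (verified by the suite).
* **Degrees of freedom.** Exogenous variances and covariances are free
  parameters. This yields df = 5 for models 1 and 2 and df = 9 for model 3
  with their 6- and 7-variable covariance matrices — the accounting
  consistent with the fit statistics those models produce.
* **Bootstrap.** RMSEA and path distributions come from refits on 95%
  subsamples drawn without replacement (100 replicates by default);
  confidence intervals are mean ± 1.96·sd of the replicates, 1.96 being the
  conventional normal margin. Non-convergent replicates are excluded and
  counted.
* **Holm family.** The 7-variable correlation matrix has 21 unique pairs;
  the Holm step-down correction therefore uses m = 21, not 49 — counting
  both orders of a symmetric pair would double-correct.

Stepwise regression follows the SPSS defaults the field's reports are based
on: forward entry at partial-F p < 0.05, backward removal at p > 0.10, ties
broken by larger |t| (equivalently, larger absolute partial correlation),
with per-step adjusted R², standardized betas, and collinear candidates
dropped with a warning.

## Problem sizes and determinism

The test suite runs at sizes chosen to make sampling error negligible
relative to the tolerances: 10⁴-row cohorts for SEM recovery (±0.05) and
correlation calibration (±0.08), 200 tracks for staircase convergence
(±1 dB), 1000–3000 draws for distributional checks. Every randomized
artifact — stimuli, tracks, cohorts, bootstrap — is reproducible from a
single master seed via the hierarchical `derive_seed()` fan-out, and the
full battery report replays byte-identically.

## Known limitations

* Observers are stationary and memoryless; sequential effects, lapses of
  attention over a session, and the pattern task's memory load are not
  modelled, so simulated thresholds are cleaner than human ones.
* The SEM engine covers covariance structures with ML estimation only — no
  mean structures, ordinal/WLSMV estimation, or missing-data FIML.
* The contour generator produces smooth, gap-free contours; tests of the
  cleaning pipeline plant artificial gaps and artifacts rather than replay
  real tracker errors.
* Passing calibration checks on the synthetic cohort demonstrates internal
  consistency of the generator and engine, not claims about any human
  dataset.
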