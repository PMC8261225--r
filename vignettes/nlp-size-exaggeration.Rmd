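---
title: "Nonlinear vocal phenomena and apparent body size: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear vocal phenomena and apparent body size: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlpvoice)
```

## The problem

Nonlinear vocal phenomena (NLP) — subharmonics, amplitude modulation and
deterministic chaos — are deviations from regular vocal-fold vibration that
give intense vocalizations (roars, screams, angry yells) their harsh
quality. A long-standing hypothesis in bioacoustics holds that NLP lower
the perceived pitch of a vocalization and thereby exaggerate the apparent
body size of the vocalizer. Testing it requires stimuli that differ *only*
in the presence and type of NLP, and listener experiments analysed at the
trial level with participant- and stimulus-level heterogeneity.

`nlpvoice` implements the full computational chain for such a study:

1. **Parametric resynthesis** of short nonverbal vocalizations in four
   conditions (no NLP, amplitude modulation, subharmonics, chaos) from a
   pitch contour and a spectral envelope, with a fully controlled glottal
   source.
2. **Objective acoustic verification** (pitch tracking, sideband spacing,
   envelope-modulation roughness, spectral centroid).
3. **Deterministic experiment designs** for a rating task, a
   two-alternative forced choice (2AFC) task with ties, and an implicit
   association test (IAT).
4. A **synthetic listener cohort** that simulates responses to all three
   experiments around configurable population effects.
5. **Multilevel inference** that recovers those effects with medians and
   95% intervals.

Because real listener data cannot be collected here, the generative
defaults of the cohort are the study-scale conditions (82 prototypes, 328
stimuli, 301/192/184 participants) with the published contrast estimates
as population effects; the package's acceptance checks are parameter
recovery: simulate the full experiments, re-fit the models, and require
the recovered estimates to fall inside the published intervals.

## Synthesis model

The glottal source is an additive stack of harmonics $k f_0(t)$ up to
Nyquist. Each harmonic's phase is the integral of its instantaneous
frequency; its amplitude is the source rolloff (default −6 dB/octave, the
classic idealized glottal slope) times the spectral envelope gain at
$k f_0(t)$. The envelope is either a smoothed gain curve or a formant set
(Lorentzian resonance profiles over a −40 dB floor). Unvoiced frames are
silent. Harmonics carry fixed quadratic (Schroeder-style) phase offsets,
which keep the crest factor of the stack low so that stimuli normalized to
−20 dBFS RMS stay far from clipping; the offsets are independent of the
number of harmonics synthesized, so enlarging the stack (e.g. when jitter
lowers $f_0$) never changes the phases of existing harmonics.

The three manipulations are injected only inside the prototype's annotated
NLP segments, with raised-cosine edge ramps (5 ms) strictly inside the
segment so that the waveform outside is sample-identical to the no-NLP
version:

* **Amplitude modulation** multiplies the signal by a raised sinusoid
  (configurable shape) with rate $M$ and peak-to-trough depth $d$:
  $e(t) = a + b\cos 2\pi M t$, $a = 1-d/2$, $b = d/2$, rescaled by
  $1/\sqrt{a^2+b^2/2}$ so segment RMS is preserved. This produces the
  textbook sidebands at $kf_0 \pm M$ with amplitude $b/2$ relative to each
  carrier harmonic.
* **Subharmonics** add a second voiced component at $g_0 = f_0/g$,
  $g \in \{2,3,4\}$, filtered through the same envelope with the same
  rolloff and mixed at a relative depth; it fills the spectrum between the
  harmonics of $f_0$ and, at full depth with $g=2$, doubles the period so
  that a pitch tracker (and a listener) hears an octave drop.
* **Chaos** is emulated as strong jitter: inside the segment, $f_0$ is
  multiplied frame-wise by $2^{d/12}$ with $d$ drawn uniformly in
  $\pm$`jitter_depth` semitones (default 6) and redrawn every
  `jitter_period` (default 10 ms, the contour frame step — about three
  pitch periods at typical $f_0$; faster redraws would require sub-frame
  contours). This smears the harmonics toward broadband energy
  concentrated near the formants. Jitter is a purely kinematic emulation;
  no vocal-fold dynamical system is modelled. The jittered phase track
  rejoins the no-NLP track at each segment end (a one-sample
  discontinuity), which is what makes the condition-purity invariant exact
  rather than approximate.

All stochastic draws (jitter, NLP parameters) are reproducible from seeds;
`resynthesize()` derives a deterministic per-prototype jitter seed so
repeated calls agree bit-for-bit.

## Acoustic verification

The pitch tracker is frame-wise normalized autocorrelation (40 ms window,
10 ms hop, 40–1000 Hz search, voicing threshold 0.45). Periodic signals
peak at every multiple of the true period, so the tracker picks the
*shortest* lag whose peak is within 5% of the best peak — the true
repetition rate. A full-depth $g=2$ subharmonic lengthens the true period,
so period doubling is tracked at $f_0/2$; this is the tracker-level
analogue of the perceptual pitch drop.

Roughness is operationalized as the fraction of amplitude-envelope
modulation-spectrum power inside a 30–150 Hz band (config-exposed), the
modulation range perceived as rough; the original study's objective
roughness measure is not printed, so this is the package's own definition,
chosen for transparency and monotonicity in both AM depth and jitter
depth. Sideband spacing is estimated as the dominant envelope-modulation
frequency (for AM these are mathematically identical), with parabolic
interpolation, a 20× in-band prominence requirement, a 2% global
prominence requirement, and an exclusion of ±6% around the known voice
fundamental so that envelope ripple at $f_0$ is not mistaken for
modulation.

## The synthetic cohort

`generate_prototypes()` emulates the stimulus corpus: durations
$\mathcal N(1, 0.5^2)$ s truncated to $[0.3, 1.7]$ (symmetric truncation
keeps the mean at 1 s), log-uniform base $f_0$ of 150–350 Hz (male) or
250–550 Hz (female) — the elevated ranges of intense vocalizations —
smooth random contour shapes (spline through knots with 2-semitone sd),
schwa-like formants scaled by sex, and 1–2 NLP segments covering 40–80% of
the duration. Per-prototype NLP parameters: AM rate
$\mathcal N(90, 20^2)$ Hz truncated to 30–150 Hz, AM and subharmonic
depths uniform on 0.3–0.9, divisor $g$ drawn 2:3:4 with weights
0.5/0.3/0.2, jitter depth uniform on 4–8 semitones. These distributions
are configuration defaults; the original per-stimulus ranges are not
printed and were chosen here as field-typical values.

Rating responses follow a Gaussian latent model per trial:

$$y = \beta_{0,s} + v_{p,s} + \delta_{s,c} + w_{p,c,s} + u_{r,s} + \varepsilon$$

(scale baseline, prototype intercept, condition effect,
prototype-by-condition deviation, participant intercept, residual),
clipped — not rescaled — into the slider bounds, because visual-analogue
sliders truncate. Baselines sit far enough from the bounds that clipping
is rare (< ~2% of trials on the most extreme cells). Pitch is simulated in
semitones and stored as the 62–4300 Hz log-scale slider value; height in
cm on a 128–202 cm slider; the other four scales on 0–100. Prototype
intercepts are correlated across scales (a prototype that sounds low also
sounds dark and large), with the published between-scale correlations
where printed and moderate plausible values elsewhere, projected to the
nearest correlation matrix. Variance components per scale were chosen so
that the simulated inter-rater agreement reproduces the study's pattern —
psychoacoustic scales with mean per-rater r of roughly 0.75–0.85 and ICC
0.4–0.6, ecological scales near 0.55 and ICC about 0.2 — since those
agreement statistics are the only printed constraint on the random-effect
magnitudes (the original model specifications are in unprinted
supplementary material).

The 2AFC simulator draws a latent size difference
$\mathrm{size}(A) - \mathrm{size}(B)$ plus prototype-level deviations and
unit Gaussian noise; $|$difference$| <$ tie threshold yields "similar".
The tie threshold (0.27) makes about 20% of responses ties (the study does
not report a tie rate). The three configured chaos-contrast probability
differences are inverted analytically (closed-form marginal probit +
`uniroot`) into latent condition sizes, so the *marginal* simulated
$\Delta = P(\text{larger}) - P(\text{smaller})$ matches the configured
targets exactly in expectation; the AM and subharmonic sizes follow from
the chaos-vs-AM and chaos-vs-subharmonics targets, which leaves their
contrasts with "none" small — consistent with the study's finding that
those contrasts were indistinguishable from catch-pair noise.

The IAT simulator gives each of six sound pairs (two per NLP type) its own
group of ~30 participants, two blocks of 40 trials: errors are Bernoulli
with a participant intercept (sd 0.5 on the log-odds), baseline error 6%
and a +0.8 log-odds congruency shift (odds ratio ≈ 2.2); response times
are lognormal (median 600 ms, sdlog 0.25, participant sd 0.12) with a
+100 ms additive shift in incongruent blocks. The study prints no IAT
effect magnitudes in its main text, so these are plausible field values
and no acceptance target depends on them.

## Experiment designs

All allocations are pure functions of their inputs and a seed. Rating: per
participant, one randomly chosen psychoacoustic and one ecological scale,
50 stimuli per block, no stimulus repeated within participant. The phrase
"rated 50 stimuli in two blocks" is read as 50 *per block* (100
trials/participant) because only that reading reproduces the reported
~15 ratings per stimulus per scale ($301 \times 50 / (328 \times 3) =
15.3$). 2AFC: 47 experimental pairs sampled without replacement from the
492 enumerated pairs plus 3 catch trials (a random stimulus paired with
itself), randomly interleaved, presentation order randomized within pair.
IAT: participants spread evenly over the six sound pairs, block order
randomized.

## Inference

Each rating scale is fit with a Gaussian multilevel model
(`lme4::lmer`): fixed condition effects, random intercepts for
participants, prototypes and prototype-by-condition cells. Pitch responses
are log-transformed to semitones before modelling so contrasts are in
semitones; height contrasts are in cm, the rest in percentage points.
Three uncertainty backends share one contract (median + central 95%
interval over draws):

* `"wald"` (default): draws from the asymptotic Gaussian distribution of
  the fixed effects. For Gaussian linear mixed models at these sample
  sizes this matches the parametric bootstrap to Monte-Carlo error at a
  small fraction of the cost, which matters for replicate-heavy checks.
* `"bootstrap"`: a genuine parametric bootstrap (simulate from the fitted
  model, refit, default 200 replicates).
* `"mcmc"`: Gibbs sampling via JAGS with weakly informative priors
  (diffuse normals on fixed effects, uniform priors on standard
  deviations).

The backend-equivalence test requires point estimates to agree within 10%
of the effect magnitude on a fixed dataset.

The 2AFC data are fit with a three-category ordinal probit regression on
signed condition indicators, so one latent size per condition drives all
contrasts; the reported quantity is the fitted
$\Delta = P(\text{first larger}) - P(\text{first smaller})$, ignoring
ties, in percent. Intervals come from a cluster bootstrap over
participants (which propagates listener heterogeneity without requiring a
random-effects ordinal fitter). The region of practical equivalence is the
central 95% interval of the same quantity computed for catch pairs of
identical stimuli; contrasts whose interval fails to clear it are flagged
as indistinguishable from noise. IAT errors are fit with a multilevel
logistic model and response times with a multilevel location model, per
sound pair and at population level; intervals that fail to exclude the
null (odds ratio 1, shift 0) are flagged.

Inter-rater agreement follows the study's procedure: each participant's
responses are correlated with the per-stimulus aggregated means
(leave-self-in, which inflates r by roughly $1/\sqrt{n_\text{raters}}$
under independence — a property of the procedure, reproduced rather than
corrected), plus a two-way random-effects absolute-agreement ICC estimated
from crossed variance components, which accommodates the incomplete
rating design.

## Numerical choices and degenerate inputs

Sample rate 16 kHz, mono, 16-bit WAV; RMS target −20 dBFS. Contours use a
fixed 10 ms step; durations snap to the frame grid. `uniroot` tolerance
1e−10 for the 2AFC calibration. Pitch-tracker ties (peaks within 5%)
resolve to the shortest qualifying lag; sub-bin peak positions use
parabolic interpolation. Raters with fewer than 3 trials or zero variance
are excluded from mean-r with a message. Zero-variance/zero-effect
simulations, all-unvoiced contours, silent input, missing catch trials and
single-block IAT data are all handled explicitly (identity outputs, NA
with a warning, or an informative error).

## Problem sizes in the test suite

The packaged checks run the full study-scale design where the quantity
under test demands it (20 replicate rating experiments with 301
participants; 20 replicate 2AFC experiments with 192), and reduced designs
elsewhere: interval calibration uses 50 replicates of a 20-prototype /
60-participant rating experiment (150 nominal-95% intervals), and the
backend-equivalence and null-recovery tests use 12–15 prototypes and
40–60 participants. The AM round-trip check synthesizes 200 stimuli. These
sizes were chosen to make the Monte-Carlo tolerances meaningful while
keeping the default test run quick.

## What the synthetic cohort does and does not show

The simulators reproduce the study's *design* (counts, scales, blocks,
catch trials) and its *reported effect structure* (population contrasts,
agreement pattern, between-scale correlations). Passing recovery tests
therefore demonstrates that the estimation pipeline is unbiased and
correctly calibrated for data of this structure — not that the published
effects are true of human listeners, and not that real rating noise is
Gaussian, clipping-truncated, or free of order and learning effects (none
of which are modelled). Real vocalizations also contain unvoiced/aperiodic
energy and formant dynamics that the fully voiced synthetic prototypes
omit. The synthesis stage is likewise a controlled emulation: chaos as
pure jitter, no frequency jumps (not manipulated in the experiments), no
perceptual loudness model — loudness is simply held constant by RMS
normalization.
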