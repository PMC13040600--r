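---
title: "Tracking emotional-memory trajectories: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking emotional-memory trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific setting

A three-session recall design measures how emotional memories evolve:
participants encode negative and neutral picture memories, then mentally
recall them immediately after encoding, after a night of sleep, and seven
days later, with EEG recorded throughout and the intervening night scored
as a hypnogram. Two questions drive the analysis chain this package
implements:

1. **Neural stability.** Can a classifier trained to separate negative
   from neutral recall at one moment (and in one session) still separate
   them at other moments and sessions? Stable cross-session decodability
   indicates that the brain re-instantiates the same emotion-specific
   representation over the week — the signature of *impaired* emotional
   dissipation; its absence indicates adaptive fading.
2. **Sleep coupling.** Do features of the post-encoding night — especially
   slow-wave sleep (SWS, stage N3) and REM jointly — predict how strongly
   negative memories and their affective charge decay over the week?

Participant-level EEG from such studies is not publicly deposited, so the
package ships a synthetic-data module that generates inputs with exactly
the statistical structure the analyses assume. Every downstream stage is
developed and tested against that generator plus hand-built fixtures and
independent oracles.

## The decoding model

Features at time $t$ are the per-channel voltages of one epoch at that
sample. A linear support-vector machine (L2-regularized hinge loss,
$C = 1$) is trained at $t$ and evaluated at every time $t'$, producing a
train-time × test-time matrix of *balanced* accuracies (mean of per-class
accuracies); chance is 0.5. Within a session, fourfold stratified
cross-validation is repeated 50 times (default), with the majority class
randomly subsampled to balance per repeat. Between sessions there is no
cross-validation — the sessions are independent sets — so the classifier
trains on all retained trials of one session and tests on all retained
trials of the other, averaged over balancing repeats. Feature z-scoring
statistics are always computed on the training fold/session only and
applied to the test data; the test suite verifies that this keeps
signal-free data at chance (0.500 ± 0.02 at the acceptance scale).

Only trials flagged correct on the configured recall measure enter
decoding (`measure = "objective_correct"` in the pipeline), mirroring the
practice of decoding correct-recall trials only.

The optimizer is a LIBLINEAR-style dual coordinate descent written in C++.
Choices the field's reports usually leave open, fixed here and exposed as
configuration: linear kernel with $C = 1$; 20-ms decoding grid by default
(full resolution optional); random-subsampling class balancing; optional
pseudo-trial averaging (`pseudo_trial_size`, default 1 = single trials);
balanced accuracy. None of these is claimed to reproduce any specific
laboratory's unpublished choices.

## Cluster-based permutation inference

Per-cell one-sample $t$ statistics (maps − 0.5), or two-sample pooled
$t$ for group differences, are thresholded at the two-tailed $p < 0.05$
$t$ quantile; suprathreshold cells are clustered by 4-connectivity (no
diagonals — conservative and standard) and scored by mass (sum of $t$ —
sensitive to strong compact effects). The null is the permutation
distribution of the **maximum absolute cluster mass over both signs**,
from random sign flips of per-subject centered maps (one-sample) or group
relabelling preserving sizes (two-sample). Monte-Carlo $p$-values use the
add-one rule and can never be 0; when the exact arrangement count
($2^n$ sign patterns or $\binom{n_A+n_B}{n_A}$ assignments) is within the
permutation budget, the null is enumerated exhaustively instead.

**Design note.** A common toolbox convention tests positive and negative
clusters against sign-matched max-mass nulls, each at full α. The union of
the two tails then exceeds the nominal family-wise rate (approaching 2α).
Because this package treats the empirical family-wise error as a tested
contract (≤ 0.065 at α = 0.05 over 300 null simulations), it uses the
combined max-|mass| null, which controls the two-tailed family-wise rate
at α exactly; the measured rate is 0.03–0.05 across seeds. A related
consequence: swapping the two groups reproduces cluster $p$-values exactly
under exhaustive enumeration, and only up to Monte-Carlo error under
sampling — the test suite asserts each on its own path.

## Sleep metrics and the SWS × REM composite

Hypnograms are 30-s AASM stage codes (W, N1, N2, N3, R) between 0-based
lights-off/lights-on epoch boundaries, with arousal events as
(onset, duration) pairs. For one night:

* TIB = 0.5 · (lights_on − lights_off) min; SOL = 0.5 · epochs to the
  first epoch of *any* sleep stage; TST = 0.5 · non-wake epochs;
* WASO counts **all** wake from sleep onset to lights-on, terminal wake
  included. Conventions differ here; this one is chosen so that
  `TIB = SOL + TST + WASO` holds as an exact identity, which is
  property-tested over random hypnograms.
* SE = 100 · TST / TIB; stage percentages are of TST; the arousal index is
  events per hour of TST.
* The SWS × REM composite is the product of the N3 and REM **proportions
  of TST** (not percentages, not minutes, not normalized quantiles — the
  plain product reading of "SWS × REM"). Its range is [0, 0.25], maximal
  when each stage fills half of sleep. Nights without sleep flag SOL,
  stage percentages, the arousal index, and the composite as `NA`.

## Behavioral scores and correlation statistics

Memory decay = subject-level mean accuracy at post-sleep **minus** at the
7-day delay (positive = forgetting), per emotion; with
`exclude_pass = TRUE`, "pass" responses leave the denominator so errors
reflect only wrong negative/neutral judgments. Affect change = delayed
**minus** post-sleep mean rating (negative arousal change = calming).
Ratings are treated as numeric means here; ordinal mixed models are
deliberately out of scope.

Sleep–behavior screening uses Spearman correlations (average ranks on
ties; two-sided $p$ from the $t$ approximation) with Benjamini–Hochberg
step-up correction **within the family of 9 sleep metrics per outcome and
group** (TST, SE, WASO, N1/N2/N3/REM percentages, arousal index,
SWS × REM). Group comparisons of correlations use Fisher's r-to-z:
$z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)/
\sqrt{1/(n_1-3) + 1/(n_2-3)}$, with Cohen's
$q = \operatorname{atanh} r_1 - \operatorname{atanh} r_2$. Huber robust
regression (IRLS, tuning 1.345, MAD scale, convergence Δβ < 1e−8 or 100
iterations) supports testing whether the composite predicts decay beyond
SWS and REM individually; rank-deficient designs abort naming the
collinear columns. Participant-level ±3 SD trimming is available as a
sensitivity analysis (`trim_sd_subjects()`, `trim_sd` in the pipeline).

## What the generator emulates — and what it does not

Each synthetic trial is
`noise + class_sign · snr · noise_RMS · pattern ⊗ envelope`, where the
spatial `pattern` (unit norm, 64 channels by default) is drawn per session
from a shared/unique Gaussian mixture so that sessions correlate at
`stability_rho` — the single interpretable knob that reproduces the
stable-in-insomnia vs unstable-in-controls dissociation
(defaults `c(HC = 0, ID = 1)`). The envelope is a Hann window over the
effect window (500–3000 ms by default). Noise is per-channel 1/f-power
plus white noise mixed through a random spatial covariance — minimal
realism for EEG without fitting real spectra.

`snr` is an amplitude ratio against noise RMS and is **arbitrary**: no
published effect size exists in µV for emotion decoding during recall.
The defaults (`ID = 0.5`, `HC = 0.02`) were chosen once so that the
insomnia-like group decodes clearly above chance at realistic trial counts
while the control-like group sits at chance, and are not tuned thereafter.
Hypnograms come from a first-order Markov chain over stages at 30-s
resolution (default transition matrix chosen for plausible stage
occupancies — roughly N2-dominant with ~15–25% N3 and REM — and an 8-h
time in bed); arousals arrive as a Poisson process during sleep at
10/h by default. Behavioral outcomes are Bernoulli draws from
group × emotion × session cell logits plus a subject random intercept
(SD 0.5); default logits give near-ceiling recall post-encoding, mild
overnight loss, and a 7-day drop that is much smaller for negative cues in
the insomnia-like group. Ratings use a latent Gaussian with fixed
half-integer thresholds shared across groups (group effects act on latent
means only). In groups with nonzero `sleep_behavior_rho`, the subject's
negative-memory decay latent correlates with the normal scores of their
*realized* SWS × REM at the configured ρ (default HC −0.45, ID 0, the
magnitude of the reported sleep–decay correlations); `decay_effect = 1.2`
scales how strongly that latent moves the delayed-session logit, set so
binomial trial noise does not swamp the latent correlation at
24 cues/emotion.

What the generator does **not** emulate — so a green test does not
establish it: real ERP morphology (P300/LPP shapes), sleep
spindle/slow-oscillation microstructure, REM fragmentation beyond the
arousal index, non-stationary artifacts (the rejection stage is exercised
with hand-built fixtures instead), volume-conduction-realistic topography,
and any ordinal-regression structure in ratings beyond the latent shift.

## Numerical choices and degenerate inputs

* FIR filters are windowed-sinc (Hamming) with MNE-style automatic
  transition bandwidths, applied zero-phase via group-delay compensation
  with odd-reflection padding; the kernel is capped at the signal length
  (short fixtures get a wider transition band). A band-pass kernel has
  exactly zero DC gain by construction. Resampling is integer-factor
  decimation, valid because the pass-band must lie below the target
  Nyquist.
* The last artifact-rejection window is anchored at the epoch end when the
  step does not tile exactly, so coverage is complete; rejection marks
  trials rather than deleting them. Subject exclusion is strict:
  a rejected fraction of exactly 20% is retained.
* Preprocessing records applied steps and refuses out-of-order application
  (e.g. baseline after rejection) unless `force = TRUE`.
* The SVM stops when the maximal projected-gradient violation falls below
  `tol` (1e−3) or after `max_epochs` sweeps; z-scoring guards zero-variance
  features (SD set to 1). Ties in the decision value classify as the
  positive (negative-emotion) class deterministically.
* Epoch windows are half-open `[start, end)` ms with t = 0 at cue onset;
  units are µV end to end (EDF physical dimensions converted on read).
* Cluster $p$-value tie comparisons use a 1e−9 relative tolerance so an
  observed arrangement re-appearing in an exhaustive null counts as a tie
  regardless of floating-point noise.
* All randomness flows from explicit integer seeds through a deterministic
  child-seed derivation (CRC32 of a labelled path, kept below $2^{31}$);
  identical config + seed reproduces every artifact bit-identically, and
  the C++ kernels draw from R's RNG so they obey `set.seed()`.

## Known limitations

ICA-based artifact removal, automatic sleep staging, mixed-effects and
ordinal regression, ERP component analysis, and channel interpolation are
deliberately out of scope. The EDF reader supports the continuous,
single-sampling-rate dialect only. Between-session decoding assumes
identical channel sets and time axes (no montage alignment). The
generator's effect sizes are stated-world choices, not estimates; analyses
of real data should revisit them.
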