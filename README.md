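# emotraj

Tools for tracking how emotional memories — and their neural signatures —
evolve across a week of repeated recall, for researchers studying sleep and
emotional memory in clinical populations (e.g. insomnia disorder vs healthy
sleepers).

The package implements a complete, reproducible analysis chain for a
three-session recall design (post-encoding, post-sleep, 7-day delayed) with
an overnight polysomnography record in between:

1. **Synthetic study generator** — multi-session epoched EEG with an
   emotion-discriminative spatial pattern whose *cross-session stability*
   is a single knob (`stability_rho`), first-order-Markov hypnograms, and
   per-cue behavioral tables whose negative-memory decay can be latently
   coupled to realized sleep architecture. No participant data are needed
   to exercise or test any stage.
2. **Wake-EEG preprocessing** — zero-phase FIR band-pass (0.1–30 Hz) and
   50 Hz notch filtering, integer resampling (500 → 250 Hz),
   common-average re-referencing, pre-stimulus baseline correction, and
   moving-window peak-to-peak artifact rejection (200 ms windows, 100 ms
   step, ±100 µV), with >20%-artifact subject exclusion. Minimal EDF
   read/write is included for continuous recordings.
3. **Temporal-generalization decoding** — per-timepoint binary linear SVM
   (negative vs neutral) with fourfold cross-validation repeated 50 times,
   class balancing by subsampling, and train-fold-only feature z-scoring;
   within- and between-session decoding yields the 3 × 3 session grid of
   train-time × test-time accuracy matrices. Chance is 0.5.
4. **Cluster-based permutation inference** — one-sample (vs chance) and
   two-sample (group difference) tests on time–time accuracy maps:
   pointwise *t* thresholding, 4-connected clusters scored by mass
   (sum of *t*), and a max-|mass| permutation null (sign flips or group
   relabelling; exhaustive enumeration when feasible), default 10,000
   permutations at α = 0.05, two-tailed.
5. **Sleep macrostructure** — TIB, TST, SOL, WASO, SE, stage minutes and
   percentages, arousal index, and the SWS × REM composite (product of the
   N3 and REM proportions of TST) from 30-s AASM hypnograms. The
   conventions guarantee `TIB = SOL + TST + WASO` exactly.
6. **Correlation statistics** — per-subject memory-decay
   (post-sleep − delayed) and affect-change (delayed − post-sleep) scores,
   Spearman correlations with Benjamini–Hochberg FDR within the 9-metric
   family, Fisher r-to-z comparison of independent correlations with
   Cohen's *q*, and Huber robust regression (IRLS, k = 1.345).

A YAML-driven pipeline (`run_pipeline()`) chains all stages with one
mandatory seed and writes a run manifest with checksummed outputs;
identical configs reproduce every artifact bit-identically.

## Worked example

```r
library(emotraj)

cfg <- sim_config(n_subjects_per_group = 4, n_trials_per_condition = 24,
                  n_channels = 16, sfreq = 100, epoch_window = c(-200, 800),
                  effect_window = c(200, 700), seed = 2026)
rec <- simulate_subject_eeg(cfg, "ID01")   # an insomnia-like subject

dcfg <- decoding_config(n_repeats = 5, time_step_ms = 100, seed = 1)
res <- decode_within_session(rec$sessions$post_encoding, dcfg)
round(setNames(diag(res$accuracy), res$times_ms), 2)
#> -200 -100    0  100  200  300  400  500  600  700
#> 0.57 0.41 0.50 0.44 0.68 0.48 0.65 0.71 0.61 0.52
```

Decoding hovers at chance (0.5) before the effect window and rises once the
emotion-specific pattern is active (here peaking at 0.71 at 500 ms; the
"ID-like" default `stability_rho = 1` also makes these patterns transfer
between sessions, which `decode_between_sessions()` measures). Sleep
metrics come straight from the simulated hypnogram:

```r
compute_sleep_metrics(simulate_hypnogram(cfg, "ID01"))
#> <sleep_metrics> TIB 480.0  TST 400.5  SOL 11.5  WASO 68.0  SE 83.4%
#>   min: N1 20.5 N2 202.5 N3 119.5 REM 58.0; arousal idx 7.94/h; SWSxREM 0.0432
```

`SWSxREM 0.0432` is the product of the N3 and REM proportions of total
sleep time — the composite used to relate deep + REM sleep jointly to
overnight memory processing. Comparing a sleep–behavior correlation
between two groups:

```r
fisher_z_compare(-0.45, 32, -0.01, 31)
#> z = -1.79, p = 0.073, Cohen q = -0.47
```

## Command line

```sh
Rscript inst/cli/emotraj.R run          --config analysis.yaml
Rscript inst/cli/emotraj.R simulate     --config sim.yaml --out data/ --seed 7
Rscript inst/cli/emotraj.R sleepmetrics --in hypnograms/ --out metrics.csv
```

See `vignettes/emotion-memory-trajectories.Rmd` for the model, parameter,
and design-choice documentation.
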