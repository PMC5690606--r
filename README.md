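# glassbold

Tools for charting the functional development of visual cortex from
longitudinal block-design BOLD fMRI, built around Glass-pattern stimulation
of striate (V1) and extrastriate (V4, MT-V5) visual areas.

## The scientific problem

Single-neuron properties in primate visual cortex look adult-like within
weeks of birth, yet visual behavior matures over months to years. One way to
probe this mismatch is to track *population-level* signals: does coherent
BOLD activity to structured visual stimuli emerge early (as receptive-field
physiology would suggest) or late (as behavior would suggest), and does it
emerge hierarchically — V1 before extrastriate areas?

The package implements a complete analysis pipeline for this question, plus
a synthetic longitudinal BOLD generator with known ground truth so that
every stage has a parameter-recovery test:

1. **Stimulus/schedule generation** (`glass_spec`, `generate_glass_pattern`,
   `build_palindromic_schedule`, `build_pinwheel_schedule`): Glass-pattern
   dipole fields (concentric, radial, random; static at 1 s refresh or
   dynamic at 33 ms), palindromic block/blank schedules (A-B-C-C-B-A blocks
   of 36–48 s, blanks of 24–36 s), and the 48 s on/off pinwheel localizer.
2. **Synthetic BOLD** (`ground_truth`, `session_config`, `simulate_run`,
   `make_longitudinal_study`): voxel × volume series at TR = 6 s with
   baseline, linear drift, a double-gamma HRF response whose amplitude
   follows a Naka-Rushton curve in age, per-contrast multivoxel
   class-difference structure, and Gaussian (optionally AR(1)) noise.
3. **Preprocessing** (`detrend_run`): per-voxel linear detrending with an
   intensity-adjustment QC summary. No spatial smoothing.
4. **GLM mapping** (`build_design`, `fit_glm`, `threshold_map`,
   `percent_significant`, `onset_regression`): two-predictor OLS GLM
   (baseline + convolved stimulus boxcar), FDR (maps) or within-VOI
   Bonferroni (summaries) thresholding, and the onset-age regression that
   requires four or more consecutive significant sessions.
5. **Spectral SNR** (`spectral_snr`, `voi_snr`): amplitude at the stimulus
   alternation fundamental (FF = 0.625 cycles/min for the pinwheel) divided
   by the mean amplitude at the non-harmonic flankers 0.5 FF and 1.5 FF.
6. **MVPA** (`rank_voxels`, `assemble_patterns`, `chance_level`,
   `crossvalidate`): voxels ranked by pinwheel responsiveness (positive t
   only, truncated at 70), patterns collapsed per epoch with a one-volume
   (6 s) delay, and 8-fold cross-validated linear maximum-margin
   classification against an exact binomial chance model.
7. **Developmental trajectories** (`dprime`, `bootstrap_dprime`,
   `fit_naka_rushton`, `criterion_age`, `bootstrap_trajectory`,
   `compare_crossing_ages`): the sensitivity index

   d' = (mu_acc − 0.5) / sqrt( (sigma_acc² + (p₀.₉₅,ₙ − 0.5)²) / 2 )

   with p₀.₉₅,ₙ the 95% binomial quantile proportion for n patterns;
   1000-sample bootstrap; the constrained Naka-Rushton fit

   d'(A) = d'₀ + d'max · Aⁿ / (A_halfmaxⁿ + Aⁿ),  d'₀ = 0,
   d'max ∈ [0, 12],  n ∈ (0, 4]

   and the age at which the fitted curve exceeds the d' = 2 criterion.
8. **Pipeline** (`study_config`, `run_study`, `analyze_session`): simulate →
   detrend → GLM/SNR → MVPA → trajectory, deterministic under a master seed,
   with CSV/JSON outputs (`write_study`) and a small CLI at
   `inst/cli/glassbold.R`.

## Worked example

```r
library(glassbold)

truth <- ground_truth(
  voi_params = list("V1"    = list(dmax = 6, a_half = 12, n = 2),
                    "V4"    = list(dmax = 6, a_half = 28, n = 2),
                    "MT-V5" = list(dmax = 6, a_half = 28, n = 2)),
  contrast_params = list(
    structured_vs_random = list(dmax = 0, a_half = 20, n = 2)))

cfg <- study_config(ages = c(4, 8, 14, 20, 26, 32, 40, 47), truth = truth,
                    contrasts = c("stimulus_vs_blank", "structured_vs_random"),
                    seed = 11)
res <- run_study(cfg)
res$trajectories[, c("contrast", "voi", "dmax", "a_half", "criterion_age")]
```

Output printed by this exact call (seed 11):

```
              contrast   voi     dmax    a_half criterion_age
1    stimulus_vs_blank    V1 8.935795 12.710235      8.881293
2    stimulus_vs_blank    V4 5.877288 17.899315     15.169173
3    stimulus_vs_blank MT-V5 7.662313 22.492338     17.339782
4 structured_vs_random    V1 0.000000  4.148108            NA
5 structured_vs_random    V4 0.000000  4.196359            NA
6 structured_vs_random MT-V5 0.000000  4.248840            NA
```

Reading it: the estimated V1 half-max age (12.7 mo) recovers the generative
truth (12 mo), the stimulus-vs-blank criterion age is youngest in V1 and
older in both extrastriate areas (hierarchical development), and the
structured-vs-random contrast — generated with zero class signal — never
reaches d' = 2 (`NA` = not reached), reproducing the null form-signal
behavior the generator encodes.

The single-session worked example:

```r
d <- dprime(mu_acc = 1.0, sigma_acc = 0, n = 189)   # ceiling sensitivity
round(d$dprime)          # 12
chance_level(100)$upper  # 0.58
```

## Data formats

Schedules are BIDS-style events TSV (`onset`, `duration`, `trial_type`);
runs are voxel × volume TSV matrices with a VOI label column
(`write_run`/`read_run`); results are CSV/JSON. Ingesting scanner images is
out of scope: runs are expected to be motion-corrected and mask-extracted
upstream (e.g. exported to text from NIfTI with any standard tool).
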