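---
title: "Models and methods: developmental trajectories of visual cortical BOLD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glassbold)
```

# The question and the measurement model

Receptive-field physiology in infant macaque visual cortex looks adult-like
within weeks of birth, while visual behavior matures over one to two years.
`glassbold` implements a population-level assay of this mismatch: track how
reliably multivoxel BOLD patterns discriminate Glass-pattern stimulus
classes as a function of age, separately for V1 and the extrastriate areas
V4 and MT-V5, and summarize each area's trajectory by the age at which a
sensitivity criterion is first exceeded. The package contains both the
analysis chain and a generative model of the data it expects, so every stage
is testable by parameter recovery without access to animal data.

# Stimuli and schedules

Glass patterns are fields of dot pairs (dipoles) sharing an orientation
rule: tangential to the circle through the dipole midpoint (concentric),
aligned with the radius (radial), or independently uniform (random — no
global structure). Defaults follow the experimental configuration: a
30 × 23 deg field, 10 dots/deg², 0.12 deg dots, 0.414 deg dipole
separation, 100% coherence for structured patterns. Static presentation
refreshes the field each second; dynamic presentation every 33 ms, giving a
motion impression without coherent direction.

Design choices the stimulus description leaves open:

* **Dot placement.** Dipole midpoints are uniform over the field; dots may
  overlap and dipoles may protrude past the field edge (clipping is a
  rendering concern). This is the simplest model consistent with random
  positions and keeps separation statistics exact.
* **Random dipoles keep the 0.414 deg separation** and randomize only the
  orientation. Whether the original stimuli preserved the separation for
  random patterns is not stated; we flag rather than resolve the ambiguity
  (a separation change would alter local dot statistics, not the
  orientation-rule contrast the analysis targets).
* **Orientation convention**: degrees counterclockwise from the positive x
  axis, folded mod 180 (dipoles are axial).
* **Coherence** is a per-dipole Bernoulli event, so the realized coherent
  fraction fluctuates with binomial sampling error — matching how a
  coherence sweep would behave physically.

Schedules are palindromic: blocks of 36–48 s in the order A-B-C-C-B-A with
24–36 s blanks between all blocks, runs starting and ending blank. The
pinwheel localizer alternates 48 s on / 48 s off, so its fundamental
frequency is 1/1.6 = 0.625 cycles/min. Schedules serialize as BIDS-style
events TSV; the analysis consumes schedules, never pixels (rendering to PNG
is available but optional).

# The synthetic longitudinal generator

Each voxel's series is

```
baseline + drift·t + amp(age, VOI) · (stimulus boxcar ⊛ HRF)
         + Σ_contrast ±w/2 · (class boxcar ⊛ HRF) + noise
```

sampled at TR = 6 s. The HRF is the canonical double-gamma (response delay
6 s, undershoot delay 16 s, undershoot ratio 1/6, unit dispersions), peak
near 5 s, peak-normalized — the source experiment states a double-gamma
model with a roughly 5 s delay but no parameters, so the community default
is used and is configurable. Noise is white Gaussian by default with an
optional AR(1) coefficient to exercise robustness; the experiment reports no
noise model.

**Ground truth and the mapping constants.** Target discriminability per VOI
and contrast follows the same Naka-Rushton curve the analysis fits
(`d(A) = dmax·Aⁿ/(a_halfⁿ + Aⁿ)`, offset 0). Two constants convert target
discriminability into signal: `amp_per_d` scales the mean stimulus-evoked
amplitude (fraction of baseline per unit d'), `w_per_d` the norm of a
class-difference weight vector drawn once per run from a standard normal.
Their defaults (5e-4 and 0.4) are calibrated analytically, not empirically:
an epoch-averaged pattern over ~7 volumes has noise SD ≈ noise_sd/√7, and a
linear classifier pooling 70 voxels sees separation ≈ amp·√70/(noise_sd/√7)
for the univariate component and ≈ ‖w‖/(noise_sd/√7) for the weight-vector
component. The defaults make that pooled separation approximately the target
d', so the generator delivers the discriminability it promises instead of
inflating it by the √pool-size factor a per-voxel calibration would give.
The true mapping from neural maturation to BOLD amplitude is unknown; this
scaling is a modelling convenience and is documented as such. The
high-contrast pinwheel drives BOLD far more strongly than Glass patterns at
every age, modelled by a ×10 amplitude multiplier (`pinwheel_gain`).

Per-session stimulus-block counts are drawn within the empirical range
32–189 (sessions pair each of six conditions — three pattern classes ×
static/dynamic — twice per palindromic cycle). Ages are post-natal months;
no post-conception correction.

What the generator does **not** emulate: anatomy and cortical folding,
motion, slice structure, EPI artifacts, physiological noise spectra, and
HRF maturation. A green end-to-end test therefore establishes that the
pipeline recovers developmental structure *of the kind modelled*, not that
it is robust to everything real data can do.

# Preprocessing

Per-voxel least-squares linear detrending with the mean re-added
(idempotent, mean-preserving), plus a QC summary of the maximum absolute
correction as a percent of voxel mean and its 95th percentile across voxels.
The upstream experiment detrended "per slice and per voxel"; synthetic data
has no slice structure, so only the per-voxel stage is implemented — a
documented deviation. No spatial smoothing, matching the source pipeline.
Zero-mean voxels get an undefined (NA) adjustment with a warning rather than
a division by zero.

# GLM mapping and the onset regression

The design has two predictors (n volumes × m = 2): a baseline column and
the stimulus boxcar convolved with the HRF. The blank predictor is realized
as the intercept — with m = 2 and a stimulus contrast this is equivalent to
an explicit convolved blank regressor and keeps the design full-rank.
Convolution uses the closed form for boxcars (each epoch contributes
H(t−onset) − H(t−onset−duration), H the running HRF integral), which is
exact, fast, and free of FFT length pathologies.

Inference is ordinary least squares per voxel, two-sided t with n − m
degrees of freedom (the source says "T-test" without sidedness; its maps
are symmetric). Thresholding: Benjamini-Hochberg step-up FDR at q = 0.05
for maps; within-VOI Bonferroni at alpha = 0.05 for the percent-significant
summaries. Both are provided because the source uses FDR for maps and
Bonferroni for the onset figure; no attempt is made to reconcile them.

The onset regression takes the per-session percent-significant series in
age order, qualifies only when ≥ 4 consecutive sessions have significant
voxels, fits a line to all significant sessions from the first of that
streak onward, and reports the abscissa intercept −b₀/b₁ as the onset age.
Non-positive or undefined slopes return an explicit not-qualified result.

# Spectral SNR

Amplitude of the DFT bin nearest the fundamental alternation frequency,
divided by the mean amplitude at 0.5 FF and 1.5 FF (non-harmonic flankers =
stimulus-independent noise estimate); signal present when SNR > 1. No taper
is applied: simulated records hold integer cycle counts, making the FF bin
exact whenever record length is a multiple of 96 s; for ragged real records
the nearest-bin lookup is the documented behavior. The default operates on
VOI-mean series (the aggregation used for per-session quality summaries);
per-voxel application is available.

# MVPA

**Feature selection.** Voxels are ranked within each VOI by the t-value of
the pinwheel GLM — a metric independent of every Glass-pattern contrast —
keeping only positive responders (negative BOLD is excluded throughout) and
truncating at 70 so pool sizes are comparable across VOIs, sessions and
ages. Ties break by ascending voxel index; fewer than 70 positive voxels
retains all of them with a warning; none at all flags the session.

**Pattern assembly.** One pattern per schedule epoch: the mean of the
volumes inside the epoch's boxcar shifted by exactly one volume (6 s, the
volume acquisition time — a deliberately conservative fixed hemodynamic
delay). Epochs of the two classes are paired in temporal order and
unmatched epochs dropped, keeping folds balanced and chance at 0.5. The
total pattern count fed to a classifier is capped at 189 — the top of the
empirical per-session range — so the binomial chance model operates in its
calibrated regime. Contrasts: stimulus vs blank (all Glass epochs against
blanks), dynamic vs static (both structured and random), structured vs
random (static patterns only). A session lacking a class (e.g. no random
dipoles) is dropped for that contrast, with a message, and analysis
continues.

**Classification.** Condition pairs are dealt (seeded) into 8 disjoint
folds covering every pattern exactly once; per fold, a linear
maximum-margin classifier is trained on the remaining pairs and scored on
the held-out patterns. Per-voxel z-scoring is fit on training folds only
(the source is silent on standardization; it is on by default and
toggleable, and the calibration tests pass either way). The classifier is
an L2-regularized squared-hinge primal SVM (C = 1, intercept unpenalized)
solved by damped Newton with the exact active-set Hessian — no SVM library
is required and the solve is deterministic. The session metric is the
accuracy at the full 70-voxel pool; the accuracy-vs-pool-size trace is
computed on request.

**Chance model.** The upper chance boundary is the smallest k with
Binomial(n, 1/2) CDF ≥ 0.95, as a proportion; the symmetric lower boundary
supports below-chance detection. n is the total pattern count used by the
classifier (the source says "number of patterns used in the classifier
training"; whether held-out counts were meant is ambiguous and flagged). A
session is non-significant when mean accuracy + 1 SD fails to exceed the
upper boundary, or the mean falls below the lower boundary.

# Sensitivity index, bootstrap, and trajectories

The sensitivity index standardizes accuracy against its chance
distribution:

d' = (mu_acc − 1/2) / sqrt( (sigma_acc² + (p₀.₉₅,ₙ − 1/2)²) / 2 )

It is zero exactly at chance, increasing in accuracy, decreasing in fold
spread and in chance spread (few patterns → wide chance band → attenuated
d'). At perfect accuracy, zero spread, and the maximum pattern count
(n = 189, chance level 106/189) it evaluates to ≈ 11.6 — the ≈ 12 ceiling
that motivates the asymptote bound below.

The bootstrap resamples the 8 fold accuracies with replacement (B = 1000),
recomputing d' per replicate; its mean stays close to the plug-in value and
its spread reflects fold-to-fold variance.

Trajectories are fit by constrained least squares to the Naka-Rushton
function with offset fixed at 0, asymptote in [0, 12], shape in (0, 4] (to
avoid step-function fits), half-max age positive and otherwise free.
Saturating fits are initialization-sensitive, so 8 starts are used (two
log-spaced half-max ages crossed with shapes 0.5/1/2/4), best residual
wins, each solved by projected quasi-Newton (L-BFGS-B). Sessions flagged
below-chance enter the fit with their computed d' (they are reported, not
censored); a configuration switch can exclude them.

**Criterion age.** The age at which the fitted curve exceeds d' = 2 (the
conservative significance criterion; roughly one SD above chance), obtained
by analytic inversion A = a_half·(c/(dmax−c))^(1/shape). Not reached when
the asymptote does not exceed the criterion. An optional `max_age` treats
crossings older than the oldest session as not reached as well: a crossing
placed beyond the sampled range is pure extrapolation, and in null-signal
simulations every spurious crossing fell there (58+ months for studies
ending at 47). The study pipeline reports both the raw analytic crossing
and the in-range flag.

**Trajectory bootstrap and comparisons.** Each replicate resamples fold
accuracies within every session (sessions paired by replicate index),
recomputes all d' values, refits the curve, and records the criterion age.
The source describes bootstrapping d' and reporting confidence intervals on
crossing ages without spelling out the refit linkage; paired-by-replicate
refitting is the documented choice here, and the pairwise test
(`compare_crossing_ages`) reports the fraction of replicates in which one
area's crossing is not older than another's, treating not-reached as
infinitely old.

# Numerical choices and degenerate inputs

* Binomial quantiles use the exact CDF (`qbinom`), verified against
  exhaustive enumeration for all n ≤ 200.
* FDR uses the step-up rule verified against a brute-force all-subsets
  oracle on small inputs.
* d' is undefined (an error) only when both the fold spread and the chance
  spread are zero, which cannot occur for finite n.
* Degenerate trajectory data (all d' ≤ 0) fit to a zero asymptote and
  report not-reached; flat onset-regression data return not-qualified.
* All randomness flows from explicit seeds; rerunning a study with the same
  configuration is bit-identical.

# Known limitations

* With ~12 noisy sessions (d' noise SD around 0.5), the half-max age of a
  saturating fit is only weakly identified: its median relative error sits
  near 15% even at the global least-squares optimum (verified against a
  dense grid-search oracle), because the asymptote, shape and half-max
  trade off. The criterion age — the quantity the analysis reports — is far
  more stable (median error about 1 month in the same simulations).

* The generator's amplitude scaling is a modelling convenience; absolute
  d' levels in simulation should not be read as predictions for real data.
* Real-data ingestion expects motion-corrected, mask-extracted text
  matrices; there is no image I/O in the package.
* The GLM percent-significant summaries saturate quickly at high SNR, so
  simulated onset regressions are most informative near threshold.
* Bonferroni-within-VOI and FDR answer different questions; the defaults
  follow the convention of each output type and are not reconciled.
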