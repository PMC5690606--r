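#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response delay 6 s, undershoot delay
#' 16 s, unit dispersions, undershoot ratio 1/6), rescaled so the peak equals
#' 1. The peak sits near 5 s, matching the roughly 5 s BOLD lag of
#' block-design responses.
#'
#' @param t Time grid in seconds (t >= 0).
#' @return Numeric vector of responses, peak-normalized to 1.
#' @export
hrf <- function(t) {
  stopifnot(all(t >= 0))
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  # normalize on a fine grid so the scale does not depend on the caller's grid
  tg <- seq(0, 32, by = 0.01)
  peak <- max(stats::dgamma(tg, shape = 6, rate = 1) -
                stats::dgamma(tg, shape = 16, rate = 1) / 6)
  h / peak
}

#' Session configuration for the synthetic BOLD generator
#'
#' @param age Age at scan in post-natal months.
#' @param tr Repetition time in seconds (volume acquisition time).
#' @param n_voxels Voxels per volume of interest (single number or named
#'   vector over `vois`).
#' @param vois Character vector of VOI labels.
#' @param baseline Baseline signal intensity (arbitrary scanner units).
#' @param noise_sd Standard deviation of additive Gaussian noise, same units
#'   as `baseline`.
#' @param drift_range Range (length 2) of the per-voxel linear drift slope in
#'   intensity units per volume; slopes are drawn uniformly in this range.
#' @param ar1 AR(1) coefficient for temporally correlated noise (0 = white).
#' @param seed Integer seed.
#' @return An object of class `session_config`.
#' @export
session_config <- function(age, tr = 6, n_voxels = 80,
                           vois = c("V1", "V4", "MT-V5"),
                           baseline = 100, noise_sd = 1,
                           drift_range = c(-0.005, 0.005),
                           ar1 = 0, seed = NULL) {
  if (tr <= 0) stop("tr must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(n_voxels) == 1) n_voxels <- stats::setNames(rep(n_voxels, length(vois)), vois)
  if (any(n_voxels < 1)) stop("need at least one voxel per VOI", call. = FALSE)
  structure(list(age = age, tr = tr, n_voxels = n_voxels, vois = vois,
                 baseline = baseline, noise_sd = noise_sd,
                 drift_range = drift_range, ar1 = ar1, seed = seed),
            class = "session_config")
}

#' Naka-Rushton ground truth for a developmental simulation
#'
#' Target discriminability follows the saturating curve
#' `d(A) = d0 + dmax * A^n / (a_half^n + A^n)` in age A (months), with d0
#' fixed at 0. Two mapping constants convert target discriminability into
#' signal: `amp_per_d` scales the mean stimulus-evoked amplitude (fraction of
#' baseline per unit d'), and `w_per_d` scales the norm of the class-difference
#' weight vector over voxels (intensity units per unit d'). The defaults give
#' a ~3% peak block response at d' = 6 against 1% noise — a realistic
#' high-field block-design effect size.
#'
#' @param voi_params Named list over VOIs; each element a list with `dmax`,
#'   `a_half` (months) and `n` (shape, in (0, 4]) for the overall
#'   stimulus-evoked response.
#' @param contrast_params Named list over multivoxel contrasts (e.g.
#'   `dynamic_vs_static`, `structured_vs_random`); each element either a list
#'   per VOI or a single list applied to all VOIs, same fields as above.
#'   A `dmax` of 0 encodes a null contrast (no class signal), the generative
#'   analogue of the structured-vs-random null finding.
#' @param amp_per_d Fraction of baseline per unit target d'. The default is
#'   calibrated so that the separation available to a pooled 70-voxel linear
#'   classifier (epoch-averaged patterns, unit noise) approximates the target
#'   discriminability rather than exceeding it by the sqrt-of-pool-size
#'   factor univariate scaling would give.
#' @param w_per_d Class-difference weight-vector norm (intensity units) per
#'   unit target d'; calibrated the same way (the norm is already a pooled
#'   quantity, so it only compensates for epoch averaging of noise).
#' @param pinwheel_gain Multiplier on the stimulus-evoked amplitude for
#'   pinwheel (high-contrast localizer) schedules, which drive BOLD far more
#'   strongly than Glass patterns at every age.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(voi_params, contrast_params = list(),
                         amp_per_d = 0.0005, w_per_d = 0.4,
                         pinwheel_gain = 10) {
  check_nr <- function(p, where) {
    stopifnot(is.list(p))
    if (p$dmax < 0) stop("dmax must be >= 0 in ", where, call. = FALSE)
    if (p$n <= 0 || p$n > 4) stop("shape n must be in (0, 4] in ", where, call. = FALSE)
  }
  for (v in names(voi_params)) check_nr(voi_params[[v]], v)
  structure(list(voi_params = voi_params, contrast_params = contrast_params,
                 amp_per_d = amp_per_d, w_per_d = w_per_d,
                 pinwheel_gain = pinwheel_gain),
            class = "ground_truth")
}

#' Evaluate the Naka-Rushton curve
#'
#' @param age Age in months.
#' @param dmax Asymptotic level.
#' @param a_half Age at half-maximum (months).
#' @param n Shape (slope) parameter.
#' @param d0 Offset (fixed 0 throughout the pipeline).
#' @return d'(age).
#' @export
naka_rushton <- function(age, dmax, a_half, n, d0 = 0) {
  d0 + dmax * age^n / (a_half^n + age^n)
}

truth_for <- function(params, voi) {
  if (!is.null(params[[voi]]) && is.list(params[[voi]]) &&
      !is.null(params[[voi]]$dmax)) params[[voi]] else params
}

# Convolve a 0/1 epoch indicator (defined by onsets/durations) with the HRF
# and sample at volume times. Uses the closed form for boxcar convolution:
# each epoch contributes H(t - onset) - H(t - onset - duration), with H the
# running integral of the HRF (zero for t < 0, saturated past the HRF
# support). O(n_events * n_volumes), no FFT. Peak-normalized to 1.
convolve_boxcar <- function(onsets, durations, n_vol, tr, dt = 0.01) {
  support <- 50  # seconds; the double-gamma response is ~0 beyond this
  tg <- seq(0, support, by = dt)
  Hc <- cumsum(hrf(tg)) * dt
  Hfun <- function(x) {
    x <- pmax(0, pmin(x, support))
    Hc[pmin(length(Hc), floor(x / dt) + 1)]
  }
  tvol <- (0:(n_vol - 1)) * tr
  reg <- numeric(n_vol)
  for (i in seq_along(onsets)) {
    reg <- reg + Hfun(tvol - onsets[i]) - Hfun(tvol - onsets[i] - durations[i])
  }
  reg / max(reg, .Machine$double.eps)
}

#' Simulate one synthetic BOLD run
#'
#' Each voxel's series is baseline + linear drift + an age-dependent
#' stimulus-evoked component (condition boxcar convolved with the HRF) + a
#' class-specific multivoxel component + Gaussian noise (optionally AR(1)).
#' The stimulus-evoked amplitude per VOI is
#' `baseline * amp_per_d * d_target(age)`; each contrast contributes a fixed
#' signed weight vector (norm `w_per_d * d_contrast(age)`, drawn once per run
#' from a standard normal then rescaled) added with opposite sign for the two
#' classes. This creates MVPA-decodable structure that a univariate GLM can
#' miss, while the overall response drives the stimulus-vs-blank contrast.
#'
#' @param config A [session_config()].
#' @param truth A [ground_truth()]; its VOIs must be covered by `config$vois`.
#' @param schedule A `stim_schedule` driving the run.
#' @return A `bold_run`: list with `data` (voxel x volume matrix), `tr`,
#'   `schedule`, `voi` (VOI label per voxel) and `age`.
#' @export
simulate_run <- function(config, truth, schedule) {
  stopifnot(inherits(config, "session_config"), inherits(truth, "ground_truth"))
  if (!all(names(truth$voi_params) %in% config$vois))
    stop("ground truth references a VOI missing from the session config", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  n_vol <- floor(schedule_duration(schedule) / config$tr)
  voi_of <- rep(config$vois, config$n_voxels[config$vois])
  n_vox <- length(voi_of)

  stim <- !(schedule$trial_type %in% c("blank", "pinwheel_off"))
  stim_reg <- convolve_boxcar(schedule$onset[stim], schedule$duration[stim],
                              n_vol, config$tr)

  Y <- matrix(config$baseline, n_vox, n_vol)
  slope <- stats::runif(n_vox, config$drift_range[1], config$drift_range[2])
  Y <- Y + outer(slope, seq_len(n_vol) - 1)

  # overall stimulus-evoked amplitude, per VOI at this age; the high-contrast
  # pinwheel localizer drives BOLD much harder than Glass patterns
  gain_mult <- if (any(schedule$trial_type == "pinwheel_on"))
    (truth$pinwheel_gain %||% 10) else 1
  for (v in config$vois) {
    p <- truth$voi_params[[v]]
    if (is.null(p)) next
    amp <- gain_mult * config$baseline * truth$amp_per_d *
      naka_rushton(config$age, p$dmax, p$a_half, p$n)
    rows <- which(voi_of == v)
    # per-voxel responsiveness profile: positive, mean 1
    gain <- abs(stats::rnorm(length(rows), 1, 0.3))
    Y[rows, ] <- Y[rows, ] + amp * gain %o% stim_reg
  }

  # class-difference structure per contrast
  labels <- unique(schedule$trial_type[stim])
  for (cn in names(truth$contrast_params)) {
    cdef <- contrast_def(cn)
    cls <- condition_classes(labels, cdef)
    if (is.null(cls)) next
    for (v in config$vois) {
      p <- truth_for(truth$contrast_params[[cn]], v)
      wnorm <- truth$w_per_d * naka_rushton(config$age, p$dmax, p$a_half, p$n)
      rows <- which(voi_of == v)
      w <- stats::rnorm(length(rows))
      nw <- sqrt(sum(w^2))
      w <- if (nw > 0) w / nw * wnorm else w
      for (side in c(1, -1)) {
        conds <- if (side == 1) cls$a else cls$b
        ev <- stim & schedule$trial_type %in% conds
        if (!any(ev)) next
        reg <- convolve_boxcar(schedule$onset[ev], schedule$duration[ev],
                               n_vol, config$tr)
        Y[rows, ] <- Y[rows, ] + (side / 2) * w %o% reg
      }
    }
  }

  if (config$noise_sd > 0) {
    eps <- matrix(stats::rnorm(n_vox * n_vol, 0, config$noise_sd), n_vox, n_vol)
    if (config$ar1 != 0) {
      for (k in 2:n_vol) eps[, k] <- config$ar1 * eps[, k - 1] +
          sqrt(1 - config$ar1^2) * eps[, k]
    }
    Y <- Y + eps
  }
  structure(list(data = Y, tr = config$tr, schedule = schedule,
                 voi = voi_of, age = config$age),
            class = "bold_run")
}

#' Generate a longitudinal synthetic study
#'
#' One session per requested age. Each session holds a pinwheel localizer run
#' and a Glass-pattern run whose pattern count (number of stimulus blocks) is
#' drawn within the empirical per-session range 32-189. Conditions cross
#' pattern class (concentric, radial, random) with presentation mode
#' (static, dynamic) in a palindromic block order.
#'
#' @param ages Numeric vector of session ages in months (non-empty).
#' @param truth A [ground_truth()].
#' @param config_template A [session_config()] providing everything but age
#'   and seed; per-session seeds derive from `master_seed`.
#' @param master_seed Integer master seed.
#' @param pattern_range Integer range the per-session stimulus-block count is
#'   drawn from.
#' @param pinwheel_duration Pinwheel localizer duration in seconds.
#' @param conditions Condition labels cycled palindromically.
#' @return A `synth_study`: list with `sessions` (each a list holding `age`,
#'   `glass` and `pinwheel` `bold_run`s, `n_patterns`), `truth`, `master_seed`.
#' @export
make_longitudinal_study <- function(ages, truth,
                                    config_template = session_config(age = NA),
                                    master_seed = 1,
                                    pattern_range = c(32, 189),
                                    pinwheel_duration = 576,
                                    conditions = c("concentric_static",
                                                   "radial_static",
                                                   "random_static",
                                                   "concentric_dynamic",
                                                   "radial_dynamic",
                                                   "random_dynamic")) {
  if (length(ages) == 0) stop("ages must be non-empty", call. = FALSE)
  set.seed(master_seed)
  session_seeds <- sample.int(2^31 - 2, 2 * length(ages))
  per_cycle <- 2 * length(conditions)
  sessions <- vector("list", length(ages))
  for (i in seq_along(ages)) {
    set.seed(session_seeds[2 * i - 1])
    target <- sample(seq(pattern_range[1], pattern_range[2]), 1)
    n_cycles <- max(1, min(floor(pattern_range[2] / per_cycle),
                           max(ceiling(pattern_range[1] / per_cycle),
                               round(target / per_cycle))))
    block_dur <- sample(seq(36, 48, by = 6), 1)
    blank_dur <- sample(seq(24, 36, by = 6), 1)
    sched <- build_palindromic_schedule(conditions, block_dur, blank_dur, n_cycles)
    cfg <- config_template
    cfg$age <- ages[i]
    cfg$seed <- session_seeds[2 * i - 1]
    glass <- simulate_run(cfg, truth, sched)
    pin_cfg <- cfg
    pin_cfg$seed <- session_seeds[2 * i]
    pin <- simulate_run(pin_cfg, truth, build_pinwheel_schedule(pinwheel_duration))
    sessions[[i]] <- list(age = ages[i], glass = glass, pinwheel = pin,
                          n_patterns = n_cycles * per_cycle)
  }
  structure(list(sessions = sessions, truth = truth, master_seed = master_seed),
            class = "synth_study")
}

#' Write a bold_run to plain-text files
#'
#' The voxel x volume matrix goes to a TSV (one row per voxel, with `voi`
#' label in the first column), the schedule to a BIDS-style events TSV.
#'
#' @param run A `bold_run`.
#' @param prefix Path prefix; writes `<prefix>_bold.tsv` and
#'   `<prefix>_events.tsv`.
#' @return Invisibly, the written paths.
#' @export
write_run <- function(run, prefix) {
  df <- data.frame(voi = run$voi, run$data, check.names = FALSE)
  bold_path <- paste0(prefix, "_bold.tsv")
  utils::write.table(df, bold_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ev_path <- paste0(prefix, "_events.tsv")
  write_events(run$schedule, ev_path)
  invisible(c(bold_path, ev_path))
}

#' @rdname write_run
#' @param tr Repetition time of the stored run (not serialized in the TSV).
#' @param age Age in months attached to the restored run.
#' @export
read_run <- function(prefix, tr = 6, age = NA) {
  df <- utils::read.delim(paste0(prefix, "_bold.tsv"), check.names = FALSE)
  sched <- read_events(paste0(prefix, "_events.tsv"))
  structure(list(data = as.matrix(df[, -1, drop = FALSE]), tr = tr,
                 schedule = sched, voi = df$voi, age = age),
            class = "bold_run")
}
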