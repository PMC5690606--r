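#' Analyze one session end-to-end
#'
#' Runs the per-session stages: per-voxel linear detrending, the pinwheel
#' localizer GLM and voxel ranking per VOI, spectral SNR on VOI-mean pinwheel
#' series, the Glass-pattern GLM with within-VOI Bonferroni thresholding
#' (percent significant voxels), and cross-validated MVPA with d' per
#' contrast and VOI.
#'
#' @param session A session from [make_longitudinal_study()] (list with
#'   `age`, `glass`, `pinwheel`).
#' @param contrasts Character vector of contrast names to run.
#' @param pool_size MVPA voxel pool size (default 70).
#' @param alpha Per-VOI Bonferroni alpha for the GLM summary.
#' @param seed Seed for the fold assignment.
#' @return List with `glm` (data frame: voi, pct_significant, any_significant),
#'   `snr` (data frame), `mvpa` (data frame: contrast, voi, mu_acc,
#'   sigma_acc, dprime, below_chance, n, plus fold accuracies as a list
#'   column), `age`.
#' @export
analyze_session <- function(session, contrasts = c("stimulus_vs_blank",
                                                   "dynamic_vs_static",
                                                   "structured_vs_random"),
                            pool_size = 70, alpha = 0.05, seed = NULL) {
  glass <- detrend_run(session$glass)$run
  pin <- detrend_run(session$pinwheel)$run
  vois <- unique(glass$voi)

  pin_design <- build_design(pin$schedule, pin$tr, ncol(pin$data))
  pin_glm <- fit_glm(pin, pin_design)
  rankings <- lapply(stats::setNames(vois, vois), function(v)
    suppressWarnings(rank_voxels(pin_glm, pin$voi == v, truncate = pool_size)))

  snr <- voi_snr(pin, ff_per_min = attr(pin$schedule, "ff_per_min") %||% 0.625)

  glass_design <- build_design(glass$schedule, glass$tr, ncol(glass$data))
  glass_glm <- fit_glm(glass, glass_design)
  glm_rows <- do.call(rbind, lapply(vois, function(v) {
    in_voi <- glass$voi == v
    mask <- threshold_map(glass_glm, "bonferroni_within_voi",
                          level = alpha, voi = in_voi)
    data.frame(voi = v, pct_significant = percent_significant(mask, sum(in_voi)),
               any_significant = any(mask))
  }))

  mvpa_rows <- list()
  for (cn in contrasts) {
    for (v in vois) {
      rk <- rankings[[v]]
      if (rk$flagged) next
      pm <- suppressMessages(assemble_patterns(glass, cn, rk))
      if (is.null(pm)) next
      cv <- tryCatch(
        suppressWarnings(
          crossvalidate(pm, pool_size = min(pool_size, length(rk$voxels)),
                        seed = seed)),
        error = function(e) {
          warning(sprintf("contrast %s dropped for session at %.1f mo: %s",
                          cn, session$age, conditionMessage(e)))
          NULL
        })
      if (is.null(cv)) next
      d <- dprime(cv$mu_acc, cv$sigma_acc, cv$n, cv$below_chance)
      mvpa_rows[[length(mvpa_rows) + 1]] <- data.frame(
        contrast = cn, voi = v, mu_acc = cv$mu_acc, sigma_acc = cv$sigma_acc,
        dprime = d$dprime, below_chance = cv$below_chance, n = cv$n,
        fold_accuracies = I(list(cv$fold_accuracies)))
    }
  }
  list(glm = glm_rows, snr = snr,
       mvpa = do.call(rbind, mvpa_rows), age = session$age)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Study configuration
#'
#' @param ages Session ages in months.
#' @param truth A [ground_truth()] for simulation.
#' @param contrasts Contrast names to analyze.
#' @param vois VOI labels.
#' @param n_voxels Voxels per VOI.
#' @param noise_sd Noise SD (intensity units).
#' @param pool_size MVPA pool size.
#' @param criterion d' criterion for the crossing age.
#' @param B Bootstrap replicates for trajectory CIs (0 disables).
#' @param exclude_below_chance Drop below-chance-flagged sessions from the
#'   trajectory fits (default FALSE: they enter with their computed d').
#' @param seed Master seed.
#' @param outdir Output directory (NULL = no files written).
#' @return A `study_config` list.
#' @export
study_config <- function(ages, truth,
                         contrasts = c("stimulus_vs_blank",
                                       "dynamic_vs_static",
                                       "structured_vs_random"),
                         vois = c("V1", "V4", "MT-V5"), n_voxels = 80,
                         noise_sd = 1, pool_size = 70, criterion = 2,
                         B = 0, exclude_below_chance = FALSE,
                         seed = 1, outdir = NULL) {
  structure(list(ages = ages, truth = truth, contrasts = contrasts,
                 vois = vois, n_voxels = n_voxels, noise_sd = noise_sd,
                 pool_size = pool_size, criterion = criterion, B = B,
                 exclude_below_chance = exclude_below_chance,
                 seed = seed, outdir = outdir),
            class = "study_config")
}

#' Run a complete synthetic study: simulate, analyze, fit trajectories
#'
#' Simulates a longitudinal study from the configured ground truth, analyzes
#' every session ([analyze_session()]), fits the constrained Naka-Rushton
#' trajectory per VOI and contrast with its criterion age (optionally
#' bootstrapped), and runs the onset-age regression on the GLM
#' percent-significant series per VOI. Identical config and seed give
#' identical outputs; per-session failures are logged and skipped.
#'
#' @param config A [study_config()].
#' @return A `study_result`: list with `sessions` (per-session data frames),
#'   `mvpa` (long data frame over sessions), `glm` (long data frame),
#'   `trajectories` (data frame: contrast, voi, dmax, a_half, shape,
#'   criterion_age, ci_lo, ci_hi), `onsets` (data frame per voi),
#'   `config`.
#' @export
run_study <- function(config) {
  template <- session_config(age = NA, n_voxels = config$n_voxels,
                             vois = config$vois, noise_sd = config$noise_sd)
  study <- make_longitudinal_study(config$ages, config$truth, template,
                                   master_seed = config$seed)
  ord <- order(config$ages)
  sessions <- study$sessions[ord]

  analyzed <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    analyzed[[i]] <- tryCatch(
      analyze_session(sessions[[i]], config$contrasts,
                      pool_size = config$pool_size,
                      seed = config$seed + i),
      error = function(e) {
        warning(sprintf("session at %.1f mo failed: %s",
                        sessions[[i]]$age, conditionMessage(e)))
        NULL
      })
  }
  keep <- !vapply(analyzed, is.null, logical(1))
  analyzed <- analyzed[keep]

  mvpa_long <- do.call(rbind, lapply(analyzed, function(a)
    if (!is.null(a$mvpa)) cbind(age = a$age, a$mvpa) else NULL))
  glm_long <- do.call(rbind, lapply(analyzed, function(a)
    cbind(age = a$age, a$glm)))

  traj_rows <- list()
  for (cn in unique(mvpa_long$contrast)) {
    for (v in unique(mvpa_long$voi)) {
      sub <- mvpa_long[mvpa_long$contrast == cn & mvpa_long$voi == v, ]
      if (isTRUE(config$exclude_below_chance)) sub <- sub[!sub$below_chance, ]
      if (nrow(sub) < 4) next
      fit <- fit_naka_rushton(sub$age, sub$dprime)
      ca <- criterion_age(fit, config$criterion)
      ci <- c(NA_real_, NA_real_)
      if (config$B > 0) {
        sess_list <- lapply(seq_len(nrow(sub)), function(i)
          list(age = sub$age[i], fold_accuracies = sub$fold_accuracies[[i]],
               n = sub$n[i]))
        bt <- bootstrap_trajectory(sess_list, B = config$B,
                                   seed = config$seed, criterion = config$criterion)
        ci <- bt$ci95
      }
      traj_rows[[length(traj_rows) + 1]] <- data.frame(
        contrast = cn, voi = v, dmax = fit$dmax, a_half = fit$a_half,
        shape = fit$shape, criterion_age = ca,
        reached_in_range = !is.na(ca) && ca <= max(sub$age),
        ci_lo = ci[1], ci_hi = ci[2])
    }
  }
  trajectories <- do.call(rbind, traj_rows)

  onset_rows <- list()
  for (v in unique(glm_long$voi)) {
    sub <- glm_long[glm_long$voi == v, ]
    sub <- sub[order(sub$age), ]
    reg <- onset_regression(sub$age, sub$pct_significant, sub$any_significant)
    onset_rows[[length(onset_rows) + 1]] <- data.frame(
      voi = v, qualified = reg$qualified,
      onset_age = if (reg$qualified) reg$onset_age else NA_real_,
      slope = if (reg$qualified) reg$slope else NA_real_,
      r_squared = if (reg$qualified) reg$r_squared else NA_real_)
  }
  onsets <- do.call(rbind, onset_rows)

  out <- structure(list(sessions = analyzed, mvpa = mvpa_long, glm = glm_long,
                        trajectories = trajectories, onsets = onsets,
                        config = config),
                   class = "study_result")
  if (!is.null(config$outdir)) write_study(out, config$outdir)
  out
}

#' Write study results as CSV/JSON
#'
#' @param result A `study_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_study <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    df2 <- df
    if ("fold_accuracies" %in% names(df2))
      df2$fold_accuracies <- vapply(df2$fold_accuracies,
                                    function(a) paste(a, collapse = ";"),
                                    character(1))
    utils::write.csv(df2, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result$mvpa, "mvpa_sessions.csv")
  wr(result$glm, "glm_sessions.csv")
  if (!is.null(result$trajectories)) wr(result$trajectories, "trajectories.csv")
  wr(result$onsets, "onset_regressions.csv")
  manifest <- list(package_version = as.character(utils::packageVersion("glassbold")),
                   seed = result$config$seed,
                   ages = result$config$ages,
                   contrasts = result$config$contrasts,
                   generated = "run_study")
  jp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, jp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, jp))
}
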