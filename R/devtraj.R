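#' Sensitivity index from cross-validated accuracy
#'
#' Standardized distance between the mean classification accuracy and its
#' chance distribution:
#' `d' = (mu_acc - 0.5) / sqrt(0.5 * (sigma_acc^2 + (p - 0.5)^2))`
#' where `p` is the upper binomial chance boundary for `n` patterns
#' ([chance_level()]). The chance spread `p - 0.5` shrinks with the pattern
#' count, so sessions with few patterns need larger accuracies for the same
#' d'. The ceiling — perfect accuracy with zero spread at the maximum pattern
#' count of 189 — is about 12.
#'
#' @param mu_acc Mean of the fold accuracies, in \[0, 1\].
#' @param sigma_acc SD of the fold accuracies (>= 0).
#' @param n Pattern count used by the classifier.
#' @param below_chance Optional flag carried through from [crossvalidate()].
#' @return A `sensitivity_index`: list with `dprime`, `mu_acc`, `sigma_acc`,
#'   `chance_spread`, `n`, `significant` (`dprime > 2` and not below chance).
#' @export
dprime <- function(mu_acc, sigma_acc, n, below_chance = FALSE) {
  stopifnot(mu_acc >= 0, mu_acc <= 1, sigma_acc >= 0, n >= 1)
  spread <- chance_level(n)$upper - 0.5
  denom <- sqrt(0.5 * (sigma_acc^2 + spread^2))
  if (denom == 0)
    stop("zero accuracy spread and zero chance spread: d' undefined", call. = FALSE)
  d <- (mu_acc - 0.5) / denom
  structure(list(dprime = d, mu_acc = mu_acc, sigma_acc = sigma_acc,
                 chance_spread = spread, n = n,
                 significant = (d > 2) && !below_chance),
            class = "sensitivity_index")
}

#' Bootstrap the sensitivity index from fold accuracies
#'
#' Each of the B replicates resamples the 8 fold accuracies with replacement
#' and re-evaluates mean, SD and d'. The replicate mean stays close to the
#' plug-in d'; the spread reflects the fold-to-fold variance.
#'
#' @param fold_accuracies The per-fold accuracies from [crossvalidate()].
#' @param n Pattern count (binomial chance n).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Seed for resampling.
#' @return A `bootstrap_dist`: list with `dprime` (B values), `mean`,
#'   `ci95` (percentile interval), `plug_in`, `B`, `seed`.
#' @export
bootstrap_dprime <- function(fold_accuracies, n, B = 1000, seed = NULL) {
  stopifnot(B >= 1)
  if (length(unique(fold_accuracies)) < 2)
    warning("fewer than 2 distinct fold accuracies: degenerate bootstrap")
  if (!is.null(seed)) set.seed(seed)
  k <- length(fold_accuracies)
  spread <- chance_level(n)$upper - 0.5
  ds <- vapply(seq_len(B), function(b) {
    a <- sample(fold_accuracies, k, replace = TRUE)
    (mean(a) - 0.5) / sqrt(0.5 * (stats::sd(a)^2 + spread^2))
  }, numeric(1))
  plug <- dprime(mean(fold_accuracies), stats::sd(fold_accuracies), n)$dprime
  structure(list(dprime = ds, mean = mean(ds),
                 ci95 = stats::quantile(ds, c(0.025, 0.975), names = FALSE),
                 plug_in = plug, B = B, seed = seed),
            class = "bootstrap_dist")
}

#' Constrained Naka-Rushton fit of d' against age
#'
#' Least-squares fit of `d'(A) = d0 + dmax * A^n / (a_half^n + A^n)` with the
#' offset fixed at `d0 = 0`, the asymptote restricted to \[0, ceiling\]
#' (ceiling 12, the d' attainable at perfect accuracy), the shape `n` kept in
#' (0, 4\] to avoid step-function fits, and `a_half` unrestricted (positive).
#' Saturating fits are initialization-sensitive, so a multi-start is used:
#' a log-spaced a_half grid crossed with shapes \{0.5, 1, 2, 4\}, best
#' residual wins (L-BFGS-B within bounds).
#'
#' @param ages Session ages in months (>= 4 points).
#' @param dp d' values, one per session.
#' @param ceiling Upper bound for dmax (default 12).
#' @param shape_max Upper bound for the shape parameter (default 4).
#' @return A `naka_rushton_fit`: list with `dmax`, `a_half`, `shape`, `d0`
#'   (0), `rss`, `ages`, `dp`, `convergence`.
#' @export
fit_naka_rushton <- function(ages, dp, ceiling = 12, shape_max = 4) {
  stopifnot(length(ages) == length(dp))
  if (length(ages) < 4) stop("need at least 4 (age, d') points", call. = FALSE)
  rss_fun <- function(par) {
    pred <- naka_rushton(ages, par[1], par[2], par[3])
    sum((dp - pred)^2)
  }
  lower <- c(0, 1e-3, 1e-3)
  upper <- c(ceiling, Inf, shape_max)
  a_grid <- exp(seq(log(max(min(ages), 1)), log(max(ages) * 2), length.out = 2))
  starts <- expand.grid(dmax = max(max(dp), 0.5),
                        a_half = a_grid, shape = c(0.5, 1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), rss_fun, method = "L-BFGS-B",
                   lower = lower, upper = pmin(upper, c(ceiling, 1e6, shape_max)),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  structure(list(dmax = best$par[1], a_half = best$par[2],
                 shape = best$par[3], d0 = 0, rss = best$value,
                 ages = ages, dp = dp, convergence = best$convergence),
            class = "naka_rushton_fit")
}

#' Criterion age: when the fitted trajectory exceeds a d' criterion
#'
#' Analytic inversion `A = a_half * (c / (dmax - c))^(1/shape)` with
#' `c = criterion - d0`. Not reached when the asymptote does not exceed the
#' criterion (including degenerate flat fits).
#'
#' @param fit A `naka_rushton_fit`.
#' @param criterion The d' criterion (default 2, slightly stricter than one
#'   SD above chance).
#' @param max_age When supplied, a crossing older than `max_age` (typically
#'   the oldest session studied) also counts as not reached: the fitted
#'   trajectory remains below the criterion over the studied range, and the
#'   analytic crossing is pure extrapolation.
#' @return Age in months, or `NA_real_` when the criterion is never reached.
#' @export
criterion_age <- function(fit, criterion = 2, max_age = NULL) {
  cc <- criterion - fit$d0
  if (fit$shape <= 0 || fit$dmax <= cc) return(NA_real_)
  age <- fit$a_half * (cc / (fit$dmax - cc))^(1 / fit$shape)
  if (!is.null(max_age) && age > max_age) return(NA_real_)
  age
}

#' Bootstrap the developmental trajectory and its criterion age
#'
#' For every replicate, each session's fold accuracies are resampled with
#' replacement (sessions paired by replicate index), d' is recomputed per
#' session, the Naka-Rushton curve refit, and the criterion age recorded.
#' The resulting criterion-age distribution supports confidence intervals
#' and pairwise comparisons between areas or contrasts.
#'
#' @param sessions List of per-session lists, each with `age`,
#'   `fold_accuracies` and `n` (pattern count).
#' @param B Number of replicates (default 1000).
#' @param seed Seed.
#' @param criterion d' criterion (default 2).
#' @param ... Passed to [fit_naka_rushton()].
#' @return A `trajectory_bootstrap`: list with `criterion_ages` (B values,
#'   `NA` = not reached), `ci95` (of the reached replicates), `point_fit`,
#'   `point_age`, `B`, `seed`.
#' @export
bootstrap_trajectory <- function(sessions, B = 1000, seed = NULL,
                                 criterion = 2, ...) {
  if (!is.null(seed)) set.seed(seed)
  ages <- vapply(sessions, `[[`, numeric(1), "age")
  spread <- vapply(sessions, function(s) chance_level(s$n)$upper - 0.5,
                   numeric(1))
  point_dp <- vapply(sessions, function(s)
    dprime(mean(s$fold_accuracies), stats::sd(s$fold_accuracies), s$n)$dprime,
    numeric(1))
  point_fit <- fit_naka_rushton(ages, point_dp, ...)
  crit_ages <- vapply(seq_len(B), function(b) {
    dp <- vapply(seq_along(sessions), function(i) {
      a <- sample(sessions[[i]]$fold_accuracies,
                  length(sessions[[i]]$fold_accuracies), replace = TRUE)
      (mean(a) - 0.5) / sqrt(0.5 * (stats::sd(a)^2 + spread[i]^2))
    }, numeric(1))
    criterion_age(fit_naka_rushton(ages, dp, ...), criterion)
  }, numeric(1))
  reached <- crit_ages[!is.na(crit_ages)]
  structure(list(criterion_ages = crit_ages,
                 ci95 = if (length(reached) >= 2)
                   stats::quantile(reached, c(0.025, 0.975), names = FALSE)
                 else c(NA_real_, NA_real_),
                 point_fit = point_fit,
                 point_age = criterion_age(point_fit, criterion),
                 B = B, seed = seed),
            class = "trajectory_bootstrap")
}

#' One-sided bootstrap comparison of criterion ages
#'
#' Tests the hypothesis that area/contrast A reaches the criterion *older*
#' than B: p is the fraction of paired replicates with `age_A <= age_B`.
#' Replicates where the criterion is not reached count as infinitely old.
#'
#' @param dist_a,dist_b `trajectory_bootstrap` results (same B, paired by
#'   replicate index).
#' @return One-sided p-value.
#' @export
compare_crossing_ages <- function(dist_a, dist_b) {
  a <- dist_a$criterion_ages
  b <- dist_b$criterion_ages
  if (length(a) == 0 || length(b) == 0) stop("empty distributions", call. = FALSE)
  if (length(a) != length(b))
    stop("distributions must come from the same B", call. = FALSE)
  a[is.na(a)] <- Inf
  b[is.na(b)] <- Inf
  mean(a <= b)
}
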