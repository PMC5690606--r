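#' Build a two-predictor GLM design matrix
#'
#' Column 1 is the baseline (intercept, modelling the blank level); column 2
#' is the stimulus predictor: a 0/1 boxcar over all stimulus epochs convolved
#' with the double-gamma HRF and sampled at the TR. With two predictors and a
#' stimulus contrast this is equivalent to an explicit blank regressor.
#'
#' @param schedule A `stim_schedule`.
#' @param tr Repetition time in seconds.
#' @param n_vol Number of volumes; defaults to `floor(duration / tr)`.
#' @return An n_vol x 2 matrix with columns `baseline`, `stimulus`.
#' @export
build_design <- function(schedule, tr, n_vol = NULL) {
  if (schedule_duration(schedule) < 2 * tr)
    stop("schedule must span at least two volumes", call. = FALSE)
  if (is.null(n_vol)) n_vol <- floor(schedule_duration(schedule) / tr)
  stim <- !(schedule$trial_type %in% c("blank", "pinwheel_off"))
  if (!any(stim)) stop("schedule contains no stimulus events", call. = FALSE)
  pred <- convolve_boxcar(schedule$onset[stim], schedule$duration[stim], n_vol, tr)
  X <- cbind(baseline = 1, stimulus = pred)
  X
}

#' Fit a voxelwise ordinary-least-squares GLM
#'
#' Per voxel: beta = (X'X)^-1 X'y, t = c'beta / se(c'beta), two-sided p from
#' Student's t with n - m degrees of freedom. Fully vectorized over voxels.
#'
#' @param run A `bold_run` (or a voxel x volume matrix).
#' @param design Design matrix from [build_design()].
#' @param contrast Contrast weight vector (default tests the stimulus beta).
#' @return A `glm_result`: list with `beta` (voxels x predictors), `t`, `p`,
#'   `df`, `contrast`.
#' @export
fit_glm <- function(run, design, contrast = c(0, 1)) {
  Y <- if (inherits(run, "bold_run")) run$data else run
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  stopifnot(ncol(Y) == nrow(design))
  if (qr(design)$rank < ncol(design))
    stop("design matrix is rank-deficient", call. = FALSE)
  XtX_inv <- solve(crossprod(design))
  B <- Y %*% design %*% XtX_inv            # voxels x m betas
  resid <- Y - B %*% t(design)
  df <- nrow(design) - ncol(design)
  s2 <- rowSums(resid^2) / df
  cvar <- drop(t(contrast) %*% XtX_inv %*% contrast)
  tval <- drop(B %*% contrast) / sqrt(s2 * cvar)
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(beta = B, t = tval, p = pval, df = df, contrast = contrast),
            class = "glm_result")
}

#' Threshold a statistical map
#'
#' `fdr` applies the Benjamini-Hochberg step-up procedure at rate `level`
#' (the map-making default); `bonferroni_within_voi` divides alpha by the
#' number of voxels in the VOI (the onset-summary default).
#'
#' @param result A `glm_result` (or a numeric vector of p-values).
#' @param method `"fdr"` or `"bonferroni_within_voi"`.
#' @param level q for FDR, alpha for Bonferroni (default 0.05).
#' @param voi Indices or logical mask defining the VOI; required for
#'   Bonferroni, and restricts FDR to the VOI when supplied.
#' @return Logical significance mask over the (VOI-restricted) voxels.
#' @export
threshold_map <- function(result, method = c("fdr", "bonferroni_within_voi"),
                          level = 0.05, voi = NULL) {
  method <- match.arg(method)
  p <- if (inherits(result, "glm_result")) result$p else result
  if (!is.null(voi)) p <- p[voi]
  if (anyNA(p)) stop("p-values contain NA", call. = FALSE)
  if (method == "fdr") {
    stats::p.adjust(p, method = "BH") <= level
  } else {
    p <= level / length(p)
  }
}

#' Percentage of VOI voxels in a significance mask
#'
#' @param mask Logical vector over the VOI's voxels (or indices into `voi`).
#' @param voi The VOI voxel set (any vector; only its length is used) or its
#'   size.
#' @return 100 * |mask| / |voi|.
#' @export
percent_significant <- function(mask, voi) {
  n_voi <- if (length(voi) == 1 && is.numeric(voi)) voi else length(voi)
  if (n_voi == 0) stop("empty VOI", call. = FALSE)
  100 * sum(mask) / n_voi
}

#' Onset-age regression over longitudinal percent-significant values
#'
#' Qualifies only when at least `min_consecutive` consecutive sessions (in
#' age order) have significant voxels; the line is then fit, minimizing
#' squared error, to all significant sessions from the first of that streak
#' onward. The age at which the line crosses zero (abscissa intercept,
#' `-intercept/slope`) estimates when significant voxels start to appear.
#'
#' @param ages Session ages in months, sorted ascending.
#' @param pct Percent significant voxels per session.
#' @param significant Logical: session has a non-empty significance mask.
#' @param min_consecutive Streak length required to qualify (default 4).
#' @return An `onset_regression`: list with `qualified` (logical), and when
#'   qualified `slope`, `intercept`, `r_squared`, `onset_age` (months),
#'   `sessions_used` (indices). Degenerate (non-positive slope) fits return
#'   `qualified = FALSE` with `reason`.
#' @export
onset_regression <- function(ages, pct, significant, min_consecutive = 4) {
  stopifnot(length(ages) == length(pct), length(pct) == length(significant))
  if (is.unsorted(ages)) stop("sessions must be sorted by age", call. = FALSE)
  r <- rle(significant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= min_consecutive)
  if (length(ok) == 0)
    return(structure(list(qualified = FALSE, reason = "fewer than four consecutive significant sessions"),
                     class = "onset_regression"))
  first <- starts[ok[1]]
  use <- which(significant & seq_along(ages) >= first)
  fit <- stats::lm(pct[use] ~ ages[use])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    return(structure(list(qualified = FALSE, reason = "non-positive or undefined slope"),
                     class = "onset_regression"))
  structure(list(qualified = TRUE, slope = slope, intercept = intercept,
                 r_squared = summary(fit)$r.squared,
                 onset_age = -intercept / slope, sessions_used = use),
            class = "onset_regression")
}
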