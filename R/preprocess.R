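#' Per-voxel linear detrending with intensity-adjustment QC
#'
#' Removes the least-squares linear trend from every voxel's time series and
#' re-adds the voxel mean, so means are preserved and the operation is
#' idempotent. The QC summary reports, per voxel, the maximum absolute
#' correction as a percentage of the voxel mean, and the 95th percentile of
#' those percentages across voxels — a minimal-preprocessing quality check
#' (spatial smoothing is deliberately not applied).
#'
#' @param run A `bold_run` with at least 3 volumes.
#' @return A list with `run` (detrended `bold_run`) and `qc` (class
#'   `qc_summary`: `percent_adjustment` per voxel, with `NA` for zero-mean
#'   voxels, and `p95`).
#' @export
detrend_run <- function(run) {
  Y <- run$data
  n_vol <- ncol(Y)
  if (n_vol < 3) stop("need at least 3 volumes to detrend", call. = FALSE)
  tt <- seq_len(n_vol)
  tc <- tt - mean(tt)
  # per-voxel OLS slope against centered time, fully vectorized
  mu <- rowMeans(Y)
  slope <- (Y %*% tc) / sum(tc^2)
  fitted_trend <- slope %*% t(tc)            # zero-mean trend component
  out <- Y - fitted_trend
  correction <- abs(fitted_trend)
  max_corr <- apply(correction, 1, max)
  pct <- ifelse(abs(mu) > .Machine$double.eps^0.5, 100 * max_corr / abs(mu), NA_real_)
  if (anyNA(pct)) warning("zero-mean voxel(s): adjustment percentage undefined")
  qc <- structure(list(percent_adjustment = as.numeric(pct),
                       p95 = stats::quantile(pct, 0.95, na.rm = TRUE, names = FALSE)),
                  class = "qc_summary")
  run$data <- out
  list(run = run, qc = qc)
}

#' Write a QC summary to CSV
#' @param qc A `qc_summary`.
#' @param path Output CSV path.
#' @export
write_qc <- function(qc, path) {
  utils::write.csv(data.frame(voxel = seq_along(qc$percent_adjustment),
                              percent_adjustment = qc$percent_adjustment),
                   path, row.names = FALSE)
  invisible(path)
}
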