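#' Glass-pattern stimulus specification
#'
#' A Glass pattern is a field of paired dots ("dipoles") whose common
#' orientation rule creates a global percept. Concentric patterns orient every
#' dipole tangentially to the circle through its midpoint, radial patterns
#' align dipoles with the radius, and random patterns draw orientations
#' independently and uniformly.
#'
#' @param field_width Field width in degrees of visual angle.
#' @param field_height Field height in degrees.
#' @param dot_density Dots per square degree (two dots per dipole).
#' @param dot_diameter Dot diameter in degrees (used only when rendering).
#' @param dipole_separation Center-to-center distance between the two dots of
#'   a dipole, in degrees (often written dx).
#' @param pattern_class One of `"concentric"`, `"radial"`, `"random"`.
#' @param coherence Fraction of dipoles that follow the orientation rule;
#'   the remainder get independent uniform orientations.
#' @param seed Integer seed making field generation reproducible.
#' @return An object of class `glass_spec`.
#' @export
glass_spec <- function(field_width = 30, field_height = 23,
                       dot_density = 10, dot_diameter = 0.12,
                       dipole_separation = 0.414,
                       pattern_class = c("concentric", "radial", "random"),
                       coherence = 1, seed = NULL) {
  pattern_class <- match.arg(pattern_class)
  if (!is.numeric(dot_density) || dot_density <= 0)
    stop("dot_density must be > 0", call. = FALSE)
  if (!is.numeric(dipole_separation) || dipole_separation <= 0)
    stop("dipole_separation must be > 0", call. = FALSE)
  if (field_width <= 0 || field_height <= 0)
    stop("field dimensions must be > 0", call. = FALSE)
  if (!is.numeric(coherence) || coherence < 0 || coherence > 1)
    stop("coherence must lie in [0, 1]", call. = FALSE)
  structure(list(field_width = field_width, field_height = field_height,
                 dot_density = dot_density, dot_diameter = dot_diameter,
                 dipole_separation = dipole_separation,
                 pattern_class = pattern_class, coherence = coherence,
                 seed = seed),
            class = "glass_spec")
}

#' Generate a Glass-pattern dipole field
#'
#' Dipole midpoints are drawn uniformly over the field (dots may overlap; no
#' exclusion zone). The dipole count is `round(dot_density * area / 2)` so the
#' realized dot count matches the requested density. Each dipole is flagged
#' coherent with probability `coherence`; coherent dipoles follow the class
#' rule, the rest get independent uniform orientations. Orientations are in
#' degrees counterclockwise from the positive x axis; the concentric rule is
#' midpoint polar angle + 90 degrees, the radial rule is the polar angle
#' itself. Dipoles whose second dot falls outside the field are kept (clipping
#' is a rendering concern), so separation statistics are exact.
#'
#' @param spec A [glass_spec()].
#' @return A `dipole_field`: a data frame with midpoint coordinates
#'   (`mid_x`, `mid_y`), dot coordinates (`x1`, `y1`, `x2`, `y2`),
#'   `orientation` (degrees) and logical `coherent`; the spec is attached as
#'   attribute `spec`.
#' @export
generate_glass_pattern <- function(spec) {
  stopifnot(inherits(spec, "glass_spec"))
  area <- spec$field_width * spec$field_height
  n_dip <- round(spec$dot_density * area / 2)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  mid_x <- stats::runif(n_dip, -spec$field_width / 2, spec$field_width / 2)
  mid_y <- stats::runif(n_dip, -spec$field_height / 2, spec$field_height / 2)
  coherent <- stats::runif(n_dip) < spec$coherence
  theta_polar <- atan2(mid_y, mid_x) * 180 / pi
  rule <- switch(spec$pattern_class,
                 concentric = theta_polar + 90,
                 radial     = theta_polar,
                 random     = stats::runif(n_dip, 0, 180))
  orientation <- ifelse(coherent & spec$pattern_class != "random",
                        rule, stats::runif(n_dip, 0, 180))
  if (spec$pattern_class == "random") orientation <- rule  # all random anyway
  orientation <- orientation %% 180
  half <- spec$dipole_separation / 2
  dx <- half * cos(orientation * pi / 180)
  dy <- half * sin(orientation * pi / 180)
  out <- data.frame(mid_x = mid_x, mid_y = mid_y,
                    x1 = mid_x - dx, y1 = mid_y - dy,
                    x2 = mid_x + dx, y2 = mid_y + dy,
                    orientation = orientation, coherent = coherent)
  attr(out, "spec") <- spec
  class(out) <- c("dipole_field", class(out))
  out
}

#' Within-dipole center distances of a field
#' @param field A `dipole_field`.
#' @return Numeric vector of center-to-center distances in degrees.
#' @export
dipole_separations <- function(field) {
  sqrt((field$x2 - field$x1)^2 + (field$y2 - field$y1)^2)
}

#' Render a static or dynamic Glass-pattern sequence
#'
#' Static presentation regenerates a new same-class field every second;
#' dynamic presentation every 33 ms (the rapid refresh that yields a motion
#' impression without coherent direction). The frame count is the ceiling of
#' `duration / refresh`.
#'
#' @param spec A [glass_spec()]; its seed (if any) seeds the whole sequence.
#' @param mode `"static"` or `"dynamic"`.
#' @param duration Sequence duration in seconds (> 0).
#' @return A list with `fields` (list of `dipole_field`), `timestamps`
#'   (frame onsets, seconds) and `refresh` (seconds).
#' @export
render_sequence <- function(spec, mode = c("static", "dynamic"), duration) {
  mode <- match.arg(mode)
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be > 0", call. = FALSE)
  refresh <- if (mode == "static") 1 else 0.033
  n_frames <- ceiling(duration / refresh)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  frame_spec <- spec
  frame_spec$seed <- NULL  # frames draw from the stream seeded above
  fields <- lapply(seq_len(n_frames), function(i) generate_glass_pattern(frame_spec))
  list(fields = fields,
       timestamps = (seq_len(n_frames) - 1) * refresh,
       refresh = refresh)
}

#' Write rendered frames as PNG files
#'
#' Optional: the analysis pipeline consumes schedules, never pixels.
#'
#' @param sequence Result of [render_sequence()].
#' @param dir Output directory (created if needed).
#' @param width,height Image size in pixels.
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(sequence, dir, width = 512, height = 393) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(sequence$fields))
  for (i in seq_along(sequence$fields)) {
    f <- sequence$fields[[i]]
    sp <- attr(f, "spec")
    paths[i] <- file.path(dir, sprintf("frame_%04d.png", i))
    grDevices::png(paths[i], width = width, height = height)
    graphics::par(mar = c(0, 0, 0, 0), bg = "grey50")
    graphics::plot(NA, xlim = c(-sp$field_width / 2, sp$field_width / 2),
                   ylim = c(-sp$field_height / 2, sp$field_height / 2),
                   axes = FALSE, xlab = "", ylab = "", asp = 1)
    graphics::points(c(f$x1, f$x2), c(f$y1, f$y2), pch = 19,
                     cex = sp$dot_diameter * width / sp$field_width / 10,
                     col = "white")
    grDevices::dev.off()
  }
  invisible(paths)
}

new_schedule <- function(onset, duration, trial_type) {
  out <- data.frame(onset = onset, duration = duration,
                    trial_type = as.character(trial_type),
                    stringsAsFactors = FALSE)
  attr(out, "total_duration") <- if (nrow(out)) max(out$onset + out$duration) else 0
  class(out) <- c("stim_schedule", class(out))
  out
}

#' Build a palindromic block/blank schedule
#'
#' Within a cycle the condition order is the supplied list followed by its
#' reverse (A-B-C-C-B-A), with a blank before every block and a terminal
#' blank; consecutive cycles share the boundary blank, so runs always start
#' and end with a blank epoch.
#'
#' @param conditions Character vector of condition labels (non-empty).
#' @param block_duration Stimulus block duration in seconds; the design range
#'   is 36-48 s (values outside warn but are honored).
#' @param blank_duration Blank epoch duration in seconds; design range 24-36 s.
#' @param n_cycles Number of palindromic cycles.
#' @return A `stim_schedule` data frame with columns `onset`, `duration`,
#'   `trial_type` (seconds, 0-based, contiguous, non-overlapping).
#' @export
build_palindromic_schedule <- function(conditions, block_duration = 48,
                                       blank_duration = 24, n_cycles = 1) {
  if (length(conditions) == 0) stop("conditions must be non-empty", call. = FALSE)
  if (block_duration < 36 || block_duration > 48)
    warning("block_duration outside the design range [36, 48] s")
  if (blank_duration < 24 || blank_duration > 36)
    warning("blank_duration outside the design range [24, 36] s")
  cycle <- c(conditions, rev(conditions))
  blocks <- rep(cycle, n_cycles)
  labels <- character(2 * length(blocks) + 1)
  durs <- numeric(length(labels))
  labels[seq(1, length(labels), by = 2)] <- "blank"
  durs[seq(1, length(labels), by = 2)] <- blank_duration
  labels[seq(2, length(labels) - 1, by = 2)] <- blocks
  durs[seq(2, length(labels) - 1, by = 2)] <- block_duration
  onsets <- cumsum(c(0, durs[-length(durs)]))
  new_schedule(onsets, durs, labels)
}

#' Build a pinwheel on/off localizer schedule
#'
#' The high-contrast rotating pinwheel alternates with a blank background
#' every 48 s, so the fundamental alternation frequency is
#' 1/96 s = 1/1.6 min^-1 = 0.625 cycles per minute.
#'
#' @param total_duration Total schedule duration in seconds (>= 96).
#' @param epoch Half-period in seconds (default 48).
#' @return A `stim_schedule` of alternating `pinwheel_on` / `pinwheel_off`
#'   epochs, with attribute `ff_per_min` (fundamental frequency, cycles/min).
#' @export
build_pinwheel_schedule <- function(total_duration, epoch = 48) {
  if (total_duration < 2 * epoch)
    stop("total_duration must cover at least one on/off cycle", call. = FALSE)
  n_epochs <- floor(total_duration / epoch)
  labels <- rep(c("pinwheel_on", "pinwheel_off"), length.out = n_epochs)
  onsets <- (seq_len(n_epochs) - 1) * epoch
  out <- new_schedule(onsets, rep(epoch, n_epochs), labels)
  attr(out, "ff_per_min") <- 60 / (2 * epoch)
  out
}

#' Read / write schedules as BIDS-style events TSV
#'
#' Tab-separated files with columns `onset`, `duration`, `trial_type`
#' (seconds, 0-based).
#'
#' @param schedule A `stim_schedule`.
#' @param path File path.
#' @return `read_events` returns a `stim_schedule`; `write_events` invisibly
#'   returns `path`.
#' @export
write_events <- function(schedule, path) {
  utils::write.table(as.data.frame(schedule)[, c("onset", "duration", "trial_type")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset", "duration", "trial_type") %in% names(df)))
    stop("events file must have columns onset, duration, trial_type", call. = FALSE)
  new_schedule(df$onset, df$duration, df$trial_type)
}

#' Total duration of a schedule in seconds
#' @param schedule A `stim_schedule`.
#' @export
schedule_duration <- function(schedule) attr(schedule, "total_duration")
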