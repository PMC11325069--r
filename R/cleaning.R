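#' Signal-cleaning configuration
#'
#' Thresholds and band edges for motion scrubbing, band-pass filtering and
#' confound regression. Defaults: scrub frames with framewise displacement
#' above 0.5 mm or DVARS above 0.5 percent-signal-change; band-pass
#' 0.009-0.08 Hz; 50 mm head radius for converting rotations to arc length.
#'
#' @param fd_threshold_mm Framewise-displacement threshold (mm).
#' @param dv_threshold DVARS threshold (percent of global mean signal).
#' @param band_low_hz,band_high_hz Passband edges (Hz); must satisfy
#'   `band_low_hz < band_high_hz` and `band_high_hz < 1/(2*tr)`.
#' @param head_radius_mm Radius used to turn rotations into displacements.
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(fd_threshold_mm = 0.5, dv_threshold = 0.5,
                            band_low_hz = 0.009, band_high_hz = 0.08,
                            head_radius_mm = 50) {
  fd_threshold_mm <- assert_number(fd_threshold_mm, "fd_threshold_mm", 0, lower_open = TRUE)
  dv_threshold <- assert_number(dv_threshold, "dv_threshold", 0, lower_open = TRUE)
  band_low_hz <- assert_number(band_low_hz, "band_low_hz", 0, lower_open = TRUE)
  band_high_hz <- assert_number(band_high_hz, "band_high_hz", 0, lower_open = TRUE)
  if (band_low_hz >= band_high_hz) {
    stop("`band_low_hz` must be below `band_high_hz`", call. = FALSE)
  }
  head_radius_mm <- assert_number(head_radius_mm, "head_radius_mm", 0, lower_open = TRUE)
  structure(list(fd_threshold_mm = fd_threshold_mm, dv_threshold = dv_threshold,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 head_radius_mm = head_radius_mm),
            class = "cleaning_config")
}

#' Framewise displacement
#'
#' Power-style per-frame head-motion summary: the sum of absolute
#' frame-to-frame changes in the three translations (mm) plus the three
#' rotations (radians) converted to arc length at the given head radius.
#' The first frame has FD 0 by convention.
#'
#' @param motion_params `T x 6` matrix: translations (mm) then rotations (rad).
#' @param head_radius_mm Head radius in mm (default 50).
#' @return Numeric trace of length `T`.
#' @export
framewise_displacement <- function(motion_params, head_radius_mm = 50) {
  motion_params <- assert_matrix(motion_params, "motion_params")
  if (ncol(motion_params) != 6L) {
    stop("`motion_params` must have 6 columns (3 translations, 3 rotations)",
         call. = FALSE)
  }
  if (nrow(motion_params) < 2L) stop("need at least 2 frames", call. = FALSE)
  d <- abs(diff(motion_params))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
}

#' DVARS
#'
#' Root-mean-square (over nodes) of the frame-to-frame signal difference,
#' expressed as a percentage of the global mean signal. The first frame is 0.
#'
#' @param timeseries `n_nodes x T` matrix of raw-scale signals.
#' @return Numeric trace of length `T`.
#' @export
dvars <- function(timeseries) {
  timeseries <- assert_matrix(timeseries, "timeseries")
  if (ncol(timeseries) < 2L) stop("need at least 2 frames", call. = FALSE)
  gm <- mean(timeseries)
  if (gm <= 0) {
    stop("global mean signal is not positive; DVARS percent scale is undefined",
         call. = FALSE)
  }
  d <- timeseries[, -1L, drop = FALSE] - timeseries[, -ncol(timeseries), drop = FALSE]
  c(0, sqrt(colMeans(d^2)) / gm * 100)
}

#' Scrub high-motion volumes
#'
#' Drops every frame whose framewise displacement or DVARS exceeds its
#' threshold (union rule).
#'
#' @param timeseries `n_nodes x T` matrix.
#' @param fd_trace,dv_trace Length-`T` traces (see [framewise_displacement()],
#'   [dvars()]).
#' @param config A [cleaning_config()].
#' @return A `cleaned_series`: list with `timeseries` (kept frames),
#'   `kept_frame_indices`, and `volumes_removed`.
#' @export
scrub_volumes <- function(timeseries, fd_trace, dv_trace,
                          config = cleaning_config()) {
  timeseries <- assert_matrix(timeseries, "timeseries")
  n_frames <- ncol(timeseries)
  if (length(fd_trace) != n_frames || length(dv_trace) != n_frames) {
    stop("motion/DVARS traces must align with the frames", call. = FALSE)
  }
  keep <- fd_trace <= config$fd_threshold_mm & dv_trace <= config$dv_threshold
  if (!any(keep)) stop("scrubbing removed every frame", call. = FALSE)
  structure(list(
    timeseries = timeseries[, keep, drop = FALSE],
    kept_frame_indices = which(keep),
    volumes_removed = sum(!keep)
  ), class = "cleaned_series")
}

#' Zero-phase band-pass filter
#'
#' Discrete-Fourier-domain filter: frequency bins outside
#' `[band_low_hz, band_high_hz]` are zeroed and the series inverted back,
#' which is zero-phase by construction, has unit passband gain and removes
#' the mean (the DC bin lies below any positive low edge).
#'
#' @param timeseries `n_nodes x T` matrix (`T >= 30`).
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param config A [cleaning_config()].
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(timeseries, tr_seconds, config = cleaning_config()) {
  timeseries <- assert_matrix(timeseries, "timeseries")
  n_frames <- ncol(timeseries)
  if (n_frames < 30L) stop("need at least 30 frames to band-pass", call. = FALSE)
  nyquist <- 1 / (2 * tr_seconds)
  if (config$band_high_hz >= nyquist) {
    stop(sprintf("band edge %.4g Hz is not below the Nyquist frequency %.4g Hz",
                 config$band_high_hz, nyquist), call. = FALSE)
  }
  freqs <- (seq_len(n_frames) - 1) / (n_frames * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs)  # fold negative frequencies
  keep <- freqs >= config$band_low_hz & freqs <= config$band_high_hz
  if (!any(keep)) {
    stop("no frequency bin falls inside the passband for this TR and length",
         call. = FALSE)
  }
  spec <- stats::mvfft(t(timeseries))
  spec[!keep, ] <- 0
  t(Re(stats::mvfft(spec, inverse = TRUE))) / n_frames
}

#' Regress confounds out of node time-series
#'
#' Per-node ordinary-least-squares residualization against a common confound
#' matrix (which must contain an intercept column). Residuals are orthogonal
#' to every confound column.
#'
#' @param timeseries `n_nodes x T` matrix.
#' @param confounds `T x p` full-rank matrix including an intercept.
#' @return Residual matrix, `n_nodes x T`.
#' @export
regress_confounds <- function(timeseries, confounds) {
  timeseries <- assert_matrix(timeseries, "timeseries")
  confounds <- assert_matrix(confounds, "confounds")
  n_frames <- ncol(timeseries)
  if (nrow(confounds) != n_frames) {
    stop("`confounds` rows must match the number of frames", call. = FALSE)
  }
  if (ncol(confounds) >= n_frames) {
    stop("more confounds than frames", call. = FALSE)
  }
  has_intercept <- any(apply(confounds, 2, function(col) {
    all(col == col[1L]) && col[1L] != 0
  }))
  if (!has_intercept) {
    stop("`confounds` must include an intercept column", call. = FALSE)
  }
  dec <- qr(confounds)
  if (dec$rank < ncol(confounds)) {
    nm <- colnames(confounds)
    if (is.null(nm)) nm <- paste0("V", seq_len(ncol(confounds)))
    bad <- nm[dec$pivot[(dec$rank + 1L):ncol(confounds)]]
    stop(sprintf("confound matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  t(qr.resid(dec, t(timeseries)))
}

#' Run the full cleaning stage on one subject
#'
#' Order follows the source pipeline: scrub, then band-pass, then confound
#' regression, with confound regressors put through the identical scrub and
#' filter so the regression cannot reintroduce removed frequencies. Set
#' `scrub_first = FALSE` to instead filter the full-length series and drop
#' flagged frames afterwards.
#'
#' @param timeseries `n_nodes x T` matrix on its raw (positive-mean) scale.
#' @param motion_params `T x 6` motion matrix.
#' @param tr_seconds Repetition time in seconds.
#' @param config A [cleaning_config()].
#' @param extra_confounds Optional `T x q` matrix of additional confounds
#'   (e.g. tissue mean signals); motion parameters and an intercept are
#'   always included.
#' @param scrub_first Scrub before filtering (default) or after.
#' @return A `cleaned_series` (see [scrub_volumes()]) whose `timeseries` is
#'   filtered and residualized.
#' @export
clean_series <- function(timeseries, motion_params, tr_seconds,
                         config = cleaning_config(), extra_confounds = NULL,
                         scrub_first = TRUE) {
  fd <- framewise_displacement(motion_params, config$head_radius_mm)
  dv <- dvars(timeseries)
  confounds <- motion_params
  if (!is.null(extra_confounds)) confounds <- cbind(confounds, extra_confounds)
  finish <- function(ts, conf) {
    ts <- bandpass(ts, tr_seconds, config)
    conf <- bandpass(t(conf), tr_seconds, config)  # filter regressors identically
    regress_confounds(ts, cbind(intercept = 1, t(conf)))
  }
  if (scrub_first) {
    scrubbed <- scrub_volumes(timeseries, fd, dv, config)
    if (ncol(scrubbed$timeseries) < 30L) {
      stop("fewer than 30 frames survive scrubbing; cannot filter", call. = FALSE)
    }
    scrubbed$timeseries <- finish(scrubbed$timeseries,
                                  confounds[scrubbed$kept_frame_indices, , drop = FALSE])
    scrubbed
  } else {
    filtered <- finish(timeseries, confounds)
    scrub_volumes(filtered, fd, dv, config)
  }
}
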