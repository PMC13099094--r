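#' Spatiotemporal stimulus container
#'
#' A stimulus is a movie of Weber-contrast frames together with the metadata
#' needed to interpret it physically: the presentation rate and the size of a
#' pixel on the retinal surface. Weber contrast of a pixel is
#' \eqn{(I - \bar I)/\bar I} with \eqn{\bar I} the pixel's temporal mean
#' intensity, so a full-contrast binary checkerboard takes values exactly
#' -1 and +1.
#'
#' Frames are stored as an `H x W x T` array (`frames[, , t]` is frame `t`).
#'
#' @param frames numeric array `H x W x T` of Weber contrast values, or an
#'   `H x W` matrix for a single frame.
#' @param frame_rate_hz presentation rate in Hz (> 0).
#' @param pixel_size_um side length of one pixel on the retina, in
#'   micrometers (> 0).
#' @param origin integer `(row, col)` offset of this crop in full-field
#'   coordinates (1-based; `c(1, 1)` for an uncropped stimulus).
#' @param kind one of `"white_noise"`, `"grating"`, `"movie"`.
#' @return An object of class `rsc_stimulus`.
#' @seealso [gen_white_noise()], [gen_reversing_grating()],
#'   [gen_surrogate_movie()], [read_stimulus()]
#' @export
stimulus <- function(frames, frame_rate_hz, pixel_size_um,
                     origin = c(1L, 1L),
                     kind = c("white_noise", "grating", "movie")) {
  kind <- match.arg(kind)
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stopf("`frames` must be an H x W x T array")
  }
  if (!is.numeric(frame_rate_hz) || frame_rate_hz <= 0) {
    stopf("`frame_rate_hz` must be > 0")
  }
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0) {
    stopf("`pixel_size_um` must be > 0")
  }
  structure(
    list(frames = frames,
         frame_rate_hz = as.numeric(frame_rate_hz),
         pixel_size_um = as.numeric(pixel_size_um),
         origin = as.integer(origin),
         kind = kind),
    class = "rsc_stimulus")
}

#' @export
print.rsc_stimulus <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<rsc_stimulus: %s, %d x %d px, %d frames @ %.4g Hz, %.3g um/px>\n",
              x$kind, d[1], d[2], d[3], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

#' @export
dim.rsc_stimulus <- function(x) dim(x$frames)

n_frames <- function(stim) dim(stim$frames)[3]

# Pixel-major view: npix x T matrix, pixel index column-major over (row, col).
stim_matrix <- function(stim) {
  d <- dim(stim$frames)
  m <- stim$frames
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

#' Binned spike-count container
#'
#' Spike counts per stimulus frame bin, one row per trial. When paired with a
#' stimulus, `bin_rate_hz` equals the stimulus frame rate (responses are
#' binned at the projector refresh rate).
#'
#' @param counts non-negative integer matrix (trials x bins) or vector
#'   (single trial).
#' @param bin_rate_hz binning rate in Hz.
#' @param spike_times_s optional list of raw spike-time vectors (seconds),
#'   one per trial.
#' @return An object of class `rsc_spike_train`.
#' @export
spike_train <- function(counts, bin_rate_hz, spike_times_s = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1L)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("`counts` must be non-negative integers")
  }
  if (!is.numeric(bin_rate_hz) || bin_rate_hz <= 0) {
    stopf("`bin_rate_hz` must be > 0")
  }
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts,
         bin_rate_hz = as.numeric(bin_rate_hz),
         spike_times_s = spike_times_s),
    class = "rsc_spike_train")
}

#' @export
print.rsc_spike_train <- function(x, ...) {
  cat(sprintf("<rsc_spike_train: %d trial(s) x %d bins @ %.4g Hz, %d spikes>\n",
              nrow(x$counts), ncol(x$counts), x$bin_rate_hz, sum(x$counts)))
  invisible(x)
}

#' Temporal filter
#'
#' A length-`M` tap vector, most-recent-first: `taps[1]` weights the current
#' frame, `taps[2]` the previous one, and so on. Filters estimated from data
#' are normalized to unit Euclidean norm.
#'
#' @param taps numeric tap vector, most-recent-first.
#' @param tap_rate_hz sampling rate of the taps in Hz.
#' @param normalize if `TRUE`, divide by the Euclidean norm.
#' @export
temporal_filter <- function(taps, tap_rate_hz, normalize = FALSE) {
  taps <- as.numeric(taps)
  if (normalize) {
    nrm <- sqrt(sum(taps^2))
    if (nrm == 0) stopf("cannot normalize an all-zero temporal filter")
    taps <- taps / nrm
  }
  structure(list(taps = taps, tap_rate_hz = as.numeric(tap_rate_hz)),
            class = "rsc_temporal_filter")
}

#' Spatial filter over a crop
#'
#' @param weights numeric `H' x W'` weight matrix.
#' @param origin `(row, col)` crop offset in full-field coordinates.
#' @param normalization `"unit_norm"` (Euclidean norm 1, signed weights) or
#'   `"gaussian_fit"` (non-negative weights, zero beyond the 3-sigma ellipse
#'   of an elliptical Gaussian fit).
#' @export
spatial_filter <- function(weights, origin = c(1L, 1L),
                           normalization = c("unit_norm", "gaussian_fit")) {
  normalization <- match.arg(normalization)
  weights <- as.matrix(weights)
  if (normalization == "unit_norm") {
    nrm <- sqrt(sum(weights^2))
    if (nrm == 0) stopf("cannot normalize an all-zero spatial filter")
    weights <- weights / nrm
  } else if (any(weights < 0)) {
    stopf("gaussian_fit spatial filters must be non-negative")
  }
  structure(list(weights = weights, origin = as.integer(origin),
                 normalization = normalization),
            class = "rsc_spatial_filter")
}

#' Elliptical Gaussian receptive-field fit
#'
#' Receptive-field size is reported as the diameter of the circle with the
#' same area as the 1.5-sigma ellipse of the fit:
#' `rf_size_um = 2 * 1.5 * sqrt(sigma_x * sigma_y) * pixel_size_um`.
#'
#' @param center `(x, y)` center in pixels (column, row).
#' @param sigma_x,sigma_y standard deviations along the principal axes, px.
#' @param angle rotation of the ellipse, radians.
#' @param amplitude peak amplitude of the fit.
#' @param pixel_size_um pixel size used to derive `rf_size_um`.
#' @export
gaussian_rf <- function(center, sigma_x, sigma_y, angle, amplitude,
                        pixel_size_um) {
  if (sigma_x <= 0 || sigma_y <= 0) stopf("sigmas must be > 0")
  structure(
    list(center = as.numeric(center), sigma_x = sigma_x, sigma_y = sigma_y,
         angle = angle, amplitude = amplitude,
         pixel_size_um = as.numeric(pixel_size_um),
         rf_size_um = 2 * 1.5 * sqrt(sigma_x * sigma_y) * pixel_size_um),
    class = "rsc_gaussian_rf")
}

#' Simulated eye-position trace
#'
#' Per-frame gaze offsets in monitor pixels, with each frame labeled as part
#' of a saccade or a fixation. Traces are built in independent chunks; the
#' offset resets to (0, 0) at each chunk start and chunks drifting more than
#' the rejection bound in any direction are regenerated.
#'
#' @param offsets integer matrix `T x 2` of per-frame `(dx, dy)` offsets.
#' @param labels character vector of `"saccade"` / `"fixation"` per frame.
#' @param chunk_starts 1-based indices of chunk starts.
#' @export
eye_trace <- function(offsets, labels, chunk_starts = 1L) {
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 2L || nrow(offsets) != length(labels)) {
    stopf("`offsets` must be T x 2 with one label per frame")
  }
  if (!all(labels %in% c("saccade", "fixation"))) {
    stopf("labels must be 'saccade' or 'fixation'")
  }
  structure(list(offsets = offsets, labels = labels,
                 chunk_starts = as.integer(chunk_starts)),
            class = "rsc_eye_trace")
}
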