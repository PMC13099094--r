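#' Bin spike times at stimulus frame resolution
#'
#' Counts spikes in the half-open interval `[frame_times[i], frame_times[i+1])`
#' for each frame `i`; spikes before the first frame or at/after the last
#' frame time are dropped. With `n` frame times this yields `n - 1` bins.
#'
#' @param spike_times_s numeric vector of spike times, seconds.
#' @param frame_times_s strictly increasing frame onset times, seconds; the
#'   last element closes the final bin.
#' @return An [spike_train()] with a single trial and `bin_rate_hz` set to
#'   the median frame rate.
#' @examples
#' st <- bin_spikes(c(0.001, 0.005), seq(0, 2, by = 1) / 85)
#' st$counts
#' @export
bin_spikes <- function(spike_times_s, frame_times_s) {
  if (length(frame_times_s) < 2L) stopf("need at least 2 frame times")
  if (any(diff(frame_times_s) <= 0)) {
    stopf("`frame_times_s` must be strictly increasing")
  }
  n_bins <- length(frame_times_s) - 1L
  idx <- findInterval(spike_times_s, frame_times_s)  # bin i: [t_i, t_{i+1})
  idx <- idx[idx >= 1L & idx <= n_bins &
               spike_times_s < frame_times_s[n_bins + 1L]]
  spike_train(tabulate(idx, nbins = n_bins),
              bin_rate_hz = 1 / stats::median(diff(frame_times_s)),
              spike_times_s = list(as.numeric(spike_times_s)))
}

# ---- plain-text containers -------------------------------------------------
# A stimulus file is text: line 1 is a JSON metadata object, each following
# line is one frame, flattened column-major (H*W values, "%.17g" so doubles
# round-trip bit-exactly).

#' Write / read a stimulus container
#'
#' Plain-text container: a JSON metadata header line (`frame_rate_hz`,
#' `pixel_size_um`, `height`, `width`, `n_frames`, `origin`, `kind`)
#' followed by one line per frame with `H * W` values in column-major order.
#' A write/read round-trip reproduces frames bit-exactly and metadata
#' exactly.
#'
#' @param stim an [stimulus()].
#' @param path file path.
#' @return `read_stimulus` returns an [stimulus()]; `write_stimulus`
#'   invisibly returns `path`.
#' @export
write_stimulus <- function(stim, path) {
  stopifnot(inherits(stim, "rsc_stimulus"))
  d <- dim(stim$frames)
  meta <- jsonlite::toJSON(
    list(frame_rate_hz = stim$frame_rate_hz,
         pixel_size_um = stim$pixel_size_um,
         height = d[1], width = d[2], n_frames = d[3],
         origin = stim$origin, kind = stim$kind),
    auto_unbox = TRUE, digits = NA)
  m <- stim_matrix(stim)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(as.character(meta), con)
  for (t in seq_len(d[3])) {
    writeLines(paste(sprintf("%.17g", m[, t]), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stopf("stimulus file '%s' is empty", path)
  meta <- jsonlite::fromJSON(lines[1])
  for (field in c("frame_rate_hz", "pixel_size_um", "height", "width",
                  "n_frames", "kind")) {
    if (is.null(meta[[field]])) {
      stopf("stimulus file '%s' is missing metadata field '%s'", path, field)
    }
  }
  if (length(lines) - 1L != meta$n_frames) {
    stopf("stimulus file '%s': expected %d frame lines, found %d",
          path, meta$n_frames, length(lines) - 1L)
  }
  vals <- vapply(lines[-1], function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  }, numeric(meta$height * meta$width), USE.NAMES = FALSE)
  frames <- array(vals, dim = c(meta$height, meta$width, meta$n_frames))
  stimulus(frames, meta$frame_rate_hz, meta$pixel_size_um,
           origin = meta$origin %||% c(1L, 1L), kind = meta$kind)
}

#' Read / write spike-time CSV files
#'
#' Spike files are CSV with header `trial,time_s`: one row per spike, times
#' in seconds, trial numbers 1-based.
#'
#' @param path file path.
#' @return `read_spikes` returns a data.frame with columns `trial`, `time_s`.
#' @export
read_spikes <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!all(c("trial", "time_s") %in% names(df))) {
    stopf("spike file '%s' must have columns 'trial' and 'time_s'", path)
  }
  df[, c("trial", "time_s")]
}

#' @rdname read_spikes
#' @param spike_times_s list of numeric spike-time vectors, one per trial,
#'   or a single numeric vector (one trial).
#' @export
write_spikes <- function(spike_times_s, path) {
  if (is.numeric(spike_times_s)) spike_times_s <- list(spike_times_s)
  df <- data.frame(
    trial = rep(seq_along(spike_times_s), lengths(spike_times_s)),
    time_s = unlist(spike_times_s, use.names = FALSE) %||% numeric(0))
  data.table::fwrite(df, path)
  invisible(path)
}
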