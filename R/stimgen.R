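#' Generate binary checkerboard white noise
#'
#' Each stimulus square is drawn i.i.d. from \{-1, +1\} with probability 0.5,
#' held constant within the square, and redrawn every frame. The standard
#' experimental configuration is a 150 x 200 square checkerboard with 4
#' monitor pixels per square at 7.5 um/px, i.e. 30 um x 30 um squares,
#' updated at 85 Hz.
#'
#' @param n_frames number of frames.
#' @param squares_hw integer `(rows, cols)` of stimulus squares.
#' @param square_px monitor pixels per square side (>= 1).
#' @param pixel_size_um monitor pixel size on the retina, um.
#' @param frame_rate_hz update rate, Hz.
#' @param seed RNG seed; the stimulus is deterministic given the seed.
#' @param canvas_px optional `(height, width)` pixel canvas; must be at least
#'   `squares_hw * square_px`. Defaults to exactly that size.
#' @return An [stimulus()] of kind `"white_noise"`.
#' @export
gen_white_noise <- function(n_frames, squares_hw, square_px = 1L,
                            pixel_size_um = 7.5, frame_rate_hz = 85,
                            seed = NULL, canvas_px = NULL) {
  square_px <- as.integer(square_px)
  if (square_px < 1L) stopf("`square_px` must be >= 1")
  hw <- as.integer(squares_hw)
  need <- hw * square_px
  if (!is.null(canvas_px) && any(as.integer(canvas_px) < need)) {
    stopf("canvas %s px cannot hold %d x %d squares of %d px",
          paste(canvas_px, collapse = "x"), hw[1], hw[2], square_px)
  }
  draws <- with_seed(seed, {
    array(sample(c(-1, 1), n_frames * hw[1] * hw[2], replace = TRUE),
          dim = c(hw[1], hw[2], n_frames))
  })
  frames <- if (square_px == 1L) {
    draws
  } else {
    draws[rep(seq_len(hw[1]), each = square_px),
          rep(seq_len(hw[2]), each = square_px), , drop = FALSE]
  }
  stimulus(frames, frame_rate_hz, pixel_size_um, kind = "white_noise")
}

#' Generate a contrast-reversing grating
#'
#' Vertical square-wave grating of alternating -1 / +1 stripes that flips
#' polarity every `reversal_period_s` (500 ms in the standard protocol, i.e.
#' a 1 Hz stimulus period). `phase_px` shifts the stripe boundaries to the
#' right. A stripe width equal to the field width degenerates to spatially
#' uniform full-field flicker.
#'
#' @param stripe_width_px stripe width in pixels (>= 1).
#' @param phase_px phase shift of the stripe boundary, pixels.
#' @param reversal_period_s time between polarity reversals, seconds.
#' @param n_periods number of full stimulus periods (two reversals each).
#' @param frame_rate_hz frame rate, Hz.
#' @param height_px,width_px field size in pixels.
#' @param pixel_size_um pixel size, um.
#' @return An [stimulus()] of kind `"grating"`.
#' @export
gen_reversing_grating <- function(stripe_width_px, phase_px = 0,
                                  reversal_period_s = 0.5, n_periods = 12,
                                  frame_rate_hz = 85,
                                  height_px = 40, width_px = 40,
                                  pixel_size_um = 7.5) {
  if (stripe_width_px < 1) stopf("`stripe_width_px` must be >= 1")
  cols <- seq_len(width_px) - 1L
  profile <- ifelse(((cols - phase_px) %/% stripe_width_px) %% 2 == 0, 1, -1)
  base <- matrix(profile, nrow = height_px, ncol = width_px, byrow = TRUE)
  frames_per_rev <- max(1L, round(reversal_period_s * frame_rate_hz))
  n_frames <- 2L * n_periods * frames_per_rev
  t_idx <- seq_len(n_frames) - 1L
  sign_t <- ifelse((t_idx %/% frames_per_rev) %% 2 == 0, 1, -1)
  frames <- array(0, dim = c(height_px, width_px, n_frames))
  for (t in seq_len(n_frames)) frames[, , t] <- base * sign_t[t]
  stimulus(frames, frame_rate_hz, pixel_size_um, kind = "grating")
}

#' Convert RGB to linear luminance
#'
#' `0.2126 R + 0.7152 G + 0.0722 B` (Rec. 709 luma coefficients), the
#' grayscale conversion applied to movie frames before display.
#'
#' @param r,g,b channel values in `[0, 1]` (vectorized).
#' @return luminance, same shape as the inputs.
#' @export
rgb_to_luminance <- function(r, g, b) {
  0.2126 * r + 0.7152 * g + 0.0722 * b
}

#' Frame-repeat schedule for 24 Hz -> 85 Hz upsampling
#'
#' Each movie frame is shown for 3 or 4 projector frames with probabilities
#' 0.46 and 0.54, so the expected upsampling factor is
#' 3 * 0.46 + 4 * 0.54 = 3.54 (= 85/24).
#'
#' @param n_movie_frames number of source movie frames (>= 1).
#' @param seed RNG seed.
#' @return integer vector of per-frame repeat counts in \{3, 4\}.
#' @export
frame_repeat_schedule <- function(n_movie_frames, seed = NULL) {
  if (n_movie_frames < 1) stopf("`n_movie_frames` must be >= 1")
  with_seed(seed, 3L + stats::rbinom(n_movie_frames, 1L, 0.54))
}

#' Gaze-shift simulation parameters
#'
#' Defaults follow the statistics used to emulate marmoset active vision:
#' saccade amplitudes ~ Exponential(scale 200 um), saccade durations of 2, 3,
#' or 4 frames (23.5, 35.3, 47.1 ms at 85 Hz) with probabilities
#' (0.35, 0.4, 0.25), fixation durations of a 100 ms refractory period plus
#' an Exponential(scale 200 ms) tail, and fixational jitter drawn per frame
#' update and axis from a zero-mean Gaussian with SD 2 monitor pixels.
#' Traces are generated in 10 s chunks, resetting the gaze offset to (0, 0)
#' at each chunk start; chunks whose offset exceeds 200 monitor pixels in
#' any direction are rejected and regenerated.
#'
#' @param saccade_amp_scale_um exponential scale of saccade amplitude, um.
#' @param saccade_dur_frames possible saccade durations, frames.
#' @param saccade_dur_probs probabilities of each duration (sum to 1).
#' @param fixation_scale_ms exponential scale of fixation duration, ms.
#' @param fixation_refractory_ms fixation refractory period, ms.
#' @param jitter_sd_px per-axis SD of fixational jitter steps, monitor px.
#' @param chunk_s chunk length, seconds.
#' @param max_drift_px chunk rejection bound on |dx|, |dy|, monitor px.
#' @export
gaze_params <- function(saccade_amp_scale_um = 200,
                        saccade_dur_frames = c(2L, 3L, 4L),
                        saccade_dur_probs = c(0.35, 0.4, 0.25),
                        fixation_scale_ms = 200,
                        fixation_refractory_ms = 100,
                        jitter_sd_px = 2,
                        chunk_s = 10,
                        max_drift_px = 200) {
  if (abs(sum(saccade_dur_probs) - 1) > 1e-12) {
    stopf("saccade duration probabilities must sum to 1")
  }
  if (saccade_amp_scale_um <= 0 || fixation_scale_ms <= 0 ||
      jitter_sd_px <= 0 || chunk_s <= 0) {
    stopf("gaze scales must be > 0")
  }
  structure(list(saccade_amp_scale_um = saccade_amp_scale_um,
                 saccade_dur_frames = as.integer(saccade_dur_frames),
                 saccade_dur_probs = saccade_dur_probs,
                 fixation_scale_ms = fixation_scale_ms,
                 fixation_refractory_ms = fixation_refractory_ms,
                 jitter_sd_px = jitter_sd_px,
                 chunk_s = chunk_s,
                 max_drift_px = max_drift_px),
            class = "rsc_gaze_params")
}

#' Draw saccade amplitudes
#'
#' Amplitudes are exponentially distributed with the configured scale
#' parameter (mean), in micrometers. Exposed separately so the amplitude
#' distribution can be validated directly.
#'
#' @param n number of draws.
#' @param params a [gaze_params()].
#' @param seed RNG seed.
#' @return numeric vector of amplitudes, um.
#' @export
draw_saccade_amplitudes <- function(n, params = gaze_params(), seed = NULL) {
  with_seed(seed, stats::rexp(n, rate = 1 / params$saccade_amp_scale_um))
}

# One chunk of gaze trace; returns list(offsets, labels) or NULL if rejected.
gaze_chunk <- function(n_frames, frame_rate_hz, pixel_size_um, p) {
  offsets <- matrix(0, nrow = n_frames, ncol = 2L)
  labels <- character(n_frames)
  pos <- c(0, 0)            # continuous gaze position, monitor px
  t <- 1L
  while (t <= n_frames) {
    # fixation: refractory + exponential tail, rounded to >= 1 whole frame
    fix_ms <- p$fixation_refractory_ms +
      stats::rexp(1, rate = 1 / p$fixation_scale_ms)
    fix_frames <- max(1L, round(fix_ms / 1000 * frame_rate_hz))
    for (k in seq_len(fix_frames)) {
      if (t > n_frames) break
      pos <- pos + stats::rnorm(2L, mean = 0, sd = p$jitter_sd_px)
      offsets[t, ] <- round(pos)
      labels[t] <- "fixation"
      t <- t + 1L
    }
    if (t > n_frames) break
    # saccade: exponential amplitude, uniform direction, 2-4 frame duration
    amp_px <- stats::rexp(1, rate = 1 / p$saccade_amp_scale_um) / pixel_size_um
    dir <- stats::runif(1, 0, 2 * pi)
    target <- pos + amp_px * c(cos(dir), sin(dir))
    dur <- sample(p$saccade_dur_frames, 1L, prob = p$saccade_dur_probs)
    start <- pos
    for (k in seq_len(dur)) {
      if (t > n_frames) break
      pos <- start + (target - start) * k / dur
      offsets[t, ] <- round(pos)
      labels[t] <- "saccade"
      t <- t + 1L
    }
  }
  if (max(abs(offsets)) > p$max_drift_px) return(NULL)
  list(offsets = offsets, labels = labels)
}

#' Simulate a gaze trace of saccades and fixational eye movements
#'
#' Alternates fixations (refractory + exponential duration, Gaussian
#' positional jitter each frame update) with saccades (exponential amplitude,
#' uniform direction, 2-4 frame duration, linear interpolation from start to
#' target). See [gaze_params()] for the parameter conventions. Offsets are
#' rounded to whole monitor pixels because frames can only be shifted by
#' whole pixels.
#'
#' @param duration_s trace duration, seconds (> 0).
#' @param frame_rate_hz frame rate, Hz.
#' @param pixel_size_um monitor pixel size on the retina, um (converts
#'   saccade amplitudes from um to pixels).
#' @param params a [gaze_params()].
#' @param seed RNG seed.
#' @param max_attempts rejection-sampling cap per chunk.
#' @return An [eye_trace()].
#' @export
simulate_gaze_trace <- function(duration_s, frame_rate_hz = 85,
                                pixel_size_um = 7.5,
                                params = gaze_params(), seed = NULL,
                                max_attempts = 1000L) {
  if (duration_s <= 0) stopf("`duration_s` must be > 0")
  n_total <- round(duration_s * frame_rate_hz)
  chunk_frames <- round(params$chunk_s * frame_rate_hz)
  with_seed(seed, {
    offsets <- matrix(0L, nrow = 0L, ncol = 2L)
    labels <- character(0)
    chunk_starts <- integer(0)
    while (nrow(offsets) < n_total) {
      n_f <- min(chunk_frames, n_total - nrow(offsets))
      chunk <- NULL
      for (att in seq_len(max_attempts)) {
        chunk <- gaze_chunk(n_f, frame_rate_hz, pixel_size_um, params)
        if (!is.null(chunk)) break
      }
      if (is.null(chunk)) {
        stopf("gaze chunk rejected %d times; lower the drift or amplitudes",
              max_attempts)
      }
      chunk_starts <- c(chunk_starts, nrow(offsets) + 1L)
      offsets <- rbind(offsets, chunk$offsets)
      labels <- c(labels, chunk$labels)
    }
    eye_trace(offsets, labels, chunk_starts)
  })
}

#' Apply gaze shifts to a frame stack
#'
#' Translates each frame by its integer `(dx, dy)` offset (dx rightward in
#' columns, dy downward in rows); border pixels uncovered by the shifted
#' frame are set to `fill_value` (gray, i.e. zero Weber contrast, by
#' default).
#'
#' @param frames `H x W x T` array.
#' @param trace an [eye_trace()] with one offset per frame.
#' @param fill_value value for uncovered border pixels.
#' @return shifted `H x W x T` array.
#' @export
apply_gaze_shifts <- function(frames, trace, fill_value = 0) {
  d <- dim(frames)
  if (nrow(trace$offsets) != d[3]) {
    stopf("trace length (%d) must equal number of frames (%d)",
          nrow(trace$offsets), d[3])
  }
  if (any(abs(trace$offsets[, 1]) >= d[2]) ||
      any(abs(trace$offsets[, 2]) >= d[1])) {
    stopf("gaze offset magnitude exceeds frame size")
  }
  out <- array(fill_value, dim = d)
  for (t in seq_len(d[3])) {
    dx <- trace$offsets[t, 1]; dy <- trace$offsets[t, 2]
    src_r <- max(1, 1 - dy):min(d[1], d[1] - dy)
    src_c <- max(1, 1 - dx):min(d[2], d[2] - dx)
    out[src_r + dy, src_c + dx, t] <- frames[src_r, src_c, t]
  }
  out
}

#' Surrogate naturalistic movie configuration
#'
#' The surrogate movie stands in for a licensed naturalistic film: spatially
#' correlated frames with a 1/f^2 radial power spectrum (the hallmark of
#' natural scenes), slow temporal correlation within fixations, gaze-shift
#' global motion, a mean intensity at 76% of the white-noise level, and a
#' space-time RMS contrast of 45% of the mean intensity.
#'
#' @param n_frames frames to generate.
#' @param height,width frame size, pixels.
#' @param spectral_exponent target exponent of the 1/f^alpha power spectrum.
#' @param mean_level_fraction mean intensity relative to the white-noise
#'   mean level (display bookkeeping; contrast is what matters downstream).
#' @param rms_contrast target space-time RMS contrast (fraction of mean).
#' @param seed RNG seed.
#' @export
movie_config <- function(n_frames, height = 64, width = 64,
                         spectral_exponent = 2.0,
                         mean_level_fraction = 0.76,
                         rms_contrast = 0.45, seed = NULL) {
  if (rms_contrast < 0) stopf("`rms_contrast` must be >= 0")
  structure(list(n_frames = as.integer(n_frames), height = as.integer(height),
                 width = as.integer(width),
                 spectral_exponent = spectral_exponent,
                 mean_level_fraction = mean_level_fraction,
                 rms_contrast = rms_contrast, seed = seed),
            class = "rsc_movie_config")
}

# One spatially 1/f^(exponent) correlated field, unit variance, via
# frequency-domain filtering of Gaussian white noise.
pink_field <- function(height, width, exponent) {
  z <- matrix(stats::rnorm(height * width), height, width)
  fz <- stats::fft(z)
  fy <- c(0:(height %/% 2), -((height - height %/% 2 - 1):1)) / height
  fx <- c(0:(width %/% 2), -((width - width %/% 2 - 1):1)) / width
  f <- sqrt(outer(fy^2, fx^2, `+`))
  f[1, 1] <- Inf                       # zero out DC
  amp <- f^(-exponent / 2)
  field <- Re(stats::fft(fz * amp, inverse = TRUE)) / (height * width)
  field / stats::sd(field)
}

#' Generate a surrogate naturalistic movie
#'
#' Builds frames by filtering Gaussian white fields in the frequency domain
#' with amplitude proportional to `f^(-exponent/2)` (so power follows
#' `1/f^exponent`), evolves them slowly between gaze events with an AR(1)
#' mixture (new field injected at each chunk), maps them affinely into a
#' non-negative intensity range with the configured mean level and RMS
#' contrast (clipping at zero intensity), applies simulated gaze shifts, and
#' finally converts intensities to Weber contrast per pixel by subtracting
#' and dividing by that pixel's temporal mean.
#'
#' @param config a [movie_config()].
#' @param gaze a [gaze_params()], or `NULL` to skip gaze shifts.
#' @param seed RNG seed (overrides `config$seed` if given).
#' @param frame_rate_hz frame rate, Hz.
#' @param pixel_size_um pixel size, um.
#' @return An [stimulus()] of kind `"movie"` with attribute
#'   `realized_rms_contrast`.
#' @export
gen_surrogate_movie <- function(config, gaze = gaze_params(), seed = NULL,
                                frame_rate_hz = 85, pixel_size_um = 7.5) {
  seed <- seed %||% config$seed
  h <- config$height; w <- config$width; n <- config$n_frames
  with_seed(seed, {
    # temporally correlated pink fields: AR(1) with slow drift plus a fresh
    # field injected every ~0.5 s so scene content changes between fixations
    rho <- 0.98
    fields <- array(0, dim = c(h, w, n))
    cur <- pink_field(h, w, config$spectral_exponent)
    refresh <- max(1L, round(frame_rate_hz / 2))
    for (t in seq_len(n)) {
      if (t > 1L) {
        innov <- pink_field(h, w, config$spectral_exponent)
        mix <- if (t %% refresh == 0L) 0.7 else rho
        cur <- mix * cur + sqrt(1 - mix^2) * innov
      }
      fields[, , t] <- cur
    }
    # affine map to intensity: mean level m, sd = rms_contrast * m, clip >= 0
    m <- config$mean_level_fraction
    intens <- m + fields * (config$rms_contrast * m)
    n_clip <- sum(intens < 0)
    intens[intens < 0] <- 0
    if (n_clip / length(intens) > 0.05) {
      warning(sprintf(
        "rms_contrast %.2f clipped %.1f%% of pixels; realized contrast %.3f",
        config$rms_contrast, 100 * n_clip / length(intens),
        stats::sd(intens) / mean(intens)), call. = FALSE)
    }
    # realized contrast is measured on the generated intensity movie before
    # gaze shifts: on desk-scale canvases the gray border fill of shifted
    # frames would otherwise dominate the statistic (full-size frames are
    # essentially unaffected)
    realized_rms <- stats::sd(intens) / mean(intens)
    if (!is.null(gaze)) {
      trace <- simulate_gaze_trace(n / frame_rate_hz, frame_rate_hz,
                                   pixel_size_um, gaze)
      # On canvases smaller than the drift bound, clamp offsets so the
      # shifted frame always overlaps the canvas (full-size frames as used
      # experimentally are never affected).
      bound <- (min(h, w) - 1L) %/% 2L
      trace$offsets <- pmax(pmin(trace$offsets, bound), -bound)
      intens <- apply_gaze_shifts(intens, trace, fill_value = m)
    }
    # Weber conversion per pixel against its own temporal mean
    pix_mean <- rowMeans(matrix(intens, h * w, n), na.rm = TRUE)
    pix_mean[pix_mean == 0] <- 1
    weber <- (matrix(intens, h * w, n) - pix_mean) / pix_mean
    frames <- array(weber, dim = c(h, w, n))
    stim <- stimulus(frames, frame_rate_hz, pixel_size_um, kind = "movie")
    attr(stim, "realized_rms_contrast") <- realized_rms
    stim
  })
}
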