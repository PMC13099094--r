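#' Robust standard deviation
#'
#' `1.4826 * median(|x - median(x)|)` — the median absolute deviation scaled
#' to be a consistent estimator of the standard deviation of a normal
#' distribution (1.4826 = 1 / qnorm(0.75) to four decimals).
#'
#' @param values numeric vector (length >= 2).
#' @return robust SD estimate.
#' @export
robust_std <- function(values) {
  if (length(values) < 2L) stopf("need at least 2 values")
  1.4826 * stats::median(abs(values - stats::median(values)))
}

#' Compute the spatiotemporal spike-triggered average
#'
#' `STA[tau] = sum_t n_t z_{t - tau} / sum_t n_t` for lags
#' `tau = 0 .. window_frames - 1`, summed over eligible bins of all trials.
#' Spikes during the first `window_frames - 1` bins of each trial are
#' excluded so every contributing snippet has full support.
#'
#' @param stim an [stimulus()].
#' @param spikes an [spike_train()] binned at the stimulus frame rate. For
#'   multi-trial trains the same stimulus is assumed for every row (frozen
#'   segments); distinct training trials should be concatenated into one
#'   row with `trial_starts` marking boundaries.
#' @param window_frames STA window length M (30 frames = 353 ms at 85 Hz).
#' @param trial_starts 1-based bin indices where trials begin (exclusion
#'   rule is applied after each).
#' @return list of class `rsc_sta`: `kernel` (`H x W x M` array, lag 1 =
#'   most recent frame), `n_spikes_used`, `window_frames`.
#' @export
compute_sta <- function(stim, spikes, window_frames = 30L,
                        trial_starts = 1L) {
  M <- as.integer(window_frames)
  Z <- stim_matrix(stim)
  Tn <- ncol(Z)
  n <- colSums(spikes$counts)                # total counts per bin
  if (length(n) != Tn) {
    stopf("spike train has %d bins but stimulus has %d frames",
          length(n), Tn)
  }
  eligible <- rep(TRUE, Tn)
  for (s in trial_starts) {
    eligible[s:min(Tn, s + M - 2L)] <- FALSE
  }
  idx <- which(eligible & n > 0)
  n_used <- sum(n[idx])
  if (n_used == 0) stopf("no eligible spikes for the STA")
  sta <- matrix(0, nrow(Z), M)
  nv <- n[idx]
  for (tau in 0:(M - 1L)) {
    sta[, tau + 1L] <- Z[, idx - tau, drop = FALSE] %*% nv
  }
  sta <- sta / n_used
  d <- dim(stim$frames)
  structure(list(kernel = array(sta, dim = c(d[1], d[2], M)),
                 n_spikes_used = n_used, window_frames = M,
                 frame_rate_hz = stim$frame_rate_hz,
                 pixel_size_um = stim$pixel_size_um),
            class = "rsc_sta")
}

#' Extract spatial and temporal components from an STA
#'
#' Selects pixels whose absolute peak intensity over time exceeds six times
#' the robust standard deviation of all pixels' absolute peaks around their
#' median; the temporal component is the mean time course of the selected
#' pixels, the spatial component the projection of the 3D STA onto the
#' temporal component. The spatial component is cropped to a square window
#' around the pixel with the largest temporal variance, and both components
#' are normalized to unit Euclidean norm.
#'
#' @param sta an `rsc_sta` from [compute_sta()].
#' @param threshold_sd selection threshold in robust SDs (default 6).
#' @param crop_squares side of the spatial crop in stimulus pixels
#'   (40 squares = 1200 um in the standard configuration); clipped to the
#'   available field.
#' @return list: `spatial` ([spatial_filter()], unit norm), `temporal`
#'   ([temporal_filter()], unit norm), `center_rc` (row, col of the
#'   max-variance pixel), `selected` (logical matrix of selected pixels).
#' @export
extract_components <- function(sta, threshold_sd = 6, crop_squares = 40L) {
  d <- dim(sta$kernel)
  K <- matrix(sta$kernel, d[1] * d[2], d[3])    # npix x M
  peaks <- apply(abs(K), 1L, max)
  thr <- stats::median(peaks) + threshold_sd * robust_std(peaks)
  sel <- peaks > thr
  if (!any(sel)) {
    stopf("no pixel exceeds %g robust SDs; record longer or lower the threshold",
          threshold_sd)
  }
  temporal <- colMeans(K[sel, , drop = FALSE])
  tnorm <- sqrt(sum(temporal^2))
  spatial_full <- as.numeric(K %*% temporal) / tnorm   # projection onto unit v
  # crop around the max temporal-variance pixel
  v_pix <- apply(K, 1L, stats::var)
  center <- arrayInd(which.max(v_pix), c(d[1], d[2]))[1, ]
  half <- crop_squares %/% 2L
  rows <- max(1L, center[1] - half):min(d[1], center[1] + half - 1L)
  cols <- max(1L, center[2] - half):min(d[2], center[2] + half - 1L)
  sp <- matrix(spatial_full, d[1], d[2])[rows, cols, drop = FALSE]
  list(spatial = spatial_filter(sp, origin = c(rows[1], cols[1]),
                                normalization = "unit_norm"),
       temporal = temporal_filter(temporal, sta$frame_rate_hz,
                                  normalize = TRUE),
       center_rc = center,
       selected = matrix(sel, d[1], d[2]))
}

# Elliptical Gaussian surface evaluated on (rows, cols) grids.
gauss2d <- function(rows, cols, amp, cx, cy, sx, sy, theta) {
  ct <- cos(theta); st <- sin(theta)
  xr <- (cols - cx) * ct + (rows - cy) * st
  yr <- -(cols - cx) * st + (rows - cy) * ct
  amp * exp(-0.5 * ((xr / sx)^2 + (yr / sy)^2))
}

#' Fit an elliptical Gaussian to a spatial component
#'
#' Least-squares fit of `A exp(-((x')^2 / 2 sx^2 + (y')^2 / 2 sy^2))` in
#' rotated coordinates, initialized from the moments of the positive part
#' of the component. The returned filter is the fit evaluated on the
#' (optionally nearest-neighbour upsampled) grid with values beyond the
#' 3-sigma ellipse set to exactly zero. Receptive-field size is the
#' diameter of the circle matching the area of the 1.5-sigma ellipse.
#'
#' @param spatial a unit-norm [spatial_filter()] with a dominant positive
#'   lobe (flip the sign of OFF-cell components first, or pass the spatial
#'   component as returned for an ON cell).
#' @param pixel_size_um pixel size of the (possibly upsampled) grid, um.
#' @param upsample_factor nearest-neighbour upsampling factor (1 = none;
#'   4 maps 30-um stimulus squares onto 7.5-um monitor pixels).
#' @return list: `rf` ([gaussian_rf()]), `filter` ([spatial_filter()] of
#'   normalization `"gaussian_fit"`), `converged` flag.
#' @export
fit_gaussian_rf <- function(spatial, pixel_size_um, upsample_factor = 1L) {
  w <- spatial$weights
  if (max(w) <= 0) stopf("spatial component needs a dominant positive lobe")
  up <- as.integer(upsample_factor)
  if (up > 1L) {
    w <- w[rep(seq_len(nrow(w)), each = up), rep(seq_len(ncol(w)), each = up)]
    pixel_size_um <- pixel_size_um / up
  }
  h <- nrow(w); wd <- ncol(w)
  rows <- matrix(seq_len(h), h, wd)
  cols <- matrix(seq_len(wd), h, wd, byrow = TRUE)
  # moment init from the positive part
  pos <- pmax(w, 0)
  msum <- sum(pos)
  cx0 <- sum(cols * pos) / msum
  cy0 <- sum(rows * pos) / msum
  sx0 <- sqrt(sum((cols - cx0)^2 * pos) / msum)
  sy0 <- sqrt(sum((rows - cy0)^2 * pos) / msum)
  par0 <- c(max(w), cx0, cy0, max(sx0, 0.5), max(sy0, 0.5), 0)
  obj <- function(p) {
    if (p[1] <= 0 || p[4] <= 0 || p[5] <= 0) return(1e12)
    sum((gauss2d(rows, cols, p[1], p[2], p[3], p[4], p[5], p[6]) - w)^2)
  }
  fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
  if (fit$convergence != 0) {
    fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-12))
    if (fit2$value <= fit$value) fit <- fit2
    if (fit$convergence != 0) {
      stopf("Gaussian RF fit did not converge (residual SS %.3g)", fit$value)
    }
  }
  p <- fit$par
  rf <- gaussian_rf(center = c(p[2], p[3]), sigma_x = p[4], sigma_y = p[5],
                    angle = p[6], amplitude = p[1],
                    pixel_size_um = pixel_size_um)
  surf <- gauss2d(rows, cols, p[1], p[2], p[3], p[4], p[5], p[6])
  # Mahalanobis distance in sigma units; zero beyond the 3-sigma ellipse
  ct <- cos(p[6]); st <- sin(p[6])
  xr <- (cols - p[2]) * ct + (rows - p[3]) * st
  yr <- -(cols - p[2]) * st + (rows - p[3]) * ct
  surf[(xr / p[4])^2 + (yr / p[5])^2 > 9] <- 0
  list(rf = rf,
       filter = spatial_filter(surf, origin = spatial$origin,
                               normalization = "gaussian_fit"),
       converged = TRUE)
}

#' Spike-train autocorrelogram
#'
#' Counts ordered spike pairs with lags in `[0, 75 ms)` at 0.5 ms
#' resolution (150 bins), excluding zero-lag self-pairs, and normalizes to
#' unit sum.
#'
#' @param spike_times_s spike times, seconds (>= 2 spikes).
#' @param bin_ms bin width, ms.
#' @param max_lag_ms maximum lag, ms.
#' @return list of class `rsc_autocorrelogram`: `values` (unit sum),
#'   `lag_ms` (bin left edges).
#' @export
autocorrelogram <- function(spike_times_s, bin_ms = 0.5, max_lag_ms = 75) {
  ts <- sort(as.numeric(spike_times_s))
  if (length(ts) < 2L) stopf("need at least 2 spikes")
  n_bins <- round(max_lag_ms / bin_ms)
  counts <- integer(n_bins)
  max_lag_s <- max_lag_ms / 1000
  for (i in seq_along(ts)) {
    j <- i + 1L
    while (j <= length(ts) && ts[j] - ts[i] < max_lag_s) {
      lag <- ts[j] - ts[i]
      b <- floor(lag / (bin_ms / 1000)) + 1L
      if (b >= 1L && b <= n_bins) counts[b] <- counts[b] + 1L
      j <- j + 1L
    }
  }
  if (sum(counts) == 0) {
    stopf("no spike pairs within %g ms", max_lag_ms)
  }
  structure(list(values = counts / sum(counts),
                 lag_ms = (seq_len(n_bins) - 1L) * bin_ms),
            class = "rsc_autocorrelogram")
}
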