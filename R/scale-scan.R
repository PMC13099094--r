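#' Standard smoothing-sigma grid
#'
#' The 20 standard deviations used for the spatial-scale scan: 0.8 to 6.4
#' in steps of 0.4, then 7.2, 8.0, 8.8, 10.4 and 12.0 pixels. With 7.5 um
#' pixels and the scale defined as three standard deviations of the filter,
#' these correspond to spatial scales of 18-270 um.
#'
#' @return numeric vector of 20 sigmas, pixels.
#' @export
scan_sigma_grid <- function() {
  c(seq(0.8, 6.4, by = 0.4), 7.2, 8.0, 8.8, 10.4, 12.0)
}

#' Scan spatial-smoothing scales with the SC model
#'
#' For each smoothing sigma, the temporally convolved stimulus is smoothed
#' with a circular Gaussian before computing the LSC channel (the Imean
#' computation is unaffected), and the SC model is refitted from scratch.
#' Relative performance is the ratio of test-set Pearson r at that sigma to
#' the unsmoothed baseline r. The scale of a smoothing sigma is defined as
#' three standard deviations of the filter (matching the receptive-field
#' size convention). The optimal scale is found by interpolating through
#' the three points bracketing the discrete maximum at 0.1 um resolution
#' (the unique parabola through three points; ties broken toward the
#' smaller scale).
#'
#' @param conv_train,counts_train training convolved stimulus and counts.
#' @param conv_test test-segment convolved stimulus.
#' @param psth_test trial-averaged test response (same bins as
#'   `conv_test`).
#' @param spatial `gaussian_fit` [spatial_filter()].
#' @param sigmas_px sigma grid, pixels (default [scan_sigma_grid()]).
#' @param trial_starts trial boundaries in the training segment.
#' @return list of class `rsc_scale_scan`: `sigmas_px`, `scales_um`,
#'   `rel_performance`, `r_baseline`, `r_per_scale`, `optimal_scale_um`,
#'   `optimal_ratio`, `interpolated` flag.
#' @export
scan_smoothing_scales <- function(conv_train, counts_train, conv_test,
                                  psth_test, spatial,
                                  sigmas_px = scan_sigma_grid(),
                                  trial_starts = 1L) {
  valid_test <- seq(conv_test$valid_from, dim(conv_test$h)[3])
  eval_fit <- function(ctr, cte) {
    fit <- fit_encoding_model("SC", ctr, spatial, counts_train,
                              trial_starts = trial_starts)
    pred <- predict_rate(fit, cte)
    evaluate_prediction(pred[valid_test], psth_test[valid_test])
  }
  r0 <- eval_fit(conv_train, conv_test)
  r_scale <- vapply(sigmas_px, function(sg) {
    smt <- smooth_lsc_conv(conv_train, sg)
    smte <- smooth_lsc_conv(conv_test, sg)
    eval_fit(smt, smte)
  }, numeric(1))
  rel <- r_scale / r0
  scales_um <- 3 * sigmas_px * conv_train$pixel_size_um
  k <- which.max(rel)                 # which.max takes the first (smallest
                                      # scale) on ties
  out <- list(sigmas_px = sigmas_px, scales_um = scales_um,
              rel_performance = rel, r_baseline = r0, r_per_scale = r_scale,
              interpolated = FALSE)
  if (length(sigmas_px) >= 3L && k > 1L && k < length(sigmas_px)) {
    idx <- (k - 1L):(k + 1L)
    fine <- seq(scales_um[k - 1L], scales_um[k + 1L], by = 0.1)
    co <- stats::lm.fit(cbind(1, scales_um[idx], scales_um[idx]^2),
                        rel[idx])$coefficients
    yy <- co[1] + co[2] * fine + co[3] * fine^2
    j <- which.max(yy)
    out$optimal_scale_um <- fine[j]
    out$optimal_ratio <- yy[j]
  } else {
    out$optimal_scale_um <- scales_um[k]
    out$optimal_ratio <- rel[k]
  }
  out$interpolated <- length(sigmas_px) >= 3L && k > 1L && k < length(sigmas_px)
  class(out) <- "rsc_scale_scan"
  out
}

# SC-model channels with smoothing applied to the LSC path only: returns a
# conv-like object carrying both the raw h (for Imean) and the smoothed h
# (for LSC); compute_imean_lsc dispatches on the attribute.
smooth_lsc_conv <- function(conv, sigma_px) {
  out <- spatial_smooth(conv, sigma_px)
  attr(out, "imean_h") <- conv$h
  out
}
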