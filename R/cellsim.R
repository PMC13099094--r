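#' Biphasic temporal kernel
#'
#' Difference of two gamma-shaped lobes, peaking near 50 ms, 30 taps at
#' 85 Hz, normalized to unit Euclidean norm and returned most-recent-first.
#' Any smooth biphasic kernel suffices for the recovery tests; this one
#' mimics the shape of empirically measured RGC temporal filters.
#'
#' @param n_taps filter length.
#' @param tap_rate_hz sampling rate, Hz.
#' @param peak_s time-to-peak of the positive lobe, seconds.
#' @param polarity `"ON"` (positive-going peak) or `"OFF"` (negated).
#' @param balanced if `TRUE`, rescale the second lobe so the taps sum to
#'   zero — a fully transient (parasol-like) filter with no response to
#'   sustained input; the default keeps a sustained component.
#' @return A [temporal_filter()].
#' @export
biphasic_kernel <- function(n_taps = 30L, tap_rate_hz = 85,
                            peak_s = 0.05, polarity = c("ON", "OFF"),
                            balanced = FALSE) {
  polarity <- match.arg(polarity)
  t_s <- (seq_len(n_taps) - 1) / tap_rate_hz     # lag of each tap
  gammaf <- function(t, k, theta) {
    ifelse(t <= 0 & k > 1, 0, t^(k - 1) * exp(-t / theta))
  }
  k1 <- 4; th1 <- peak_s / (k1 - 1)
  k2 <- 6; th2 <- 1.4 * peak_s / (k2 - 1)
  lobe1 <- gammaf(t_s, k1, th1) / max(gammaf(t_s, k1, th1))
  lobe2 <- gammaf(t_s, k2, th2) / max(gammaf(t_s, k2, th2))
  w2 <- if (balanced) sum(lobe1) / sum(lobe2) else 0.55
  v <- lobe1 - w2 * lobe2
  if (polarity == "OFF") v <- -v
  temporal_filter(v, tap_rate_hz, normalize = TRUE)
}

#' Construct a ground-truth model ganglion cell
#'
#' An LNLN cascade: Gaussian spatial subunits tiling a disc, each filter
#' normalized to unit Euclidean norm; a shared biphasic temporal kernel;
#' subunit outputs passed through a rectifier (`relu`) or left `linear`;
#' pooled with Gaussian-envelope weights (3 sigma of the envelope equals the
#' receptive-field diameter); and a softplus output nonlinearity. With a
#' `linear` subunit nonlinearity the cascade collapses exactly to an LN
#' cell. Used as ground truth for parameter-recovery and model-comparison
#' tests.
#'
#' @param layout `"grid"` or `"hex"` subunit tiling.
#' @param n_subunits number of subunits (>= 1).
#' @param subunit_diameter_um subunit diameter (3 sigma of the subunit
#'   Gaussian, matching the receptive-field size convention), um; must be
#'   smaller than `rf_diameter_um`.
#' @param rf_diameter_um receptive-field diameter, um.
#' @param pixel_size_um stimulus pixel size, um.
#' @param subunit_nl `"relu"` or `"linear"`.
#' @param polarity `"ON"` or `"OFF"`.
#' @param center `(row, col)` of the RF center in stimulus pixels; defaults
#'   to mid-field when the cell is evaluated.
#' @param out_nl softplus output parameters `c(a, b, c)`; `a` is rescaled by
#'   [cell_rate()] calibration.
#' @param mean_rate_target_hz target mean rate under binary white noise, Hz.
#' @param kernel optional [temporal_filter()] overriding the default
#'   biphasic kernel (OFF polarity still negates it).
#' @param seed RNG seed (small random rotation of the hex layout).
#' @return An object of class `rsc_gt_cell`.
#' @export
make_model_cell <- function(layout = c("hex", "grid"), n_subunits = 7L,
                            subunit_diameter_um = 30,
                            rf_diameter_um = 90,
                            pixel_size_um = 30,
                            subunit_nl = c("relu", "linear"),
                            polarity = c("ON", "OFF"),
                            center = NULL,
                            out_nl = c(a = 1, b = 2.5, c = -2),
                            mean_rate_target_hz = 5,
                            kernel = NULL,
                            seed = NULL) {
  layout <- match.arg(layout)
  subunit_nl <- match.arg(subunit_nl)
  polarity <- match.arg(polarity)
  if (n_subunits < 1L) stopf("need at least one subunit")
  if (subunit_diameter_um >= rf_diameter_um) {
    stopf("`subunit_diameter_um` must be smaller than `rf_diameter_um`")
  }
  # size conventions follow the receptive-field definition: a circular
  # profile of diameter D corresponds to 3 standard deviations (the 1.5-sigma
  # contour), so sigma = D / 3
  rf_radius_px <- rf_diameter_um / 2 / pixel_size_um
  su_sigma_px <- subunit_diameter_um / pixel_size_um / 3

  # subunit centers tiling a disc of rf_diameter
  centers <- if (n_subunits == 1L) {
    matrix(0, 1L, 2L)
  } else if (layout == "hex") {
    pts <- matrix(0, 1L, 2L)
    ring <- 1L
    spacing <- subunit_diameter_um / pixel_size_um * 0.9
    while (nrow(pts) < n_subunits) {
      ang <- seq(0, 2 * pi, length.out = 6L * ring + 1L)[-(6L * ring + 1L)]
      pts <- rbind(pts, spacing * ring * cbind(cos(ang), sin(ang)))
      ring <- ring + 1L
    }
    pts[seq_len(n_subunits), , drop = FALSE]
  } else {
    side <- ceiling(sqrt(n_subunits))
    spacing <- subunit_diameter_um / pixel_size_um * 0.9
    g <- expand.grid(x = seq_len(side), y = seq_len(side))
    g <- sweep(as.matrix(g), 2, (side + 1) / 2)
    g <- g[order(rowSums(g^2)), , drop = FALSE] * spacing
    g[seq_len(n_subunits), , drop = FALSE]
  }
  # keep all centers inside the disc
  r <- sqrt(rowSums(centers^2))
  if (any(r > rf_radius_px)) {
    centers <- centers * min(1, rf_radius_px / max(r) * 0.95)
  }
  # snap centers to the stimulus-square lattice: a subunit pools whole
  # stimulus squares (the checkerboard square is the resolution unit), and
  # fractional offsets would smear pixel-scale subunits across squares
  centers <- round(centers)
  centers <- centers[!duplicated(centers), , drop = FALSE]
  if (nrow(centers) < n_subunits) {
    n_subunits <- nrow(centers)
  }
  # Gaussian pooling envelope, 3 sigma = rf diameter
  env_sigma <- 2 * rf_radius_px / 3
  w <- exp(-rowSums(centers^2) / (2 * max(env_sigma, 1e-9)^2))
  w <- w / sum(w)

  structure(
    list(layout = layout,
         subunit_centers = centers,          # (x, y) px relative to RF center
         subunit_sigma_px = su_sigma_px,
         subunit_weights = w,
         temporal_kernel = kernel %||% biphasic_kernel(polarity = "ON"),
         subunit_nl = subunit_nl,
         out_nl = out_nl,
         polarity = polarity,
         center = center,
         rf_diameter_um = rf_diameter_um,
         subunit_diameter_um = subunit_diameter_um,
         pixel_size_um = pixel_size_um,
         mean_rate_target_hz = mean_rate_target_hz,
         rate_scale = NULL),
    class = "rsc_gt_cell")
}

# Subunit filter bank for a cell on a given pixel grid: npix x n matrix of
# unit-norm Gaussian filters (OFF polarity carried by the temporal kernel).
cell_filter_bank <- function(cell, height, width, center_rc = NULL) {
  if (is.null(center_rc)) {
    center_rc <- cell$center %||%
      c(floor((height + 1) / 2), floor((width + 1) / 2))
  }
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  n <- nrow(cell$subunit_centers)
  Q <- matrix(0, height * width, n)
  for (i in seq_len(n)) {
    cx <- center_rc[2] + cell$subunit_centers[i, 1]
    cy <- center_rc[1] + cell$subunit_centers[i, 2]
    g <- exp(-((cols - cx)^2 + (rows - cy)^2) /
               (2 * cell$subunit_sigma_px^2))
    Q[, i] <- g / sqrt(sum(g^2))
  }
  Q
}

#' Expected firing rate of a ground-truth cell
#'
#' `rate(t) = a * softplus(b * sum_i w_i nl(q_i . h_t) + c)` where `h` is
#' the stimulus convolved with the cell's temporal kernel (OFF cells negate
#' the kernel), `q_i` are unit-norm Gaussian subunit filters, and `nl` is
#' ReLU or identity. The drive is standardized by its own SD and the output
#' scale `a` is calibrated so the mean rate over the given stimulus equals
#' `mean_rate_target_hz` (the calibration is stored in the returned
#' attribute and can be reused via `rate_scale`).
#'
#' @param cell an `rsc_gt_cell`.
#' @param stim an [stimulus()] covering the cell's spatial extent.
#' @param rate_scale optional `(drive_sd, a_scale)` from a previous
#'   calibration, to evaluate test stimuli with training calibration.
#' @return numeric rate series, Hz; attributes `rate_scale` and
#'   `valid_from` (first index with full temporal-filter support).
#' @export
cell_rate <- function(cell, stim, rate_scale = NULL) {
  d <- dim(stim$frames)
  kern <- cell$temporal_kernel
  if (cell$polarity == "OFF") kern$taps <- -kern$taps
  conv <- temporal_convolve(stim, kern)
  Q <- cell_filter_bank(cell, d[1], d[2])
  H <- conv_matrix(conv)                       # npix x T
  drive <- crossprod(Q, H)                     # n_subunits x T
  if (cell$subunit_nl == "relu") drive <- pmax(drive, 0)
  pooled <- as.numeric(crossprod(cell$subunit_weights, drive))
  valid <- seq(conv$valid_from, length(pooled))
  if (is.null(rate_scale)) {
    drive_sd <- stats::sd(pooled[valid])
    if (drive_sd == 0) drive_sd <- 1
  } else {
    drive_sd <- rate_scale[1]
  }
  a <- cell$out_nl[["a"]]; b <- cell$out_nl[["b"]]; cc <- cell$out_nl[["c"]]
  raw <- softplus(pooled / drive_sd, a = a, b = b, c = cc)
  if (is.null(rate_scale)) {
    a_scale <- cell$mean_rate_target_hz / mean(raw[valid])
  } else {
    a_scale <- rate_scale[2]
  }
  rate <- raw * a_scale
  attr(rate, "rate_scale") <- c(drive_sd, a_scale)
  attr(rate, "valid_from") <- conv$valid_from
  rate
}

#' Sample Poisson spike counts from a rate series
#'
#' Counts per bin are i.i.d. Poisson across trials with mean
#' `rate / frame_rate_hz` (no refractoriness), matching the Poisson
#' likelihood used for model fitting.
#'
#' @param rate rate series, Hz.
#' @param frame_rate_hz bin rate, Hz.
#' @param n_trials number of independent trials.
#' @param seed RNG seed.
#' @return An [spike_train()] with `n_trials` rows.
#' @export
sample_spikes <- function(rate, frame_rate_hz = 85, n_trials = 1L,
                          seed = NULL) {
  lambda <- rate / frame_rate_hz
  if (any(lambda < 0)) stopf("negative rates are impossible under softplus")
  with_seed(seed, {
    counts <- matrix(stats::rpois(n_trials * length(lambda),
                                  rep(lambda, each = n_trials)),
                     nrow = n_trials)
    spike_train(counts, frame_rate_hz)
  })
}
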