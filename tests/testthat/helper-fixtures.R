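# Shared fixture builders. Everything is generated in code at test time; no
# stored data files.

# A gaussian_fit spatial filter on an n x n grid (circular, sigma px).
mk_gauss_filter <- function(n = 12, sigma = 2, cx = (n + 1) / 2,
                            cy = (n + 1) / 2) {
  rows <- matrix(seq_len(n), n, n)
  cols <- t(rows)
  g <- exp(-((cols - cx)^2 + (rows - cy)^2) / (2 * sigma^2))
  g[((cols - cx)^2 + (rows - cy)^2) > (3 * sigma)^2] <- 0
  spatial_filter(g, normalization = "gaussian_fit")
}

# Full receptive-field pipeline on simulated responses: STA, components,
# Gaussian fit, and the conv crop matching the fitted filter window.
rf_pipeline <- function(stim, spikes, crop_squares = NULL) {
  sta <- compute_sta(stim, spikes)
  crop_squares <- crop_squares %||% min(dim(stim)[1:2])
  comps <- extract_components(sta, crop_squares = crop_squares)
  sp <- comps$spatial
  if (max(sp$weights) < -min(sp$weights)) sp$weights <- -sp$weights
  gfit <- fit_gaussian_rf(sp, stim$pixel_size_um)
  o <- sp$origin
  wd <- dim(gfit$filter$weights)
  rows <- o[1]:(o[1] + wd[1] - 1L)
  cols <- o[2]:(o[2] + wd[2] - 1L)
  list(sta = sta, comps = comps, gfit = gfit, rows = rows, cols = cols,
       crop = function(conv) retinasc:::crop_conv(conv, rows, cols))
}

# Planted logical-OR cell on an 8 x 8 crop: S sharply rectified subunits.
# Returns the convolved stimulus, binary responses and the planted filters.
plant_or_cell <- function(S, n_seconds = 240, gain = 16,
                          seed_stim = 21, seed_resp = 22) {
  wn <- gen_white_noise(round(n_seconds * 85), c(8, 8), pixel_size_um = 30,
                        seed = seed_stim)
  conv <- temporal_convolve(wn, biphasic_kernel())
  H <- retinasc:::conv_matrix(conv)
  mkq <- function(cx, cy, sig = 0.8) {
    rows <- matrix(1:8, 8, 8)
    cols <- t(rows)
    g <- exp(-((cols - cx)^2 + (rows - cy)^2) / (2 * sig^2))
    as.numeric(g / sqrt(sum(g^2)))
  }
  ctrs <- list(c(3, 3), c(6, 6), c(3, 6), c(6, 3))[seq_len(S)]
  Qp <- do.call(cbind, lapply(ctrs, function(cc) mkq(cc[1], cc[2])))
  drv <- crossprod(Qp, H) * gain
  G <- 1 / (1 + exp(-(-1.5 * gain + drv)))
  P <- 1 - apply(1 - G, 2, prod)
  y <- withr::with_seed(seed_resp, stats::rbinom(length(P), 1, P))
  y[1:29] <- 0L
  list(conv = conv, y = y, Qp = Qp, P = P)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
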