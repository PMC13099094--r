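#' Temporally convolve a stimulus with a filter
#'
#' Causal per-pixel convolution
#' `h_st = sum_{tau = 0}^{M-1} z_{s, t - tau} v_tau`. Bins `t < M` (1-based)
#' lack full filter support and are flagged via `valid_from`.
#'
#' @param stim an [stimulus()].
#' @param filter a [temporal_filter()] (taps most-recent-first), with
#'   length at most the number of frames.
#' @return list of class `rsc_conv`: `h` (`H x W x T` array), `valid_from`
#'   (first 1-based index with full support, = M), plus stimulus metadata.
#' @export
temporal_convolve <- function(stim, filter) {
  v <- filter$taps
  M <- length(v)
  Z <- stim_matrix(stim)
  Tn <- ncol(Z)
  if (M > Tn) stopf("filter length %d exceeds %d frames", M, Tn)
  # causal FIR along time for every pixel at once (C-level)
  Ht <- stats::filter(t(Z), v, method = "convolution", sides = 1L)
  H <- t(Ht)
  if (M > 1L) {
    # leading bins lack full support (flagged via valid_from); fill them
    # with the partial sums over the available past
    for (t in 1:(M - 1L)) {
      taps <- v[1:t]
      H[, t] <- Z[, t:1, drop = FALSE] %*% taps
    }
  }
  d <- dim(stim$frames)
  structure(list(h = array(H, dim = d), valid_from = M,
                 frame_rate_hz = stim$frame_rate_hz,
                 pixel_size_um = stim$pixel_size_um),
            class = "rsc_conv")
}

conv_matrix <- function(conv) {
  d <- dim(conv$h)
  m <- conv$h
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

# Crop a convolved stimulus to a row/col window (1-based, inclusive).
crop_conv <- function(conv, rows, cols) {
  structure(list(h = conv$h[rows, cols, , drop = FALSE],
                 valid_from = conv$valid_from,
                 frame_rate_hz = conv$frame_rate_hz,
                 pixel_size_um = conv$pixel_size_um),
            class = "rsc_conv")
}

#' Weighted mean intensity and local spatial contrast
#'
#' From the temporally convolved stimulus `h_st` and a non-negative spatial
#' filter `u_s` (the Gaussian RF fit):
#' `Imean_t = sum_s u_s h_st / sum_s u_s` and
#' `LSC_t = sqrt(sum_s u_s (h_st - Imean_t)^2 / sum_s u_s)`, the weighted
#' standard deviation of pixel intensities inside the receptive field.
#'
#' @param conv an `rsc_conv` from [temporal_convolve()]. Its spatial
#'   dimensions must match the filter (crop the convolved stimulus to the
#'   filter's window first if needed).
#' @param spatial a `gaussian_fit` [spatial_filter()] (weights >= 0, not
#'   all zero).
#' @return list: `imean`, `lsc` (numeric series of length T),
#'   `valid_from`.
#' @export
compute_imean_lsc <- function(conv, spatial) {
  u <- as.numeric(spatial$weights)
  su <- sum(u)
  if (su <= 0) stopf("spatial filter weights sum to zero")
  if (any(u < 0)) stopf("Imean/LSC require non-negative (gaussian_fit) weights")
  H <- conv_matrix(conv)
  if (nrow(H) != length(u)) {
    stopf("spatial filter (%d px) does not match convolved stimulus (%d px)",
          length(u), nrow(H))
  }
  # LSC is always computed from conv$h (smoothed, if a scale-scan smoothing
  # was applied), around its own weighted mean; the reported Imean channel
  # comes from the unsmoothed field when one is attached.
  wmean <- as.numeric(crossprod(u, H)) / su
  ex2 <- as.numeric(crossprod(u, H^2)) / su
  lsc <- sqrt(pmax(ex2 - wmean^2, 0))
  raw <- attr(conv, "imean_h")
  imean <- if (is.null(raw)) {
    wmean
  } else {
    dim(raw) <- c(nrow(H), ncol(H))
    as.numeric(crossprod(u, raw)) / su
  }
  list(imean = imean, lsc = lsc, valid_from = conv$valid_from)
}

#' Parameterized softplus nonlinearity
#'
#' `f(x) = a * log(1 + exp(b * x + c))`, evaluated in an overflow-safe form
#' (`log1p(exp(y))` for y <= 0 and `y + log1p(exp(-y))` otherwise), stable
#' for `|b x + c|` up to ~1e3 and monotone nondecreasing in `x` for
#' `b > 0`.
#'
#' @param x input (vectorized).
#' @param a,b,c softplus parameters; `a >= 0`.
#' @return `f(x)`, same shape as `x`.
#' @export
softplus <- function(x, a = 1, b = 1, c = 0) {
  if (a < 0) stopf("`a` must be >= 0")
  y <- b * x + c
  a * softplus1(y)
}

# log(1 + exp(y)), overflow safe
softplus1 <- function(y) {
  out <- numeric(length(y))
  pos <- y > 0
  out[pos] <- y[pos] + log1p(exp(-y[pos]))
  out[!pos] <- log1p(exp(y[!pos]))
  dim(out) <- dim(y)
  out
}

sigmoid <- function(y) 1 / (1 + exp(-y))

#' Poisson negative log-likelihood
#'
#' `L = -sum_t n_t log(lambda_t) + sum_t lambda_t`, with the
#' parameter-independent `log(n_t!)` term dropped.
#'
#' @param counts observed spike counts `n_t`.
#' @param rates predicted expected counts `lambda_t` per bin; must be
#'   strictly positive wherever `n_t > 0`.
#' @return the scalar negative log-likelihood.
#' @export
poisson_nll <- function(counts, rates) {
  if (length(counts) != length(rates)) stopf("length mismatch")
  if (any(rates < 0)) stopf("negative rates")
  if (any(rates == 0 & counts > 0)) {
    stopf("zero predicted rate with observed spikes: likelihood is -Inf")
  }
  pos <- counts > 0
  -sum(counts[pos] * log(rates[pos])) + sum(rates)
}

# ---- LN / SC fitting -------------------------------------------------------

zscore_apply <- function(x, stats) (x - stats[1]) / stats[2]

# Align a convolved stimulus with a spatial filter's crop window: when the
# spatial dimensions disagree, crop the stimulus using the filter's origin.
conv_for_filter <- function(conv, spatial) {
  d <- dim(conv$h)
  wd <- dim(spatial$weights)
  if (d[1] == wd[1] && d[2] == wd[2]) return(conv)
  o <- spatial$origin
  if (o[1] < 1 || o[2] < 1 || o[1] + wd[1] - 1L > d[1] ||
      o[2] + wd[2] - 1L > d[2]) {
    stopf("spatial filter window (%dx%d at %d,%d) does not fit the %dx%d stimulus",
          wd[1], wd[2], o[1], o[2], d[1], d[2])
  }
  rows <- o[1]:(o[1] + wd[1] - 1L)
  cols <- o[2]:(o[2] + wd[2] - 1L)
  out <- crop_conv(conv, rows, cols)
  raw <- attr(conv, "imean_h")
  if (!is.null(raw)) {
    dim(raw) <- d
    attr(out, "imean_h") <- raw[rows, cols, , drop = FALSE]
  }
  out
}

ln_sc_channels <- function(conv, spatial, model) {
  conv <- conv_for_filter(conv, spatial)
  if (model == "LN") {
    # Eq. 3 activation with the Gaussian-fit filter; the filter's overall
    # scale is absorbed by Z-scoring
    u <- as.numeric(spatial$weights)
    x <- as.numeric(crossprod(u, conv_matrix(conv)))
    list(imean = x, lsc = NULL)
  } else {
    il <- compute_imean_lsc(conv, spatial)
    list(imean = il$imean, lsc = il$lsc)
  }
}

#' Fit an LN or SC encoding model by Poisson maximum likelihood
#'
#' The LN model predicts `lambda_t = f(z(x_t))` with `x_t` the spatially
#' filtered convolved stimulus and `f` the softplus of [softplus()]; the SC
#' model predicts `lambda_t = f(z(Imean_t) + w z(LSC_t))`, adding a local
#' spatial contrast channel with weight `w` (`w = 0` reduces the SC model
#' to an LN model). Channels are Z-scored by their training mean/SD, which
#' are stored in the returned parameters and reused at prediction time.
#' Optimization is L-BFGS-B with analytic gradients from inits
#' `a = max(n_t)`, `b = 1`, `c = -2` (and `w = 0`), with bound `a >= 0`.
#'
#' @param model `"LN"` or `"SC"`.
#' @param conv training-segment `rsc_conv`, cropped to the filter window.
#' @param spatial `gaussian_fit` [spatial_filter()] over the same window.
#' @param counts training spike counts per bin (vector, aligned to the
#'   convolved frames).
#' @param trial_starts 1-based bin indices of trial boundaries; the first
#'   `M - 1` bins after each are excluded from the likelihood.
#' @return list of class `rsc_encoding_model`: `model`, `params`
#'   (`a, b, c[, w]`), `zscore_stats` (per-channel `(mean, sd)`),
#'   `spatial`, `nll`, `convergence`.
#' @export
fit_encoding_model <- function(model = c("LN", "SC"), conv, spatial, counts,
                               trial_starts = 1L) {
  model <- match.arg(model)
  ch <- ln_sc_channels(conv, spatial, model)
  Tn <- length(ch$imean)
  if (length(counts) != Tn) stopf("counts/stimulus length mismatch")
  valid <- rep(TRUE, Tn)
  for (s in trial_starts) valid[s:min(Tn, s + conv$valid_from - 2L)] <- FALSE
  n <- as.numeric(counts[valid])
  zs <- list(imean = c(mean(ch$imean[valid]), stats::sd(ch$imean[valid])))
  if (zs$imean[2] <= 0) stopf("degenerate (constant) Imean channel")
  x1 <- zscore_apply(ch$imean[valid], zs$imean)
  if (model == "SC") {
    zs$lsc <- c(mean(ch$lsc[valid]), stats::sd(ch$lsc[valid]))
    if (zs$lsc[2] <= 0) stopf("degenerate (constant) LSC channel")
    x2 <- zscore_apply(ch$lsc[valid], zs$lsc)
  }

  nll_grad <- function(p) {
    a <- p[1]; b <- p[2]; cc <- p[3]
    lin <- if (model == "SC") x1 + p[4] * x2 else x1
    y <- b * lin + cc
    sp <- softplus1(y)
    lam <- a * sp
    bad <- lam <= 0 & n > 0
    if (any(bad)) lam[bad] <- 1e-300
    nll <- -sum(n[n > 0] * log(lam[n > 0])) + sum(lam)
    sig <- sigmoid(y)
    # d nll / d lam = 1 - n / lam
    dlam <- 1 - n / pmax(lam, 1e-300)
    ga <- sum(dlam * sp)
    gb <- a * sum(dlam * sig * lin)
    gc <- a * sum(dlam * sig)
    gr <- c(ga, gb, gc)
    if (model == "SC") gr <- c(gr, a * b * sum(dlam * sig * x2))
    attr(nll, "gradient") <- gr
    nll
  }
  p0 <- c(max(n), 1.0, -2.0)
  lower <- c(0, -Inf, -Inf)
  if (model == "SC") { p0 <- c(p0, 0.0); lower <- c(lower, -Inf) }
  fit <- stats::optim(p0, fn = function(p) as.numeric(nll_grad(p)),
                      gr = function(p) attr(nll_grad(p), "gradient"),
                      method = "L-BFGS-B", lower = lower,
                      control = list(maxit = 500, factr = 1e4))
  if (!fit$convergence %in% c(0L, 1L)) {
    stopf("L-BFGS-B failed (code %d): %s", fit$convergence, fit$message)
  }
  params <- c(a = fit$par[1], b = fit$par[2], c = fit$par[3])
  if (model == "SC") params <- c(params, w = fit$par[4])
  structure(list(model = model, params = params, zscore_stats = zs,
                 spatial = spatial, nll = fit$value,
                 convergence = fit$convergence),
            class = "rsc_encoding_model")
}

#' Predict firing rates from a fitted LN or SC model
#'
#' Applies the stored training Z-scoring statistics to the model channels
#' and evaluates the softplus output; rates are non-negative everywhere.
#'
#' @param fit an `rsc_encoding_model` from [fit_encoding_model()].
#' @param conv an `rsc_conv` over the same spatial window as the training
#'   data.
#' @return numeric rate series (expected counts per bin) with attribute
#'   `valid_from`.
#' @export
predict_rate <- function(fit, conv) {
  if (is.null(fit$zscore_stats)) {
    stopf("model carries no Z-scoring statistics; refusing to predict")
  }
  ch <- ln_sc_channels(conv, fit$spatial, fit$model)
  x <- zscore_apply(ch$imean, fit$zscore_stats$imean)
  if (fit$model == "SC") {
    x <- x + fit$params[["w"]] * zscore_apply(ch$lsc, fit$zscore_stats$lsc)
  }
  rate <- softplus(x, a = fit$params[["a"]], b = fit$params[["b"]],
                   c = fit$params[["c"]])
  attr(rate, "valid_from") <- conv$valid_from
  rate
}

#' Response reliability metrics
#'
#' Fraction of explainable variance
#' `FEV = (sigma^2_total - sigma^2_noise) / sigma^2_total`, where the total
#' variance is taken over all bins and trials and the noise variance is the
#' across-trial variance per bin averaged over bins; and the symmetrized
#' coefficient of determination, averaging `R^2` of the odd-trial mean
#' predicting the even-trial mean and vice versa. Cells with `FEV < 0.15`
#' or negative `R^2` are flagged for exclusion.
#'
#' @param counts trials x bins matrix of test-segment spike counts
#'   (>= 2 trials).
#' @param fev_threshold exclusion threshold on FEV.
#' @return list: `fev`, `r2_sym`, `excluded`.
#' @export
reliability_metrics <- function(counts, fev_threshold = 0.15) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L) stopf("need at least 2 trials")
  var_total <- stats::var(as.numeric(counts))
  var_noise <- mean(apply(counts, 2L, stats::var))
  fev <- (var_total - var_noise) / var_total
  odd <- colMeans(counts[seq(1, nrow(counts), by = 2), , drop = FALSE])
  even <- colMeans(counts[seq(2, nrow(counts), by = 2), , drop = FALSE])
  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  r2_sym <- (r2(even, odd) + r2(odd, even)) / 2
  list(fev = fev, r2_sym = r2_sym,
       excluded = fev < fev_threshold || r2_sym < 0)
}

#' Evaluate a prediction against a trial-averaged PSTH
#'
#' Standard Pearson correlation coefficient between the predicted rate and
#' the across-trial average response.
#'
#' @param pred predicted rate series.
#' @param psth trial-averaged response, same length.
#' @return Pearson r.
#' @export
evaluate_prediction <- function(pred, psth) {
  if (length(pred) != length(psth)) stopf("length mismatch")
  if (stats::sd(pred) == 0 || stats::sd(psth) == 0) {
    stopf("zero-variance input: correlation undefined")
  }
  stats::cor(as.numeric(pred), as.numeric(psth))
}

#' Smooth convolved-stimulus frames with a circular Gaussian
#'
#' Separable Gaussian smoothing with kernel support truncated at six
#' standard deviations diameter (radius `floor(3 sigma + 0.5)`), reflect
#' boundary handling, kernel normalized to unit sum so the spatial DC is
#' preserved.
#'
#' @param frames `H x W x T` array (or an `rsc_conv`, smoothed in place).
#' @param sigma_px Gaussian SD in pixels (> 0).
#' @return object of the same type, smoothed frame by frame.
#' @export
spatial_smooth <- function(frames, sigma_px) {
  if (sigma_px <= 0) stopf("`sigma_px` must be > 0")
  if (inherits(frames, "rsc_conv")) {
    out <- frames
    out$h <- spatial_smooth(frames$h, sigma_px)
    return(out)
  }
  r <- max(1L, floor(3 * sigma_px + 0.5))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  d <- dim(frames)
  Kh <- smooth_matrix(d[1], k, r)
  Kw <- if (d[2] == d[1]) Kh else smooth_matrix(d[2], k, r)
  # separable smoothing as two dense matmuls across all frames at once
  m <- matrix(frames, d[1], d[2] * d[3])
  tmp <- array(Kh %*% m, dim = d)
  tp <- aperm(tmp, c(2L, 1L, 3L))
  sm <- Kw %*% matrix(tp, d[2], d[1] * d[3])
  aperm(array(sm, dim = c(d[2], d[1], d[3])), c(2L, 1L, 3L))
}

# n x n banded 1D smoothing operator with reflect ('symmetric') boundary
# handling folded into the band weights
smooth_matrix <- function(n, k, r) {
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- i + seq(-r, r)
    # reflect indices: ... 2 1 | 1 2 ... n | n n-1 ...
    src <- ifelse(src < 1L, 1L - src, src)
    src <- ifelse(src > n, 2L * n + 1L - src, src)
    src <- pmin(pmax(src, 1L), n)      # guard for kernels wider than 2n
    for (j in seq_along(src)) K[i, src[j]] <- K[i, src[j]] + k[j]
  }
  K
}
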