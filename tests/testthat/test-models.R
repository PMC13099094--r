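# models: convolution, Imean/LSC, softplus, Poisson likelihood, fitting,
# reliability, smoothing

test_that("temporal convolution matches the brute-force definition", {
  stim <- gen_white_noise(40, c(5, 6), pixel_size_um = 30, seed = 21)
  tf <- temporal_filter(c(0.5, 0.3, -0.2), 85)
  conv <- temporal_convolve(stim, tf)
  expect_equal(conv$valid_from, 3L)
  # brute-force triple loop
  for (t in c(3, 17, 40)) {
    direct <- tf$taps[1] * stim$frames[, , t] +
      tf$taps[2] * stim$frames[, , t - 1] + tf$taps[3] * stim$frames[, , t - 2]
    expect_equal(conv$h[, , t], direct, tolerance = 1e-12)
  }
  # delta filter is the identity
  d <- temporal_convolve(stim, temporal_filter(c(1, 0, 0), 85))
  expect_equal(d$h[, , 3:40], stim$frames[, , 3:40])
  # constant stimulus: h = z * sum(v)
  cst <- stimulus(array(0.7, c(3, 3, 10)), 85, 30)
  cc <- temporal_convolve(cst, tf)
  expect_equal(as.numeric(cc$h[1, 1, 3:10]), rep(0.7 * sum(tf$taps), 8))
  expect_error(temporal_convolve(stimulus(array(1, c(2, 2, 2)), 85, 30),
                                 temporal_filter(rep(1, 5), 85)), "exceeds")
})

test_that("Imean and LSC match the weighted-moment definitions", {
  stim <- gen_white_noise(30, c(5, 6), pixel_size_um = 30, seed = 22)
  tf <- temporal_filter(c(0.6, 0.3, 0.1), 85)
  conv <- temporal_convolve(stim, tf)
  set.seed(23)
  u <- matrix(runif(30), 5, 6)
  il <- compute_imean_lsc(conv, spatial_filter(u, normalization = "gaussian_fit"))
  for (t in c(5, 18, 30)) {
    im <- sum(u * conv$h[, , t]) / sum(u)
    ls <- sqrt(sum(u * (conv$h[, , t] - im)^2) / sum(u))
    expect_equal(il$imean[t], im, tolerance = 1e-12)
    expect_equal(il$lsc[t], ls, tolerance = 1e-12)
  }
  # two-pixel frame (+1, -1) with equal weights: Imean 0, LSC 1
  c2 <- structure(list(h = array(c(1, -1), c(1, 2, 1)), valid_from = 1,
                       frame_rate_hz = 85, pixel_size_um = 30),
                  class = "rsc_conv")
  il2 <- compute_imean_lsc(c2, spatial_filter(matrix(1, 1, 2),
                                              normalization = "gaussian_fit"))
  expect_equal(il2$imean, 0)
  expect_equal(il2$lsc, 1)
  # uniform frame: LSC = 0
  c3 <- structure(list(h = array(0.4, c(2, 2, 1)), valid_from = 1,
                       frame_rate_hz = 85, pixel_size_um = 30),
                  class = "rsc_conv")
  il3 <- compute_imean_lsc(c3, spatial_filter(matrix(1, 2, 2),
                                              normalization = "gaussian_fit"))
  expect_equal(il3$imean, 0.4)
  expect_equal(il3$lsc, 0)
  expect_error(compute_imean_lsc(c3, structure(
    list(weights = matrix(0, 2, 2), normalization = "gaussian_fit"),
    class = "rsc_spatial_filter")), "zero")
})

test_that("softplus is correct, stable and differentiable", {
  expect_equal(softplus(0, a = 2, b = 1, c = 0), 2 * log(2))
  expect_equal(softplus(3, a = 1.5, b = 2, c = -1),
               1.5 * log1p(exp(5)))
  # no underflow warnings deep in the rectified regime
  expect_silent(v <- softplus(-700, a = 1, b = 1, c = 0))
  expect_equal(v, 0)
  expect_equal(softplus(1000, a = 1, b = 1, c = 0), 1000)
  # derivative vs central finite differences
  f <- function(x) softplus(x, a = 1.3, b = 2.1, c = -0.7)
  for (x0 in c(-3, 0, 2)) {
    num <- (f(x0 + 1e-6) - f(x0 - 1e-6)) / 2e-6
    ana <- 1.3 * 2.1 * retinasc:::sigmoid(2.1 * x0 - 0.7)
    expect_lt(abs(num - ana) / abs(ana), 1e-6)
  }
  expect_error(softplus(1, a = -1), "a")
})

test_that("poisson_nll matches the dropped-constant formula", {
  expect_equal(poisson_nll(c(1, 2), c(1, 2)),
               -(1 * log(1) + 2 * log(2)) + 3)
  expect_equal(poisson_nll(rep(0, 4), c(1, 2, 3, 4)), 10)
  # n = lambda is the elementwise stationary point
  lam <- c(0.5, 1, 2)
  eps <- 1e-6
  for (i in 1:3) {
    lp <- lam; lp[i] <- lp[i] + eps
    lm <- lam; lm[i] <- lm[i] - eps
    g <- (poisson_nll(lam, lp) - poisson_nll(lam, lm)) / (2 * eps)
    expect_lt(abs(g), 1e-6)
  }
  expect_error(poisson_nll(c(1, 0), c(0, 1)), "likelihood")
})

test_that("LN/SC predictions obey the reduction and scaling contracts", {
  stim <- gen_white_noise(3000, c(8, 8), pixel_size_um = 30, seed = 24)
  conv <- temporal_convolve(stim, biphasic_kernel())
  sp <- mk_gauss_filter(8, 1.5)
  il <- compute_imean_lsc(conv, sp)
  lam <- softplus(scale(il$imean)[, 1], a = 0.1, b = 2, c = -1)
  counts <- withr::with_seed(25, rpois(length(lam), lam))
  counts[1:29] <- 0
  fit_sc <- fit_encoding_model("SC", conv, sp, counts)
  # w = 0 reduces the SC prediction to the LN prediction on z(Imean)
  fit0 <- fit_sc
  fit0$params[["w"]] <- 0
  fit_ln <- fit_sc
  fit_ln$model <- "LN"
  fit_ln$params <- fit_sc$params[c("a", "b", "c")]
  p_sc0 <- predict_rate(fit0, conv)
  # LN uses the raw filter projection; rescale its z-stats to compare
  x_ln <- as.numeric(crossprod(as.numeric(sp$weights),
                               retinasc:::conv_matrix(conv)))
  fit_ln$zscore_stats <- list(imean = c(mean(x_ln[30:3000]),
                                        sd(x_ln[30:3000])))
  p_ln <- predict_rate(fit_ln, conv)
  expect_equal(cor(p_sc0[30:3000], p_ln[30:3000]), 1, tolerance = 1e-9)
  # doubling a doubles the rate pointwise
  fit2 <- fit_sc
  fit2$params[["a"]] <- 2 * fit_sc$params[["a"]]
  expect_equal(as.numeric(predict_rate(fit2, conv)),
               2 * as.numeric(predict_rate(fit_sc, conv)))
  expect_true(all(predict_rate(fit_sc, conv) >= 0))
  # prediction without z-scoring stats refuses to run
  broken <- fit_sc
  broken$zscore_stats <- NULL
  expect_error(predict_rate(broken, conv), "Z-scoring")
  # refitting identical data is deterministic
  fit_b <- fit_encoding_model("SC", conv, sp, counts)
  expect_identical(fit_sc$params, fit_b$params)
})

test_that("SC nests LN in test performance", {
  # property: fitted SC test r >= fitted LN test r - 0.02, any dataset
  stim <- gen_white_noise(6000, c(8, 8), pixel_size_um = 30, seed = 26)
  conv <- temporal_convolve(stim, biphasic_kernel())
  sp <- mk_gauss_filter(8, 1.5)
  il <- compute_imean_lsc(conv, sp)
  vi <- 30:6000
  for (w_true in c(0, 0.5)) {
    z <- function(x) (x - mean(x[vi])) / sd(x[vi])
    lam <- softplus(z(il$imean) + w_true * z(il$lsc), a = 0.15, b = 2.5,
                    c = -2)
    counts <- withr::with_seed(27, rpois(length(lam), lam))
    counts[1:29] <- 0
    tr <- 1:4500; te <- 4530:6000
    conv_tr <- retinasc:::crop_conv(conv, 1:8, 1:8)
    conv_tr$h <- conv$h[, , tr, drop = FALSE]
    conv_te <- retinasc:::crop_conv(conv, 1:8, 1:8)
    conv_te$h <- conv$h[, , te, drop = FALSE]
    fl <- fit_encoding_model("LN", conv_tr, sp, counts[tr])
    fs <- fit_encoding_model("SC", conv_tr, sp, counts[tr])
    pl <- predict_rate(fl, conv_te)
    ps <- predict_rate(fs, conv_te)
    r_ln <- cor(pl[30:length(te)], lam[te][30:length(te)])
    r_sc <- cor(ps[30:length(te)], lam[te][30:length(te)])
    expect_gte(r_sc, r_ln - 0.02)
  }
})

test_that("reliability metrics follow their definitions", {
  # identical trials: FEV = 1, symmetrized R^2 = 1
  tr <- matrix(rep(c(0, 1, 3, 2, 0, 1), 4), nrow = 4, byrow = TRUE)
  rm <- reliability_metrics(tr)
  expect_equal(rm$fev, 1)
  expect_equal(rm$r2_sym, 1)
  expect_false(rm$excluded)
  # constant-rate Poisson: FEV -> 0 (all variance is noise)
  set.seed(28)
  po <- matrix(rpois(40 * 500, 0.5), nrow = 40)
  rm2 <- reliability_metrics(po)
  expect_lt(abs(rm2$fev), 0.05)
  expect_true(rm2$excluded)
  # threshold rule at the stated 0.15 cut
  expect_true(reliability_metrics(po, fev_threshold = 0.15)$excluded)
  expect_error(reliability_metrics(matrix(1, 1, 5)), "2 trials")
})

test_that("evaluate_prediction is plain Pearson correlation", {
  expect_equal(evaluate_prediction(c(1, 2, 3), c(2, 4, 6)), 1)
  psth <- c(0.2, 0.5, 0.1, 0.9)
  expect_equal(evaluate_prediction(psth, psth), 1)
  expect_equal(evaluate_prediction(-psth + 1, psth), -1)
  expect_error(evaluate_prediction(rep(1, 4), psth), "variance")
  expect_error(evaluate_prediction(1:3, 1:4), "length")
})

test_that("spatial smoothing preserves DC and matches the Gaussian kernel", {
  cst <- array(2.5, c(10, 10, 2))
  expect_equal(spatial_smooth(cst, 1.7), cst)
  # impulse response equals the truncated normalized Gaussian
  imp <- array(0, c(25, 25, 1)); imp[13, 13, 1] <- 1
  sm <- spatial_smooth(imp, 2)
  r <- floor(3 * 2 + 0.5)
  k <- exp(-(-r:r)^2 / 8); k <- k / sum(k)
  # center row of the separable 2D response: k scaled by the center tap
  expect_equal(sm[13, (13 - r):(13 + r), 1], k * k[r + 1], tolerance = 1e-12)
  expect_equal(sm[(13 - r):(13 + r), (13 - r):(13 + r), 1], outer(k, k),
               tolerance = 1e-12)
  expect_equal(sum(sm), 1)
  # large sigma drives a +-1 checkerboard toward its spatial mean
  cb <- array(rep_len(c(-1, 1), 16 * 16), c(16, 16, 1))
  smc <- spatial_smooth(cb, 8)
  expect_lt(max(abs(smc - mean(cb))), 0.15)
  expect_error(spatial_smooth(cst, 0), "sigma")
})

test_that("Imean is smoothing-invariant and LSC shrinks under smoothing", {
  stim <- gen_white_noise(400, c(12, 12), pixel_size_um = 30, seed = 29)
  conv <- temporal_convolve(stim, biphasic_kernel())
  sp <- mk_gauss_filter(12, 2)
  base <- compute_imean_lsc(conv, sp)
  sm <- retinasc:::smooth_lsc_conv(conv, 2)
  il <- compute_imean_lsc(sm, sp)
  expect_equal(il$imean, base$imean)
  vi <- 30:400
  expect_lt(mean(il$lsc[vi]), mean(base$lsc[vi]))
})

test_that("scan interpolation finds the parabola peak at 0.1 um resolution", {
  # synthetic relative-performance curve with a known interior peak
  sig <- c(1, 2, 3)
  scales <- 3 * sig * 7.5
  peak_true <- 50
  rel <- 1.1 - ((scales - peak_true) / 40)^2
  co <- stats::lm.fit(cbind(1, scales, scales^2), rel)$coefficients
  fine <- seq(scales[1], scales[3], by = 0.1)
  yy <- co[1] + co[2] * fine + co[3] * fine^2
  expect_equal(fine[which.max(yy)], peak_true, tolerance = 0.1)
})
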