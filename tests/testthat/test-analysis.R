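# analysis: reversing-grating index, 2D histograms, LSC sensitivity, RAPSD,
# clustering

test_that("the reversing-grating index is the F2/F1 amplitude ratio", {
  t5 <- (0:199) * 0.005            # 1 s PSTH at 5 ms bins
  pure <- reversing_grating_index(1 + cos(2 * pi * 1 * t5))
  expect_equal(pure$index, 0, tolerance = 1e-12)
  # one condition carries F2, another a weak F1: index = 1 / eps
  eps <- 0.25
  mixed <- reversing_grating_index(list(1 + cos(2 * pi * 2 * t5),
                                        1 + eps * cos(2 * pi * 1 * t5)))
  expect_equal(mixed$index, 1 / eps, tolerance = 1e-10)
  expect_equal(mixed$argmax_f2, 1L)
  expect_equal(mixed$argmax_f1, 2L)
  expect_error(reversing_grating_index(rep(1, 200)), "undefined")
})

test_that("RGI orders linear and rectified model cells correctly", {
  # transient (balanced-kernel) cells probed with gratings at or below the
  # subunit scale, resolved at 7.5 um monitor pixels; responses calibrated
  # once on white noise and reused across grating conditions
  battery <- function(nl) {
    cell <- make_model_cell(n_subunits = 19, subunit_diameter_um = 30,
                            rf_diameter_um = 180, pixel_size_um = 7.5,
                            subunit_nl = nl, out_nl = c(a = 1, b = 2, c = 0),
                            mean_rate_target_hz = 10,
                            kernel = biphasic_kernel(balanced = TRUE),
                            seed = 4)
    wn <- gen_white_noise(30 * 85, c(9, 9), square_px = 4,
                          pixel_size_um = 7.5, seed = 44)
    rs <- attr(cell_rate(cell, wn), "rate_scale")
    psths <- list()
    for (wd in c(2, 4, 8)) {
      for (ph in unique(round(seq(0, wd - 1, length.out = min(wd, 4))))) {
        g <- gen_reversing_grating(stripe_width_px = wd, phase_px = ph,
                                   reversal_period_s = 0.5, n_periods = 3,
                                   frame_rate_hz = 84, height_px = 36,
                                   width_px = 36, pixel_size_um = 7.5)
        r <- cell_rate(cell, g, rate_scale = rs)
        psths <- c(psths, list(rowMeans(matrix(r[85:(84 * 3)], nrow = 84))))
      }
    }
    reversing_grating_index(psths, stim_freq_hz = 1, bin_s = 1 / 84)$index
  }
  rgi_lin <- battery("linear")
  rgi_rec <- battery("relu")
  expect_lt(rgi_lin, 1)
  expect_gt(rgi_rec, 1)
  expect_gt(rgi_rec, 3 * rgi_lin)
})

test_that("2D rate histograms bin and average correctly", {
  # toy 6-sample input, hand-checked cell means
  im <- c(0, 0, 1, 1, 0.2, 0.9)
  ls <- c(0, 1, 0, 1, 0.1, 0.95)
  ct <- c(1, 2, 3, 4, 5, 6)
  h <- rate_histogram_2d(im, ls, ct, mode = "equal_40")
  # bin width 1/40: samples 1 & 5 share the low/low corner region check
  expect_equal(dim(h$mean_rate), c(40L, 40L))
  expect_equal(sum(h$count), 6L)
  expect_equal(max(h$mean_rate, na.rm = TRUE), 1)   # normalized display
  # sample 1 sits alone in the low/low corner bin (bin width 1/40)
  expect_equal(h$count[1, 1], 1L)
  # quantile mode: equal counts per axis bin within +-1, edges dropped
  set.seed(36)
  imq <- rnorm(6000); lsq <- rexp(6000); ctq <- rpois(6000, 1)
  hq <- rate_histogram_2d(imq, lsq, ctq, mode = "quantile_60_trimmed")
  margins <- table(cut(imq, hq$imean_edges, include.lowest = TRUE))
  expect_lte(diff(range(margins)), 1)
  expect_equal(dim(hq$mean_rate), c(58L, 58L))
  expect_error(rate_histogram_2d(numeric(0), numeric(0), numeric(0)),
               "empty")
})

test_that("rate depending only on Imean yields identical row profiles", {
  set.seed(37)
  im <- rnorm(20000); ls <- rexp(20000)
  rate <- softplus(im, a = 2, b = 2, c = 0)
  h <- rate_histogram_2d(im, ls, rate, mode = "quantile_60_trimmed")
  # correlate row profiles of well-filled rows
  rows <- which(rowSums(is.finite(h$mean_rate)) > 40)
  r1 <- h$mean_rate[rows[2], ]; r2 <- h$mean_rate[rows[length(rows) - 1], ]
  ok <- is.finite(r1) & is.finite(r2)
  expect_gt(cor(r1[ok], r2[ok]), 0.95)
})

test_that("the softplus family fit recovers planted parameters", {
  k_true <- 0.5
  l_i <- seq(0.2, 1.4, length.out = 20)
  c_i_true <- 0.8 - k_true * l_i
  x <- seq(-2, 2, length.out = 58)
  mr <- t(sapply(seq_along(l_i), function(i)
    2.3 * log1p(exp(3.1 * (x - c_i_true[i])))))
  hist <- structure(list(mean_rate = mr, count = matrix(100, 20, 58),
                         imean_centers = x, lsc_centers = l_i,
                         mode = "quantile_60_trimmed"),
                    class = "rsc_hist2d")
  fam <- fit_softplus_family(hist)
  expect_lt(abs(fam$a - 2.3) / 2.3, 0.05)
  expect_lt(abs(fam$b - 3.1) / 3.1, 0.05)
  expect_lt(max(abs(fam$c_i - c_i_true)), 0.02)
  # identical rows give equal thresholds
  hist2 <- hist
  hist2$mean_rate <- matrix(rep(mr[1, ], 20), 20, byrow = TRUE)
  fam2 <- fit_softplus_family(hist2)
  expect_lt(diff(range(fam2$c_i)), 1e-6)
  # shifting one row's input shifts its threshold equivariantly
  expect_equal(fam$c_i[5] - fam$c_i[10],
               c_i_true[5] - c_i_true[10], tolerance = 1e-6)
})

test_that("LSC sensitivity is -1/slope with LOF outlier removal", {
  # planted line: c_i = c0 - k * l_i  =>  regression of l on c has slope
  # -1/k and sensitivity -1/m = k
  k <- 0.5
  l_i <- seq(0.1, 1.5, length.out = 25)
  c_i <- 1.2 - k * l_i
  sens <- lsc_sensitivity(c_i, l_i)
  expect_equal(sens$sensitivity, k, tolerance = 1e-10)
  expect_false(any(sens$outlier_mask))
  # a gross outlier pair is removed and the slope survives
  c_o <- c(c_i, 5); l_o <- c(l_i, 4)
  sens_o <- lsc_sensitivity(c_o, l_o)
  expect_true(sens_o$outlier_mask[26])
  expect_lt(abs(sens_o$sensitivity - k) / k, 0.02)
  # constant l against varying c: slope ~ 0 -> infinite-sensitivity flag
  inf_case <- lsc_sensitivity(seq(0, 1, length.out = 10), rep(1, 10))
  expect_true(inf_case$infinite)
  expect_equal(inf_case$sensitivity, Inf)
})

test_that("LOF scores flag density outliers", {
  set.seed(38)
  x <- cbind(rnorm(40), rnorm(40))
  x <- rbind(x, c(8, 8))
  sc <- lof_scores(x, k = 5)
  expect_gt(sc[41], 2 * max(sc[1:40]))   # far point clearly separated
  expect_lt(median(sc[1:40]), 1.5)       # bulk scores near 1
  expect_error(lof_scores(x[1:4, ], k = 5), "more than")
})

test_that("LSC sensitivity orders linear and rectified cells", {
  sens_for <- function(cell) {
    wn <- gen_white_noise(240 * 85, c(12, 12), pixel_size_um = 30, seed = 4)
    rate <- cell_rate(cell, wn)
    counts <- sample_spikes(rate, 85, seed = 5)$counts[1, ]
    rfp <- rf_pipeline(wn, spike_train(counts, 85))
    conv <- rfp$crop(temporal_convolve(wn, rfp$comps$temporal))
    il <- compute_imean_lsc(conv, rfp$gfit$filter)
    vi <- 30:length(counts)
    # noiseless rate histogram: the oracle probes the statistic itself,
    # not Poisson sampling noise in the thresholds
    h <- rate_histogram_2d(il$imean[vi], il$lsc[vi], as.numeric(rate[vi]),
                           mode = "quantile_60_trimmed")
    fam <- fit_softplus_family(h)
    lsc_sensitivity(fam$c_i, fam$l_i)$sensitivity
  }
  # smooth Gaussian-RF linear control cell
  s_lin <- sens_for(make_model_cell(n_subunits = 1,
                                    subunit_diameter_um = 89,
                                    rf_diameter_um = 90, pixel_size_um = 30,
                                    subunit_nl = "linear",
                                    mean_rate_target_hz = 10, seed = 3))
  s_rec <- sens_for(make_model_cell(n_subunits = 7,
                                    subunit_diameter_um = 30,
                                    rf_diameter_um = 90, pixel_size_um = 30,
                                    subunit_nl = "relu",
                                    mean_rate_target_hz = 10, seed = 3))
  expect_lt(abs(s_lin), 0.1)
  expect_gt(s_rec, 0.2)
})

test_that("RAPSD satisfies DC, whiteness and Parseval properties", {
  cst <- matrix(4, 16, 16)
  r <- rapsd(cst)
  expect_equal(r$power[1], (16 * 4)^2 / 1)  # DC term: (sum/N)^2
  expect_true(all(r$power[-1] == 0))
  # white noise: flat in log-log over mid frequencies
  set.seed(39)
  wn <- array(sample(c(-1, 1), 64 * 64 * 60, TRUE), c(64, 64, 60))
  rw <- rapsd(wn)
  sel <- rw$freq >= 2 & rw$freq <= 24
  slope <- coef(lm(log(rw$power[sel]) ~ log(rw$freq[sel])))[2]
  expect_lt(abs(slope), 0.1)
  # Parseval: sum over all DFT samples of |h|^2 / N^2 = sum h^2 / N^2;
  # reconstruct the total from per-bin means and counts
  fr <- matrix(rnorm(32 * 32), 32, 32)
  rp <- rapsd(fr)
  f1 <- c(0:16, -(15:1))
  rad <- floor(sqrt(outer(f1^2, f1^2, `+`)))
  nbin <- as.numeric(table(factor(as.integer(rad), levels = rp$freq)))
  expect_equal(sum(rp$power * nbin), sum(fr^2), tolerance = 1e-8)
  expect_error(rapsd(matrix(0, 3, 4)), "square")
})

test_that("rapsd matches a direct double-loop DFT oracle", {
  set.seed(40)
  N <- 8
  fr <- matrix(rnorm(N * N), N, N)
  # Eq.-style direct transform with 1/N normalization
  pow <- matrix(0, N, N)
  for (k in 0:(N - 1)) for (l in 0:(N - 1)) {
    s <- 0
    for (m in 0:(N - 1)) for (n in 0:(N - 1)) {
      s <- s + fr[m + 1, n + 1] * exp(-2i * pi * (m * k + n * l) / N)
    }
    pow[k + 1, l + 1] <- Mod(s / N)^2
  }
  fsign <- c(0:(N / 2), -((N / 2 - 1):1))
  rad <- floor(sqrt(outer(fsign^2, fsign^2, `+`)))
  oracle <- tapply(as.numeric(pow), as.integer(rad), mean)
  r <- rapsd(fr)
  expect_equal(unname(r$power), unname(as.numeric(oracle)),
               tolerance = 1e-10)
})

test_that("feature clustering separates archetypes and is duplication-stable", {
  set.seed(41)
  n_per <- 12
  # archetype A: fast biphasic filter, large RF, fast ACG decay
  mk_cells <- function(peak_s, rf, acg_tau, n) {
    tf <- t(sapply(seq_len(n), function(i)
      biphasic_kernel(peak_s = peak_s)$taps + rnorm(30, sd = 0.02)))
    acg <- t(sapply(seq_len(n), function(i) {
      v <- exp(-(0:149) * 0.5 / acg_tau) + abs(rnorm(150, sd = 0.01))
      v / sum(v)
    }))
    list(tf = tf, rf = rf + rnorm(n, sd = rf * 0.05), acg = acg)
  }
  a <- mk_cells(0.035, 300, 3, n_per)
  b <- mk_cells(0.07, 100, 20, n_per)
  res <- build_features_and_cluster(rbind(a$tf, b$tf), c(a$rf, b$rf),
                                    rbind(a$acg, b$acg), k = 2, seed = 42)
  lab <- res$labels
  expect_equal(length(unique(lab[1:n_per])), 1L)
  expect_equal(length(unique(lab[n_per + 1:n_per])), 1L)
  expect_true(lab[1] != lab[n_per + 1])
  # retained PCA dimensions explain >= 90% of the variance
  ve <- cumsum(res$pca$sdev^2) / sum(res$pca$sdev^2)
  expect_gte(ve[res$n_components], 0.9)
  # duplicating every cell preserves the partition structure
  res2 <- build_features_and_cluster(rbind(a$tf, b$tf, a$tf, b$tf),
                                     rep(c(a$rf, b$rf), 2),
                                     rbind(a$acg, b$acg, a$acg, b$acg),
                                     k = 2, seed = 42)
  first <- res2$labels[1:(2 * n_per)]
  second <- res2$labels[2 * n_per + 1:(2 * n_per)]
  expect_equal(first, second)
  expect_error(build_features_and_cluster(a$tf, a$rf, a$acg, k = 50),
               "exceeds")
})
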