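#' Reversing-grating index (F2/F1)
#'
#' For each grating condition (stripe width x spatial phase), computes the
#' Fourier amplitude of the 1 s trial-averaged PSTH at the stimulus
#' frequency (F1, 1 Hz) and at twice the stimulus frequency (F2, 2 Hz).
#' The index is the largest F2 across all conditions divided by the
#' largest F1 across all conditions; frequency-doubled (F2-dominated)
#' responses mark nonlinear spatial summation.
#'
#' @param psths list (or single vector) of trial-averaged PSTHs, each one
#'   stimulus period long (1 s at 5 ms bins = 200 samples by default).
#' @param stim_freq_hz stimulus frequency, Hz.
#' @param bin_s PSTH bin width, seconds.
#' @return list of class `rsc_rgi`: `index`, `F1`, `F2`, `argmax_f1`,
#'   `argmax_f2` (condition indices).
#' @export
reversing_grating_index <- function(psths, stim_freq_hz = 1, bin_s = 0.005) {
  if (is.numeric(psths)) psths <- list(psths)
  amps <- vapply(psths, function(p) {
    n <- length(p)
    dur <- n * bin_s
    k1 <- round(stim_freq_hz * dur)       # DFT index of the fundamental
    sp <- Mod(stats::fft(p)) / n * 2      # one-sided amplitude
    c(F1 = sp[k1 + 1L], F2 = sp[2L * k1 + 1L])
  }, numeric(2))
  F1 <- max(amps[1, ]); F2 <- max(amps[2, ])
  if (F1 <= 1e-12 * max(1, max(abs(unlist(psths))))) {
    stopf("largest F1 is zero: reversing-grating index undefined")
  }
  structure(list(index = F2 / F1, F1 = F1, F2 = F2,
                 argmax_f1 = which.max(amps[1, ]),
                 argmax_f2 = which.max(amps[2, ])),
            class = "rsc_rgi")
}

#' Two-dimensional firing-rate histogram over (Imean, LSC)
#'
#' Bins the Imean and LSC signals independently and averages the firing
#' response over all time points falling in each bin pair. `equal_40`
#' (display) mode uses 40 equal-width bins per axis and normalizes rates
#' to the histogram maximum; `quantile_60_trimmed` (analysis) mode uses 60
#' equal-count bins per axis, drops the first and last bin of each axis,
#' and keeps raw mean rates.
#'
#' @param imean,lsc signal series.
#' @param counts spike counts (or rates) per bin, same length.
#' @param mode `"equal_40"` or `"quantile_60_trimmed"`.
#' @return list of class `rsc_hist2d`: `mean_rate` (LSC rows x Imean
#'   columns; `NA` where empty), `count`, `imean_edges`, `lsc_edges`,
#'   `imean_centers`, `lsc_centers`, `mode`.
#' @export
rate_histogram_2d <- function(imean, lsc, counts,
                              mode = c("equal_40", "quantile_60_trimmed")) {
  mode <- match.arg(mode)
  if (length(imean) == 0L) stopf("empty input")
  stopifnot(length(imean) == length(lsc), length(lsc) == length(counts))
  edges <- function(x, n, quant) {
    if (quant) {
      e <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n + 1L),
                                  names = FALSE))
      if (length(e) < 3L) stopf("signal too discrete for quantile binning")
      e
    } else {
      seq(min(x), max(x), length.out = n + 1L)
    }
  }
  n_bins <- if (mode == "equal_40") 40L else 60L
  quant <- mode == "quantile_60_trimmed"
  ie <- edges(imean, n_bins, quant)
  le <- edges(lsc, n_bins, quant)
  bi <- pmin(pmax(findInterval(imean, ie, rightmost.closed = TRUE), 1L),
             length(ie) - 1L)
  bl <- pmin(pmax(findInterval(lsc, le, rightmost.closed = TRUE), 1L),
             length(le) - 1L)
  ni <- length(ie) - 1L; nl <- length(le) - 1L
  cnt <- matrix(0L, nl, ni)
  sums <- matrix(0, nl, ni)
  for (t in seq_along(bi)) {
    cnt[bl[t], bi[t]] <- cnt[bl[t], bi[t]] + 1L
    sums[bl[t], bi[t]] <- sums[bl[t], bi[t]] + counts[t]
  }
  mr <- sums / cnt
  mr[cnt == 0L] <- NA_real_
  keep_i <- seq_len(ni); keep_l <- seq_len(nl)
  if (quant) {                      # drop first/last bin of each axis
    keep_i <- 2:(ni - 1L); keep_l <- 2:(nl - 1L)
    mr <- mr[keep_l, keep_i, drop = FALSE]
    cnt <- cnt[keep_l, keep_i, drop = FALSE]
  } else {
    mr <- mr / max(mr, na.rm = TRUE)      # display normalization
  }
  centers <- function(e) (head(e, -1L) + tail(e, -1L)) / 2
  structure(list(mean_rate = mr, count = cnt,
                 imean_edges = ie, lsc_edges = le,
                 imean_centers = centers(ie)[keep_i],
                 lsc_centers = centers(le)[keep_l],
                 mode = mode),
            class = "rsc_hist2d")
}

#' Fit a shared-shape softplus family to histogram rows
#'
#' Joint least squares of `f_i(x) = a log(1 + exp(b (x - c_i)))` over all
#' non-empty histogram cells, with `a` and `b` shared across rows and one
#' horizontal threshold `c_i` per row. The `c_i` are LSC-dependent
#' thresholds of mean luminosity beyond which firing rises.
#'
#' @param hist an `rsc_hist2d` (typically `quantile_60_trimmed`).
#' @param min_rows minimum number of non-empty rows required.
#' @return list: `a`, `b`, `c_i` (per retained row), `rows` (row indices
#'   retained), `l_i` (LSC level per row = bin center), `rss`,
#'   `converged`.
#' @export
fit_softplus_family <- function(hist, min_rows = 3L) {
  mr <- hist$mean_rate
  rows <- which(rowSums(is.finite(mr)) >= 3L)
  if (length(rows) < min_rows) stopf("fewer than %d usable rows", min_rows)
  x <- hist$imean_centers
  obs <- lapply(rows, function(r) {
    ok <- is.finite(mr[r, ])
    list(x = x[ok], y = mr[r, ok])
  })
  ymax <- max(vapply(obs, function(o) max(o$y), numeric(1)))
  xrange <- diff(range(x))
  n_r <- length(rows)
  # init: c_i near each row's half-max crossing, b from the grid scale
  c0 <- vapply(obs, function(o) {
    o$x[which.min(abs(o$y - 0.5 * max(o$y)))]
  }, numeric(1))
  # parameters: log a, log b, c_1..c_N  (a, b > 0 for an increasing family)
  p0 <- c(log(max(ymax / log(2), 1e-3)), log(4 / max(xrange, 1e-12)), c0)
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    val <- 0
    gr <- numeric(length(p))
    for (j in seq_len(n_r)) {
      u <- b * (obs[[j]]$x - p[2L + j])
      s <- softplus1(u)
      sig <- sigmoid(u)
      r <- a * s - obs[[j]]$y
      val <- val + sum(r^2)
      gr[1] <- gr[1] + 2 * sum(r * a * s)              # d/d log a
      gr[2] <- gr[2] + 2 * sum(r * a * sig * u)        # d/d log b
      gr[2L + j] <- -2 * a * b * sum(r * sig)          # d/d c_j
    }
    attr(val, "gradient") <- gr
    val
  }
  # the (a, b) scales are poorly known a priori: deterministic multi-start
  # over log-scale offsets, keeping the best residual sum of squares
  fit <- NULL
  for (da in c(-2, 0, 2)) {
    for (db in c(-1, 0, 1)) {
      cand <- try(stats::optim(
        p0 + c(da, db, rep(0, n_r)),
        fn = function(p) as.numeric(obj(p)),
        gr = function(p) attr(obj(p), "gradient"),
        method = "BFGS",
        control = list(maxit = 5000, reltol = 1e-14)), silent = TRUE)
      if (inherits(cand, "try-error") || !all(is.finite(cand$par))) next
      if (is.null(fit) || cand$value < fit$value) fit <- cand
    }
  }
  if (is.null(fit)) {
    stopf("softplus family fit did not converge from any start")
  }
  list(a = exp(fit$par[1]), b = exp(fit$par[2]),
       c_i = fit$par[-(1:2)], rows = rows,
       l_i = hist$lsc_centers[rows], rss = fit$value, converged = TRUE)
}

#' Local Outlier Factor scores
#'
#' Density-based outlier scores (Breunig et al.) with `k` nearest
#' neighbours; scores near 1 indicate inliers, substantially larger values
#' indicate outliers.
#'
#' @param x numeric matrix (rows = points) or vector.
#' @param k number of neighbours (default 5).
#' @return numeric LOF score per point.
#' @export
lof_scores <- function(x, k = 5L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= k) stopf("need more than k = %d points", k)
  D <- as.matrix(stats::dist(x))
  diag(D) <- Inf
  knn <- t(apply(D, 1L, function(d) order(d)[seq_len(k)]))
  kdist <- vapply(seq_len(n), function(i) D[i, knn[i, k]], numeric(1))
  # reachability distance and local reachability density
  lrd <- vapply(seq_len(n), function(i) {
    reach <- pmax(kdist[knn[i, ]], D[i, knn[i, ]])
    1 / mean(reach)
  }, numeric(1))
  vapply(seq_len(n), function(i) mean(lrd[knn[i, ]]) / lrd[i], numeric(1))
}

#' LSC sensitivity from threshold/contrast pairs
#'
#' Removes outlier `(c_i, l_i)` pairs by Local Outlier Factor (5
#' neighbours, score > `lof_cutoff`), regresses the LSC levels `l_i` on
#' the thresholds `c_i` by ordinary least squares, and reports
#' `sensitivity = -1/m` with `m` the slope — zero for cells whose firing
#' ignores local spatial contrast, positive for nonlinear cells whose
#' threshold drops as contrast rises.
#'
#' @param c_i per-row softplus thresholds (independent variable).
#' @param l_i per-row LSC levels (dependent variable).
#' @param lof_cutoff LOF score above which a pair is discarded.
#' @return list of class `rsc_lsc_sensitivity`: `sensitivity`, `slope`,
#'   `intercept`, `outlier_mask`, `infinite` flag (slope below machine
#'   tolerance).
#' @export
lsc_sensitivity <- function(c_i, l_i, lof_cutoff = 1.5) {
  stopifnot(length(c_i) == length(l_i))
  pts <- cbind(c_i, l_i)
  out_mask <- rep(FALSE, length(c_i))
  if (length(c_i) > 6L) {
    # scale axes before LOF so neither dominates the distance
    scl <- apply(pts, 2L, function(v) max(stats::sd(v), 1e-12))
    out_mask <- lof_scores(sweep(pts, 2L, scl, `/`), k = 5L) > lof_cutoff
  }
  if (sum(!out_mask) < 3L) stopf("fewer than 3 pairs after outlier removal")
  cc <- c_i[!out_mask]; ll <- l_i[!out_mask]
  co <- stats::lm.fit(cbind(1, cc), ll)$coefficients
  m <- unname(co[2])
  infinite <- abs(m) < .Machine$double.eps^.5
  structure(list(sensitivity = if (infinite) Inf else -1 / m,
                 slope = unname(m), intercept = unname(co[1]),
                 outlier_mask = out_mask, infinite = infinite),
            class = "rsc_lsc_sensitivity")
}

#' Radially averaged power spectral density
#'
#' For each square `N x N` frame, computes the discrete 2D Fourier
#' transform with `1/N` normalization, the power of each component, and
#' the mean power in radial bins of unit width centered on the
#' zero-frequency term (bin of a sample = floor of its Euclidean distance
#' from DC); curves are averaged across frames.
#'
#' @param frames `N x N` matrix or `N x N x T` array.
#' @return list of class `rsc_rapsd`: `power` (mean power per radial
#'   bin), `freq` (radial bin index, cycles per frame).
#' @export
rapsd <- function(frames) {
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  d <- dim(frames)
  if (d[1] != d[2]) stopf("frames must be square (got %d x %d)", d[1], d[2])
  N <- d[1]
  # signed frequency index of each DFT sample
  f1 <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1))
  rad <- floor(sqrt(outer(f1^2, f1^2, `+`)))
  bins <- sort(unique(as.integer(rad)))
  acc <- numeric(length(bins))
  idx <- match(as.integer(rad), bins)
  for (t in seq_len(d[3])) {
    P <- Mod(stats::fft(frames[, , t]) / N)^2
    acc <- acc + unname(vapply(split(as.numeric(P), idx), mean, numeric(1)))
  }
  structure(list(power = acc / d[3], freq = bins), class = "rsc_rapsd")
}

# ---- cell-type features and clustering -------------------------------------

# kmeans++ seeding, then Lloyd refinement via stats::kmeans
kmeanspp <- function(X, k, nstart = 10L) {
  n <- nrow(X)
  best <- NULL
  for (rs in seq_len(nstart)) {
    centers <- matrix(0, k, ncol(X))
    centers[1L, ] <- X[sample.int(n, 1L), ]
    d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
    for (j in seq_len(k - 1L) + 1L) {
      prob <- d2 / sum(d2)
      centers[j, ] <- X[sample.int(n, 1L, prob = prob), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
    }
    km <- suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

#' Build cell-type feature vectors and cluster them
#'
#' Feature vector per cell: the 30 temporal-filter taps, the
#' receptive-field size, and the scores of the first ten principal
#' components of the (per-entry Z-scored) autocorrelograms. Each feature
#' entry is then Z-scored across cells, reduced by PCA retaining 90% of
#' the variance, and clustered with KMeans++ (10 restarts, best inertia).
#' Labels are returned for manual curation downstream.
#'
#' @param temporal_filters matrix, one row per cell (e.g. 30 taps).
#' @param rf_sizes_um numeric vector of RF sizes.
#' @param autocorrelograms matrix, one row per cell (e.g. 150 bins).
#' @param k number of clusters (6-8 in the standard workflow).
#' @param seed RNG seed.
#' @param n_acg_pcs autocorrelogram PCA scores to keep.
#' @param var_explained PCA variance fraction retained in the final
#'   reduction.
#' @return list: `labels` (integer per cell), `features` (Z-scored
#'   matrix), `pca` (the `prcomp` object), `n_components`, `kmeans`.
#' @export
build_features_and_cluster <- function(temporal_filters, rf_sizes_um,
                                       autocorrelograms, k, seed = NULL,
                                       n_acg_pcs = 10L,
                                       var_explained = 0.9) {
  tf <- as.matrix(temporal_filters)
  acg <- as.matrix(autocorrelograms)
  n <- nrow(tf)
  if (k > n) stopf("k = %d exceeds the number of cells (%d)", k, n)
  stopifnot(length(rf_sizes_um) == n, nrow(acg) == n)
  zcol <- function(m) {
    s <- apply(m, 2L, stats::sd)
    s[s == 0] <- 1
    sweep(sweep(m, 2L, colMeans(m)), 2L, s, `/`)
  }
  acg_pcs <- stats::prcomp(zcol(acg), center = FALSE, scale. = FALSE)
  n_pc <- min(n_acg_pcs, ncol(acg_pcs$x))
  feats <- cbind(tf, rf_sizes_um, acg_pcs$x[, seq_len(n_pc), drop = FALSE])
  feats <- zcol(feats)
  if (!all(is.finite(feats))) stopf("non-finite feature entries")
  pca <- stats::prcomp(feats, center = FALSE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  n_comp <- which(cum >= var_explained)[1]
  X <- pca$x[, seq_len(n_comp), drop = FALSE]
  km <- with_seed(seed, kmeanspp(X, k))
  list(labels = km$cluster, features = feats, pca = pca,
       n_components = n_comp, kmeans = km)
}
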