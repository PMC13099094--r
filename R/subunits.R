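# ---- Adam optimizer (analytic gradients, minibatch) ------------------------
# Small generic Adam over a named list of parameter arrays. The training
# protocols here mirror common deep-learning practice: Adam with mean-reduced
# losses, a plateau scheduler (lr x 0.8 after 5 stale validation epochs),
# early stopping after 50 stale epochs, at most 500 epochs, keeping the
# best-validation state.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Shared epoch driver: calls train_epoch(lr) (which updates parameters via
# closures) and val_loss(), handling scheduler / early stopping bookkeeping.
train_loop <- function(train_epoch, val_loss, lr,
                       max_epochs = 500L, plateau_epochs = 5L,
                       early_stop_epochs = 50L, lr_factor = 0.8,
                       get_state = NULL) {
  best <- Inf; best_state <- NULL
  stale_sched <- 0L; stale_stop <- 0L
  history <- numeric(0)
  for (epoch in seq_len(max_epochs)) {
    train_epoch(lr, epoch)
    vl <- val_loss()
    history <- c(history, vl)
    if (vl < best - 1e-10) {
      best <- vl
      if (!is.null(get_state)) best_state <- get_state()
      stale_sched <- 0L; stale_stop <- 0L
    } else {
      stale_sched <- stale_sched + 1L
      stale_stop <- stale_stop + 1L
    }
    if (stale_sched >= plateau_epochs) {
      lr <- lr * lr_factor
      stale_sched <- 0L
    }
    if (stale_stop >= early_stop_epochs) break
  }
  list(best_val = best, best_state = best_state, history = history,
       epochs_run = length(history))
}

# ---- STC -------------------------------------------------------------------

#' Crop a convolved stimulus around a receptive field for STC analysis
#'
#' Selects the smallest square region (in stimulus pixels) enclosing the
#' 3-sigma contour of the Gaussian receptive-field fit, up to a maximum
#' side length, centered on the RF center and clipped to the field.
#'
#' @param conv an `rsc_conv` over the white-noise stimulus grid.
#' @param rf a [gaussian_rf()] whose center is in the same pixel
#'   coordinates as `conv`.
#' @param max_side maximum crop side, stimulus pixels (default 16).
#' @return list: `conv` (cropped), `rows`, `cols` (1-based index windows).
#' @export
crop_for_stc <- function(conv, rf, max_side = 16L) {
  d <- dim(conv$h)
  cx <- rf$center[1]; cy <- rf$center[2]
  if (cx < 1 || cx > d[2] || cy < 1 || cy > d[1]) {
    stopf("receptive-field center (%.1f, %.1f) lies outside the stimulus",
          cx, cy)
  }
  # half-extents of the 3-sigma ellipse along the pixel axes
  ct <- cos(rf$angle); st <- sin(rf$angle)
  ex <- 3 * sqrt((rf$sigma_x * ct)^2 + (rf$sigma_y * st)^2)
  ey <- 3 * sqrt((rf$sigma_x * st)^2 + (rf$sigma_y * ct)^2)
  side <- min(as.integer(max_side), ceiling(2 * max(ex, ey)))
  side <- max(side, 1L)
  half_lo <- (side - 1L) %/% 2L
  r0 <- round(cy) - half_lo; c0 <- round(cx) - half_lo
  r0 <- min(max(1L, r0), d[1] - side + 1L)
  c0 <- min(max(1L, c0), d[2] - side + 1L)
  rows <- r0:(r0 + side - 1L); cols <- c0:(c0 + side - 1L)
  list(conv = crop_conv(conv, rows, cols), rows = rows, cols = cols)
}

#' Spike-triggered covariance analysis
#'
#' Eigendecomposition of the covariance of the spike-triggered ensemble of
#' temporally convolved (cropped) stimulus frames, each frame weighted by
#' its spike count. The full spectrum and all eigenvectors are returned.
#'
#' @param conv cropped `rsc_conv`.
#' @param counts spike counts per bin (vector aligned to frames).
#' @param trial_starts trial boundaries (first `M - 1` bins after each are
#'   excluded).
#' @return list of class `rsc_stc`: `eigenvalues` (decreasing),
#'   `eigenvectors` (columns, orthonormal, over the crop), `mean`
#'   (spike-triggered average over the crop), `n_spikes`, `crop_dim`.
#' @export
compute_stc <- function(conv, counts, trial_starts = 1L) {
  H <- conv_matrix(conv)                 # p x T
  Tn <- ncol(H)
  if (length(counts) != Tn) stopf("counts/frames length mismatch")
  valid <- rep(TRUE, Tn)
  for (s in trial_starts) valid[s:min(Tn, s + conv$valid_from - 2L)] <- FALSE
  idx <- which(valid & counts > 0)
  n_spk <- sum(counts[idx])
  p <- nrow(H)
  if (n_spk <= p) {
    stopf("%d spikes for a %d-dimensional crop: STC is rank-deficient",
          n_spk, p)
  }
  X <- t(H[, idx, drop = FALSE])
  cw <- stats::cov.wt(X, wt = as.numeric(counts[idx]), method = "unbiased")
  eg <- eigen(cw$cov, symmetric = TRUE)
  structure(list(eigenvalues = eg$values, eigenvectors = eg$vectors,
                 mean = cw$center, n_spikes = n_spk,
                 crop_dim = dim(conv$h)[1:2]),
            class = "rsc_stc")
}

#' Select an STC basis by eigenvalue deviation from the median
#'
#' Picks the `k` eigenvectors whose eigenvalues deviate most (in absolute
#' value) from the median eigenvalue, catching both the high-variance and
#' the low-variance tail. Ties are broken by original index order.
#'
#' @param stc an `rsc_stc`.
#' @param k basis size (default 16).
#' @return matrix `U` with `k` rows, each an eigenvector (orthonormal
#'   rows).
#' @export
select_basis <- function(stc, k = 16L) {
  lam <- stc$eigenvalues
  if (length(lam) < k) stopf("spectrum shorter than k = %d", k)
  dev <- abs(lam - stats::median(lam))
  ord <- order(dev, decreasing = TRUE)
  pick <- ord[seq_len(k)]              # deviation order; ties by index
  t(stc$eigenvectors[, pick, drop = FALSE])
}

# ---- logical-OR model ------------------------------------------------------

or_forward <- function(S, A, alpha) {
  X <- S %*% A
  G <- sigmoid(sweep(X, 2L, alpha, `+`))
  # P = 1 - prod(1 - g); log-domain product for stability
  logq <- rowSums(log1p(-pmin(G, 1 - 1e-12)))
  P <- -expm1(logq)
  list(G = G, P = pmin(pmax(P, 1e-12), 1 - 1e-12))
}

#' Fit the logical-OR subunit-discovery model
#'
#' Transforms an STC basis into localized subunit filters by fitting the
#' probabilistic spiking model
#' `P_t = 1 - prod_i [1 - g_i(A_i . U h_t)]` with logistic
#' `g_i(x) = 1 / (1 + exp(-(alpha_i + x)))`, minimizing the Bernoulli
#' negative log-likelihood of the binarized spike train by mini-batch Adam
#' (lr 5e-3, batch 512, lr x 0.8 on a 5-epoch validation plateau, early
#' stop after 50 stale epochs, best-validation state kept). A Group-Lasso
#' penalty on the functional subunit norms `sum_i ||q_i||_2`
#' (`q_i = U' A_i`; equal to `||A_i||_2` for an orthonormal basis) with
#' strength `1e-4 N_f / 400` is applied after a 50-epoch warm-up. After
#' training, subunits with norm below 10% of the maximum are pruned and
#' survivors normalized to unit norm; the pre-normalization norms seed the
#' subunit-model weights.
#'
#' @param U STC basis (rows = eigenvectors over the crop) from
#'   [select_basis()].
#' @param conv cropped `rsc_conv` (training segment).
#' @param counts spike counts per bin; binarized internally.
#' @param seed RNG seed (initialization of `A` and batch shuffling).
#' @param n_subunits number of functional subunits at initialization.
#' @param max_epochs,warmup_epochs training-budget controls (defaults are
#'   the full protocol; reduce for desk-scale tests).
#' @param val_fraction fraction of bins held out (contiguous tail) for
#'   validation.
#' @param trial_starts trial boundaries.
#' @return list of class `rsc_logical_or`: `q` (p x n matrix of unit-norm
#'   subunit filters), `p_init` (pre-normalization norms), `A`, `alpha`,
#'   `U`, `crop_dim`, `val_history`.
#' @export
fit_logical_or <- function(U, conv, counts, seed = NULL, n_subunits = 16L,
                           max_epochs = 500L, warmup_epochs = 50L,
                           val_fraction = 0.2, trial_starts = 1L) {
  H <- conv_matrix(conv)
  Tn <- ncol(H)
  valid <- rep(TRUE, Tn)
  for (s in trial_starts) valid[s:min(Tn, s + conv$valid_from - 2L)] <- FALSE
  y <- as.numeric(counts > 0)            # binarized responses
  idx <- which(valid)
  S_all <- t(U %*% H[, idx, drop = FALSE])   # N x k projections
  y_all <- y[idx]
  N <- nrow(S_all)
  n_val <- floor(val_fraction * N)
  if (n_val < 1L) stopf("validation split is empty")
  tr <- seq_len(N - n_val); va <- (N - n_val + 1L):N
  S_tr <- S_all[tr, , drop = FALSE]; y_tr <- y_all[tr]
  S_va <- S_all[va, , drop = FALSE]; y_va <- y_all[va]
  k <- nrow(U); Nf <- ncol(U)
  lam_gl <- 1e-4 * Nf / 400

  env <- new.env(parent = emptyenv())
  with_seed(seed, {
    env$params <- list(A = matrix(stats::rnorm(k * n_subunits, sd = 0.01),
                                  k, n_subunits),
                       alpha = rep(0, n_subunits))
    env$state <- adam_init(env$params)

    bern <- function(P, yv) -mean(yv * log(P) + (1 - yv) * log1p(-P))
    val_loss <- function() {
      or_fw <- or_forward(S_va, env$params$A, env$params$alpha)
      bern(or_fw$P, y_va)                # plateau detection unpenalized
    }
    n_tr <- length(y_tr)
    train_epoch <- function(lr, epoch) {
      perm <- sample.int(n_tr)
      batches <- split(perm, ceiling(seq_along(perm) / 512))
      penalized <- epoch > warmup_epochs
      for (b in batches) {
        A <- env$params$A; alpha <- env$params$alpha
        S <- S_tr[b, , drop = FALSE]; yb <- y_tr[b]
        fw <- or_forward(S, A, alpha)
        B <- length(b)
        # dL/dx_it = [-(n)(1-P)/P + (1-n)] g_it / B  (mean reduction)
        coef <- (-yb * (1 - fw$P) / fw$P + (1 - yb)) / B
        dX <- coef * fw$G
        gA <- crossprod(S, dX)
        galpha <- colSums(dX)
        if (penalized) {
          nrm <- sqrt(colSums(A^2))
          nz <- nrm > 1e-12
          gA[, nz] <- gA[, nz] +
            lam_gl * sweep(A[, nz, drop = FALSE], 2L, nrm[nz], `/`)
        }
        upd <- adam_step(env$params, list(A = gA, alpha = galpha),
                         env$state, lr)
        env$params <- upd$params
        env$state <- upd$state
      }
    }
    res <- train_loop(train_epoch, val_loss, lr = 5e-3,
                      max_epochs = max_epochs,
                      get_state = function() env$params)
    env$params <- res$best_state %||% env$params
    env$history <- res$history
  })
  A <- env$params$A; alpha <- env$params$alpha
  Q <- crossprod(U, A)                    # p x n functional subunits
  nrm <- sqrt(colSums(Q^2))
  keep <- nrm >= 0.1 * max(nrm)
  Qk <- Q[, keep, drop = FALSE]
  structure(list(q = sweep(Qk, 2L, nrm[keep], `/`),
                 p_init = nrm[keep],
                 A = A[, keep, drop = FALSE], alpha = alpha[keep],
                 U = U, crop_dim = dim(conv$h)[1:2],
                 n_initial = n_subunits, val_history = env$history),
            class = "rsc_logical_or")
}

#' Evaluate the logical-OR spike probability
#'
#' @param or_fit an `rsc_logical_or` (or any list with `q`, `alpha`).
#' @param conv cropped `rsc_conv`.
#' @return per-bin spike probability in (0, 1).
#' @export
predict_logical_or <- function(or_fit, conv) {
  H <- conv_matrix(conv)
  drives <- t(crossprod(or_fit$q * rep(or_fit$p_init,
                                       each = nrow(or_fit$q)), H))
  # q columns are unit-norm with the fitted scale in p_init; reconstruct the
  # fitted drive q_raw . h = p_init * (q . h)
  G <- sigmoid(sweep(drives, 2L, or_fit$alpha, `+`))
  -expm1(rowSums(log1p(-pmin(G, 1 - 1e-12))))
}

# ---- subunit model ---------------------------------------------------------

#' Fit the LNLN subunit model
#'
#' `lambda_t = f_sub(sum_i p_i ReLU(q_i . h_t))` with
#' `f_sub(x) = a log(1 + exp(x + c))`. Subunit filters `q_i` come from
#' [fit_logical_or()] and stay fixed; the weights `p` (clamped
#' non-negative after each update) and the output parameters `a`, `c` are
#' trained by mini-batch Adam (lr 1e-3, batch 512, same scheduler and
#' early stopping as the logical-OR model) on the Poisson negative
#' log-likelihood. Training proceeds in two stages: stage 1 adds an l1
#' penalty (strength 1e-4) on `p` and prunes subunits whose weight falls
#' below 10% of the maximum; stage 2 reinitializes with the survivors and
#' retrains without regularization.
#'
#' @param q p x n matrix of unit-norm subunit filters.
#' @param conv cropped `rsc_conv` (training segment).
#' @param counts spike counts per bin.
#' @param seed RNG seed (batch shuffling).
#' @param p_init initial subunit weights (default all 1).
#' @param max_epochs per-stage epoch cap (500 for the full protocol).
#' @param val_fraction held-out tail fraction for validation.
#' @param trial_starts trial boundaries.
#' @return list of class `rsc_subunit_model`: `q` (surviving filters),
#'   `p`, `out_nl` (`a`, `c`), `kept` (indices into the input filters),
#'   `val_history` per stage.
#' @export
fit_subunit_model <- function(q, conv, counts, seed = NULL, p_init = NULL,
                              max_epochs = 500L, val_fraction = 0.2,
                              trial_starts = 1L) {
  if (is.null(dim(q))) q <- matrix(q, ncol = 1L)
  n_su <- ncol(q)
  if (n_su < 1L) stopf("need at least one subunit filter")
  H <- conv_matrix(conv)
  Tn <- ncol(H)
  valid <- rep(TRUE, Tn)
  for (s in trial_starts) valid[s:min(Tn, s + conv$valid_from - 2L)] <- FALSE
  idx <- which(valid)
  R_all <- pmax(t(crossprod(q, H[, idx, drop = FALSE])), 0)  # N x n ReLU drives
  y_all <- as.numeric(counts[idx])
  N <- nrow(R_all)
  n_val <- floor(val_fraction * N)
  if (n_val < 1L) stopf("validation split is empty")
  tr <- seq_len(N - n_val); va <- (N - n_val + 1L):N

  run_stage <- function(R, y, Rv, yv, p0, a0, c0, l1, max_ep) {
    env <- new.env(parent = emptyenv())
    env$params <- list(p = p0, a = a0, c = c0)
    env$state <- adam_init(env$params)
    pois <- function(lam, yv2) mean(lam - yv2 * log(pmax(lam, 1e-300)))
    val_loss <- function() {
      yq <- Rv %*% env$params$p + env$params$c
      pois(env$params$a * softplus1(yq), yv)
    }
    n_tr <- length(y)
    train_epoch <- function(lr, epoch) {
      perm <- sample.int(n_tr)
      batches <- split(perm, ceiling(seq_along(perm) / 512))
      for (b in batches) {
        p <- env$params$p; a <- env$params$a; cc <- env$params$c
        Rb <- R[b, , drop = FALSE]; yb <- y[b]
        yq <- as.numeric(Rb %*% p) + cc
        sp <- softplus1(yq)
        lam <- pmax(a * sp, 1e-300)
        B <- length(b)
        dlam <- (1 - yb / lam) / B
        sig <- sigmoid(yq)
        gp <- as.numeric(crossprod(Rb, dlam * a * sig)) + l1
        ga <- sum(dlam * sp)
        gc <- sum(dlam * a * sig)
        upd <- adam_step(env$params, list(p = gp, a = ga, c = gc),
                         env$state, lr)
        env$params <- upd$params
        env$params$p <- pmax(env$params$p, 0)   # non-negativity clamp
        env$params$a <- max(env$params$a, 1e-6)
        env$state <- upd$state
      }
    }
    res <- train_loop(train_epoch, val_loss, lr = 1e-3, max_epochs = max_ep,
                      get_state = function() env$params)
    list(params = res$best_state %||% env$params, history = res$history)
  }

  with_seed(seed, {
    a0 <- max(max(y_all), 1)
    s1 <- run_stage(R_all[tr, , drop = FALSE], y_all[tr],
                    R_all[va, , drop = FALSE], y_all[va],
                    p0 = p_init %||% rep(1, n_su), a0 = a0, c0 = -2,
                    l1 = 1e-4, max_ep = max_epochs)
    pw <- s1$params$p
    keep <- which(pw >= 0.1 * max(pw))
    if (length(keep) == 0L) stopf("all subunits pruned in stage 1")
    s2 <- run_stage(R_all[tr, keep, drop = FALSE], y_all[tr],
                    R_all[va, keep, drop = FALSE], y_all[va],
                    p0 = pw[keep], a0 = s1$params$a, c0 = s1$params$c,
                    l1 = 0, max_ep = max_epochs)
    structure(list(q = q[, keep, drop = FALSE], p = s2$params$p,
                   out_nl = c(a = s2$params$a, c = s2$params$c),
                   kept = keep,
                   val_history = list(stage1 = s1$history,
                                      stage2 = s2$history)),
              class = "rsc_subunit_model")
  })
}

#' Predict rates from a fitted subunit model
#'
#' Evaluates `f_sub(sum_i p_i ReLU(q_i . h_t))` exactly; rates are
#' non-negative. With all subunit drives negative the ReLU output is zero
#' and the rate is the constant `f_sub(0)`.
#'
#' @param model an `rsc_subunit_model` (or a list with `q`, `p`,
#'   `out_nl`).
#' @param conv cropped `rsc_conv` matching the training crop.
#' @return numeric rate series (expected counts per bin).
#' @export
predict_subunit <- function(model, conv) {
  H <- conv_matrix(conv)
  if (nrow(H) != nrow(model$q)) {
    stopf("crop (%d px) does not match subunit filters (%d px)",
          nrow(H), nrow(model$q))
  }
  R <- pmax(t(crossprod(model$q, H)), 0)
  y <- as.numeric(R %*% model$p) + model$out_nl[["c"]]
  model$out_nl[["a"]] * softplus1(y)
}
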