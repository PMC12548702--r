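# Lagged linear forward models (temporal response functions) estimated by
# regularized least squares, with contiguous-segment cross-validation.

#' EEG recording container
#'
#' @param data Channel x time numeric matrix (microvolts).
#' @param fs Sampling rate (Hz).
#' @param channel_labels Channel names (default Ch1..ChN).
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stopf("EEG data must be finite")
  if (is.null(channel_labels)) channel_labels <- paste0("Ch", seq_len(nrow(data)))
  stopifnot(length(channel_labels) == nrow(data), fs > 0)
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Cross-validation configuration
#'
#' @param n_segments Contiguous segments (default 6: five train, one test,
#'   rotated).
#' @param lambda_grid Ridge-parameter candidates (default `10^(-4:4)`).
#' @param lag_window Lag window in ms (default `c(-100, 500)`).
#' @param seed Integer seed for any randomized step.
#' @return A `cv_config` list.
#' @export
cv_config <- function(n_segments = 6L, lambda_grid = 10^(-4:4),
                      lag_window = c(-100, 500), seed = 1L) {
  stopifnot(n_segments >= 2L, all(lambda_grid > 0), length(lag_window) == 2L,
            lag_window[1] <= lag_window[2])
  structure(list(n_segments = as.integer(n_segments),
                 lambda_grid = as.numeric(lambda_grid),
                 lag_window = as.numeric(lag_window),
                 seed = as.integer(seed)),
            class = "cv_config")
}

#' @noRd
lag_samples <- function(lag_window, fs) {
  seq(round(lag_window[1] * fs / 1000), round(lag_window[2] * fs / 1000))
}

#' Build a lagged design matrix
#'
#' Column `(f, tau)` holds feature `f` shifted by `tau` samples
#' (`X[t, (f, tau)] = F[t - tau, f]`); samples shifted out of range are zero
#' (zero-padding preserves causality). Columns are ordered feature-major with
#' lag varying fastest. The number of lags is
#' `round((t_max - t_min) * fs / 1000) + 1` (61 for `[-100, 500]` ms at
#' 100 Hz).
#'
#' @param feats A [feature_matrix()].
#' @param lag_window Lag window in ms, `c(t_min, t_max)`.
#' @param fs Rate (Hz); must equal `feats$fs`.
#' @return A `lagged_design` with sparse `values`, `lag_axis` (ms),
#'   `feature_labels`, `n_lags`.
#' @export
lag_matrix <- function(feats, lag_window = c(-100, 500), fs = feats$fs) {
  stopifnot(inherits(feats, "feature_matrix"))
  if (abs(fs - feats$fs) > 1e-9) stopf("fs mismatch between request and features")
  lags <- lag_samples(lag_window, fs)
  n_lags <- length(lags)
  Ft <- methods::as(methods::as(feats$values, "generalMatrix"), "TsparseMatrix")
  n <- nrow(Ft)
  n_feat <- ncol(Ft)
  i0 <- Ft@i                # 0-based rows
  j0 <- Ft@j
  x0 <- Ft@x
  nnz <- length(i0)
  ii <- rep(i0, times = n_lags) + rep(lags, each = nnz)
  jj <- rep(j0, times = n_lags) * n_lags + rep(seq_len(n_lags) - 1L, each = nnz)
  xx <- rep(x0, times = n_lags)
  keep <- ii >= 0L & ii < n
  X <- Matrix::sparseMatrix(i = ii[keep] + 1L, j = jj[keep] + 1L,
                            x = xx[keep], dims = c(n, n_feat * n_lags))
  structure(list(values = X, lag_axis = lags * 1000 / fs, fs = fs,
                 n_lags = n_lags, feature_labels = feats$feature_labels),
            class = "lagged_design")
}

#' @noRd
design_stats <- function(X, Y) {
  list(XtX = as.matrix(Matrix::crossprod(X)),
       XtY = as.matrix(Matrix::crossprod(X, Y)),
       n = nrow(X))
}

# Solve (XtX + lambda * M) W = XtY. M defaults to the identity; "derivative"
# uses a banded second-difference roughness penalty over lags within each
# feature.
#' @noRd
ridge_solve <- function(XtX, XtY, lambda, penalty = "identity",
                        n_lags = NULL) {
  p <- nrow(XtX)
  M <- if (identical(penalty, "identity")) {
    diag(p)
  } else if (identical(penalty, "derivative")) {
    stopifnot(!is.null(n_lags), p %% n_lags == 0L)
    D <- diff(diag(n_lags), differences = 2L)
    Mi <- crossprod(D)
    kronecker(diag(p %/% n_lags), Mi)
  } else stopf("unknown penalty '%s'", penalty)
  A <- XtX + lambda * M
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    stopf("normal equations are numerically singular (lambda = %g); increase lambda",
          lambda)
  }
  backsolve(R, backsolve(R, XtY, transpose = TRUE))
}

#' @noRd
new_trf_model <- function(W, design, eeg, lambda, lag_window) {
  n_lags <- design$n_lags
  n_feat <- length(design$feature_labels)
  n_chan <- ncol(W)
  weights <- aperm(array(W, dim = c(n_lags, n_feat, n_chan)), c(2L, 1L, 3L))
  dimnames(weights) <- list(design$feature_labels, NULL, eeg$channel_labels)
  structure(list(weights = weights, lambda = lambda,
                 lag_window = lag_window, lag_axis = design$lag_axis,
                 fs = design$fs, feature_labels = design$feature_labels,
                 channel_labels = eeg$channel_labels),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<trf_model> %d features x %d lags x %d channels, lambda = %g, lags [%g, %g] ms\n",
              d[1], d[2], d[3], x$lambda, x$lag_window[1], x$lag_window[2]))
  invisible(x)
}

#' Fit a TRF by ridge regression
#'
#' Solves the penalized normal equations
#' `(S'S + lambda M) w = S'r` per channel, where `S` is the lagged design
#' matrix, and reshapes the weights to feature x lag x channel. With
#' `lambda = 0` this is the ordinary least-squares forward model; a singular
#' system then raises an error rather than silently pseudo-inverting.
#'
#' @param feats A [feature_matrix()] (or a prebuilt `lagged_design`).
#' @param eeg An [eeg_recording()] time-aligned with `feats`.
#' @param lambda Ridge parameter (>= 0).
#' @param lag_window Lag window in ms.
#' @param penalty `"identity"` (standard ridge) or `"derivative"` (banded
#'   second-derivative roughness penalty).
#' @return A `trf_model`.
#' @export
ridge_fit <- function(feats, eeg, lambda, lag_window = c(-100, 500),
                      penalty = "identity") {
  design <- if (inherits(feats, "lagged_design")) feats else
    lag_matrix(feats, lag_window)
  stopifnot(inherits(eeg, "eeg_recording"))
  if (nrow(design$values) != ncol(eeg$data)) {
    stopf("design (%d samples) and EEG (%d samples) are not time-aligned",
          nrow(design$values), ncol(eeg$data))
  }
  st <- design_stats(design$values, t(eeg$data))
  W <- ridge_solve(st$XtX, st$XtY, lambda, penalty, design$n_lags)
  new_trf_model(W, design, eeg, lambda, lag_window)
}

#' @noRd
flatten_weights <- function(model) {
  # inverse of the reshape in new_trf_model: (feature-major, lag fastest)
  w <- aperm(model$weights, c(2L, 1L, 3L))
  dim(w) <- c(dim(model$weights)[1] * dim(model$weights)[2],
              dim(model$weights)[3])
  w
}

#' Predict EEG from a TRF model and score the prediction
#'
#' Prediction is `S w`; the score is the Pearson correlation between
#' predicted and observed EEG per channel (defined as 0 when either side has
#' zero variance), summarized by the channel mean.
#'
#' @param model A `trf_model`.
#' @param feats The stimulus [feature_matrix()].
#' @param eeg The observed [eeg_recording()].
#' @return List with `r` (per channel), `mean_r`, and `prediction`
#'   (time x channel).
#' @export
predict_trf <- function(model, feats, eeg) {
  design <- if (inherits(feats, "lagged_design")) feats else
    lag_matrix(feats, model$lag_window, model$fs)
  W <- flatten_weights(model)
  P <- as.matrix(design$values %*% W)
  r <- vapply(seq_len(ncol(P)), function(c) safe_cor(P[, c], eeg$data[c, ]), 1)
  names(r) <- eeg$channel_labels
  list(r = r, mean_r = mean(r), prediction = P)
}

#' @noRd
cor_by_channel <- function(P, Yobs) {
  vapply(seq_len(ncol(P)), function(c) safe_cor(P[, c], Yobs[, c]), 1)
}

#' Segment-based cross-validated TRF fit
#'
#' The recording is split into `n_segments` contiguous equal-length segments.
#' For each rotation one segment is held out; within the remaining training
#' segments an inner leave-one-segment-out loop selects the ridge parameter
#' maximizing the mean validation correlation; the model is refit on all
#' training segments at the selected lambda and scored on the held-out
#' segment. The returned model is refit on the full recording at the modal
#' selected lambda (ties to the smaller value).
#'
#' @param feats A [feature_matrix()].
#' @param eeg An [eeg_recording()].
#' @param cfg A [cv_config()].
#' @param penalty Passed to the ridge solver.
#' @return List with `model` (trf_model), `perf` (data frame: segment,
#'   lambda, r), `mean_r`, `lambda` and per-channel fold correlations
#'   `r_channel` (segment x channel).
#' @export
crossval_fit <- function(feats, eeg, cfg = cv_config(), penalty = "identity") {
  stopifnot(inherits(feats, "feature_matrix"), inherits(eeg, "eeg_recording"))
  design <- lag_matrix(feats, cfg$lag_window)
  n <- nrow(design$values)
  if (n != ncol(eeg$data)) stopf("features and EEG are not time-aligned")
  span <- design$n_lags
  if (n < cfg$n_segments * span) stopf("recording too short for %d segments",
                                       cfg$n_segments)
  Y <- t(eeg$data)
  segs <- contiguous_segments(n, cfg$n_segments)
  st <- lapply(segs, function(ix) design_stats(design$values[ix, , drop = FALSE],
                                               Y[ix, , drop = FALSE]))
  add_stats <- function(ids) {
    Reduce(function(a, b) list(XtX = a$XtX + b$XtX, XtY = a$XtY + b$XtY,
                               n = a$n + b$n), st[ids])
  }
  nl <- cfg$lambda_grid
  lam_star <- numeric(cfg$n_segments)
  fold_r <- matrix(NA_real_, cfg$n_segments, nrow(eeg$data))
  for (o in seq_len(cfg$n_segments)) {
    train <- setdiff(seq_len(cfg$n_segments), o)
    val_score <- matrix(NA_real_, length(train), length(nl))
    for (vi in seq_along(train)) {
      v <- train[vi]
      sub <- add_stats(setdiff(train, v))
      Xv <- design$values[segs[[v]], , drop = FALSE]
      Yv <- Y[segs[[v]], , drop = FALSE]
      for (li in seq_along(nl)) {
        W <- ridge_solve(sub$XtX, sub$XtY, nl[li], penalty, design$n_lags)
        val_score[vi, li] <- mean(cor_by_channel(as.matrix(Xv %*% W), Yv))
      }
    }
    li_star <- which.max(colMeans(val_score))
    lam_star[o] <- nl[li_star]
    full_train <- add_stats(train)
    W <- ridge_solve(full_train$XtX, full_train$XtY, lam_star[o], penalty,
                     design$n_lags)
    Xo <- design$values[segs[[o]], , drop = FALSE]
    fold_r[o, ] <- cor_by_channel(as.matrix(Xo %*% W), Y[segs[[o]], , drop = FALSE])
  }
  tab <- table(lam_star)
  lambda_final <- min(as.numeric(names(tab)[tab == max(tab)]))
  all_st <- add_stats(seq_len(cfg$n_segments))
  W <- ridge_solve(all_st$XtX, all_st$XtY, lambda_final, penalty, design$n_lags)
  model <- new_trf_model(W, design, eeg, lambda_final, cfg$lag_window)
  perf <- data.frame(segment = seq_len(cfg$n_segments), lambda = lam_star,
                     r = rowMeans(fold_r))
  list(model = model, perf = perf, mean_r = mean(perf$r),
       lambda = lambda_final, r_channel = fold_r)
}
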