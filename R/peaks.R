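# N1/P2 peak extraction from TRF weights, amplitude-vs-IOI curve fits, and
# the gradient-score permutation test.

#' Peak search windows
#'
#' @param n1_window N1 search window in ms (minimum; default `c(70, 160)`).
#' @param p2_window P2 search window in ms (maximum; default `c(160, 300)`).
#' @param channel_set Channel labels to average before peak extraction
#'   (`NULL` = all channels; typically a fronto-central set).
#' @param baseline_window Pre-onset lag window in ms whose mean is
#'   subtracted from each bin's weight curve before peak measurement
#'   (standard evoked-response baselining; `NULL` disables).
#' @return A `peak_windows` list.
#' @export
peak_windows <- function(n1_window = c(70, 160), p2_window = c(160, 300),
                         channel_set = NULL, baseline_window = c(-100, 0)) {
  stopifnot(length(n1_window) == 2L, length(p2_window) == 2L,
            n1_window[1] < n1_window[2], p2_window[1] < p2_window[2])
  structure(list(n1_window = n1_window, p2_window = p2_window,
                 channel_set = channel_set, baseline_window = baseline_window),
            class = "peak_windows")
}

#' Extract per-bin N1/P2 peaks from a TRF model
#'
#' Averages the weights over the requested channel set, then takes the
#' minimum in the N1 window and the maximum in the P2 window per feature
#' (bin). Latency ties resolve to the first sample of the window.
#'
#' @param model A `trf_model` (features = IOI bins, labelled by their upper
#'   IOI edge).
#' @param wins A [peak_windows()].
#' @return A `peak_table` data frame: `bin_upper_edge`, `n1_amplitude`,
#'   `n1_latency_ms`, `p2_amplitude`, `p2_latency_ms`.
#' @export
extract_peaks <- function(model, wins = peak_windows()) {
  stopifnot(inherits(model, "trf_model"))
  chans <- if (is.null(wins$channel_set)) model$channel_labels else wins$channel_set
  ci <- match(chans, model$channel_labels)
  if (anyNA(ci)) stopf("unknown channels: %s",
                       paste(chans[is.na(ci)], collapse = ", "))
  avg <- apply(model$weights[, , ci, drop = FALSE], c(1, 2), mean)
  lag <- model$lag_axis
  if (!is.null(wins$baseline_window)) {
    ib <- which(lag >= wins$baseline_window[1] & lag < wins$baseline_window[2])
    if (length(ib)) avg <- avg - rowMeans(avg[, ib, drop = FALSE])
  }
  in_win <- function(w) which(lag >= w[1] & lag <= w[2])
  i_n1 <- in_win(wins$n1_window)
  i_p2 <- in_win(wins$p2_window)
  if (!length(i_n1) || !length(i_p2)) stopf("peak windows outside lag window")
  edge <- suppressWarnings(as.numeric(model$feature_labels))
  res <- data.frame(
    bin_upper_edge = edge,
    n1_amplitude = apply(avg[, i_n1, drop = FALSE], 1, min),
    n1_latency_ms = lag[i_n1[apply(avg[, i_n1, drop = FALSE], 1, which.min)]],
    p2_amplitude = apply(avg[, i_p2, drop = FALSE], 1, max),
    p2_latency_ms = lag[i_p2[apply(avg[, i_p2, drop = FALSE], 1, which.max)]]
  )
  structure(res, class = c("peak_table", "data.frame"))
}

#' @noRd
component_amplitudes <- function(table, component) {
  component <- match.arg(component, c("N1", "P2"))
  ord <- order(table$bin_upper_edge)
  a <- if (component == "N1") table$n1_amplitude else table$p2_amplitude
  list(x = table$bin_upper_edge[ord], a = a[ord], component = component)
}

#' Gradient (rate-of-change) score
#'
#' Sum of consecutive differences of peak amplitudes ordered by bin IOI. By
#' the telescoping identity this equals last minus first amplitude;
#' `signed = FALSE` gives the sum of absolute differences instead.
#'
#' @param table A `peak_table`.
#' @param component `"N1"` or `"P2"`.
#' @param signed Use signed consecutive differences (default) or absolute.
#' @return Scalar score.
#' @export
gradient_score <- function(table, component = c("N1", "P2"), signed = TRUE) {
  ca <- component_amplitudes(table, match.arg(component))
  d <- diff(ca$a)
  if (signed) sum(d) else sum(abs(d))
}

#' @noRd
r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  1 - sum((y - yhat)^2) / sst
}

#' Fit amplitude-versus-IOI curves
#'
#' Least-squares fits of three families to peak amplitude as a function of
#' the bin's upper IOI edge: logistic `A / (1 + exp(-k (x - x0)))`,
#' exponential `A (1 - exp(-x / tau))`, and a second-degree polynomial.
#' Nonlinear families use bounded multi-start Nelder-Mead (5 deterministic
#' starts). Points from several bin models may be pooled before calling.
#'
#' @param table A `peak_table` (possibly row-bound across bin models).
#' @param component `"N1"` or `"P2"`.
#' @return List of `fit_result`s (one per family: `family`, `params`,
#'   `r_squared`, `fitted`) plus attribute `best` naming the family with
#'   maximal R-squared.
#' @export
fit_amplitude_curves <- function(table, component = c("N1", "P2")) {
  ca <- component_amplitudes(table, match.arg(component))
  x <- ca$x; y <- ca$a
  if (length(x) < 3L) stopf("need >= 3 points for 3-parameter curve fits")
  rngy <- diff(range(y))
  scale0 <- if (rngy > 0) rngy else 1
  fits <- list()

  fit_family <- function(family, par0, fn) {
    # 5 deterministic multi-starts around par0
    jit <- rbind(1, 0.5, 2, 0.8, 1.25)
    best <- NULL
    for (s in seq_len(nrow(jit))) {
      p0 <- par0 * jit[s, 1]
      opt <- tryCatch(
        stats::optim(p0, function(p) sum((y - fn(p, x))^2),
                     method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
    yhat <- fn(best$par, x)
    structure(list(family = family, params = best$par,
                   r_squared = r_squared(y, yhat), fitted = yhat),
              class = "fit_result")
  }

  sgn <- if (mean(y) < 0) -1 else 1
  fits$logistic <- fit_family(
    "logistic",
    c(A = sgn * max(abs(y)), k = 1 / max(stats::sd(x), 0.1), x0 = stats::median(x)),
    function(p, x) p[1] / (1 + exp(-p[2] * (x - p[3]))))
  fits$exponential <- fit_family(
    "exponential",
    c(A = sgn * max(abs(y)), tau = max(stats::median(x), 0.1)),
    function(p, x) p[1] * (1 - exp(-x / max(p[2], 1e-6))))
  pf <- stats::lm(y ~ x + I(x^2))
  fits$poly2 <- structure(list(family = "poly2", params = stats::coef(pf),
                               r_squared = r_squared(y, stats::fitted(pf)),
                               fitted = stats::fitted(pf)),
                          class = "fit_result")
  r2 <- vapply(fits, function(f) f$r_squared, 1)
  attr(fits, "best") <- names(fits)[which.max(r2)]
  fits
}

#' Bin-allocation permutation test of the gradient score
#'
#' Fits the observed binned-onset TRF (cross-validated lambda selection),
#' extracts N1/P2 peaks and their gradient scores, then repeats the fit for
#' `n_perm` random reallocations of onsets to bins (per-bin counts
#' preserved; same lambda as the observed model). Two-sided p-value with
#' add-one correction: `p = (1 + #{|null| >= |observed|}) / (n_perm + 1)`.
#'
#' @param onsets An [onset_events()] table with IOIs computed.
#' @param eeg An [eeg_recording()].
#' @param spec A [make_uniform_bins()] result.
#' @param cfg A [cv_config()].
#' @param wins A [peak_windows()].
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed.
#' @param lambda Fixed ridge parameter; `NULL` (default) selects it by
#'   cross-validation on the observed model.
#' @return A `permutation_result`: per component, `observed`, `null_scores`,
#'   `p_value` (and `p_fdr`, initialized to `p_value`; see
#'   [adjust_fdr_across_models()]). Also carries the observed `peak_table`
#'   and fitted model.
#' @export
permutation_test <- function(onsets, eeg, spec, cfg = cv_config(),
                             wins = peak_windows(), n_perm = 100L, seed = 1L,
                             lambda = NULL) {
  n_samples <- ncol(eeg$data)
  feats <- binned_onset_matrix(onsets, spec, eeg$fs, n_samples)
  if (is.null(lambda)) {
    cvf <- crossval_fit(feats, eeg, cfg)
    model <- cvf$model
    lambda <- cvf$lambda
  } else {
    model <- ridge_fit(feats, eeg, lambda, cfg$lag_window)
  }
  obs_tab <- extract_peaks(model, wins)
  obs <- c(N1 = gradient_score(obs_tab, "N1"),
           P2 = gradient_score(obs_tab, "P2"))
  Y <- t(eeg$data)
  null_scores <- matrix(NA_real_, n_perm, 2L,
                        dimnames = list(NULL, c("N1", "P2")))
  seeds <- with_local_seed(seed, sample.int(.Machine$integer.max, n_perm))
  for (b in seq_len(n_perm)) {
    pf <- permute_bin_allocation(onsets, spec, eeg$fs, n_samples, seeds[b])
    pd <- lag_matrix(pf, cfg$lag_window)
    st <- design_stats(pd$values, Y)
    W <- ridge_solve(st$XtX, st$XtY, lambda, "identity", pd$n_lags)
    pm <- new_trf_model(W, pd, eeg, lambda, cfg$lag_window)
    ptab <- extract_peaks(pm, wins)
    null_scores[b, ] <- c(gradient_score(ptab, "N1"),
                          gradient_score(ptab, "P2"))
  }
  pval <- vapply(c("N1", "P2"), function(k) {
    (1 + sum(abs(null_scores[, k]) >= abs(obs[k]))) / (n_perm + 1)
  }, 1)
  structure(list(observed = obs, null_scores = null_scores,
                 p_value = pval, p_fdr = pval, n_perm = n_perm,
                 peak_table = obs_tab, model = model, lambda = lambda),
            class = "permutation_result")
}

#' FDR-adjust permutation p-values across bin models
#'
#' Benjamini-Hochberg adjustment applied per component across a family of
#' permutation results (e.g., the seven bin models, 2 to 8 bins).
#'
#' @param results List of `permutation_result`s.
#' @return The list with each element's `p_fdr` replaced by the adjusted
#'   values.
#' @export
adjust_fdr_across_models <- function(results) {
  stopifnot(all(vapply(results, inherits, TRUE, "permutation_result")))
  for (k in c("N1", "P2")) {
    p <- vapply(results, function(r) r$p_value[[k]], 1)
    padj <- stats::p.adjust(p, method = "BH")
    for (i in seq_along(results)) results[[i]]$p_fdr[[k]] <- padj[i]
  }
  results
}
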