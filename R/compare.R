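# Paired comparisons of model prediction accuracies and training-data
# matched model variants.

#' Paired Wilcoxon signed-rank comparison
#'
#' Two-sided signed-rank test on per-participant prediction accuracies.
#' Zero differences are dropped; tied absolute differences get mid-ranks.
#' For fewer than 10 non-zero pairs the p-value comes from exact enumeration
#' of all sign assignments (respecting ties); otherwise from the normal
#' approximation with tie and continuity corrections. `W` is the sum of
#' positive-difference ranks and the effect size is `rho = |Z| / sqrt(n)`.
#'
#' @param a,b Numeric vectors of per-participant scores (paired).
#' @param n_comparisons Bonferroni multiplier for the reported corrected
#'   p-value (default 1).
#' @return A `comparison_result`: `W`, `Z`, `p` (corrected, capped at 1),
#'   `p_raw`, `rho`, `n` (non-zero pairs).
#' @export
wilcoxon_compare <- function(a, b, n_comparisons = 1L) {
  stopifnot(length(a) == length(b), n_comparisons >= 1L)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(W = 0, Z = 0, p = 1, p_raw = 1, rho = 0, n = 0L),
                     class = "comparison_result"))
  }
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  sigma <- sqrt(sigma2)
  cc <- if (W == mu) 0 else sign(W - mu) * 0.5
  Z <- if (sigma > 0) (W - mu - cc) / sigma else 0
  if (n < 10L) {
    # exact two-sided p by enumeration over all 2^n sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wnull <- as.numeric(signs %*% rk)
    p_raw <- min(1, 2 * min(mean(Wnull <= W), mean(Wnull >= W)))
  } else {
    p_raw <- 2 * stats::pnorm(-abs(Z))
  }
  structure(list(W = W, Z = Z, p = min(1, p_raw * n_comparisons),
                 p_raw = p_raw, rho = abs(Z) / sqrt(n), n = n),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("W = %g, Z = %.2f, p = %.4g (raw %.4g), rho = %.2f, n = %d\n",
              x$W, x$Z, x$p, x$p_raw, x$rho, x$n))
  invisible(x)
}

#' Onset-count-matched single-onset feature matrices
#'
#' Draws `n_reps` random subsets of exactly `n_keep` eligible onsets (without
#' replacement) and encodes each as a single binary onset vector, matching
#' the per-bin training-data volume of a binned model.
#'
#' @param onsets An [onset_events()] table with IOIs computed.
#' @param n_keep Number of onsets per replicate.
#' @param fs Rate (Hz). @param n_samples Output length.
#' @param n_reps Number of replicates (default 100).
#' @param seed Integer seed.
#' @return List of `n_reps` single-column [feature_matrix()] objects.
#' @export
matched_onset_subsample <- function(onsets, n_keep, fs, n_samples,
                                    n_reps = 100L, seed = 1L) {
  stopifnot(inherits(onsets, "onset_events"))
  el <- which(onsets$eligible)
  if (n_keep > length(el)) stopf("n_keep (%d) exceeds eligible onsets (%d)",
                                 n_keep, length(el))
  with_local_seed(seed, {
    lapply(seq_len(n_reps), function(b) {
      pick <- sort(sample(el, n_keep))
      sub <- onsets[pick, , drop = FALSE]
      idx <- floor(sub$time * fs) + 1L
      idx <- idx[idx <= n_samples]
      feature_matrix(
        Matrix::sparseMatrix(i = idx, j = rep(1L, length(idx)),
                             x = rep(1, length(idx)),
                             dims = c(n_samples, 1L)),
        fs, "onset")
    })
  })
}

#' @noRd
concat_datasets <- function(datasets) {
  feats <- lapply(datasets, `[[`, "feats")
  eegs <- lapply(datasets, `[[`, "eeg")
  fs <- eegs[[1]]$fs
  vals <- do.call(rbind, lapply(feats, `[[`, "values"))
  dat <- do.call(cbind, lapply(eegs, `[[`, "data"))
  list(feats = feature_matrix(vals, fs, feats[[1]]$feature_labels),
       eeg = eeg_recording(dat, fs, eegs[[1]]$channel_labels))
}

#' Merged-condition (pooled) training
#'
#' Concatenates several recordings of one participant along time and runs the
#' rotating segment cross-validation with `n_segments` folds (default 12,
#' i.e., twice the per-condition segmentation when two conditions are
#' merged). Lagged designs are built per recording before concatenation, so
#' lags never cross a condition boundary.
#'
#' @param datasets List of `list(feats = feature_matrix, eeg = eeg_recording)`.
#' @param cfg A [cv_config()]; `n_segments` defaults to 12 here.
#' @return The [crossval_fit()] result on the merged data.
#' @export
merged_condition_training <- function(datasets, cfg = cv_config(n_segments = 12L)) {
  merged <- concat_datasets(datasets)
  crossval_fit(merged$feats, merged$eeg, cfg)
}

#' Generic leave-one-participant-out models
#'
#' For each participant, trains a model on the concatenation of all other
#' participants' data (ridge parameter selected by segment cross-validation
#' on the training pool) and scores it on the held-out participant.
#'
#' @param datasets Named list per participant of
#'   `list(feats = feature_matrix, eeg = eeg_recording)`.
#' @param cfg A [cv_config()].
#' @return Data frame (`participant`, `r`) of held-out channel-mean
#'   correlations, one row per participant.
#' @export
generic_lopo <- function(datasets, cfg = cv_config()) {
  n <- length(datasets)
  stopifnot(n >= 2L)
  ids <- names(datasets)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  r <- numeric(n)
  for (p in seq_len(n)) {
    train <- concat_datasets(datasets[-p])
    fit <- crossval_fit(train$feats, train$eeg, cfg)
    held <- datasets[[p]]
    r[p] <- predict_trf(fit$model, held$feats, held$eeg)$mean_r
  }
  data.frame(participant = ids, r = r)
}
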