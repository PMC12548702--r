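# Peak extraction, curve fitting, gradient score, permutation machinery.

make_model <- function(curves, lag_window = c(-100, 500), fs = 100,
                       n_chan = 2) {
  # curves: list of per-bin lag curves (length 61)
  n_lags <- round(diff(lag_window) * fs / 1000) + 1
  stopifnot(all(lengths(curves) == n_lags))
  w <- array(0, dim = c(length(curves), n_lags, n_chan))
  for (i in seq_along(curves)) for (c in seq_len(n_chan)) w[i, , c] <- curves[[i]]
  structure(list(weights = w, lambda = 1, lag_window = lag_window,
                 lag_axis = seq(lag_window[1], lag_window[2], by = 1000 / fs),
                 fs = fs, feature_labels = as.character(seq_along(curves)),
                 channel_labels = paste0("Ch", seq_len(n_chan))),
            class = "trf_model")
}

test_that("extract_peaks reads off constructed troughs and peaks exactly", {
  lag <- seq(-100, 500, by = 10)
  curve <- numeric(61)
  curve[lag == 110] <- -2
  curve[lag == 220] <- 1.5
  tab <- extract_peaks(make_model(list(curve)), peak_windows())
  expect_equal(tab$n1_amplitude, -2)
  expect_equal(tab$n1_latency_ms, 110)
  expect_equal(tab$p2_amplitude, 1.5)
  expect_equal(tab$p2_latency_ms, 220)
  # all-zero weights: amplitudes 0, latency at window start (tie rule)
  tab0 <- extract_peaks(make_model(list(numeric(61))), peak_windows())
  expect_equal(tab0$n1_amplitude, 0)
  expect_equal(tab0$n1_latency_ms, 70)
  expect_equal(tab0$p2_latency_ms, 160)
})

test_that("baseline correction removes a constant curve offset", {
  lag <- seq(-100, 500, by = 10)
  curve <- rep(0.7, 61)
  curve[lag == 110] <- 0.7 - 2
  tab <- extract_peaks(make_model(list(curve)), peak_windows())
  expect_equal(tab$n1_amplitude, -2)
  tab_nb <- extract_peaks(make_model(list(curve)),
                          peak_windows(baseline_window = NULL))
  expect_equal(tab_nb$n1_amplitude, 0.7 - 2)
})

test_that("gradient score telescopes and is bounded by max - min", {
  set.seed(6)
  for (i in 1:20) {
    nb <- sample(3:8, 1)
    tab <- structure(data.frame(bin_upper_edge = sort(runif(nb, 0.2, 8)),
                                n1_amplitude = rnorm(nb),
                                n1_latency_ms = 100,
                                p2_amplitude = rnorm(nb),
                                p2_latency_ms = 200),
                     class = c("peak_table", "data.frame"))
    for (comp in c("N1", "P2")) {
      a <- if (comp == "N1") tab$n1_amplitude else tab$p2_amplitude
      expect_equal(gradient_score(tab, comp), a[nb] - a[1])
    }
  }
  tab3 <- structure(data.frame(bin_upper_edge = 1:3, n1_amplitude = c(1, 2, 3),
                               n1_latency_ms = 100, p2_amplitude = 0,
                               p2_latency_ms = 200),
                    class = c("peak_table", "data.frame"))
  expect_equal(gradient_score(tab3, "N1"), 2)
  # brute force over all orderings of a 5-vector: |score| <= max - min
  amps <- c(0.3, -1.2, 2.5, 0.9, -0.4)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  scores <- apply(perms, 1, function(p) sum(diff(amps[p])))
  expect_true(all(abs(scores) <= max(amps) - min(amps) + 1e-12))
  expect_equal(max(scores), max(amps) - min(amps))
})

test_that("curve fits select the generating family and handle edge cases", {
  x <- c(0.4, 0.8, 1.3, 2.0, 3.1, 5.0, 8.0)
  logi <- function(x) 0.8 / (1 + exp(-2.2 * (x - 1.5)))
  set.seed(17)
  tab <- structure(data.frame(bin_upper_edge = x,
                              n1_amplitude = 0, n1_latency_ms = 100,
                              p2_amplitude = logi(x) + rnorm(7, sd = 0.002),
                              p2_latency_ms = 200),
                   class = c("peak_table", "data.frame"))
  fits <- fit_amplitude_curves(tab, "P2")
  expect_equal(attr(fits, "best"), "logistic")
  expect_gt(fits$logistic$r_squared, 0.99)
  # three points: poly2 interpolates exactly
  tab3 <- structure(data.frame(bin_upper_edge = 1:3,
                               n1_amplitude = c(-1, -2, -2.5),
                               n1_latency_ms = 100, p2_amplitude = 1,
                               p2_latency_ms = 200),
                    class = c("peak_table", "data.frame"))
  fits3 <- fit_amplitude_curves(tab3, "N1")
  expect_equal(fits3$poly2$r_squared, 1)
  # constant amplitudes: R^2 defined as 0 for every family
  tabc <- tab
  tabc$p2_amplitude <- 0.5
  fitsc <- fit_amplitude_curves(tabc, "P2")
  expect_true(all(vapply(fitsc, function(f) f$r_squared, 1) == 0))
  expect_error(fit_amplitude_curves(tab3[1:2, ], "N1"), "points")
})

test_that("best-family selection separates logistic from poly2 under 5% noise", {
  x <- c(0.4, 0.8, 1.3, 2.0, 3.1, 5.0, 8.0)
  logi <- 1 / (1 + exp(-2.5 * (x - 1.8)))
  poly <- 0.2 + 0.45 * x - 0.042 * x^2
  set.seed(23)
  hit <- 0
  n_rep <- 50
  for (b in seq_len(n_rep)) {
    for (truth in c("logistic", "poly2")) {
      y <- (if (truth == "logistic") logi else poly)
      y <- y + rnorm(7, sd = 0.05 * diff(range(y)))
      tab <- structure(data.frame(bin_upper_edge = x, n1_amplitude = 0,
                                  n1_latency_ms = 100, p2_amplitude = y,
                                  p2_latency_ms = 200),
                       class = c("peak_table", "data.frame"))
      best <- attr(fit_amplitude_curves(tab, "P2"), "best")
      hit <- hit + (best == truth)
    }
  }
  expect_gte(hit / (2 * n_rep), 0.9)
})

test_that("permutation p-value floor and FDR monotonicity hold", {
  sub <- small_subject(seed = 77, duration = 150, n_channels = 4,
                       snr_db = 20)   # strong signal: observed far outside null
  spec <- make_uniform_bins(sub$onsets$ioi[sub$onsets$eligible], 3)
  pt <- permutation_test(sub$onsets, sub$eeg, spec, cv_config(),
                         peak_windows(), n_perm = 24, seed = 3, lambda = 1)
  expect_equal(unname(pt$p_value[["N1"]]), 1 / 25)
  expect_equal(nrow(pt$null_scores), 24L)
  expect_true(all(pt$p_value >= 1 / 25))
  # BH adjustment never decreases a p-value
  res <- lapply(1:4, function(s) {
    p <- pt
    p$p_value[] <- c(0.01, 0.2, 0.04, 0.8)[s]
    p
  })
  adj <- adjust_fdr_across_models(res)
  for (i in 1:4) expect_gte(adj[[i]]$p_fdr[["N1"]], res[[i]]$p_value[["N1"]])
})
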