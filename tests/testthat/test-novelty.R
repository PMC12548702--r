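# Novelty functions and onset detection.

toy_cfg <- function(fs) novelty_config(stft_win = 256, energy_win = 81)

test_that("all novelty kinds are zero on silent audio and nonnegative in general", {
  fs <- 800
  silent <- audio_signal(rep(0, 5 * fs), fs)
  for (f in list(energy_novelty, spectral_novelty, complex_novelty)) {
    nv <- f(silent, toy_cfg(fs))
    expect_true(all(nv$values == 0))
  }
  set.seed(4)
  noisy <- audio_signal(rnorm(2 * fs, sd = 0.1), fs)
  lens <- integer(0)
  for (f in list(energy_novelty, spectral_novelty, complex_novelty)) {
    nv <- f(noisy, toy_cfg(fs))
    expect_true(all(nv$values >= 0))
    lens <- c(lens, length(nv$values))
  }
  expect_length(unique(lens), 1L)
})

test_that("energy novelty: stationary sine ~ 0, amplitude step peaks at the step", {
  fs <- 800
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  sine <- audio_signal(sin(2 * pi * 50 * t), fs)
  nv <- energy_novelty(sine, toy_cfg(fs))
  # ignore the initial transient (first 0.3 s)
  expect_lt(max(nv$values[-(1:30)]), 1e-3)

  step <- audio_signal(ifelse(t >= 1.0, sin(2 * pi * 50 * t), 0), fs)
  nvs <- energy_novelty(step, toy_cfg(fs))
  peak_at <- (which.max(nvs$values) - 1) / nvs$fs
  expect_lt(abs(peak_at - 1.0), 0.11)  # within one energy window of the step
})

test_that("energy novelty matches a direct-loop oracle on a toy signal", {
  fs <- 800
  set.seed(11)
  x <- c(rep(0, 800), rnorm(400, sd = 0.5), rep(0, 400))
  cfg <- toy_cfg(fs)
  got <- energy_novelty(audio_signal(x, fs), cfg)$values
  # oracle: square -> centred Hann convolution -> decimate -> log -> diff -> rectify
  W <- 81L
  w <- 0.5 * (1 - cos(2 * pi * (0:(W - 1)) / (W - 1)))
  w <- w / sum(w)
  xsq <- c(rep(0, W), x^2, rep(0, W))
  e <- sapply(seq_along(x), function(i) {
    sum(w * xsq[(i + W - (W - 1) %/% 2):(i + W + (W - 1) %/% 2)])
  })
  d <- fs / 100
  L <- floor(length(x) / d)
  ed <- e[1 + (seq_len(L) - 1) * d]
  oracle <- c(0, pmax(0, diff(log(1 + 10 * ed))))
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("spectral novelty flags a frequency switch that energy novelty misses", {
  fs <- 800
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  x <- ifelse(t < 2, sin(2 * pi * 55 * t), sin(2 * pi * 110 * t))
  aud <- audio_signal(x, fs)
  cfg <- toy_cfg(fs)
  sp <- spectral_novelty(aud, cfg)
  en <- energy_novelty(aud, cfg)
  switch_idx <- 2 * 100 + 1
  win <- (switch_idx - 20):(switch_idx + 20)
  # peak within half an STFT window (256 / 2 samples = 16 novelty frames)
  expect_lte(abs(which.max(sp$values) - switch_idx), 16)
  # energy novelty at the switch stays small relative to the spectral peak
  expect_lt(max(en$values[win]) / max(en$values), 0.5)
})

test_that("complex novelty: stationary sine ~ 0, pi phase jump peaks at the jump", {
  fs <- 800
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  cfg <- toy_cfg(fs)
  stat <- complex_novelty(audio_signal(sin(2 * pi * 55 * t), fs), cfg)
  jump <- complex_novelty(
    audio_signal(sin(2 * pi * 55 * t + pi * (t >= 2)), fs), cfg)
  switch_idx <- 2 * 100 + 1
  expect_lte(abs(which.max(jump$values) - switch_idx), 16)
  # interior of the stationary sine (excluding on/offset transients) ~ 0
  L <- length(stat$values)
  interior <- stat$values[40:(L - 40)]
  expect_lt(max(interior), max(jump$values) / 10)
})

test_that("combine_novelty normalizes, averages, and handles degenerate input", {
  fs <- 100
  mk <- function(v) ioitrf:::new_novelty(v, fs, "energy")
  v <- c(0, 2, 8, 4, 0, 1)
  out <- combine_novelty(list(mk(v), mk(v), mk(v)))
  expect_equal(out$values, v / 8)
  out2 <- combine_novelty(list(mk(rep(0, 6)), mk(v)))
  expect_equal(out2$values, v / 8 / 2)
  # disjoint unit peaks average to 1/3
  p1 <- c(1, 0, 0); p2 <- c(0, 1, 0); p3 <- c(0, 0, 1)
  out3 <- combine_novelty(list(mk(p1), mk(p2), mk(p3)))
  expect_equal(out3$values, rep(1 / 3, 3))
  # constant function normalizes to zero
  out4 <- combine_novelty(list(mk(rep(5, 6)), mk(v)))
  expect_equal(out4$values, v / 8 / 2)
  expect_error(combine_novelty(list(mk(v), mk(v[-1]))), "length")
})

test_that("pick_onsets follows the adaptive threshold rule", {
  fs <- 100
  mk <- function(v) ioitrf:::new_novelty(v, fs, "combined")
  # constant novelty: nothing exceeds mean + 0.05
  expect_equal(nrow(pick_onsets(mk(rep(0.3, 2000)))), 0L)
  # one wide triangular peak on a low background
  v <- rep(0.1, 2000)
  apex <- 501L
  v[(apex - 10):(apex + 10)] <- 0.1 + 0.9 * (1 - abs(-10:10) / 10)
  on <- pick_onsets(mk(v))
  expect_equal(nrow(on), 1L)
  expect_equal(on$time, (apex - 1) / fs)
  # two well-separated peaks, ascending times
  v2 <- rep(0.05, 3000)
  for (a in c(701L, 2101L)) v2[(a - 8):(a + 8)] <- 0.05 + (1 - abs(-8:8) / 8)
  on2 <- pick_onsets(mk(v2))
  expect_equal(nrow(on2), 2L)
  expect_equal(on2$time, c(700, 2100) / fs)
  expect_error(pick_onsets(mk(numeric(0))), "empty")
})

test_that("encode_onset_vector uses the floor() sample convention", {
  ev <- onset_events(c(1.0, 2.5))
  fm <- encode_onset_vector(ev, 100, 400)
  expect_equal(which(as.numeric(fm$values) != 0), c(101L, 251L))
  expect_equal(sum(fm$values), 2)
  expect_equal(sum(encode_onset_vector(onset_events(numeric(0)), 100, 50)$values), 0)
  fm3 <- encode_onset_vector(onset_events(1.234), 100, 200)
  expect_equal(which(as.numeric(fm3$values) != 0), 124L)  # 0-based index 123
})

test_that("amplitude scaling leaves spectral/complex peak locations unchanged", {
  fs <- 800
  set.seed(9)
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  x <- rnorm(length(t), sd = 0.003)
  for (on in c(0.8, 1.9)) {
    i <- round(on * fs):round((on + 0.15) * fs)
    x[i] <- x[i] + sin(2 * pi * 440 * t[i])
  }
  cfg <- toy_cfg(fs)
  for (f in list(spectral_novelty, complex_novelty)) {
    a <- f(audio_signal(x, fs), cfg)$values
    b <- f(audio_signal(3.7 * x, fs), cfg)$values
    expect_equal(which.max(a), which.max(b))
  }
})
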