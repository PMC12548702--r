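# Synthetic-data generator: onset trains with a right-skewed IOI law,
# tone-burst audio, and multichannel EEG with a known IOI-dependent N1/P2
# kernel. Every generator is a pure function of (config, seed).

#' Amplitude-recovery parameters
#'
#' Generative saturating recovery law for the event-response amplitude:
#' `a(IOI) = floor + (1 - floor) * (1 - exp(-IOI / tau_rec))`, applied
#' multiplicatively to the whole N1/P2 kernel (asymptotic component
#' amplitudes `a_inf_n1`, `a_inf_p2`). The first event of a recording (no
#' preceding onset) responds at the asymptote.
#'
#' @param a_inf_n1,a_inf_p2 Asymptotic N1 (negative lobe) and P2 (positive
#'   lobe) amplitudes, arbitrary units.
#' @param tau_rec Recovery time constant in seconds.
#' @param floor Minimum amplitude fraction at IOI -> 0 (`0 <= floor < 1`).
#' @return A `recovery_params` list.
#' @export
recovery_params <- function(a_inf_n1 = 1, a_inf_p2 = 0.7, tau_rec = 1.5,
                            floor = 0.3) {
  stopifnot(tau_rec > 0, floor >= 0, floor < 1)
  structure(list(a_inf_n1 = a_inf_n1, a_inf_p2 = a_inf_p2,
                 tau_rec = tau_rec, floor = floor),
            class = "recovery_params")
}

#' Recovery-law amplitude fraction
#'
#' @param ioi IOI in seconds (`NA`/`Inf` = fully recovered).
#' @param rec A [recovery_params()].
#' @return Amplitude fraction in `[floor, 1]`.
#' @export
recovery_amplitude <- function(ioi, rec) {
  a <- rec$floor + (1 - rec$floor) * (1 - exp(-ioi / rec$tau_rec))
  a[!is.finite(ioi)] <- 1
  a
}

# 22-channel montage with a fronto-central gain topography (max 1 at FCz/Cz,
# falling off towards temporal/parietal sites).
#' @noRd
default_montage <- function(n_channels = 22L) {
  labels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FCz", "FC2", "FC6",
              "T7", "C3", "Cz", "C4", "T8",
              "CP1", "CP2", "P3", "Pz", "P4")
  gains <- c(0.35, 0.35, 0.30, 0.55, 0.80, 0.55, 0.30,
             0.60, 0.90, 1.00, 0.90, 0.60,
             0.30, 0.70, 0.95, 0.70, 0.30,
             0.55, 0.55, 0.35, 0.45, 0.35)
  if (n_channels <= 22L) {
    list(labels = labels[seq_len(n_channels)],
         gains = gains[seq_len(n_channels)])
  } else {
    extra <- n_channels - 22L
    list(labels = c(labels, paste0("X", seq_len(extra))),
         gains = c(gains, rep(0.3, extra)))
  }
}

#' Simulation configuration
#'
#' Stated-world defaults: a lognormal IOI law whose 80th percentile is
#' 3.63 s (the skew of naturalistic soundscapes), 100 Hz EEG over 22
#' channels with a fronto-central topography, 1/f noise at a per-event SNR
#' of -10 dB, and 8 kHz tone-burst audio.
#'
#' @param duration Recording length in seconds (default 900 = 15 min).
#' @param ioi_law `list(type = "lognormal", meanlog, sdlog)` or
#'   `list(type = "exponential", rate)`.
#' @param fs_eeg EEG rate (Hz). @param fs_audio Audio rate (Hz).
#' @param n_channels Number of EEG channels.
#' @param mixing Channel gain vector (`NULL` = fronto-central default).
#' @param noise `list(exponent, snr_db)`: 1/f spectral exponent and
#'   per-event SNR in dB (RMS of the fully recovered kernel on the
#'   best-gain channel vs. noise RMS).
#' @param kernel `list(n1_lat, n1_sd, p2_lat, p2_sd)` in seconds: Gaussian
#'   N1 (negative) and P2 (positive) lobes.
#' @param burst `list(dur, rise_range, level_rms, level_sd_db, carrier_range,
#'   floor_db)` for tone-burst audio.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration = 900,
                       ioi_law = list(type = "lognormal", meanlog = 0.53,
                                      sdlog = 0.9),
                       fs_eeg = 100, fs_audio = 8000, n_channels = 22L,
                       mixing = NULL,
                       noise = list(exponent = 1, snr_db = -10),
                       kernel = list(n1_lat = 0.110, n1_sd = 0.020,
                                     p2_lat = 0.220, p2_sd = 0.030),
                       burst = list(dur = 0.15, rise_range = c(0.005, 0.03),
                                    level_rms = 0.1, level_sd_db = 3,
                                    carrier_range = c(300, 3000),
                                    floor_db = -20)) {
  stopifnot(duration > 0, fs_eeg > 0, fs_audio > 0, n_channels >= 1L)
  mont <- default_montage(n_channels)
  if (is.null(mixing)) mixing <- mont$gains
  stopifnot(length(mixing) == n_channels)
  structure(list(duration = duration, ioi_law = ioi_law, fs_eeg = fs_eeg,
                 fs_audio = fs_audio, n_channels = as.integer(n_channels),
                 mixing = mixing, channel_labels = mont$labels,
                 noise = noise, kernel = kernel, burst = burst),
            class = "sim_config")
}

#' Simulate an onset train
#'
#' IOIs are drawn i.i.d. from the configured law and cumulated into onset
#' times within `cfg$duration` (a 1-s lead-in precedes the first onset).
#'
#' @param cfg A [sim_config()]. @param seed Integer seed.
#' @return An [onset_events()] table with IOIs computed.
#' @export
simulate_onset_train <- function(cfg = sim_config(), seed = 1L) {
  law <- cfg$ioi_law
  times <- with_local_seed(seed, {
    n_guess <- ceiling(cfg$duration /
                         max(0.05, switch(law$type,
                                          lognormal = exp(law$meanlog),
                                          exponential = 1 / law$rate))) + 50L
    t <- 1
    out <- numeric(0)
    repeat {
      iois <- switch(law$type,
        lognormal = stats::rlnorm(n_guess, law$meanlog, law$sdlog),
        exponential = stats::rexp(n_guess, law$rate),
        stopf("unknown ioi law '%s'", law$type))
      tt <- t + cumsum(iois)
      out <- c(out, tt[tt <= cfg$duration - 1])
      if (length(tt) == 0L || tt[length(tt)] > cfg$duration - 1) break
      t <- tt[length(tt)]
    }
    c(1, out)
  })
  compute_ioi(onset_events(times))
}

#' Render tone-burst audio for an onset train
#'
#' Each onset becomes a tone burst with a random carrier (uniform over
#' `burst$carrier_range`), random rise time, and a log-normal level jitter
#' around `burst$level_rms`, over a white noise floor `burst$floor_db` dB
#' below the nominal burst level.
#'
#' @param onsets An [onset_events()] table.
#' @param cfg A [sim_config()]. @param seed Integer seed.
#' @return An [audio_signal()] at `cfg$fs_audio`.
#' @export
simulate_audio <- function(onsets, cfg = sim_config(), seed = 1L) {
  fs <- cfg$fs_audio
  n <- round(cfg$duration * fs)
  b <- cfg$burst
  with_local_seed(seed, {
    x <- stats::rnorm(n, sd = b$level_rms * 10^(b$floor_db / 20))
    nb <- round(b$dur * fs)
    release <- round(0.04 * fs)
    for (t0 in onsets$time) {
      i0 <- floor(t0 * fs) + 1L
      if (i0 + nb - 1L > n) next
      carrier <- stats::runif(1, b$carrier_range[1], b$carrier_range[2])
      rise <- round(stats::runif(1, b$rise_range[1], b$rise_range[2]) * fs)
      rms <- b$level_rms * 10^(stats::rnorm(1, 0, b$level_sd_db) / 20)
      tt <- (0:(nb - 1L)) / fs
      env <- rep(1, nb)
      if (rise > 0) env[1:min(rise, nb)] <- seq(0, 1, length.out = min(rise, nb))
      rel <- min(release, nb)
      env[(nb - rel + 1L):nb] <- env[(nb - rel + 1L):nb] *
        (0.5 + 0.5 * cos(pi * seq(0, 1, length.out = rel)))
      tone <- sin(2 * pi * carrier * tt) * env
      tone <- tone * rms / max(sqrt(mean(tone^2)), 1e-12)
      x[i0:(i0 + nb - 1L)] <- x[i0:(i0 + nb - 1L)] + tone
    }
    audio_signal(x, fs)
  })
}

#' @noRd
biphasic_kernel <- function(rec, kern, fs) {
  t <- seq(0, 0.4, by = 1 / fs)
  -rec$a_inf_n1 * exp(-0.5 * ((t - kern$n1_lat) / kern$n1_sd)^2) +
    rec$a_inf_p2 * exp(-0.5 * ((t - kern$p2_lat) / kern$p2_sd)^2)
}

# 1/f^exponent noise, one channel per column, unit SD.
#' @noRd
pink_noise <- function(n, n_chan, exponent) {
  W <- stats::mvfft(matrix(stats::rnorm(n * n_chan), n, n_chan))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency magnitude
  scale <- 1 / f^(exponent / 2)
  scale[1] <- 0
  X <- Re(stats::mvfft(W * scale, inverse = TRUE)) / n
  X <- sweep(X, 2, apply(X, 2, stats::sd), "/")
  X
}

#' Simulate multichannel EEG with IOI-dependent responses
#'
#' Builds a source waveform as the sum over events of the biphasic N1/P2
#' kernel scaled by the recovery law evaluated at each event's IOI, projects
#' it to channels through the mixing gains, and adds 1/f noise at the
#' configured per-event SNR.
#'
#' @param onsets An [onset_events()] table with IOIs computed.
#' @param rec A [recovery_params()].
#' @param cfg A [sim_config()]. @param seed Integer seed.
#' @return An [eeg_recording()] at `cfg$fs_eeg`.
#' @export
simulate_eeg <- function(onsets, rec = recovery_params(), cfg = sim_config(),
                         seed = 1L) {
  fs <- cfg$fs_eeg
  n <- round(cfg$duration * fs)
  k <- biphasic_kernel(rec, cfg$kernel, fs)
  amp <- recovery_amplitude(ifelse(is.na(onsets$ioi), Inf, onsets$ioi), rec)
  source <- numeric(n + length(k))
  idx <- floor(onsets$time * fs) + 1L
  for (e in seq_along(idx)) {
    if (idx[e] > n) next
    rng <- idx[e]:(idx[e] + length(k) - 1L)
    source[rng] <- source[rng] + amp[e] * k
  }
  source <- source[seq_len(n)]
  clean <- outer(cfg$mixing, source)        # channel x time
  if (is.null(cfg$noise$sd)) {
    kernel_rms <- sqrt(mean(k^2))
    noise_sd <- max(cfg$mixing) * kernel_rms * 10^(-cfg$noise$snr_db / 20)
  } else {
    noise_sd <- cfg$noise$sd
  }
  noise <- with_local_seed(seed,
                           t(pink_noise(n, cfg$n_channels, cfg$noise$exponent)))
  eeg_recording(clean + noise_sd * noise, fs, cfg$channel_labels)
}

#' Simulate a complete synthetic subject
#'
#' Onset train + EEG (and optionally audio) with ground truth attached.
#'
#' @param cfg A [sim_config()]. @param rec A [recovery_params()].
#' @param seed Integer seed. @param audio Render tone-burst audio too?
#' @return List with `onsets`, `eeg`, optionally `audio`, plus `cfg`, `rec`.
#' @export
simulate_subject <- function(cfg = sim_config(), rec = recovery_params(),
                             seed = 1L, audio = FALSE) {
  onsets <- simulate_onset_train(cfg, seed)
  eeg <- simulate_eeg(onsets, rec, cfg, seed + 1000L)
  out <- list(onsets = onsets, eeg = eeg, cfg = cfg, rec = rec)
  if (audio) out$audio <- simulate_audio(onsets, cfg, seed + 2000L)
  out
}
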