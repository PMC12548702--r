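# Per-event acoustic covariates (intensity, envelope sharpness) and the
# mixed-effects control analysis relating them to IOI.

#' Per-event intensity
#'
#' Root-mean-square amplitude of the waveform in a short window following
#' each onset (default 50 ms, matching the sharpness window).
#'
#' @param audio An [audio_signal()].
#' @param onsets An [onset_events()] table.
#' @param win Window length in seconds.
#' @return Numeric vector, one value per event.
#' @export
event_intensity <- function(audio, onsets, win = 0.05) {
  stopifnot(inherits(audio, "audio_signal"), inherits(onsets, "onset_events"))
  n <- length(audio$samples)
  vapply(onsets$time, function(t) {
    i0 <- floor(t * audio$fs) + 1L
    i1 <- min(n, i0 + round(win * audio$fs) - 1L)
    if (i0 > n) return(0)
    sqrt(mean(audio$samples[i0:i1]^2))
  }, 1)
}

# Rectified 10-ms moving-average amplitude envelope.
#' @noRd
amplitude_envelope <- function(x, fs) running_mean(abs(x), round(0.01 * fs))

#' Per-event envelope sharpness
#'
#' Slope (least-squares line) of the rectified, 10-ms-smoothed amplitude
#' envelope over the first 50 ms following each onset, in amplitude per
#' second. Scales linearly with the waveform.
#'
#' @inheritParams event_intensity
#' @return Numeric vector, one value per event.
#' @export
envelope_sharpness <- function(audio, onsets, win = 0.05) {
  stopifnot(inherits(audio, "audio_signal"), inherits(onsets, "onset_events"))
  env <- amplitude_envelope(audio$samples, audio$fs)
  n <- length(env)
  w <- round(win * audio$fs)
  vapply(onsets$time, function(t) {
    i0 <- floor(t * audio$fs) + 1L
    i1 <- min(n, i0 + w - 1L)
    if (i0 >= i1) return(0)
    seg <- env[i0:i1]
    tt <- (seq_along(seg) - 1) / audio$fs
    sum((tt - mean(tt)) * (seg - mean(seg))) / sum((tt - mean(tt))^2)
  }, 1)
}

#' Assemble an event covariate table
#'
#' One row per IOI-eligible onset: `ioi`, `intensity`, `sharpness`,
#' `participant`.
#'
#' @param onsets An [onset_events()] table with IOIs and covariates filled.
#' @param participant Participant identifier.
#' @return A data frame of class `event_covariates`.
#' @export
event_covariates <- function(onsets, participant = "P1") {
  stopifnot(inherits(onsets, "onset_events"))
  el <- onsets[onsets$eligible, , drop = FALSE]
  structure(data.frame(ioi = el$ioi, intensity = el$intensity,
                       sharpness = el$sharpness,
                       participant = as.character(participant)),
            class = c("event_covariates", "data.frame"))
}

#' Mixed-effects control analysis of IOI
#'
#' Fits `ioi ~ sharpness + intensity + sharpness:intensity +
#' (1 | participant)` by maximum likelihood and reports fixed-effect
#' estimates (beta, SE, t, two-sided p on the residual degrees of freedom),
#' the random-intercept variance, and pairwise predictor correlations (the
#' collinearity check).
#'
#' @param cov An `event_covariates` table (rows pooled across participants).
#' @return List with `fixed` (data frame), `random_intercept_variance`,
#'   `residual_variance`, `logLik`, `predictor_correlations`, and the fitted
#'   `lme4` model in `fit`.
#' @export
lme_ioi <- function(cov) {
  stopifnot(inherits(cov, "event_covariates"))
  cov <- cov[stats::complete.cases(cov[, c("ioi", "intensity", "sharpness")]), ]
  fit <- lme4::lmer(ioi ~ sharpness + intensity + sharpness:intensity +
                      (1 | participant),
                    data = cov, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  sm <- summary(fit)$coefficients
  df <- nrow(cov) - nrow(sm)
  fixed <- data.frame(term = rownames(sm), beta = sm[, "Estimate"],
                      se = sm[, "Std. Error"], t = sm[, "t value"],
                      df = df,
                      p = 2 * stats::pt(-abs(sm[, "t value"]), df),
                      row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri <- vc$vcov[vc$grp == "participant"]
  res <- vc$vcov[vc$grp == "Residual"]
  pc <- stats::cor(cov[, c("ioi", "intensity", "sharpness")])
  list(fixed = fixed, random_intercept_variance = ri,
       residual_variance = res, logLik = as.numeric(stats::logLik(fit)),
       predictor_correlations = pc, fit = fit)
}
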