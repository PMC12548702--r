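# EEG conditioning (final-stage filtering) and on-disk formats: float32
# channel-major binary with a JSON sidecar for EEG, feature matrices and TRF
# models.

# Windowed-sinc linear-phase FIR kernel (Hamming window), length order + 1.
# Symmetric, so centred convolution is zero-phase.
#' @noRd
fir_kernel <- function(cutoff, fs, order, type = c("low", "high")) {
  type <- match.arg(type)
  if (order %% 2L == 1L) order <- order + 1L      # even order -> odd length
  m <- order
  nyq <- fs / 2
  fc <- cutoff / nyq
  k <- 0:m
  h <- fc * sinc(fc * (k - m / 2))
  w <- 0.54 - 0.46 * cos(2 * pi * k / m)
  h <- h * w
  h <- h / sum(h)
  if (type == "high") {
    d <- numeric(m + 1L)
    d[m / 2 + 1L] <- 1
    h <- d - h
  }
  h
}

#' @noRd
sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Centred zero-phase FIR filtering with zero padding at the edges.
#' @noRd
fir_filter <- function(x, h) {
  half <- (length(h) - 1L) %/% 2L
  xp <- c(rep(0, length(h)), x, rep(0, length(h)))
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[(length(h) + 1L):(length(h) + length(x))])
}

#' Final-stage EEG conditioning
#'
#' Applies the band limits used for the encoding analysis: a 20 Hz low-pass
#' (order 100 at the input rate), resampling to 100 Hz, a 0.3 Hz high-pass
#' (order 518), and re-referencing to the mastoid average when TP9/TP10 are
#' present (the mastoid channels are then dropped). Filters are symmetric
#' FIRs applied by centred convolution, i.e. zero phase, so TRF peak
#' latencies are not shifted.
#'
#' @param raw An [eeg_recording()]; input rate must be at least 40 Hz.
#' @param fs_out Output rate (default 100 Hz).
#' @return A conditioned [eeg_recording()] at `fs_out`.
#' @export
prepare_eeg <- function(raw, fs_out = 100) {
  stopifnot(inherits(raw, "eeg_recording"))
  if (raw$fs < 40) stopf("EEG rate %g Hz too low (need >= 40 Hz)", raw$fs)
  h_lp <- fir_kernel(20, raw$fs, 100L, "low")
  dat <- t(apply(raw$data, 1, fir_filter, h = h_lp))
  if (abs(raw$fs - fs_out) > 1e-9) {
    dat <- t(apply(dat, 1, resample_fft, fs_in = raw$fs, fs_out = fs_out))
  }
  h_hp <- fir_kernel(0.3, fs_out, 518L, "high")
  dat <- t(apply(dat, 1, fir_filter, h = h_hp))
  labels <- raw$channel_labels
  mast <- which(labels %in% c("TP9", "TP10"))
  if (length(mast) > 0L) {
    ref <- colMeans(dat[mast, , drop = FALSE])
    dat <- sweep(dat, 2, ref)
    dat <- dat[-mast, , drop = FALSE]
    labels <- labels[-mast]
  } else {
    message("mastoid channels TP9/TP10 not found; data left as referenced")
  }
  eeg_recording(dat, fs_out, labels)
}

#' Write / read EEG as float32 binary plus JSON sidecar
#'
#' The binary file holds the channel-major float32 samples; `<path>.json`
#' records `fs`, `channel_labels` and the shape.
#'
#' @param eeg An [eeg_recording()]. @param path Binary file path.
#' @return `path` (write) or an `eeg_recording` (read).
#' @export
write_eeg_bin <- function(eeg, path) {
  stopifnot(inherits(eeg, "eeg_recording"))
  con <- file(path, "wb")
  writeBin(as.numeric(t(eeg$data)), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(
    list(fs = eeg$fs, channel_labels = eeg$channel_labels,
         n_channels = nrow(eeg$data), n_samples = ncol(eeg$data),
         dtype = "float32", order = "channel-major"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_eeg_bin
#' @export
read_eeg_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  x <- readBin(con, "numeric", meta$n_channels * meta$n_samples, size = 4,
               endian = "little")
  close(con)
  eeg_recording(t(matrix(x, nrow = meta$n_samples, ncol = meta$n_channels)),
                meta$fs, meta$channel_labels)
}

#' Write / read a feature matrix as float32 binary plus JSON sidecar
#'
#' @param feats A [feature_matrix()]. @param path Binary file path.
#' @return `path` (write) or a `feature_matrix` (read).
#' @export
write_features_bin <- function(feats, path) {
  stopifnot(inherits(feats, "feature_matrix"))
  con <- file(path, "wb")
  writeBin(as.numeric(as.matrix(feats$values)), con, size = 4,
           endian = "little")
  close(con)
  jsonlite::write_json(
    list(fs = feats$fs, feature_labels = feats$feature_labels,
         n_samples = nrow(feats$values), n_features = ncol(feats$values),
         dtype = "float32", order = "column-major"),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features_bin
#' @export
read_features_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  x <- readBin(con, "numeric", meta$n_samples * meta$n_features, size = 4,
               endian = "little")
  close(con)
  feature_matrix(matrix(x, meta$n_samples, meta$n_features), meta$fs,
                 meta$feature_labels)
}

#' Write / read a TRF model as float32 binary plus JSON sidecar
#'
#' @param model A `trf_model`. @param path Binary file path.
#' @return `path` (write) or a `trf_model` (read).
#' @export
write_trf_bin <- function(model, path) {
  stopifnot(inherits(model, "trf_model"))
  con <- file(path, "wb")
  writeBin(as.numeric(model$weights), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(
    list(dim = dim(model$weights), lambda = model$lambda,
         lag_window = model$lag_window, lag_axis = model$lag_axis,
         fs = model$fs, feature_labels = model$feature_labels,
         channel_labels = model$channel_labels, dtype = "float32"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trf_bin
#' @export
read_trf_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  x <- readBin(con, "numeric", prod(meta$dim), size = 4, endian = "little")
  close(con)
  w <- array(x, dim = meta$dim,
             dimnames = list(meta$feature_labels, NULL, meta$channel_labels))
  structure(list(weights = w, lambda = meta$lambda,
                 lag_window = meta$lag_window, lag_axis = meta$lag_axis,
                 fs = meta$fs, feature_labels = meta$feature_labels,
                 channel_labels = meta$channel_labels),
            class = "trf_model")
}
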