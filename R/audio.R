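#' Construct an audio signal
#'
#' Container for a mono waveform. Multi-channel input is collapsed by
#' averaging across channels before any novelty analysis.
#'
#' @param samples Numeric vector (or channel x time matrix) of amplitudes.
#' @param fs Sampling rate in Hz.
#' @return An object of class `audio_signal` with elements `samples` and `fs`.
#' @export
audio_signal <- function(samples, fs) {
  if (is.matrix(samples)) samples <- colMeans(samples)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stopf("audio signal is empty")
  if (!all(is.finite(samples))) stopf("audio samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stopf("fs must be > 0")
  structure(list(samples = samples, fs = fs), class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Read a WAV file as a mono audio signal
#'
#' Supports PCM 16/24/32-bit and IEEE float32 encodings; multi-channel files
#' are averaged to mono.
#'
#' @param path Path to a RIFF/WAVE file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stopf("not a RIFF file: %s", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stopf("not a WAVE file: %s", path)
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        code       = readBin(fmt_raw[1:2], "integer", 1, size = 2,
                             endian = "little", signed = FALSE),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, size = 2,
                             endian = "little", signed = FALSE),
        fs         = readBin(fmt_raw[5:8], "integer", 1, size = 4,
                             endian = "little"),
        bits       = readBin(fmt_raw[15:16], "integer", 1, size = 2,
                             endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stopf("malformed WAV: %s", path)
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  if (fmt$code == 3L || (fmt$code == 65534L && fmt$bits == 32L)) {
    x <- readBin(data_raw, "numeric", n, size = 4, endian = "little")
  } else if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n, size = 2, endian = "little") / 32768
  } else if (fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3L)
    v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else if (fmt$bits == 32L) {
    x <- readBin(data_raw, "integer", n, size = 4, endian = "little") / 2147483648
  } else {
    stopf("unsupported WAV encoding (format %d, %d bit)", fmt$code, fmt$bits)
  }
  if (fmt$n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  audio_signal(x, fmt$fs)
}

#' Write an audio signal to a WAV file
#'
#' @param audio An [audio_signal()].
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bits = 16L) {
  stopifnot(inherits(audio, "audio_signal"), bits %in% c(16L, 32L))
  x <- audio$samples
  n <- length(x)
  bytes <- bits %/% 8L
  data_size <- n * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(v, size) writeBin(as.integer(v), con, size = size,
                                     endian = "little")
  writeChar("RIFF", con, eos = NULL); wint(36L + data_size, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wint(16L, 4)
  wint(if (bits == 32L) 3L else 1L, 2); wint(1L, 2)       # format, mono
  wint(round(audio$fs), 4); wint(round(audio$fs) * bytes, 4)
  wint(bytes, 2); wint(bits, 2)
  writeChar("data", con, eos = NULL); wint(data_size, 4)
  if (bits == 32L) {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  } else {
    q <- pmax(-32768L, pmin(32767L, as.integer(round(x * 32768))))
    writeBin(q, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Resample a signal by Fourier-domain interpolation
#'
#' Truncates or zero-pads the spectrum so that the output has
#' `round(n * fs_out / fs_in)` samples (the approach of classic FFT
#' resamplers). Adequate for band-limited signals such as filtered EEG or
#' audio envelopes.
#'
#' @param x Numeric vector.
#' @param fs_in,fs_out Input and output rates (Hz).
#' @return Numeric vector at `fs_out`.
#' @export
resample_fft <- function(x, fs_in, fs_out) {
  n <- length(x)
  m <- round(n * fs_out / fs_in)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  half <- min(n, m) %/% 2L
  Y[1:(half + 1L)] <- X[1:(half + 1L)]
  if (half >= 1L) Y[(m - half + 1L):m] <- X[(n - half + 1L):n]
  if (min(n, m) %% 2L == 0L && half >= 1L) {
    # split the Nyquist bin to keep the result real
    Y[half + 1L] <- Y[half + 1L] / 2
    Y[m - half + 1L] <- Conj(Y[half + 1L])
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
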