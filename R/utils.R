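# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Seeds the base RNG, runs `code`, and restores the caller's RNG state so
#' seeded operations never perturb the global stream.
#' @noRd
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1L)) / (n - 1L)))
}

# Centered moving average with edge truncation (window w samples).
#' @noRd
running_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  if (n == 0L) return(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered Gaussian smoothing, kernel truncated at 4*sigma, zero-padded edges
# with kernel-mass renormalisation so flat regions stay flat.
#' @noRd
gauss_smooth <- function(x, sigma) {
  stopifnot(sigma > 0)
  n <- length(x)
  if (n == 0L) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  xp <- c(rep(0, half), x, rep(0, half))
  sm <- stats::filter(xp, k, method = "convolution", sides = 2)
  sm <- as.numeric(sm[(half + 1L):(half + n)])
  # renormalise by the in-range kernel mass near the edges
  mass <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k,
                        method = "convolution", sides = 2)
  mass <- as.numeric(mass[(half + 1L):(half + n)])
  sm / mass
}

# Pearson correlation defined as 0 when either argument has zero variance.
#' @noRd
safe_cor <- function(a, b) {
  sa <- stats::sd(a)
  sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0) return(0)
  stats::cor(a, b)
}

# Split n samples into k contiguous segments whose lengths differ by <= 1;
# the first (n %% k) segments get the extra sample.
#' @noRd
contiguous_segments <- function(n, k) {
  stopifnot(k >= 1L, n >= k)
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  Map(function(s, e) s:e, starts, ends)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
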