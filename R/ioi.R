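# IOI computation, uniform-count binning, and stimulus feature matrices.

#' Stimulus feature matrix
#'
#' Time x feature representation at the EEG rate. Binary onset matrices are
#' stored sparsely.
#'
#' @param values Matrix (or `Matrix` sparse matrix), time in rows.
#' @param fs Sampling rate (Hz).
#' @param feature_labels Column labels (bin upper edges as characters, or
#'   `"onset"` / `"weighted"`).
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, fs, feature_labels = NULL) {
  if (!inherits(values, "Matrix")) values <- Matrix::Matrix(values, sparse = TRUE)
  if (is.null(feature_labels)) feature_labels <- as.character(seq_len(ncol(values)))
  stopifnot(length(feature_labels) == ncol(values), fs > 0)
  structure(list(values = values, fs = fs,
                 feature_labels = as.character(feature_labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features @ %g Hz [%s]\n",
              nrow(x$values), ncol(x$values), x$fs,
              paste(x$feature_labels, collapse = ", ")))
  invisible(x)
}

#' Compute inter-onset intervals and mark eligible events
#'
#' Sets `ioi[i] = time[i] - time[i-1]`. The first event (no preceding onset)
#' and events whose IOI exceeds `max_ioi` (default 10 s, the span of reported
#' N1 recovery) are marked ineligible for the binned analyses.
#'
#' @param onsets An [onset_events()] table.
#' @param max_ioi Exclusion threshold in seconds.
#' @return The table with `ioi` and `eligible` filled in.
#' @export
compute_ioi <- function(onsets, max_ioi = 10) {
  stopifnot(inherits(onsets, "onset_events"))
  n <- nrow(onsets)
  if (n > 1L && any(diff(onsets$time) <= 0)) stopf("onset times must be sorted")
  onsets$ioi <- c(NA_real_, diff(onsets$time))
  onsets$eligible <- !is.na(onsets$ioi) & onsets$ioi <= max_ioi
  onsets
}

#' Uniform-count IOI bins
#'
#' Partitions the IOIs into `n_bins` rank-based groups whose counts differ by
#' at most one (ties broken by event order, so edges are deterministic).
#' Edges are reported as midpoints between adjacent bins' extreme values.
#'
#' @param iois Numeric vector of IOIs (seconds).
#' @param n_bins Number of bins (the study explored 2 to 8).
#' @return A `bin_spec` with `n_bins`, `edges` (length `n_bins + 1`),
#'   `counts`, and `upper` (per-bin upper data value, the "bin edge" used as
#'   the bin's IOI coordinate downstream).
#' @export
make_uniform_bins <- function(iois, n_bins) {
  iois <- as.numeric(iois)
  stopifnot(length(n_bins) == 1L, n_bins >= 1L)
  if (any(!is.finite(iois)) || any(iois <= 0)) stopf("IOIs must be positive and finite")
  if (n_bins > length(iois)) stopf("more bins (%d) than IOIs (%d)", n_bins, length(iois))
  ord <- order(iois)                       # stable: ties keep event order
  groups <- contiguous_segments(length(iois), n_bins)
  lo <- vapply(groups, function(g) iois[ord[g[1]]], 1)
  hi <- vapply(groups, function(g) iois[ord[g[length(g)]]], 1)
  inner <- (hi[-n_bins] + lo[-1]) / 2
  edges <- c(lo[1], inner, hi[n_bins])
  structure(list(n_bins = as.integer(n_bins), edges = edges,
                 counts = lengths(groups), upper = hi),
            class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  cat(sprintf("<bin_spec> %d bins, counts [%s], upper edges [%s] s\n",
              x$n_bins, paste(x$counts, collapse = ", "),
              paste(signif(x$upper, 3), collapse = ", ")))
  invisible(x)
}

#' Assign eligible onsets to IOI bins
#'
#' Interval rule: left-closed, right-open `[e_k, e_{k+1})`, last bin
#' right-closed; values below the first edge fall in bin 1, above the last in
#' bin `n_bins`.
#'
#' @param onsets An [onset_events()] table with IOIs computed.
#' @param spec A [make_uniform_bins()] result.
#' @return The table with the `bin` column filled for eligible events.
#' @export
assign_bins <- function(onsets, spec) {
  stopifnot(inherits(onsets, "onset_events"), inherits(spec, "bin_spec"))
  b <- findInterval(onsets$ioi, spec$edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  onsets$bin <- ifelse(onsets$eligible, b, NA_integer_)
  onsets
}

#' @noRd
onset_sample_index <- function(times, fs, n_samples) {
  idx <- floor(times * fs) + 1L
  keep <- idx >= 1L & idx <= n_samples
  list(idx = idx[keep], keep = keep)
}

#' Binned onset feature matrix
#'
#' One binary column per IOI bin; each eligible onset contributes a single 1
#' in its bin's column at sample `floor(time * fs)`.
#'
#' @param onsets An [onset_events()] table with IOIs computed.
#' @param spec A [make_uniform_bins()] result.
#' @param fs Rate (Hz). @param n_samples Output length.
#' @return A [feature_matrix()] with `spec$n_bins` columns labelled by the
#'   bins' upper IOI values.
#' @export
binned_onset_matrix <- function(onsets, spec, fs, n_samples) {
  onsets <- assign_bins(onsets, spec)
  el <- onsets[onsets$eligible, , drop = FALSE]
  si <- onset_sample_index(el$time, fs, n_samples)
  v <- Matrix::sparseMatrix(i = si$idx, j = el$bin[si$keep],
                            x = rep(1, length(si$idx)),
                            dims = c(n_samples, spec$n_bins))
  feature_matrix(v, fs, signif(spec$upper, 6))
}

#' Randomly permute the onset-to-bin allocation
#'
#' Onset times are unchanged; the multiset of bin labels is uniformly
#' permuted across eligible onsets (per-bin counts preserved). This is the
#' null model for the gradient permutation test: acoustic change is still
#' captured, but without a structured relation to IOI.
#'
#' @inheritParams binned_onset_matrix
#' @param seed Integer seed; fixed seed gives a bit-identical matrix.
#' @return A [feature_matrix()].
#' @export
permute_bin_allocation <- function(onsets, spec, fs, n_samples, seed) {
  onsets <- assign_bins(onsets, spec)
  el <- which(onsets$eligible)
  perm <- with_local_seed(seed, sample(onsets$bin[el]))
  onsets$bin[el] <- perm
  el_tab <- onsets[onsets$eligible, , drop = FALSE]
  si <- onset_sample_index(el_tab$time, fs, n_samples)
  v <- Matrix::sparseMatrix(i = si$idx, j = el_tab$bin[si$keep],
                            x = rep(1, length(si$idx)),
                            dims = c(n_samples, spec$n_bins))
  feature_matrix(v, fs, signif(spec$upper, 6))
}

#' Distance-weighted onset vector
#'
#' A single feature column where each eligible onset carries its IOI, min-max
#' normalized to `[0, 1]` over the recording (the parameterized alternative
#' to binning). Degenerate all-equal IOIs yield all-zero weights and a
#' warning.
#'
#' @inheritParams binned_onset_matrix
#' @return A [feature_matrix()] with one column labelled `"weighted"`.
#' @export
weighted_onset_vector <- function(onsets, fs, n_samples) {
  stopifnot(inherits(onsets, "onset_events"))
  el <- onsets[onsets$eligible, , drop = FALSE]
  rng <- range(el$ioi)
  w <- if (rng[2] > rng[1]) (el$ioi - rng[1]) / (rng[2] - rng[1]) else {
    warning("all IOIs equal; weighted onset vector is all zero")
    rep(0, nrow(el))
  }
  si <- onset_sample_index(el$time, fs, n_samples)
  v <- Matrix::sparseMatrix(i = si$idx, j = rep(1L, length(si$idx)),
                            x = w[si$keep], dims = c(n_samples, 1L))
  feature_matrix(v, fs, "weighted")
}

#' Write / read onset tables as TSV
#'
#' Columns: `time_s, ioi_s, intensity, sharpness, bin`.
#' @param onsets An [onset_events()] table. @param path File path.
#' @return `path` (write) or an `onset_events` table (read).
#' @export
write_onsets_tsv <- function(onsets, path) {
  stopifnot(inherits(onsets, "onset_events"))
  d <- data.frame(time_s = onsets$time, ioi_s = onsets$ioi,
                  intensity = onsets$intensity, sharpness = onsets$sharpness,
                  bin = onsets$bin)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_onsets_tsv
#' @export
read_onsets_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  ev <- onset_events(d$time_s, intensity = d$intensity, sharpness = d$sharpness)
  ev$ioi <- d$ioi_s
  ev$bin <- d$bin
  ev$eligible <- !is.na(d$ioi_s) & d$ioi_s <= 10
  ev
}
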