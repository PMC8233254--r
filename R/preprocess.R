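#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward and a backward pass of a Butterworth band-pass per
#' channel (zero phase distortion, squared magnitude response). The order is
#' per pass and defaults to 4, a common choice for EEG that remains stable
#' down to a 0.5 Hz high-pass edge.
#'
#' @param x Numeric vector (one channel) or `channels x samples` matrix of a
#'   continuous recording.
#' @param sfreq Sampling rate in Hz.
#' @param low,high Band edges in Hz; `0 < low < high < sfreq/2`.
#' @param order Butterworth order per pass.
#' @return Filtered signal, same shape as `x`.
#' @export
bandpass_filter <- function(x, sfreq, low = 0.5, high = 16, order = 4) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= sfreq / 2)
    stop(sprintf("high edge %g Hz must be below the Nyquist frequency %g Hz",
                 high, sfreq / 2))
  bf <- signal::butter(order, c(low, high) / (sfreq / 2), type = "pass")
  apply_rows(x, function(ch) signal::filtfilt(bf, ch))
}

apply_rows <- function(x, f) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1, f))
    dimnames(out) <- dimnames(x)
    out
  } else {
    f(x)
  }
}

#' Resample a continuous signal
#'
#' Fourier-domain resampling to a lower rate: the spectrum is truncated at
#' the new Nyquist frequency and inverse-transformed at the new length,
#' which is exact for band-limited signals away from the record edges.
#' Anti-aliasing is assumed to be handled upstream (the standard pipeline
#' low-passes at 16 Hz before downsampling to 100 Hz).
#'
#' @param x Numeric vector or `channels x samples` matrix.
#' @param sfreq_in,sfreq_out Input/output sampling rates in Hz;
#'   `sfreq_out <= sfreq_in`.
#' @return Resampled signal with attribute `"sfreq"` set to `sfreq_out`.
#' @export
resample_signal <- function(x, sfreq_in, sfreq_out) {
  if (sfreq_out > sfreq_in) stop("sfreq_out must not exceed sfreq_in")
  if (sfreq_out == sfreq_in) {
    attr(x, "sfreq") <- sfreq_out
    return(x)
  }
  ratio <- sfreq_out / sfreq_in
  out <- apply_rows(x, function(ch) fft_resample(ch, ratio))
  attr(out, "sfreq") <- sfreq_out
  out
}

# Spectrum truncation at the new length; drops the old Nyquist bin rather
# than splitting it (the pipeline has already low-passed well below it).
fft_resample <- function(ch, ratio) {
  n <- length(ch)
  n_out <- max(round(n * ratio), 1L)
  X <- stats::fft(ch)
  keep <- floor((min(n, n_out) - 1) / 2)
  Y <- complex(n_out)
  Y[1] <- X[1]
  if (keep >= 1) {
    Y[2:(keep + 1)] <- X[2:(keep + 1)]
    Y[(n_out - keep + 1):n_out] <- X[(n - keep + 1):n]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' Windows are relative to each stimulus onset and end-exclusive: an epoch
#' covers sample times `t` with `onset + window[1] <= t < onset + window[2]`.
#' Onsets whose window does not fit inside the recording are dropped with a
#' warning; the dropped count is available as attribute `"n_dropped"`.
#' Overlapping onsets yield overlapping epochs (no deduplication).
#'
#' @param x `channels x samples` matrix of a continuous recording whose first
#'   sample is at time 0.
#' @param sfreq Sampling rate in Hz.
#' @param onsets Stimulus onset times in seconds.
#' @param window Length-2 epoch window in seconds relative to onset.
#' @param labels Optional per-onset class labels in `{0, 1}`; defaults to 0.
#' @return An [epoch_collection()].
#' @export
epoch_signal <- function(x, sfreq, onsets, window = c(0, 1), labels = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  n_samp <- round((window[2] - window[1]) * sfreq)
  if (n_samp < 1) stop("epoch window contains no sample")
  if (is.null(labels)) labels <- rep(0L, length(onsets))
  stopifnot(length(labels) == length(onsets))
  start_idx <- round((onsets + window[1]) * sfreq) + 1L
  ok <- start_idx >= 1L & (start_idx + n_samp - 1L) <= ncol(x)
  if (any(!ok))
    warning(sprintf("%d onset(s) too close to the recording edge were dropped",
                    sum(!ok)))
  start_idx <- start_idx[ok]; labels <- labels[ok]
  if (length(start_idx) == 0L) stop("no onset fits inside the recording")
  data <- array(0, dim = c(length(start_idx), nrow(x), n_samp))
  for (e in seq_along(start_idx))
    data[e, , ] <- x[, start_idx[e]:(start_idx[e] + n_samp - 1L), drop = FALSE]
  times <- window[1] + (seq_len(n_samp) - 1L) / sfreq
  out <- epoch_collection(data, labels, sfreq, times, rownames(x))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean voltage over the baseline
#' interval. Note that on homoscedastic data this induces heteroscedasticity:
#' the per-sample noise standard deviation is reduced inside the baseline
#' interval and distorted outside it, which violates the homoscedasticity
#' assumption underlying time-decoupled covariance estimation. It is
#' therefore not part of the default pipeline and must be requested
#' explicitly.
#'
#' @param epochs An [epoch_collection()] whose time axis covers `baseline`.
#' @param baseline Length-2 interval `(start, end)` in seconds, end-exclusive.
#' @return A baseline-corrected [epoch_collection()].
#' @export
baseline_correct <- function(epochs, baseline = c(-0.2, 0)) {
  stopifnot(inherits(epochs, "epoch_collection"))
  eps <- 1e-6 / epochs$sfreq
  sel <- epochs$times >= baseline[1] - eps & epochs$times < baseline[2] - eps
  if (!any(sel))
    stop("baseline interval lies outside the epoch window")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  data <- epochs$data - as.vector(bl)  # (epoch, channel) recycles over samples
  epoch_collection(data, epochs$labels, epochs$sfreq, epochs$times,
                   epochs$channel_names)
}

#' Construct a feature matrix
#'
#' Container for the stacked interval-averaged voltage features: `X` is
#' `D x N` with `D = C * K`, one column per epoch, channels fastest within
#' an interval (all channels for interval 1, then all channels for
#' interval 2, ...). All covariance block indexing relies on this layout.
#'
#' @param X `D x N` numeric matrix (microvolts).
#' @param labels Length-`N` vector in `{0, 1}`.
#' @param n_channels,n_intervals Layout `(C, K)` with `D = C * K`.
#' @param widths Integer per-interval sample counts `|T_m|`.
#' @param intervals Optional originating [interval_set()].
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, labels, n_channels, n_intervals, widths,
                           intervals = NULL) {
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (nrow(X) != n_channels * n_intervals)
    stop("nrow(X) must equal n_channels * n_intervals")
  if (ncol(X) != length(labels))
    stop("one label per column required")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (length(widths) != n_intervals) stop("one width per interval required")
  structure(list(X = X, labels = labels, n_channels = n_channels,
                 n_intervals = n_intervals, widths = as.integer(widths),
                 intervals = intervals),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> D = %d (%d channels x %d intervals), N = %d epochs (%d target)\n",
              nrow(x$X), x$n_channels, x$n_intervals, ncol(x$X),
              sum(x$labels == 1L)))
  invisible(x)
}

#' Extract interval-averaged voltage features
#'
#' For every epoch, averages each channel's voltage over each feature time
#' interval and stacks the result into one column of the `D x N` feature
#' matrix (`D = C * K`, channels fastest within an interval). The operation
#' is linear in the epoch data.
#'
#' @param epochs An [epoch_collection()].
#' @param intervals An [interval_set()] lying within the epoch window; every
#'   interval must contain at least one sample at the working rate.
#' @return A [feature_matrix()].
#' @export
extract_features <- function(epochs, intervals) {
  stopifnot(inherits(epochs, "epoch_collection"))
  idx <- interval_membership(intervals, epochs$times)
  d <- dim(epochs$data)
  K <- length(idx)
  X <- matrix(0, nrow = d[2] * K, ncol = d[1])
  for (m in seq_len(K)) {
    sl <- epochs$data[, , idx[[m]], drop = FALSE]
    avg <- if (length(idx[[m]]) == 1L) sl[, , 1L] else
      apply(sl, c(1, 2), mean)                    # epochs x channels
    X[(m - 1L) * d[2] + seq_len(d[2]), ] <- t(avg)
  }
  feature_matrix(X, epochs$labels, n_channels = d[2], n_intervals = K,
                 widths = vapply(idx, length, 1L), intervals = intervals)
}

#' Unstack a feature vector into channel-by-interval form
#'
#' Inverse of the stacking used by [extract_features()]: recovers the
#' `C x K` matrix of per-interval channel values from a length-`D` feature
#' vector under the declared layout.
#'
#' @param v Length-`D` feature vector.
#' @param n_channels,n_intervals Layout `(C, K)`.
#' @return A `C x K` matrix.
#' @export
unstack_features <- function(v, n_channels, n_intervals) {
  stopifnot(length(v) == n_channels * n_intervals)
  matrix(v, nrow = n_channels, ncol = n_intervals)
}

#' Free parameters of a D-dimensional covariance matrix
#'
#' A symmetric `D x D` covariance matrix has `D * (D + 1) / 2` free
#' parameters — e.g. 12090 for the 155-dimensional feature vector of a
#' 31-channel montage with 5 time intervals, which is why regularization is
#' unavoidable at ERP calibration sample sizes.
#'
#' @param D Feature dimensionality, `>= 1`.
#' @return Integer count.
#' @export
count_free_parameters <- function(D) {
  stopifnot(D >= 1)
  as.integer(round(D * (D + 1) / 2))
}
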