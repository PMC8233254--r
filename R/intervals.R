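#' Define a set of feature time intervals
#'
#' Feature extraction averages the ERP voltage of every channel within each
#' interval. Intervals are half-open `[start, end)`: a sample at time `t`
#' belongs to interval `m` iff `start_m <= t < end_m`, so contiguous
#' boundaries never assign a sample twice.
#'
#' @param boundaries Strictly increasing numeric vector of boundary times in
#'   seconds relative to stimulus onset; `K + 1` boundaries define `K`
#'   contiguous intervals. Ignored when `starts`/`ends` are given.
#' @param starts,ends Optional explicit interval edges (seconds) for
#'   non-contiguous sets; both length `K`, with `starts < ends` and
#'   non-overlapping.
#' @return An object of class `interval_set` with fields `starts`, `ends`
#'   and `n_intervals`.
#' @examples
#' interval_set(c(0.10, 0.17, 0.23, 0.30, 0.41, 0.50))
#' @export
interval_set <- function(boundaries = NULL, starts = NULL, ends = NULL) {
  if (is.null(starts) != is.null(ends))
    stop("give both `starts` and `ends`, or neither")
  if (!is.null(starts)) {
    starts <- as.numeric(starts); ends <- as.numeric(ends)
    if (length(starts) != length(ends) || length(starts) < 1L)
      stop("`starts` and `ends` must be non-empty and of equal length")
    if (any(ends <= starts)) stop("every interval needs end > start")
    if (length(starts) > 1L) {
      o <- order(starts)
      starts <- starts[o]; ends <- ends[o]
      if (any(starts[-1L] < ends[-length(ends)]))
        stop("intervals must not overlap")
    }
  } else {
    boundaries <- as.numeric(boundaries)
    if (length(boundaries) < 2L) stop("need at least 2 boundaries")
    if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
    starts <- boundaries[-length(boundaries)]
    ends <- boundaries[-1L]
  }
  structure(list(starts = starts, ends = ends,
                 n_intervals = length(starts)),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d interval(s):\n", x$n_intervals))
  cat(paste(sprintf("  [%.3f, %.3f)", x$starts, x$ends), collapse = "\n"), "\n")
  invisible(x)
}

#' Standard ERP feature interval sets
#'
#' Boundary sets commonly used for interval-averaged ERP voltage features in
#' visual/tone oddball paradigms and in word paradigms (whose informative ERP
#' components have larger latencies). `"all"` uses every 10 ms sample of the
#' response window as its own interval.
#'
#' @param paradigm `"visual"` (also covers tone oddball) or `"word"`.
#' @param n_intervals 2, 5, 10, or `"all"`.
#' @return An [interval_set()].
#' @export
default_intervals <- function(paradigm = c("visual", "word"),
                              n_intervals = 5) {
  paradigm <- match.arg(paradigm)
  key <- as.character(n_intervals)
  if (paradigm == "visual") {
    switch(key,
      "2"  = interval_set(c(0.10, 0.18, 0.28)),
      "5"  = interval_set(c(0.10, 0.17, 0.23, 0.30, 0.41, 0.50)),
      "10" = interval_set(c(0.10, 0.14, 0.17, 0.20, 0.23, 0.27,
                            0.30, 0.35, 0.41, 0.45, 0.50)),
      "all" = interval_set(seq(0.10, 0.50, by = 0.01)),
      stop("no ", key, "-interval set for the visual/tone paradigm"))
  } else {
    switch(key,
      "2"  = interval_set(starts = c(0.40, 0.65), ends = c(0.56, 0.91)),
      "5"  = interval_set(c(0.18, 0.26, 0.40, 0.56, 0.68, 0.91)),
      "10" = interval_set(c(0.18, 0.23, 0.29, 0.40, 0.48, 0.56,
                            0.61, 0.68, 0.75, 0.82, 0.91)),
      "all" = interval_set(seq(0.18, 0.91, by = 0.01)),
      stop("no ", key, "-interval set for the word paradigm"))
  }
}

# Sample membership of each interval on a concrete time axis.
# Returns a list of integer index vectors; errors on empty intervals.
interval_membership <- function(intervals, times) {
  stopifnot(inherits(intervals, "interval_set"))
  eps <- 1e-6 * max(diff(times)[1], 1e-12)
  idx <- lapply(seq_len(intervals$n_intervals), function(m) {
    which(times >= intervals$starts[m] - eps & times < intervals$ends[m] - eps)
  })
  empty <- which(vapply(idx, length, 1L) == 0L)
  if (length(empty))
    stop(sprintf("interval [%.3f, %.3f) contains no sample at this sampling rate",
                 intervals$starts[empty[1]], intervals$ends[empty[1]]))
  idx
}

#' Number of samples per interval on a concrete time axis
#'
#' @param intervals An [interval_set()].
#' @param times Numeric vector of sample times in seconds.
#' @return Integer vector of per-interval sample counts `|T_m|`.
#' @export
interval_widths <- function(intervals, times) {
  vapply(interval_membership(intervals, times), length, 1L)
}
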