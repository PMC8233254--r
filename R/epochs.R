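#' Construct an epoch collection
#'
#' The basic container consumed by the whole pipeline: a 3-D voltage array
#' (epochs x channels x samples, microvolts) with per-epoch binary labels
#' (1 = target, 0 = non-target), the sampling rate and the stimulus-relative
#' time axis.
#'
#' @param data Numeric array `n_epochs x n_channels x n_samples` (microvolts).
#' @param labels Integer vector of length `n_epochs`, entries in `{0, 1}`.
#' @param sfreq Sampling rate in Hz.
#' @param times Sample times in seconds relative to stimulus onset; strictly
#'   increasing, uniformly spaced at `1/sfreq`.
#' @param channel_names Optional channel identifiers.
#' @return An object of class `epoch_collection`.
#' @export
epoch_collection <- function(data, labels, sfreq, times, channel_names = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (epochs x channels x samples)")
  d <- dim(data)
  labels <- as.integer(labels)
  if (length(labels) != d[1])
    stop("`labels` length must equal the number of epochs")
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 0 (non-target) or 1 (target)")
  if (length(times) != d[3])
    stop("`times` length must equal the number of samples per epoch")
  dt <- diff(times)
  if (any(dt <= 0) || max(abs(dt - 1 / sfreq)) > 1e-6 / sfreq)
    stop("`times` must be strictly increasing and uniformly spaced at 1/sfreq")
  if (is.null(channel_names))
    channel_names <- sprintf("Ch%02d", seq_len(d[2]))
  if (length(channel_names) != d[2])
    stop("`channel_names` length must equal the number of channels")
  structure(list(data = data, labels = labels, sfreq = sfreq,
                 times = as.numeric(times),
                 channel_names = as.character(channel_names)),
            class = "epoch_collection")
}

#' @export
print.epoch_collection <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_collection> %d epochs (%d target / %d non-target), %d channels, %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
              d[1], sum(x$labels == 1L), sum(x$labels == 0L), d[2], d[3],
              x$sfreq, x$times[1], x$times[d[3]]))
  invisible(x)
}

#' Number of epochs in a collection
#' @param x An `epoch_collection`.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' Subset an epoch collection by epoch and/or channel
#'
#' @param x An `epoch_collection`.
#' @param epochs Integer indices of epochs to keep (default all).
#' @param channels Integer indices of channels to keep (default all).
#' @return A new `epoch_collection`.
#' @export
subset_epochs <- function(x, epochs = NULL, channels = NULL) {
  stopifnot(inherits(x, "epoch_collection"))
  if (is.null(epochs)) epochs <- seq_len(dim(x$data)[1])
  if (is.null(channels)) channels <- seq_len(dim(x$data)[2])
  epoch_collection(x$data[epochs, channels, , drop = FALSE],
                   x$labels[epochs], x$sfreq, x$times,
                   x$channel_names[channels])
}

#' Write / read an epoch collection as plain text
#'
#' Serializes to a directory holding `metadata.json` (labels, sampling rate,
#' time axis, channel names, optional provenance echo) and `data.csv`, the
#' voltage array flattened to `(n_epochs * n_channels)` rows by `n_samples`
#' columns, epoch-major (all channels of epoch 1, then epoch 2, ...).
#'
#' @param x An `epoch_collection`.
#' @param path Directory to create/fill.
#' @param provenance Optional list echoed verbatim into the metadata (e.g. the
#'   simulation configuration and seed).
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` returns
#'   the reconstructed `epoch_collection`.
#' @export
write_epochs <- function(x, path, provenance = NULL) {
  stopifnot(inherits(x, "epoch_collection"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$data)
  meta <- list(n_epochs = d[1], n_channels = d[2], n_samples = d[3],
               labels = x$labels, sfreq = x$sfreq, times = x$times,
               channel_names = x$channel_names)
  if (!is.null(provenance)) meta$provenance <- provenance
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  utils::write.table(flat, file.path(path, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(file.path(path, "data.csv"), sep = ","))
  dimnames(flat) <- NULL
  data <- aperm(array(flat, dim = c(meta$n_channels, meta$n_epochs,
                                    meta$n_samples)), c(2, 1, 3))
  epoch_collection(data, meta$labels, meta$sfreq, meta$times,
                   meta$channel_names)
}
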