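#' Multichannel EEG record
#'
#' A lightweight container for a block of uniformly sampled multichannel EEG:
#' an `n_samples x n_channels` numeric matrix, a sampling rate in Hz and one
#' unique label per channel (10-20 site names such as `"P7"`, `"O1"`, `"O2"`,
#' `"P8"`). Amplitudes are in arbitrary units (nominally microvolts); all
#' in-package spectral features are amplitude-ratio based.
#'
#' @param samples Numeric matrix (or vector for a single channel), one column
#'   per channel. All values must be finite.
#' @param rate Sampling rate in Hz (> 0).
#' @param channels Character vector of unique channel labels, one per column.
#' @return An object of class `eeg_record`.
#' @examples
#' rec <- eeg_record(matrix(rnorm(256), ncol = 2), rate = 128,
#'                   channels = c("O1", "O2"))
#' n_samples(rec)
#' duration(rec)
#' @export
eeg_record <- function(samples, rate, channels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    abort("`samples` must be a numeric matrix or vector.")
  }
  if (is.null(channels)) {
    channels <- colnames(samples) %||% paste0("ch", seq_len(ncol(samples)))
  }
  channels <- as.character(channels)
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).")
  }
  if (length(channels) != ncol(samples)) {
    abort(sprintf("%d channel labels for %d columns.",
                  length(channels), ncol(samples)))
  }
  if (anyDuplicated(channels) || any(!nzchar(channels))) {
    abort("Channel labels must be unique and non-empty.")
  }
  if (!all(is.finite(samples))) abort("All EEG samples must be finite.")
  colnames(samples) <- channels
  structure(list(samples = samples, rate = rate, channels = channels),
            class = "eeg_record")
}

#' Eyelid closure degree trace
#'
#' A series of eyelid-closure fractions (0 = fully open, 1 = fully closed)
#' sampled at a fixed rate, 7 Hz in the reference acquisition setup.
#'
#' @param values Numeric vector of closure fractions in `[0, 1]`.
#' @param rate Sampling rate in Hz (> 0), default 7.
#' @return An object of class `ecd_trace`.
#' @examples
#' tr <- ecd_trace(c(0.1, 0.1, 0.95, 0.1), rate = 7)
#' duration(tr)
#' @export
ecd_trace <- function(values, rate = 7) {
  values <- as.numeric(values)
  if (!is.numeric(rate) || length(rate) != 1 || !is.finite(rate) || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).")
  }
  bad <- which(!is.finite(values) | values < 0 | values > 1)
  if (length(bad) > 0) {
    abort(sprintf(
      "ECD values must lie in [0, 1]; first offending sample at row %d (value %s).",
      bad[1], format(values[bad[1]])))
  }
  structure(list(values = values, rate = rate), class = "ecd_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of samples in a signal object
#' @param x An `eeg_record` or `ecd_trace`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  if (inherits(x, "eeg_record")) nrow(x$samples)
  else if (inherits(x, "ecd_trace")) length(x$values)
  else abort("Not a signal object.")
}

#' Duration of a signal object in seconds
#' @param x An `eeg_record` or `ecd_trace`.
#' @return Duration in seconds (`n_samples / rate`).
#' @export
duration <- function(x) n_samples(x) / x$rate

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$rate, duration(x)))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ecd_trace <- function(x, ...) {
  cat(sprintf("<ecd_trace> %d samples @ %g Hz (%.2f s), range [%.3f, %.3f]\n",
              length(x$values), x$rate, duration(x),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as_tibble.eeg_record <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$samples))
  dplyr::bind_cols(
    tibble::tibble(time_s = (seq_len(nrow(x$samples)) - 1) / x$rate), out)
}

#' @export
as_tibble.ecd_trace <- function(x, ...) {
  tibble::tibble(time_s = (seq_along(x$values) - 1) / x$rate, ecd = x$values)
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' Slice an EEG record by time
#'
#' Extracts the samples whose times fall in `[from_s, to_s)` (nearest-sample
#' rounding at the boundaries).
#'
#' @param record An `eeg_record`.
#' @param from_s,to_s Start (inclusive) and end (exclusive) times in seconds.
#' @return An `eeg_record` covering the requested span.
#' @export
slice_record <- function(record, from_s, to_s) {
  stopifnot(inherits(record, "eeg_record"), to_s > from_s)
  i0 <- round(from_s * record$rate) + 1
  i1 <- round(to_s * record$rate)
  i0 <- max(1L, as.integer(i0))
  i1 <- min(nrow(record$samples), as.integer(i1))
  if (i1 < i0) abort("Requested slice is empty.")
  eeg_record(record$samples[i0:i1, , drop = FALSE], record$rate,
             record$channels)
}

#' Extract one channel of an EEG record as a numeric vector
#' @param record An `eeg_record`.
#' @param channel Channel label.
#' @return Numeric vector of samples.
#' @export
channel_vector <- function(record, channel) {
  stopifnot(inherits(record, "eeg_record"))
  if (!channel %in% record$channels) {
    abort(sprintf("Unknown channel '%s' (have: %s).", channel,
                  paste(record$channels, collapse = ", ")))
  }
  as.numeric(record$samples[, channel])
}
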