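#' Design the analysis-band FIR filter
#'
#' Linear-phase Hamming-window band-pass used throughout the pipeline. At the
#' default 257 taps and 128 Hz the transition width is about 1.6 Hz, giving
#' > 50 dB single-pass stopband attenuation at 3 Hz and 32 Hz.
#'
#' @param low,high Band edges in Hz.
#' @param rate Sampling rate in Hz.
#' @param taps Filter length (odd).
#' @return Numeric vector of filter coefficients.
#' @keywords internal
fir_coefficients <- function(low = 4, high = 30, rate = 128, taps = 257) {
  if (!(0 < low && low < high && high < rate / 2)) {
    abort("Band edges must satisfy 0 < low < high < rate/2.")
  }
  signal::fir1(taps - 1, c(low, high) / (rate / 2), type = "pass",
               window = signal::hamming(taps))
}

# Causal FIR convolution; y[i] depends on x[i-taps+1..i], with samples
# before the stream start taken as zero.
causal_fir <- function(b, x) {
  np <- length(b) - 1
  y <- as.numeric(stats::filter(c(rep(0, np), x), b,
                                method = "convolution", sides = 1))
  y[(np + 1):(np + length(x))]
}

# Zero-phase (forward-backward) FIR application with zero padding.
zero_phase_fir <- function(b, x) {
  np <- length(b) - 1
  xp <- c(rep(0, np), x, rep(0, np))
  y1 <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  y1[is.na(y1)] <- 0
  y2 <- rev(as.numeric(stats::filter(rev(y1), b, method = "convolution",
                                     sides = 1)))
  y2[is.na(y2)] <- 0
  y2[(np + 1):(np + length(x))]
}

#' Band-pass filter an EEG record into the 4-30 Hz analysis band
#'
#' Applies a linear-phase FIR band-pass per channel, removing the delta band
#' (and residual eye-blink energy below ~2 Hz) and everything above the beta
#' band. Offline mode (`mode = "zero_phase"`, the default) applies the filter
#' forward and backward so the output has no phase shift; streaming mode
#' (`mode = "causal"`) applies a single causal pass and compensates the
#' (taps-1)/2-sample group delay, as used in the real-time PERCLOS path.
#'
#' @param record An [eeg_record()].
#' @param low,high Band edges in Hz (defaults 4 and 30).
#' @param taps FIR length (default 257 at 128 Hz, ~1.6 Hz transition).
#' @param mode `"zero_phase"` (offline) or `"causal"` (delay-compensated).
#' @return A filtered `eeg_record` with identical metadata.
#' @examples
#' rec <- eeg_record(sin(2 * pi * 10 * (0:1279) / 128), rate = 128,
#'                   channels = "O2")
#' filt <- fir_bandpass(rec)
#' @export
fir_bandpass <- function(record, low = 4, high = 30, taps = 257,
                         mode = c("zero_phase", "causal")) {
  stopifnot(inherits(record, "eeg_record"))
  mode <- match.arg(mode)
  b <- fir_coefficients(low, high, record$rate, taps)
  if (nrow(record$samples) < taps) {
    abort(sprintf("Record too short for the %d-tap filter (%d samples).",
                  taps, nrow(record$samples)))
  }
  delay <- (taps - 1) / 2
  out <- apply(record$samples, 2, function(x) {
    if (mode == "zero_phase") {
      zero_phase_fir(b, x)
    } else {
      # causal pass, then shift left by the group delay (future-padded with 0)
      y <- causal_fir(b, c(x, rep(0, delay)))
      y[(delay + 1):(delay + length(x))]
    }
  })
  eeg_record(out, record$rate, record$channels)
}

#' Remove blink spikes from an eyelid-closure trace
#'
#' A blink shows up as a short run of near-closed samples: every maximal run
#' with values at or above `threshold` whose duration is strictly less than
#' `max_dur` seconds is replaced by the value immediately preceding the run
#' (sustained closures of `max_dur` or longer are left untouched -- they are
#' true eye closures, not blinks). A qualifying run that starts at the first
#' sample is back-filled from the first following sub-threshold value. The
#' operation is idempotent.
#'
#' @param trace An [ecd_trace()].
#' @param threshold Closure fraction at or above which a sample can belong to
#'   a blink (default 0.9).
#' @param max_dur Maximum blink duration in seconds (default 0.4; runs at
#'   least this long are preserved).
#' @return A blink-cleaned `ecd_trace`.
#' @examples
#' tr <- ecd_trace(c(0.1, 0.1, 0.95, 1.0, 0.1), rate = 7)
#' remove_ecd_blinks(tr)$values
#' @export
remove_ecd_blinks <- function(trace, threshold = 0.9, max_dur = 0.4) {
  stopifnot(inherits(trace, "ecd_trace"))
  v <- trace$values
  if (length(v) == 0) abort("Empty trace.")
  high <- v >= threshold
  r <- rle(high)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    if (r$lengths[k] / trace$rate >= max_dur) next  # sustained closure
    i0 <- starts[k]; i1 <- ends[k]
    fill <- if (i0 > 1) {
      v[i0 - 1]
    } else {
      after <- which(!high)
      if (length(after) == 0) next  # whole trace above threshold: nothing to do
      v[after[1]]
    }
    v[i0:i1] <- fill
  }
  ecd_trace(v, trace$rate)
}

#' Label eyelid-closure fractions with their ECD group
#'
#' Maps closure fractions onto the five-group vocabulary: FO (full open,
#' ECD < 0.2), SC (slight closure, 0.2-0.4), HC (half, 0.4-0.6), AC (almost,
#' 0.6-0.8) and FC (full closure, ECD >= 0.8). Ranges are half-open with the
#' boundary belonging to the upper group, so 0.2 is SC and 0.8 is FC.
#'
#' @param value Numeric vector of closure fractions in `[0, 1]`.
#' @return Factor with levels `FO, SC, HC, AC, FC`.
#' @examples
#' label_ecd_group(c(0.19, 0.20, 0.80, 1))
#' @export
label_ecd_group <- function(value) {
  if (any(!is.finite(value) | value < 0 | value > 1)) {
    abort("ECD values must lie in [0, 1].")
  }
  idx <- pmin(findInterval(value, ECD_BREAKS), 5L)
  factor(ECD_GROUPS[idx], levels = ECD_GROUPS)
}

#' Extract the per-group analysis segments from an aligned recording
#'
#' For each ECD group, finds the longest maximal run of same-labelled samples
#' in the (blink-cleaned) closure trace, truncates it to its first
#' `max_len_s` seconds, and pairs it with the time-aligned EEG slice. Groups
#' the trace never visits are absent from the output and listed in the
#' `missing_groups` attribute. The 7 Hz trace and 128 Hz EEG are aligned by
#' sample-index-to-seconds conversion with nearest-sample rounding.
#'
#' @param trace An [ecd_trace()], already blink-cleaned (see
#'   [remove_ecd_blinks()]).
#' @param record An [eeg_record()] covering the same time span (durations
#'   must agree within one ECD sample period).
#' @param max_len_s Maximum segment length in seconds (default 10: longer
#'   runs contribute only their first 10 s).
#' @param subject Optional subject identifier carried into the output.
#' @return A tibble with one row per realized group: `subject`, `group`,
#'   `start_s`, `duration_s`, `mean_ecd` and a list-column `eeg` of
#'   `eeg_record` slices; attribute `missing_groups` names absent groups.
#' @export
extract_group_segments <- function(trace, record, max_len_s = 10,
                                   subject = NA_character_) {
  stopifnot(inherits(trace, "ecd_trace"), inherits(record, "eeg_record"))
  if (abs(duration(trace) - duration(record)) > 1 / trace$rate) {
    abort(sprintf(
      "Trace (%.3f s) and record (%.3f s) durations differ by more than one ECD sample period.",
      duration(trace), duration(record)))
  }
  labels <- as.character(label_ecd_group(trace$values))
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble::tibble(group = r$values, start = starts, len = r$lengths)
  rows <- purrr::map(ECD_GROUPS, function(g) {
    cand <- runs[runs$group == g, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    best <- cand[order(-cand$len, cand$start)[1], ]
    keep <- min(best$len, round(max_len_s * trace$rate))
    i0 <- best$start
    i1 <- i0 + keep - 1
    t0 <- (i0 - 1) / trace$rate
    t1 <- i1 / trace$rate
    tibble::tibble(
      subject = subject, group = g, start_s = t0,
      duration_s = keep / trace$rate,
      mean_ecd = mean(trace$values[i0:i1]),
      eeg = list(slice_record(record, t0, t1)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$group <- factor(out$group, levels = ECD_GROUPS)
  attr(out, "missing_groups") <- setdiff(ECD_GROUPS, as.character(out$group))
  out
}
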