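#' EEG band definitions
#'
#' Contiguous half-open frequency intervals partitioning the 4-30 Hz
#' analysis band: theta `[4, 8)`, alpha `[8, 13)`, beta `[13, 30]`. The upper
#' beta edge is closed so a bin at exactly 30 Hz is counted. Delta and gamma
#' are excluded upstream by the 4-30 Hz band-pass.
#'
#' @return A tibble with columns `band`, `lo`, `hi`.
#' @export
eeg_bands <- function() {
  tibble::tibble(band = EEG_BANDS, lo = c(4, 8, 13), hi = c(8, 13, 30))
}

#' Band power percentages of a windowed EEG channel
#'
#' Applies a Hamming window, takes the discrete Fourier transform, sums the
#' squared magnitudes of the bins whose centre frequency falls in each band,
#' and returns each band's power as a percentage of the summed power of the
#' three bands. The window gain cancels in the ratio. No zero padding is
#' used, so the frequency resolution is `1/T` for a `T`-second window.
#'
#' @param window Numeric vector of samples from a single channel.
#' @param rate Sampling rate in Hz (must exceed twice the highest band edge).
#' @param bands Band definition tibble, see [eeg_bands()].
#' @return Named numeric vector of percentages summing to 100.
#' @examples
#' x <- sin(2 * pi * 10 * (0:1279) / 128)
#' band_power_percentages(x, 128)
#' @export
band_power_percentages <- function(window, rate, bands = eeg_bands()) {
  if (length(window) == 0) abort("Empty window.")
  if (rate <= 2 * max(bands$hi)) {
    abort("Sampling rate must exceed twice the highest band edge.")
  }
  n <- length(window)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  if (n == 1) w <- 1
  spec <- Mod(fft(window * w))^2
  freqs <- (seq_len(n) - 1) * rate / n
  keep <- freqs <= rate / 2
  pow <- vapply(seq_len(nrow(bands)), function(i) {
    lo <- bands$lo[i]; hi <- bands$hi[i]
    inb <- if (i == nrow(bands)) freqs >= lo & freqs <= hi
           else freqs >= lo & freqs < hi
    sum(spec[inb & keep])
  }, numeric(1))
  tot <- sum(pow)
  if (tot == 0) abort("All band powers are zero; percentages undefined.")
  setNames(100 * pow / tot, bands$band)
}

#' Root mean square amplitude
#'
#' Square root of the mean squared sample value; the standard mean-amplitude
#' measure for zero-mean signals such as EEG.
#'
#' @param window Numeric vector of samples.
#' @return Non-negative scalar in the amplitude units of the input.
#' @examples
#' rms(rep(5, 10))
#' @export
rms <- function(window) {
  if (length(window) == 0) abort("Empty window.")
  sqrt(mean(window^2))
}

#' Normalized Shannon entropy of an amplitude histogram
#'
#' Divides the amplitude range of the window into `k` equal-width bins,
#' converts counts to probabilities and returns
#' `-sum(p * log(p, base)) / log(k, base)` (with `0 * log 0 = 0`), a
#' dimensionless value in `[0, 1]`. A constant window (zero amplitude range)
#' returns 0.
#'
#' @param window Numeric vector of samples.
#' @param k Number of histogram bins (default 10).
#' @param base Logarithm base (default 10).
#' @return Entropy in `[0, 1]`.
#' @examples
#' shannon_entropy(c(rep(0, 5), rep(1, 5)))  # two occupied bins: ~0.301
#' @export
shannon_entropy <- function(window, k = 10, base = 10) {
  if (length(window) == 0) abort("Empty window.")
  if (k < 2) abort("`k` must be at least 2.")
  lo <- min(window); hi <- max(window)
  if (hi == lo) return(0)
  idx <- pmin(floor((window - lo) / (hi - lo) * k) + 1L, k)
  p <- tabulate(idx, nbins = k) / length(window)
  p <- p[p > 0]
  -sum(p * log(p, base)) / log(k, base)
}

#' Build the per-segment feature table
#'
#' Computes, for every (segment, channel) pair, the three band power
#' percentages plus RMS and Shannon entropy on the segment's full window
#' (segments shorter than the nominal 10 s use their entire length -- down to
#' the 1 s windows of the real-time path -- with no padding), and returns one
#' row per (segment, channel, band).
#'
#' @param segments Segment tibble from [extract_group_segments()] (columns
#'   `subject`, `group`, `mean_ecd` and list-column `eeg`).
#' @param channels Channel labels to extract; defaults to the channels of the
#'   first segment's record.
#' @return A tibble with columns `subject`, `group`, `channel`, `band`,
#'   `per_percent`, `rms`, `entropy`, `observed_ecd`.
#' @export
build_feature_table <- function(segments, channels = NULL) {
  stopifnot(is.data.frame(segments), nrow(segments) > 0)
  channels <- channels %||% segments$eeg[[1]]$channels
  purrr::pmap_dfr(
    list(segments$subject, as.character(segments$group), segments$mean_ecd,
         segments$eeg),
    function(subject, group, mean_ecd, eeg) {
      missing_ch <- setdiff(channels, eeg$channels)
      if (length(missing_ch) > 0) {
        abort(sprintf("Unknown channel label(s): %s.",
                      paste(missing_ch, collapse = ", ")))
      }
      purrr::map_dfr(channels, function(ch) {
        x <- channel_vector(eeg, ch)
        per <- band_power_percentages(x, eeg$rate)
        tibble::tibble(
          subject = subject, group = group, channel = ch,
          band = names(per), per_percent = as.numeric(per),
          rms = rms(x), entropy = shannon_entropy(x),
          observed_ecd = mean_ecd)
      })
    })
}
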