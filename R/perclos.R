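#' Per-second ECD group estimation from an O2 EEG stream
#'
#' The real-time front end of the EEG-based PERCLOS algorithm: the stream is
#' band-pass filtered to 4-30 Hz with the causal (group-delay-compensated)
#' FIR, cut into non-overlapping 1-second windows aligned to the stream
#' start, and for each window the alpha power percentage is computed, mapped
#' through the fitted model to an estimated closure (clipped to `[0, 1]`)
#' and labelled with its ECD group. Exactly one label is produced per full
#' second; delay compensation looks one filter half-length (~1 s) ahead, so
#' a live deployment emits each label with that latency.
#'
#' @param eeg An [eeg_record()] (any channel set) or numeric vector of
#'   samples.
#' @param model A fitted `ecd_svr` or `simple_lr` mapping alpha power
#'   percentage to ECD fraction.
#' @param channel Channel to use when `eeg` is multichannel (default
#'   `"O2"`).
#' @param rate Sampling rate when `eeg` is a bare vector (default 128).
#' @param low,high Analysis band edges in Hz.
#' @return A tibble with one row per second: `second`, `alpha_per`, `eecd`,
#'   `group`.
#' @export
estimate_group_stream <- function(eeg, model, channel = "O2", rate = 128,
                                  low = 4, high = 30) {
  if (is.null(model) || !(inherits(model, "ecd_svr") ||
                          inherits(model, "simple_lr"))) {
    abort("`model` must be a fitted ecd_svr or simple_lr object.")
  }
  if (inherits(eeg, "eeg_record")) {
    rate <- eeg$rate
    if (length(eeg$channels) > 1 && !channel %in% eeg$channels) {
      abort(sprintf(
        "Multichannel input: select a channel (no '%s' present).", channel))
    }
    x <- if (length(eeg$channels) == 1) as.numeric(eeg$samples[, 1])
         else channel_vector(eeg, channel)
  } else {
    x <- as.numeric(eeg)
  }
  n_sec <- floor(length(x) / rate)
  if (n_sec < 1) abort("Stream shorter than 1 s.")
  b <- fir_coefficients(low, high, rate)
  delay <- (length(b) - 1) / 2
  y <- causal_fir(b, c(x, rep(0, delay)))
  y <- y[(delay + 1):(delay + length(x))]
  purrr::map_dfr(seq_len(n_sec), function(s) {
    win <- y[((s - 1) * rate + 1):(s * rate)]
    alpha <- band_power_percentages(win, rate)[["alpha"]]
    eecd <- if (inherits(model, "simple_lr")) {
      pmin(pmax(predict(model, alpha), 0), 1)
    } else {
      svr_predict(model, alpha, clip = TRUE)
    }
    tibble::tibble(second = s, alpha_per = alpha, eecd = eecd,
                   group = as.character(label_ecd_group(eecd)))
  })
}

#' Sliding PERCLOS score and two-level alarm from per-second group labels
#'
#' PERCLOS over a trailing window (default 60 s) is the fraction of seconds
#' labelled FC (closure >= 0.8). The alarm is `"warning"` at or above the
#' warning threshold (default 0.12, i.e. 7.2 s of closure per minute),
#' `"advisory"` at or above the advisory threshold (default 0.08, 4.8 s),
#' otherwise `"none"`. For elapsed times shorter than the window the
#' denominator is the elapsed number of seconds.
#'
#' @param labels Character vector (or factor) of per-second group labels.
#' @param window Window length in seconds (default 60).
#' @param advisory,warning Alarm thresholds as PERCLOS fractions (advisory
#'   must be below warning).
#' @return A tibble with one row per second: `second`, `perclos`, `alarm`.
#' @examples
#' perclos_score(c(rep("FO", 50), rep("FC", 10)))
#' @export
perclos_score <- function(labels, window = 60, advisory = 0.08,
                          warning = 0.12) {
  labels <- as.character(labels)
  if (length(labels) < 1) abort("Need at least one label.")
  stopifnot(advisory < warning, window >= 1)
  fc <- cumsum(labels == "FC")
  n <- length(labels)
  score <- vapply(seq_len(n), function(t) {
    lo <- max(0, t - window)
    (fc[t] - if (lo > 0) fc[lo] else 0) / min(t, window)
  }, numeric(1))
  alarm <- dplyr::case_when(score >= warning ~ "warning",
                            score >= advisory ~ "advisory",
                            TRUE ~ "none")
  tibble::tibble(second = seq_len(n), perclos = score,
                 alarm = factor(alarm, levels = c("none", "advisory",
                                                  "warning")))
}

#' Run the full EEG-based PERCLOS monitor over a stream
#'
#' Convenience wrapper chaining [estimate_group_stream()] and
#' [perclos_score()] into the per-second monitoring log.
#'
#' @inheritParams estimate_group_stream
#' @inheritParams perclos_score
#' @return A tibble with one row per second: `second`, `alpha_per`, `eecd`,
#'   `group`, `perclos`, `alarm`.
#' @export
perclos_monitor <- function(eeg, model, channel = "O2", rate = 128,
                            window = 60, advisory = 0.08, warning = 0.12) {
  labels <- estimate_group_stream(eeg, model, channel = channel, rate = rate)
  dplyr::left_join(labels,
                   perclos_score(labels$group, window = window,
                                 advisory = advisory, warning = warning),
                   by = "second")
}
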