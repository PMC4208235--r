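#' Configuration for the synthetic-data generator
#'
#' Collects every knob of the synthetic eyelid-closure / EEG generator in one
#' validated list. The generator emulates the statistical structure the
#' estimation method relies on: a 7 Hz eyelid-closure trace with
#' group-structured plateaus and short blink spikes, and 128 Hz multichannel
#' EEG built from band-limited noise whose theta/alpha/beta power fractions
#' follow linear laws in the local closure value -- alpha rising and beta
#' falling with eye closure, as seen over occipital sites.
#'
#' The band laws are in percent as functions of ECD in percent: the alpha
#' fraction follows `a0 + a1 * ECD%` exactly (after clipping), and theta and
#' beta split the remaining percentage in the ratio of their own laws, so the
#' three fractions always sum to one. With the defaults
#' (`alpha 20 + 0.64 E`, `theta 25 - 0.14 E`, `beta 55 - 0.50 E`) all three
#' laws hold exactly.
#'
#' @param seed Integer seed; every generator is a pure function of its
#'   inputs and this seed.
#' @param ecd_rate,eeg_rate Sampling rates in Hz (defaults 7 and 128).
#' @param channels EEG channel labels (default the four occipital sites).
#' @param alpha_law,theta_law,beta_law Numeric `c(intercept, slope)` in
#'   percent and percent-per-ECD-percent.
#' @param amplitude Overall EEG amplitude scale (arbitrary units; every
#'   in-scope feature except RMS is scale-free).
#' @param tonality Fraction of each band's power carried by a coherent
#'   quasi-sinusoidal oscillation (random frequency inside the band, random
#'   phase, per channel), the rest by band-limited noise. Occipital band
#'   rhythms -- above all closed-eye alpha -- are strongly peaked rather
#'   than flat in spectrum, and short-window power ratios are only stable
#'   when most band power is coherent; default 0.85.
#' @param blink_rate Blink events per second in generated ECD traces.
#' @param blink_peak Range the blink closure peak is drawn from (within
#'   `[0.9, 1]`).
#' @param blink_max_dur Upper bound on blink duration in seconds (< 0.4).
#' @param subject_sd Per-subject SDs `c(a0, a1)` of the alpha-law
#'   perturbations used by [gen_cohort_features()].
#' @param cohort_noise_sd SD of the per-observation alpha-percentage noise in
#'   the cohort table (default 3.2 points, i.e. ~0.05 ECD fraction at the
#'   default slope).
#' @param missing_rate Per-(subject, non-FO group) dropout probability in the
#'   cohort table; FO is never dropped.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         ecd_rate = 7, eeg_rate = 128,
                         channels = c("P7", "O1", "O2", "P8"),
                         alpha_law = c(20, 0.64),
                         theta_law = c(25, -0.14),
                         beta_law = c(55, -0.50),
                         amplitude = 20,
                         tonality = 0.85,
                         blink_rate = 0.2,
                         blink_peak = c(0.9, 1.0),
                         blink_max_dur = 0.35,
                         subject_sd = c(3, 0.04),
                         cohort_noise_sd = 3.2,
                         missing_rate = 0.1) {
  stopifnot(ecd_rate > 0, eeg_rate > 0, amplitude > 0,
            tonality >= 0, tonality <= 1,
            blink_rate >= 0, blink_max_dur < 0.4, blink_max_dur > 0,
            all(blink_peak >= 0.9), all(blink_peak <= 1),
            length(alpha_law) == 2, length(theta_law) == 2,
            length(beta_law) == 2,
            all(subject_sd >= 0), cohort_noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(
    seed = as.integer(seed), ecd_rate = ecd_rate, eeg_rate = eeg_rate,
    channels = channels, alpha_law = alpha_law, theta_law = theta_law,
    beta_law = beta_law, amplitude = amplitude, tonality = tonality,
    blink_rate = blink_rate,
    blink_peak = blink_peak, blink_max_dur = blink_max_dur,
    subject_sd = subject_sd, cohort_noise_sd = cohort_noise_sd,
    missing_rate = missing_rate), class = "synth_config")
}

# Evaluate the band-fraction laws at ECD fractions `ecd`; returns a matrix
# with columns theta/alpha/beta of fractions summing to 1.
band_fractions <- function(ecd, config) {
  e <- 100 * ecd
  a <- pmin(pmax(config$alpha_law[1] + config$alpha_law[2] * e, 1), 99) / 100
  th <- pmax(config$theta_law[1] + config$theta_law[2] * e, 0.5)
  be <- pmax(config$beta_law[1] + config$beta_law[2] * e, 0.5)
  rest <- 1 - a
  cbind(theta = rest * th / (th + be), alpha = a,
        beta = rest * be / (th + be))
}

# Run `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a scheduled eyelid-closure trace
#'
#' Builds an ECD trace from a schedule of (group, duration) plateaus. Each
#' interval's samples lie strictly inside the group's closure range (a random
#' plateau level plus small jitter), and blink spikes -- runs of at most
#' `blink_max_dur` seconds at a closure drawn from `blink_peak` -- replace
#' underlying samples at Poisson rate `blink_rate`.
#'
#' @param schedule A data frame with columns `group` (one of
#'   `FO, SC, HC, AC, FC`) and `duration_s` (> 0), or a named numeric vector
#'   of durations.
#' @param config A [synth_config()].
#' @return An [ecd_trace()] at `config$ecd_rate`.
#' @examples
#' tr <- gen_ecd_trace(c(FO = 10), synth_config(seed = 1, blink_rate = 0))
#' all(tr$values < 0.2)
#' @export
gen_ecd_trace <- function(schedule, config = synth_config()) {
  if (!is.data.frame(schedule)) {
    schedule <- tibble::tibble(group = names(schedule),
                               duration_s = as.numeric(schedule))
  }
  if (nrow(schedule) == 0) abort("Empty schedule.")
  bad <- setdiff(schedule$group, ECD_GROUPS)
  if (length(bad) > 0) {
    abort(sprintf("Unknown group label(s): %s.", paste(bad, collapse = ", ")))
  }
  if (any(schedule$duration_s <= 0)) abort("Durations must be positive.")
  rate <- config$ecd_rate
  with_seed(config$seed, {
    vals <- unlist(purrr::map2(schedule$group, schedule$duration_s,
      function(g, d) {
        n <- max(1L, round(d * rate))
        i <- match(g, ECD_GROUPS)
        lo <- ECD_BREAKS[i]; hi <- ECD_BREAKS[i + 1]
        w <- hi - lo
        level <- runif(1, lo + 0.1 * w, hi - 0.1 * w)
        x <- level + rnorm(n, sd = 0.03 * w)
        pmin(pmax(x, lo + 0.01 * w), hi - 0.01 * w)
      }))
    total_s <- length(vals) / rate
    if (config$blink_rate > 0) {
      n_blinks <- rpois(1, config$blink_rate * total_s)
      max_len <- max(1L, ceiling(config$blink_max_dur * rate) - 1L)
      if (n_blinks > 0) {
        starts <- sort(sample.int(length(vals), min(n_blinks, length(vals))))
        # enforce a one-sample gap so independent blinks do not merge into
        # runs long enough to count as sustained closures
        keep <- c(TRUE, diff(starts) > max_len + 1)
        starts <- starts[keep]
        for (s in starts) {
          len <- sample.int(max_len, 1)
          idx <- s:min(s + len - 1, length(vals))
          vals[idx] <- runif(1, config$blink_peak[1], config$blink_peak[2])
        }
      }
    }
    ecd_trace(vals, rate)
  })
}

# Band-limited unit-RMS Gaussian noise: white complex spectrum restricted to
# [lo, hi) Hz (hi inclusive for the top band), inverse FFT.
band_noise <- function(n, rate, lo, hi, closed_hi = FALSE) {
  freqs <- (seq_len(n) - 1) * rate / n
  half <- 2:(floor(n / 2) + 1)
  inband <- if (closed_hi) freqs >= lo & freqs <= hi else freqs >= lo & freqs < hi
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  sel <- intersect(which(inband), half)
  spec[sel] <- complex(real = rnorm(length(sel)), imaginary = rnorm(length(sel)))
  # conjugate symmetry for a real signal
  spec[n + 2 - sel] <- Conj(spec[sel])
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# Normalize a carrier so its short-time power is flat at 1: divide by the
# square root of its moving-average instantaneous power. Gaussian band noise
# has heavy-tailed short-window power (few independent spectral bins per
# second); real band rhythms -- especially closed-eye alpha -- hold a far
# steadier envelope, and the estimator consumes short-window power ratios,
# so the stabilized carrier is the better emulation.
stabilize_power <- function(x, width) {
  n <- length(x)
  width <- max(3L, min(as.integer(width), n))
  cs <- cumsum(c(0, x^2))
  half <- width %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  p <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  x / sqrt(pmax(p, 1e-12))
}

#' Synthesize EEG whose band composition tracks an eyelid-closure trace
#'
#' Produces a multichannel EEG record as a sum of three band-limited noise
#' carriers (theta, alpha, beta; brick-wall band confinement via
#' frequency-domain synthesis), each modulated by the square root of its
#' target power fraction evaluated at the local (linearly interpolated)
#' closure value. Measured over a stationary stretch, the band power
#' percentages therefore reproduce the configured laws. Channels carry
#' independent noise realizations of the same laws.
#'
#' @param ecd An [ecd_trace()].
#' @param config A [synth_config()].
#' @return An [eeg_record()] at `config$eeg_rate` spanning the trace.
#' @examples
#' cfg <- synth_config(seed = 2, blink_rate = 0)
#' rec <- gen_eeg_from_ecd(gen_ecd_trace(c(FC = 10), cfg), cfg)
#' @export
gen_eeg_from_ecd <- function(ecd, config = synth_config()) {
  stopifnot(inherits(ecd, "ecd_trace"))
  if (length(ecd$values) == 0) abort("Empty trace.")
  n <- round(duration(ecd) * config$eeg_rate)
  t_eeg <- (seq_len(n) - 1) / config$eeg_rate
  t_ecd <- (seq_along(ecd$values) - 1) / ecd$rate
  local_ecd <- approx(t_ecd, ecd$values, xout = t_eeg, rule = 2)$y
  frac <- band_fractions(local_ecd, config)
  bands <- eeg_bands()
  with_seed(config$seed + 1L, {
    out <- vapply(seq_along(config$channels), function(ch) {
      sig <- numeric(n)
      for (i in seq_len(nrow(bands))) {
        noise <- band_noise(n, config$eeg_rate, bands$lo[i], bands$hi[i],
                            closed_hi = i == nrow(bands))
        # individual band peaks sit mid-band (e.g. alpha at 9.5-11.5 Hz);
        # the 1.5 Hz margin also keeps the ~2 Hz mainlobe of a 1-s Hamming
        # window attributed to the right band
        f0 <- runif(1, bands$lo[i] + 1.5, bands$hi[i] - 1.5)
        tone <- sqrt(2) * cos(2 * pi * f0 * t_eeg + runif(1, 0, 2 * pi))
        carrier <- stabilize_power(
          sqrt(config$tonality) * tone + sqrt(1 - config$tonality) * noise,
          config$eeg_rate / 2)
        sig <- sig + sqrt(frac[, bands$band[i]]) * carrier
      }
      config$amplitude * sig
    }, numeric(n))
    eeg_record(out, config$eeg_rate, config$channels)
  })
}

#' Generate a cohort-level feature table
#'
#' Emulates a multi-subject study summary: each subject receives a perturbed
#' linear alpha-percentage law, realizes one observation per ECD group
#' (closure drawn inside the group range, alpha percentage from the
#' subject's law plus observation noise), and may lack non-FO groups under
#' Bernoulli dropout -- mimicking real drives where not every driver reaches
#' every closure level.
#'
#' @param n_subjects Number of subjects (>= 1; at least 2 are needed for any
#'   downstream subject-wise cross-validation). The first half are tagged
#'   `M`, the rest `F`; within each sex block the first half drive in
#'   `daytime`, the rest in `nighttime`.
#' @param config A [synth_config()].
#' @return A tibble with columns `subject`, `sex`, `daylight`, `group`,
#'   `observed_ecd` (fraction) and `alpha_per` (percent).
#' @examples
#' gen_cohort_features(4, synth_config(seed = 3))
#' @export
gen_cohort_features <- function(n_subjects, config = synth_config()) {
  if (n_subjects < 1) abort("Need at least 1 subject.")
  with_seed(config$seed + 2L, {
    purrr::map_dfr(seq_len(n_subjects), function(s) {
      a0 <- config$alpha_law[1] + rnorm(1, sd = config$subject_sd[1])
      a1 <- config$alpha_law[2] + rnorm(1, sd = config$subject_sd[2])
      sex <- if (s <= ceiling(n_subjects / 2)) "M" else "F"
      block <- if (sex == "M") s else s - ceiling(n_subjects / 2)
      block_n <- if (sex == "M") ceiling(n_subjects / 2)
                 else n_subjects - ceiling(n_subjects / 2)
      daylight <- if (block <= ceiling(block_n / 2)) "daytime" else "nighttime"
      keep <- c(TRUE, runif(4) >= config$missing_rate)  # FO never dropped
      rows <- purrr::map_dfr(which(keep), function(i) {
        lo <- ECD_BREAKS[i]; hi <- ECD_BREAKS[i + 1]
        ecd <- runif(1, lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo))
        alpha <- a0 + a1 * 100 * ecd + rnorm(1, sd = config$cohort_noise_sd)
        tibble::tibble(group = ECD_GROUPS[i], observed_ecd = ecd,
                       alpha_per = min(max(alpha, 0.5), 99.5))
      })
      dplyr::bind_cols(
        tibble::tibble(subject = s, sex = sex, daylight = daylight), rows)
    })
  })
}
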