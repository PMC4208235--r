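tone <- function(freq, rate = 128, secs = 10) {
  sin(2 * pi * freq * (0:(rate * secs - 1)) / rate)
}

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  rec10 <- eeg_record(tone(10), 128, "O2")
  out10 <- fir_bandpass(rec10)
  expect_gte(rms(out10$samples[, 1]), 0.9 * rms(rec10$samples[, 1]))

  rec2 <- eeg_record(tone(2), 128, "O2")
  out2 <- fir_bandpass(rec2)
  expect_lte(rms(out2$samples[, 1]), 0.1 * rms(rec2$samples[, 1]))

  # agreement with the impulse-response DFT oracle (single causal pass);
  # compare on the steady-state middle of the record, away from the
  # forward-backward edge transients
  b <- perclosr:::fir_coefficients(4, 30, 128, 257)
  g10 <- oracle_fir_gain(b, 10, 128)
  g2 <- oracle_fir_gain(b, 2, 128)
  mid <- 400:880
  # zero-phase application squares the magnitude response
  expect_equal(rms(out10$samples[mid, 1]) / rms(rec10$samples[mid, 1]),
               g10^2, tolerance = 0.01)
  expect_lt(rms(out2$samples[mid, 1]) / rms(rec2$samples[mid, 1]),
            max(10 * g2^2, 1e-4))
})

test_that("band-pass is linear and preserves the all-zero record", {
  zero <- eeg_record(matrix(0, 1280, 1), 128, "O2")
  expect_true(all(fir_bandpass(zero)$samples == 0))

  set.seed(11)
  x <- rnorm(1280); y <- rnorm(1280)
  fx <- fir_bandpass(eeg_record(x, 128, "a"))$samples[, 1]
  fy <- fir_bandpass(eeg_record(y, 128, "a"))$samples[, 1]
  fxy <- fir_bandpass(eeg_record(2 * x + 3 * y, 128, "a"))$samples[, 1]
  expect_lt(max(abs(fxy - (2 * fx + 3 * fy))), 1e-9)
})

test_that("band-pass rejects invalid edges and too-short records", {
  rec <- eeg_record(tone(10, secs = 1), 128, "O2")
  expect_error(fir_bandpass(rec, low = 4, high = 70), "Nyquist|rate/2")
  expect_error(fir_bandpass(rec), "too short")
})

test_that("blink removal replaces short closure runs with the previous value", {
  tr <- ecd_trace(c(0.1, 0.1, 0.95, 1.0, 0.1), 7)
  expect_equal(remove_ecd_blinks(tr)$values, rep(0.1, 5))

  # a sustained closure (>= 400 ms) is not a blink
  sustained <- ecd_trace(c(0.1, 0.95, 0.95, 0.95, 0.95, 0.1), 7)
  expect_equal(remove_ecd_blinks(sustained)$values, sustained$values)

  # nothing above threshold: identity
  low <- ecd_trace(c(0.1, 0.5, 0.8), 7)
  expect_equal(remove_ecd_blinks(low)$values, low$values)

  # run at the start back-fills from the first sub-threshold value
  lead <- ecd_trace(c(0.97, 0.95, 0.2, 0.3), 7)
  expect_equal(remove_ecd_blinks(lead)$values, c(0.2, 0.2, 0.2, 0.3))
})

test_that("blink removal is idempotent and never touches sub-threshold samples", {
  for (seed in 1:5) {
    cfg <- synth_config(seed = seed, blink_rate = 0.3)
    tr <- gen_ecd_trace(c(FO = 20, HC = 20), cfg)
    once <- remove_ecd_blinks(tr)
    twice <- remove_ecd_blinks(once)
    expect_identical(once$values, twice$values)
    low_idx <- which(tr$values < 0.9)
    expect_identical(once$values[low_idx], tr$values[low_idx])
  }
})

test_that("group labelling follows the half-open range convention", {
  expect_equal(as.character(label_ecd_group(c(0.19, 0.20, 0.80, 0, 1))),
               c("FO", "SC", "FC", "FO", "FC"))
  expect_equal(as.character(label_ecd_group(c(0.39, 0.4, 0.6, 0.79))),
               c("SC", "HC", "AC", "AC"))
  expect_error(label_ecd_group(1.2), "\\[0, 1\\]")
})

test_that("segment extraction selects the longest run, first 10 s", {
  cfg <- synth_config(seed = 2, blink_rate = 0)
  # single 12-s FO run -> one FO segment of exactly 10 s from the run start
  tr <- gen_ecd_trace(c(FO = 12), cfg)
  rec <- gen_eeg_from_ecd(tr, cfg)
  segs <- extract_group_segments(tr, rec)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$duration_s, 10)
  expect_equal(segs$start_s, 0)
  expect_equal(n_samples(segs$eeg[[1]]), 1280)
  expect_setequal(attr(segs, "missing_groups"), c("SC", "HC", "AC", "FC"))

  # two HC runs: the longer one wins (verified against an exhaustive scan)
  tr2 <- gen_ecd_trace(c(HC = 3, FO = 5, HC = 6), cfg)
  rec2 <- gen_eeg_from_ecd(tr2, cfg)
  segs2 <- extract_group_segments(tr2, rec2)
  hc <- segs2[segs2$group == "HC", ]
  labels <- as.character(label_ecd_group(tr2$values))
  r <- rle(labels)
  longest <- max(r$lengths[r$values == "HC"])
  expect_equal(hc$duration_s, longest / 7)
  expect_equal(hc$start_s, 8)
})

test_that("segment EEG slices align with the ECD runs within one sample period", {
  cfg <- synth_config(seed = 6, blink_rate = 0)
  tr <- gen_ecd_trace(c(FO = 7.3, AC = 4.6, FC = 3.1), cfg)
  rec <- gen_eeg_from_ecd(tr, cfg)
  segs <- extract_group_segments(tr, rec)
  for (i in seq_len(nrow(segs))) {
    eeg_len_s <- n_samples(segs$eeg[[i]]) / 128
    expect_lt(abs(eeg_len_s - segs$duration_s[i]), 1 / 7)
    expect_equal(as.character(label_ecd_group(segs$mean_ecd[i])),
                 as.character(segs$group[i]))
  }
  # misaligned durations are rejected
  short <- eeg_record(matrix(rnorm(128), ncol = 1), 128, "O2")
  expect_error(extract_group_segments(tr, short), "durations differ")
})
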