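#' Read and write the signal CSV dialects
#'
#' Self-describing CSV formats: the first line is `# rate_hz=<float>`, the
#' second a comma-separated header (channel labels for EEG, the single
#' column `ecd` for closure traces), followed by one row per sample.
#' Timestamps are implicit (sample index over rate). Readers are strict:
#' malformed headers, non-numeric cells or out-of-range closure values raise
#' an error naming the first offending row.
#'
#' @param path File path.
#' @param record An [eeg_record()] (for `write_eeg_csv`).
#' @param trace An [ecd_trace()] (for `write_ecd_csv`).
#' @return Readers return the corresponding signal object; writers return
#'   the input invisibly.
#' @name signals_io
NULL

read_rate_header <- function(path) {
  line <- readLines(path, n = 1)
  m <- regmatches(line, regexec("^#\\s*rate_hz=([0-9.eE+-]+)\\s*$", line))[[1]]
  if (length(m) != 2) {
    abort(sprintf("Missing '# rate_hz=<float>' header in %s.", path))
  }
  rate <- suppressWarnings(as.numeric(m[2]))
  if (!is.finite(rate) || rate <= 0) {
    abort(sprintf("Invalid rate in header of %s.", path))
  }
  rate
}

read_signal_body <- function(path) {
  df <- readr::read_csv(path, skip = 1, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  num <- purrr::map(df, function(col) suppressWarnings(as.numeric(col)))
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]) & !is.na(df[[j]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric cell in column '%s', row %d of %s.",
                    names(df)[j], bad[1], path))
    }
    if (anyNA(num[[j]])) {
      abort(sprintf("Missing value in column '%s', row %d of %s.",
                    names(df)[j], which(is.na(num[[j]]))[1], path))
    }
  }
  tibble::as_tibble(num)
}

#' @rdname signals_io
#' @export
read_eeg_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s.", path))
  rate <- read_rate_header(path)
  df <- read_signal_body(path)
  eeg_record(as.matrix(df), rate, names(df))
}

#' @rdname signals_io
#' @export
write_eeg_csv <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g", record$rate), con)
  writeLines(paste(record$channels, collapse = ","), con)
  utils::write.table(format(record$samples, digits = 15, trim = TRUE,
                            scientific = NA),
                     con, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(record)
}

#' @rdname signals_io
#' @export
read_ecd_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s.", path))
  rate <- read_rate_header(path)
  df <- read_signal_body(path)
  if (!identical(names(df), "ecd")) {
    abort(sprintf("Expected single column 'ecd' in %s.", path))
  }
  bad <- which(df$ecd < 0 | df$ecd > 1)
  if (length(bad) > 0) {
    abort(sprintf("ECD value out of [0, 1] at row %d of %s (value %s).",
                  bad[1], path, format(df$ecd[bad[1]])))
  }
  ecd_trace(df$ecd, rate)
}

#' @rdname signals_io
#' @export
write_ecd_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ecd_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz=%.10g", trace$rate), con)
  writeLines("ecd", con)
  writeLines(format(trace$values, digits = 15, trim = TRUE, scientific = NA),
             con)
  invisible(trace)
}

FEATURE_COLUMNS <- c("subject", "sex", "daylight", "group", "channel",
                     "band", "per_percent", "rms", "entropy", "observed_ecd")

#' Read and write feature tables
#'
#' Plain CSV with the canonical feature columns (`subject`, `sex`,
#' `daylight`, `group`, `channel`, `band`, `per_percent`, `rms`, `entropy`,
#' `observed_ecd`). Group and band vocabularies are validated on read; the
#' round trip is lossless.
#'
#' @param features A feature tibble.
#' @param path File path.
#' @return `read_feature_csv` returns a tibble; `write_feature_csv` returns
#'   the input invisibly.
#' @name feature_io
NULL

#' @rdname feature_io
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s.", path))
  df <- readr::read_csv(path, col_types = readr::cols(
    subject = readr::col_character(), sex = readr::col_character(),
    daylight = readr::col_character(), group = readr::col_character(),
    channel = readr::col_character(), band = readr::col_character(),
    per_percent = readr::col_double(), rms = readr::col_double(),
    entropy = readr::col_double(), observed_ecd = readr::col_double()),
    progress = FALSE)
  missing_cols <- setdiff(FEATURE_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing feature column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  bad_g <- setdiff(unique(df$group), ECD_GROUPS)
  if (length(bad_g) > 0) {
    abort(sprintf("Unknown group token(s): %s.", paste(bad_g, collapse = ", ")))
  }
  bad_b <- setdiff(unique(df$band), EEG_BANDS)
  if (length(bad_b) > 0) {
    abort(sprintf("Unknown band token(s): %s.", paste(bad_b, collapse = ", ")))
  }
  df[FEATURE_COLUMNS]
}

#' @rdname feature_io
#' @export
write_feature_csv <- function(features, path) {
  stopifnot(is.data.frame(features))
  missing_cols <- setdiff(FEATURE_COLUMNS, names(features))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing feature column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- features[FEATURE_COLUMNS]
  out$subject <- as.character(out$subject)
  out$group <- as.character(out$group)
  readr::write_csv(out, path, progress = FALSE)
  invisible(features)
}

#' Read a European Data Format (EDF) recording
#'
#' Minimal reader for standard EDF files: parses the fixed-layout ASCII
#' header, decodes the 16-bit little-endian sample records, applies the
#' per-signal physical calibration, and returns the signals as an
#' [eeg_record()]. Annotation channels (`EDF Annotations`) are skipped. All
#' retained signals must share one sampling rate.
#'
#' @param path Path to an `.edf` file.
#' @return An [eeg_record()] with channel labels taken from the EDF signal
#'   labels and `rate` from the record duration.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s.", path))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1))
  n_records <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1) abort("Invalid EDF header: no signals.")
  sig_hdr <- rawToChar(readBin(con, "raw", 256 * ns))
  take <- function(width, n = ns, offset = 0) {
    vapply(seq_len(n), function(i) {
      trimws(substr(sig_hdr, offset + (i - 1) * width + 1,
                    offset + i * width))
    }, character(1))
  }
  labels <- take(16)
  off <- ns * 16 + ns * 80 + ns * 8      # skip transducer + phys dim
  phys_min <- as.numeric(take(8, offset = off)); off <- off + ns * 8
  phys_max <- as.numeric(take(8, offset = off)); off <- off + ns * 8
  dig_min <- as.numeric(take(8, offset = off)); off <- off + ns * 8
  dig_max <- as.numeric(take(8, offset = off)); off <- off + ns * 8
  off <- off + ns * 80                   # skip prefiltering
  spr <- as.integer(take(8, offset = off))
  keep <- labels != "EDF Annotations"
  if (!any(keep)) abort("EDF file has no signal channels.")
  if (length(unique(spr[keep])) != 1 || rec_dur <= 0) {
    abort("EDF signals must share one sampling rate.")
  }
  rate <- spr[keep][1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- matrix(0, nrow = n_records * spr[keep][1], ncol = sum(keep))
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw_vals <- readBin(con, "integer", n = spr[s], size = 2,
                          endian = "little", signed = TRUE)
      if (keep[s]) {
        j <- sum(keep[seq_len(s)])
        rows <- ((r - 1) * spr[s] + 1):(r * spr[s])
        out[rows, j] <- phys_min[s] + gain[s] * (raw_vals - dig_min[s])
      }
    }
  }
  eeg_record(out, rate, labels[keep])
}

#' Serialize and restore fitted ECD models
#'
#' Writes a fitted [fit_simple_lr()] or [fit_svr()] model to a documented
#' JSON schema (model type, kernel, hyperparameters, dual coefficients and
#' support inputs, bias, min-max scaling parameters) and reads it back into
#' a functioning model object. Predictions from a restored model are
#' identical to the original's.
#'
#' @param model A `simple_lr` or `ecd_svr` object.
#' @param path File path for the JSON document.
#' @return `read_ecd_model` returns the model object; `write_ecd_model`
#'   returns the input invisibly.
#' @name model_io
NULL

#' @rdname model_io
#' @export
write_ecd_model <- function(model, path) {
  if (inherits(model, "simple_lr")) {
    doc <- list(type = "simple_lr", intercept = model$intercept,
                slope = model$slope, r_squared = model$r_squared,
                feature_scale = model$feature_scale,
                response_scale = model$response_scale)
  } else if (inherits(model, "ecd_svr")) {
    doc <- list(type = "ecd_svr", kernel = model$kernel, cost = model$cost,
                epsilon = model$epsilon, gamma = model$gamma,
                degree = model$degree, coef0 = model$coef0,
                sv = model$sv, coefs = model$coefs, rho = model$rho,
                x_min = model$x_min, x_max = model$x_max,
                y_min = model$y_min, y_max = model$y_max)
  } else {
    abort("Not a serializable model object.")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname model_io
#' @export
read_ecd_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s.", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$type, "simple_lr")) {
    structure(list(intercept = doc$intercept, slope = doc$slope,
                   r_squared = doc$r_squared,
                   feature_scale = doc$feature_scale,
                   response_scale = doc$response_scale,
                   n = NA_integer_),
              class = "simple_lr")
  } else if (identical(doc$type, "ecd_svr")) {
    structure(list(kernel = doc$kernel, cost = doc$cost,
                   epsilon = doc$epsilon, gamma = doc$gamma,
                   degree = doc$degree, coef0 = doc$coef0,
                   sv = matrix(doc$sv, ncol = 1), coefs = doc$coefs,
                   rho = doc$rho, x_min = doc$x_min, x_max = doc$x_max,
                   y_min = doc$y_min, y_max = doc$y_max),
              class = "ecd_svr")
  } else {
    abort(sprintf("Unknown model type in %s.", path))
  }
}
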