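#' Regression metrics: mean squared error and squared correlation
#'
#' MSE is the mean squared difference between estimated and observed ECD
#' (fraction scale); the squared correlation coefficient (SCC, `r^2`) is the
#' squared Pearson correlation between the two vectors.
#'
#' @param estimated,observed Numeric vectors of equal length (>= 2).
#' @return A one-row tibble with `mse` and `r_squared` (`r_squared` is `NA`
#'   with a warning when the observed vector is constant).
#' @examples
#' regression_metrics(c(0.1, 0.4, 0.9), c(0.0, 0.5, 1.0))
#' @export
regression_metrics <- function(estimated, observed) {
  if (length(estimated) != length(observed)) abort("Length mismatch.")
  if (length(estimated) < 2) abort("Need at least 2 pairs.")
  mse <- mean((estimated - observed)^2)
  r2 <- if (var(observed) == 0 || var(estimated) == 0) {
    if (var(observed) == 0) {
      warning("Observed vector is constant; r_squared undefined.")
    }
    NA_real_
  } else {
    cor(estimated, observed)^2
  }
  tibble::tibble(mse = mse, r_squared = r2)
}

#' Per-group estimation accuracy
#'
#' An estimate is correct when the group label of the (clipped) estimated
#' closure equals the observed group. Accuracy per group is the percentage
#' of correct estimates among subjects for whom the group is available;
#' subjects lacking a group (`NA` mark) are excluded from that group's
#' denominator.
#'
#' Input is either a tibble of marks (`subject`, `group`, logical `correct`
#' with `NA` for absent) or a tibble of estimates (`subject`, `group`,
#' `eecd`), from which marks are derived.
#'
#' @param data A marks or estimates tibble as described above.
#' @return A list with `marks` (tibble of per-subject marks) and `accuracy`
#'   (tibble `group`, `n_available`, `n_true`, `accuracy` in percent).
#' @export
group_accuracy <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"correct" %in% names(data)) {
    if (!all(c("group", "eecd") %in% names(data))) {
      abort("Need either a 'correct' column or 'group' + 'eecd' columns.")
    }
    ok <- !is.na(data$eecd)
    correct <- rep(NA, nrow(data))
    correct[ok] <- as.character(label_ecd_group(
      pmin(pmax(data$eecd[ok], 0), 1))) == as.character(data$group[ok])
    data$correct <- correct
  }
  marks <- data
  acc <- marks |>
    dplyr::mutate(group = factor(as.character(.data$group),
                                 levels = ECD_GROUPS)) |>
    dplyr::group_by(.data$group, .drop = FALSE) |>
    dplyr::summarise(n_available = sum(!is.na(.data$correct)),
                     n_true = sum(.data$correct, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(accuracy = 100 * .data$n_true / .data$n_available)
  list(marks = marks, accuracy = acc)
}

#' Bland-Altman agreement between estimated and observed closure
#'
#' Computes the paired differences `estimated - observed`, their mean (the
#' bias) and the limits of agreement `bias +/- 2 * SD(differences)`.
#'
#' @param estimated,observed Numeric vectors of equal length (>= 2).
#' @return A one-row tibble with `bias`, `lower`, `upper` and `sd_diff`.
#' @examples
#' bland_altman(c(0.2, 0.5, 0.9), c(0.1, 0.55, 0.95))
#' @export
bland_altman <- function(estimated, observed) {
  if (length(estimated) != length(observed)) abort("Length mismatch.")
  if (length(estimated) < 2) abort("Need at least 2 pairs.")
  d <- estimated - observed
  bias <- mean(d)
  s <- sd(d)
  tibble::tibble(bias = bias, lower = bias - 2 * s, upper = bias + 2 * s,
                 sd_diff = s)
}

#' Two-sample independent t-test
#'
#' Classical pooled-variance two-sided t-test between two metric vectors
#' (set `welch = TRUE` for the unequal-variance form). The degenerate case
#' of zero pooled variance with equal means returns `t = 0, p = 1`.
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param welch Use Welch's correction? Default `FALSE`.
#' @return A one-row tibble with `t`, `df`, `p_value`, `significant`.
#' @export
independent_t_test <- function(group_a, group_b, alpha = 0.05,
                               welch = FALSE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("Each group needs at least 2 values.")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(tibble::tibble(t = 0, df = length(group_a) + length(group_b) - 2,
                            p_value = 1, significant = FALSE))
    }
    return(tibble::tibble(t = Inf * sign(mean(group_a) - mean(group_b)),
                          df = length(group_a) + length(group_b) - 2,
                          p_value = 0, significant = TRUE))
  }
  ht <- t.test(group_a, group_b, var.equal = !welch)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, significant = ht$p.value < alpha)
}

#' Stratified mean +/- SD summaries of per-subject metrics
#'
#' Aggregates per-subject metric values overall and within strata (e.g. sex
#' or daylight condition), honouring an exclusion list of subjects (for
#' instance subjects whose two-point folds make a fold-wise `r^2`
#' uninformative).
#'
#' @param data Data frame with one row per subject.
#' @param value Metric column (tidy-eval).
#' @param by Optional stratum column (tidy-eval); when omitted only the
#'   overall row is returned.
#' @param exclude Subject identifiers to drop before aggregation (matched
#'   against `subject`).
#' @param subject Subject-identifier column (tidy-eval; default `subject`).
#' @return A tibble with `stratum`, `n`, `mean`, `sd`.
#' @export
aggregate_report <- function(data, value, by = NULL, exclude = NULL,
                             subject = subject) {
  v_quo <- enquo(value); b_quo <- enquo(by); s_quo <- enquo(subject)
  subj <- eval_tidy(s_quo, data)
  keep <- !(subj %in% exclude)
  df <- data[keep, , drop = FALSE]
  v <- eval_tidy(v_quo, df)
  out <- tibble::tibble(stratum = "overall", n = length(v),
                        mean = mean(v), sd = sd(v))
  if (!quo_is_null(b_quo)) {
    b <- as.character(eval_tidy(b_quo, df))
    strata <- purrr::map_dfr(unique(b), function(s) {
      vs <- v[b == s]
      if (length(vs) == 0) abort(sprintf("Empty stratum '%s'.", s))
      tibble::tibble(stratum = s, n = length(vs), mean = mean(vs),
                     sd = sd(vs))
    })
    out <- dplyr::bind_rows(out, strata)
  }
  out
}

#' Leave-one-subject-out evaluation of an ECD regression model
#'
#' For each subject: fits the chosen model on every other subject's
#' (feature, ECD) pairs, predicts the held-out subject, and computes the
#' fold MSE, squared correlation and per-group correctness marks. Folds from
#' subjects with fewer than `min_pairs` pairs are reported but flagged
#' non-comparable (a line always passes through two points, so their fold
#' `r^2` of 1 carries no information) and excluded from the comparative
#' aggregates. Aggregates are produced overall and by any tag columns
#' present (`sex`, `daylight`), plus per-group accuracies.
#'
#' @param data Data frame with one row per (subject, group) observation and
#'   columns named by the arguments below, plus optional `sex`/`daylight`
#'   tags.
#' @param feature,response,subject,group Columns (tidy-eval); defaults
#'   `alpha_per`, `observed_ecd`, `subject`, `group`.
#' @param model `"svr_linear"`, `"svr_rbf"`, `"svr_poly"` or `"simple_lr"`.
#' @param cost,epsilon,gamma,degree SVR hyperparameters (defaults: the
#'   reported linear operating point `C = 16.59`, `epsilon = 0.01`).
#' @param min_pairs Minimum pairs for a fold to be comparable (default 3).
#' @return A `loso_report`: list with `folds` (per-subject tibble), `marks`,
#'   `accuracy`, `aggregates` and `predictions`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
loso_evaluate <- function(data, feature = alpha_per, response = observed_ecd,
                          subject = subject, group = group,
                          model = c("svr_linear", "svr_rbf", "svr_poly",
                                    "simple_lr"),
                          cost = 16.59, epsilon = 0.01, gamma = 1,
                          degree = 3, min_pairs = 3) {
  model <- match.arg(model)
  f <- eval_tidy(enquo(feature), data)
  y <- eval_tidy(enquo(response), data)
  subj <- eval_tidy(enquo(subject), data)
  grp <- as.character(eval_tidy(enquo(group), data))
  subjects <- unique(subj)
  if (length(subjects) < 2) abort("Need at least 2 subjects.")
  sex <- if ("sex" %in% names(data)) data$sex else rep(NA_character_, nrow(data))
  daylight <- if ("daylight" %in% names(data)) data$daylight
              else rep(NA_character_, nrow(data))

  fit_fold <- function(ftr, ytr) {
    if (var(ftr) == 0) abort("A training fold has constant features.")
    switch(model,
      simple_lr = fit_simple_lr(ftr, ytr),
      svr_linear = fit_svr(ftr, ytr, kernel = "linear", cost = cost,
                           epsilon = epsilon),
      svr_rbf = fit_svr(ftr, ytr, kernel = "rbf", cost = cost,
                        epsilon = epsilon, gamma = gamma),
      svr_poly = fit_svr(ftr, ytr, kernel = "poly", cost = cost,
                         epsilon = epsilon, gamma = gamma, degree = degree))
  }
  predict_fold <- function(m, fte) {
    if (inherits(m, "simple_lr")) {
      pmin(pmax(predict(m, fte), 0), 1)
    } else {
      svr_predict(m, fte, clip = TRUE)
    }
  }

  preds <- purrr::map_dfr(subjects, function(s) {
    te <- subj == s
    m <- fit_fold(f[!te], y[!te])
    tibble::tibble(subject = s, sex = sex[te][1], daylight = daylight[te][1],
                   group = grp[te], observed = y[te],
                   estimated = predict_fold(m, f[te]))
  })

  folds <- preds |>
    dplyr::group_by(.data$subject, .data$sex, .data$daylight) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      mse = mean((.data$estimated - .data$observed)^2),
      r_squared = ifelse(var(.data$observed) > 0 & var(.data$estimated) > 0,
                         cor(.data$estimated, .data$observed)^2, NA_real_),
      .groups = "drop") |>
    dplyr::mutate(comparable = .data$n_pairs >= min_pairs) |>
    dplyr::arrange(match(.data$subject, subjects))

  acc <- group_accuracy(
    preds |>
      dplyr::transmute(.data$subject, .data$group,
                       eecd = .data$estimated) |>
      tidyr::complete(subject = subjects,
                      group = ECD_GROUPS))
  excl <- folds$subject[!folds$comparable]
  comp <- folds[!is.na(folds$r_squared), , drop = FALSE]
  agg_one <- function(metric_name) {
    base <- aggregate_report(comp, !!rlang::sym(metric_name), exclude = excl)
    extra <- purrr::map_dfr(c("sex", "daylight"), function(tag) {
      if (all(is.na(comp[[tag]]))) return(NULL)
      aggregate_report(comp, !!rlang::sym(metric_name),
                       by = !!rlang::sym(tag), exclude = excl)[-1, ]
    })
    dplyr::mutate(dplyr::bind_rows(base, extra), metric = metric_name,
                  .before = 1)
  }
  aggregates <- dplyr::bind_rows(agg_one("r_squared"), agg_one("mse"))
  structure(list(folds = folds, marks = acc$marks, accuracy = acc$accuracy,
                 aggregates = aggregates, predictions = preds,
                 model = model),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat(sprintf("<loso_report> %s, %d subjects\n", x$model, nrow(x$folds)))
  ov <- x$aggregates[x$aggregates$stratum == "overall", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %s: %.3f +/- %.3f (n = %d)\n", ov$metric[i], ov$mean[i],
                ov$sd[i], ov$n[i]))
  }
  invisible(x)
}

#' @export
tidy.loso_report <- function(x, ...) x$folds

#' @export
glance.loso_report <- function(x, ...) {
  ov <- x$aggregates[x$aggregates$stratum == "overall", ]
  tibble::tibble(
    model = x$model, n_subjects = nrow(x$folds),
    mean_r_squared = ov$mean[ov$metric == "r_squared"][1],
    sd_r_squared = ov$sd[ov$metric == "r_squared"][1],
    mean_mse = ov$mean[ov$metric == "mse"][1],
    sd_mse = ov$sd[ov$metric == "mse"][1])
}
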