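#' Plot a Bland-Altman agreement diagram
#'
#' Paired differences (estimated - observed closure) against paired means,
#' with the bias line and the bias +/- 2 SD limits of agreement.
#'
#' @param estimated,observed Numeric vectors of equal length.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(estimated, observed) {
  ba <- bland_altman(estimated, observed)
  df <- tibble::tibble(mean = (estimated + observed) / 2,
                       diff = estimated - observed)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$bias, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(ba$lower, ba$upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of estimated and observed ECD",
                  y = "Estimated - observed ECD",
                  title = sprintf("Bland-Altman: bias %.3f, limits [%.3f, %.3f]",
                                  ba$bias, ba$lower, ba$upper)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.simple_lr <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "EEG feature", y = "Estimated ECD",
                  title = sprintf("eECD = %.3g + %.3g f (R^2 = %.3f)",
                                  object$intercept, object$slope,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data, ggplot2::aes(x = .data$f, y = .data$ecd))
  }
  p
}

#' @export
autoplot.loso_report <- function(object, ...) {
  df <- object$folds |>
    dplyr::mutate(subject = factor(.data$subject,
                                   levels = .data$subject))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$subject, y = .data$r_squared,
                                   fill = .data$comparable)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70"),
                               name = "comparable fold") +
    ggplot2::labs(x = "Held-out subject", y = expression(r^2),
                  title = "Leave-one-subject-out fold performance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}

#' Plot a PERCLOS monitoring log
#'
#' Sliding PERCLOS over time with the advisory and warning thresholds and
#' alarm state colouring, from the log produced by [perclos_monitor()].
#'
#' @param log Tibble from [perclos_monitor()] (or [perclos_score()]).
#' @param advisory,warning Thresholds to draw (defaults 0.08 and 0.12).
#' @return A ggplot object.
#' @export
plot_perclos <- function(log, advisory = 0.08, warning = 0.12) {
  ggplot2::ggplot(log, ggplot2::aes(x = .data$second, y = .data$perclos)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$alarm), size = 0.8) +
    ggplot2::geom_hline(yintercept = c(advisory, warning),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(none = "forestgreen",
                                            advisory = "orange",
                                            warning = "red"),
                                 drop = FALSE) +
    ggplot2::labs(x = "Time (s)", y = "PERCLOS (trailing minute)",
                  title = "EEG-based PERCLOS drowsiness monitor") +
    ggplot2::theme_minimal()
}

#' Plot feature trends across ECD groups
#'
#' Band power percentage by closure group and band, the visual check that
#' alpha rises and beta falls as the eyes close.
#'
#' @param features Feature tibble from [build_feature_table()].
#' @return A ggplot object.
#' @export
plot_feature_trends <- function(features) {
  df <- dplyr::mutate(features,
                      group = factor(as.character(.data$group),
                                     levels = ECD_GROUPS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$per_percent,
                                   colour = .data$band,
                                   group = .data$band)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::labs(x = "ECD group", y = "Band power (%)",
                  title = "Band power percentage vs eyelid closure") +
    ggplot2::theme_minimal()
}
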