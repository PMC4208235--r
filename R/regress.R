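#' Fit a simple linear regression of eyelid closure on an EEG feature
#'
#' Closed-form least squares for the one-feature linear model
#' `ECD = alpha + beta * f + noise`: the slope is `Cov(f, ECD) / Var(f)`,
#' the intercept `mean(ECD) - slope * mean(f)`, and the goodness of fit the
#' squared Pearson correlation of the two variables.
#'
#' @param data A data frame, or a numeric feature vector (in which case
#'   `feature` is the numeric response vector).
#' @param feature,response Columns to use when `data` is a data frame
#'   (tidy-eval); ignored for the vector interface.
#' @param feature_scale,response_scale Free-text unit tags stored on the
#'   model (e.g. `"percent"`, `"fraction"`).
#' @return A `simple_lr` object with elements `intercept`, `slope`,
#'   `r_squared`, `n`; supports [predict()], [tidy()] and [glance()].
#' @examples
#' fit_simple_lr(c(40.4, 49.1, 52.1, 84.7, 85.2), c(0, 19, 47, 80, 100))
#' @export
fit_simple_lr <- function(data, feature = NULL, response = NULL,
                          feature_scale = "percent",
                          response_scale = "percent") {
  if (is.data.frame(data)) {
    f <- eval_tidy(enquo(feature), data)
    y <- eval_tidy(enquo(response), data)
  } else {
    f <- as.numeric(data)
    y <- as.numeric(feature)
  }
  if (length(f) != length(y)) abort("Feature and response lengths differ.")
  if (length(f) < 2) abort("Need at least 2 points.")
  if (var(f) == 0) abort("Feature is constant; slope undefined.")
  slope <- cov(f, y) / var(f)
  intercept <- mean(y) - slope * mean(f)
  r2 <- if (var(y) == 0) 1 else cor(f, y)^2
  structure(list(intercept = intercept, slope = slope, r_squared = r2,
                 n = length(f), feature_scale = feature_scale,
                 response_scale = response_scale),
            class = "simple_lr")
}

#' @export
print.simple_lr <- function(x, ...) {
  cat(sprintf(
    "<simple_lr> eECD = %.4g + %.4g * f   (R^2 = %.3f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
predict.simple_lr <- function(object, newdata, ...) {
  object$intercept + object$slope * as.numeric(newdata)
}

#' @export
tidy.simple_lr <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "feature"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.simple_lr <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n)
}

svr_kernel <- function(model, u, v) {
  # u: matrix of rows; v: matrix of rows; returns K(u, v) matrix
  switch(model$kernel,
    linear = u %*% t(v),
    rbf = {
      d2 <- outer(rowSums(u^2), rowSums(v^2), "+") - 2 * u %*% t(v)
      exp(-model$gamma * pmax(d2, 0))
    },
    poly = (model$gamma * (u %*% t(v)) + model$coef0)^model$degree,
    abort(sprintf("Unknown kernel '%s'.", model$kernel)))
}

#' Fit an epsilon-insensitive support vector regression of ECD on a feature
#'
#' Solves the epsilon-SVR problem (LibSVM, via \pkg{e1071}) for a single
#' EEG feature predicting eyelid closure. Features and targets are min-max
#' scaled to `[0, 1]` internally (so `epsilon` and `cost` are on the
#' fraction scale) and predictions are unscaled on output. The fitted object
#' stores the dual coefficients, support inputs, bias and scaling
#' parameters, so prediction is a plain kernel expansion independent of the
#' solver.
#'
#' @inheritParams fit_simple_lr
#' @param kernel `"linear"`, `"rbf"` or `"poly"`.
#' @param cost Regularization parameter C (> 0).
#' @param epsilon Insensitive-tube half-width on the scaled target
#'   (default 0.01).
#' @param gamma RBF width / polynomial scale (`K = exp(-g |u-v|^2)`;
#'   `K = (g u.v + coef0)^d`). Default 1 so a degree-1 polynomial equals the
#'   linear kernel.
#' @param degree Polynomial degree (integer >= 1).
#' @param coef0 Polynomial offset (default 0).
#' @return An `ecd_svr` object; supports [predict()], [tidy()], [glance()].
#' @examples
#' d <- tibble::tibble(f = c(20, 40, 60, 80, 90), ecd = c(0, .2, .5, .8, 1))
#' m <- fit_svr(d, f, ecd, kernel = "linear", cost = 100)
#' predict(m, 70)
#' @export
fit_svr <- function(data, feature = NULL, response = NULL,
                    kernel = c("linear", "rbf", "poly"),
                    cost = 1, epsilon = 0.01, gamma = 1, degree = 3,
                    coef0 = 0) {
  kernel <- match.arg(kernel)
  if (is.data.frame(data)) {
    f <- eval_tidy(enquo(feature), data)
    y <- eval_tidy(enquo(response), data)
  } else {
    f <- as.numeric(data)
    y <- as.numeric(feature)
  }
  if (length(f) != length(y)) abort("Feature and response lengths differ.")
  if (length(f) < 2) abort("Need at least 2 points.")
  stopifnot(cost > 0, epsilon >= 0)
  if (kernel == "rbf") stopifnot(gamma > 0)
  if (kernel == "poly") stopifnot(degree >= 1, degree == round(degree))
  x_min <- min(f); x_max <- max(f)
  y_min <- min(y); y_max <- max(y)
  if (x_max == x_min) abort("Feature is constant; cannot scale.")
  xs <- (f - x_min) / (x_max - x_min)
  ys <- if (y_max > y_min) (y - y_min) / (y_max - y_min) else rep(0, length(y))
  e_kernel <- c(linear = "linear", rbf = "radial", poly = "polynomial")[kernel]
  fit <- e1071::svm(matrix(xs, ncol = 1), ys, type = "eps-regression",
                    kernel = e_kernel, cost = cost, epsilon = epsilon,
                    gamma = gamma, degree = degree, coef0 = coef0,
                    scale = FALSE, tolerance = 1e-6)
  structure(list(kernel = kernel, cost = cost, epsilon = epsilon,
                 gamma = gamma, degree = degree, coef0 = coef0,
                 sv = unname(as.matrix(fit$SV)),
                 coefs = as.numeric(fit$coefs), rho = as.numeric(fit$rho),
                 x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
                 n = length(f)),
            class = "ecd_svr")
}

#' Predict eyelid closure from a fitted SVR model
#'
#' Evaluates the kernel expansion `sum(coef_i K(sv_i, x)) - rho` on the
#' scaled feature, unscales to ECD units, and by default clips to `[0, 1]`.
#'
#' @param model An `ecd_svr` object.
#' @param newdata Numeric vector of feature values (original units).
#' @param clip Clip predictions to `[0, 1]`? Default `TRUE`.
#' @return Numeric vector of estimated ECD values.
#' @export
svr_predict <- function(model, newdata, clip = TRUE) {
  stopifnot(inherits(model, "ecd_svr"))
  x <- as.numeric(newdata)
  if (anyNA(x)) abort("Feature values must be non-missing.")
  xs <- matrix((x - model$x_min) / (model$x_max - model$x_min), ncol = 1)
  if (ncol(xs) != ncol(model$sv)) abort("Feature dimensionality mismatch.")
  k <- svr_kernel(model, xs, model$sv)
  ys <- as.numeric(k %*% model$coefs) - model$rho
  y <- model$y_min + ys * (model$y_max - model$y_min)
  if (clip) y <- pmin(pmax(y, 0), 1)
  y
}

#' @export
predict.ecd_svr <- function(object, newdata, clip = TRUE, ...) {
  svr_predict(object, newdata, clip = clip)
}

#' @export
print.ecd_svr <- function(x, ...) {
  cat(sprintf(
    "<ecd_svr> kernel=%s, C=%g, epsilon=%g, %d support vectors (n = %d)\n",
    x$kernel, x$cost, x$epsilon, nrow(x$sv), x$n %||% NA_integer_))
  invisible(x)
}

#' @export
tidy.ecd_svr <- function(x, ...) {
  tibble::tibble(sv = as.numeric(x$sv), coef = x$coefs)
}

#' @export
glance.ecd_svr <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, cost = x$cost, epsilon = x$epsilon,
                 gamma = x$gamma, degree = x$degree, n_sv = nrow(x$sv))
}

default_cost_grid <- function() c(0.01, 0.1, 1, 10, 16.59, 46.62, 100, 500)

#' Grid search for SVR hyperparameters by subject-wise cross-validation
#'
#' Evaluates every hyperparameter combination by leave-one-subject-out mean
#' squared error on the supplied data and returns the minimizer. Ties are
#' broken deterministically toward smaller `cost`, then smaller
#' `gamma`/`degree`. The default cost grid is log-spaced and includes the
#' operating points reported for this method (16.59 and 46.62);
#' `full_grid = TRUE` switches to the exhaustive fine grid
#' (C in 0.01..500 step 0.01, g in 0.01..1 step 0.01, d in 1..10), which is
#' orders of magnitude slower.
#'
#' @param data Data frame with one row per (subject, observation).
#' @param feature,response,subject Columns (tidy-eval).
#' @param kernel `"linear"`, `"rbf"` or `"poly"`.
#' @param cost_grid,gamma_grid,degree_grid Candidate values; defaults depend
#'   on `kernel` and `full_grid`.
#' @param epsilon Tube half-width (default 0.01).
#' @param full_grid Use the exhaustive fine grid? Default `FALSE`.
#' @return A list with `best` (one-row tibble of hyperparameters and CV
#'   MSE), `model` (SVR refit on all data at the best setting) and
#'   `results` (CV MSE for every grid point).
#' @export
grid_search_svr <- function(data, feature, response, subject,
                            kernel = c("linear", "rbf", "poly"),
                            cost_grid = NULL, gamma_grid = NULL,
                            degree_grid = NULL, epsilon = 0.01,
                            full_grid = FALSE) {
  kernel <- match.arg(kernel)
  f <- eval_tidy(enquo(feature), data)
  y <- eval_tidy(enquo(response), data)
  subj <- eval_tidy(enquo(subject), data)
  if (length(unique(subj)) < 2) abort("Need at least 2 subjects for CV.")
  cost_grid <- cost_grid %||%
    if (full_grid) seq(0.01, 500, by = 0.01) else default_cost_grid()
  gamma_grid <- gamma_grid %||% if (kernel == "rbf") {
    if (full_grid) seq(0.01, 1, by = 0.01) else c(0.01, 0.1, 0.5, 1)
  } else 1
  degree_grid <- degree_grid %||%
    if (kernel == "poly") seq_len(if (full_grid) 10 else 5) else 1
  grid <- tidyr::expand_grid(cost = cost_grid, gamma = gamma_grid,
                             degree = degree_grid)
  if (nrow(grid) == 0) abort("Empty hyperparameter grid.")
  cv_mse <- purrr::pmap_dbl(grid, function(cost, gamma, degree) {
    errs <- purrr::map_dbl(unique(subj), function(s) {
      tr <- subj != s
      m <- fit_svr(f[tr], y[tr], kernel = kernel, cost = cost,
                   epsilon = epsilon, gamma = gamma, degree = degree)
      mean((svr_predict(m, f[!tr], clip = FALSE) - y[!tr])^2)
    })
    mean(errs)
  })
  results <- dplyr::mutate(grid, cv_mse = cv_mse)
  ord <- order(results$cv_mse, results$cost, results$gamma, results$degree)
  best <- results[ord[1], ]
  model <- fit_svr(f, y, kernel = kernel, cost = best$cost,
                   epsilon = epsilon, gamma = best$gamma,
                   degree = best$degree)
  list(best = best, model = model, results = results)
}
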