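# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the package's code paths.

# Direct discrete-transform band power: O(n^2) DFT loop, own Hamming window.
oracle_band_percent <- function(x, rate,
                                bands = list(theta = c(4, 8),
                                             alpha = c(8, 13),
                                             beta = c(13, 30))) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- x * w
  ks <- 0:(n - 1)
  pow_bin <- vapply(ks, function(k) {
    Mod(sum(xw * exp(-2i * pi * k * (0:(n - 1)) / n)))^2
  }, numeric(1))
  freqs <- ks * rate / n
  nyq <- freqs <= rate / 2
  out <- vapply(seq_along(bands), function(i) {
    b <- bands[[i]]
    inb <- if (i == length(bands)) freqs >= b[1] & freqs <= b[2]
           else freqs >= b[1] & freqs < b[2]
    sum(pow_bin[inb & nyq])
  }, numeric(1))
  100 * out / sum(out)
}

# Normal-equations least squares for ecd ~ 1 + f.
oracle_lm <- function(f, y) {
  X <- cbind(1, f)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  r <- y - X %*% beta
  ss_tot <- sum((y - mean(y))^2)
  c(intercept = beta[1], slope = beta[2], r_squared = 1 - sum(r^2) / ss_tot)
}

# Exhaustive active-set solution of the epsilon-SVR dual for tiny problems.
# beta_i = alpha_i - alpha_i^*; patterns: at -C, 0, +C, free positive (+eps
# boundary) or free negative (-eps boundary). Returns the training-point
# predictions of the optimal feasible KKT point.
oracle_svr_predict <- function(x, y, C, eps, kernel = "linear", gamma = 1,
                               degree = 1, coef0 = 0) {
  n <- length(x)
  K <- switch(kernel,
    linear = outer(x, x),
    rbf = exp(-gamma * outer(x, x, function(a, b) (a - b)^2)),
    poly = (gamma * outer(x, x) + coef0)^degree)
  states <- c("L", "Z", "U", "Fp", "Fn")
  grid <- do.call(expand.grid,
                  c(rep(list(states), n), stringsAsFactors = FALSE))
  tol <- 1e-8
  best <- NULL
  best_obj <- -Inf
  for (r in seq_len(nrow(grid))) {
    p <- as.character(grid[r, ])
    beta <- numeric(n)
    beta[p == "L"] <- -C
    beta[p == "U"] <- C
    free <- which(p %in% c("Fp", "Fn"))
    s <- ifelse(p == "Fp", 1, -1)
    if (length(free) > 0) {
      A <- rbind(cbind(K[free, free, drop = FALSE], 1),
                 c(rep(1, length(free)), 0))
      bound <- setdiff(seq_len(n), free)
      rhs <- c(y[free] - eps * s[free] -
                 if (length(bound)) K[free, bound, drop = FALSE] %*%
                   beta[bound] else 0,
               -sum(beta[bound]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      beta[free] <- sol[seq_along(free)]
      b <- sol[length(sol)]
      if (any(p[free] == "Fp" & (beta[free] <= tol | beta[free] >= C - tol)))
        next
      if (any(p[free] == "Fn" & (beta[free] >= -tol | beta[free] <= -C + tol)))
        next
    } else {
      if (abs(sum(beta)) > tol) next
      # b constrained only by the bound-point inequalities
      fx0 <- as.numeric(K %*% beta)
      lo <- -Inf; hi <- Inf
      for (i in seq_len(n)) {
        if (p[i] == "Z") { lo <- max(lo, y[i] - eps - fx0[i])
                           hi <- min(hi, y[i] + eps - fx0[i]) }
        if (p[i] == "U") hi <- min(hi, y[i] - eps - fx0[i])
        if (p[i] == "L") lo <- max(lo, y[i] + eps - fx0[i])
      }
      if (lo > hi + tol) next
      b <- (max(lo, min(hi, 0)))
    }
    fx <- as.numeric(K %*% beta) + b
    ok <- TRUE
    for (i in seq_len(n)) {
      e_i <- y[i] - fx[i]
      ok <- ok && switch(p[i],
        Z = abs(e_i) <= eps + tol,
        U = e_i >= eps - tol,
        L = e_i <= -eps + tol,
        Fp = TRUE, Fn = TRUE)
      if (!ok) break
    }
    if (!ok) next
    obj <- -0.5 * as.numeric(t(beta) %*% K %*% beta) -
      eps * sum(abs(beta)) + sum(y * beta)
    if (obj > best_obj + tol) {
      best_obj <- obj
      best <- fx
    }
  }
  best
}

# Closed-form pooled-variance two-sample t statistic and p value.
oracle_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * pt(-abs(t), df = na + nb - 2)
  c(t = t, p = p)
}

# Count maximal runs of values >= threshold shorter than max_dur seconds.
oracle_count_blinks <- function(values, rate, threshold = 0.9,
                                max_dur = 0.4) {
  r <- rle(values >= threshold)
  sum(r$values & (r$lengths / rate) < max_dur)
}

# Magnitude response of an FIR filter by direct transform of its impulse
# response.
oracle_fir_gain <- function(b, freq, rate) {
  k <- seq_along(b) - 1
  abs(sum(b * exp(-2i * pi * freq * k / rate)))
}
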