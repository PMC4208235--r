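test_that("regression metrics follow their definitional forms", {
  x <- c(0.1, 0.4, 0.8)
  expect_equal(regression_metrics(x, x),
               tibble::tibble(mse = 0, r_squared = 1))
  shifted <- regression_metrics(x + 0.1, x)
  expect_equal(shifted$mse, 0.01, tolerance = 1e-12)
  expect_equal(shifted$r_squared, 1, tolerance = 1e-12)

  set.seed(20)
  for (i in 1:10) {
    e <- runif(15); o <- runif(15)
    m <- regression_metrics(e, o)
    expect_equal(m$mse, sum((e - o)^2) / 15, tolerance = 1e-12)
    n <- 15
    num <- (n * sum(e * o) - sum(e) * sum(o))^2
    den <- (n * sum(e^2) - sum(e)^2) * (n * sum(o^2) - sum(o)^2)
    expect_equal(m$r_squared, num / den, tolerance = 1e-12)
  }
  expect_warning(regression_metrics(runif(5), rep(0.3, 5)), "constant")
  expect_error(regression_metrics(1:3, 1:4), "mismatch")
})

test_that("r_squared is invariant under positive affine transforms", {
  set.seed(21)
  e <- runif(12); o <- runif(12)
  base <- regression_metrics(e, o)$r_squared
  expect_equal(regression_metrics(2 * e + 0.3, o)$r_squared, base,
               tolerance = 1e-12)
  expect_equal(regression_metrics(e, 0.5 * o + 0.1)$r_squared, base,
               tolerance = 1e-12)
})

test_that("group accuracy reproduces the reference cohort's per-group rates", {
  acc <- group_accuracy(reference_group_marks())$accuracy
  expect_equal(acc$accuracy[acc$group == "FO"], 100)
  expect_equal(round(acc$accuracy[acc$group == "SC"], 2), 94.74)
  expect_equal(round(acc$accuracy[acc$group == "HC"], 2), 38.89)
  expect_equal(round(acc$accuracy[acc$group == "AC"], 2), 66.67)
  expect_equal(round(acc$accuracy[acc$group == "FC"], 2), 77.78)
  # absent groups are excluded from the denominators
  expect_equal(acc$n_available, c(20L, 19L, 18L, 15L, 18L))
})

test_that("group accuracy derives marks from estimates and handles
           missing groups", {
  est <- tibble::tibble(
    subject = c(1, 1, 2, 2, 3),
    group = c("FO", "FC", "FO", "HC", "FO"),
    eecd = c(0.1, 0.85, 0.15, 0.3, 0.55))
  res <- group_accuracy(est)
  acc <- res$accuracy
  expect_equal(acc$accuracy[acc$group == "FO"], 100 * 2 / 3)
  expect_equal(acc$accuracy[acc$group == "FC"], 100)
  expect_equal(acc$accuracy[acc$group == "HC"], 0)
  expect_equal(acc$n_available[acc$group == "SC"], 0)

  all_right <- tibble::tibble(subject = 1:5, group = "FO",
                              eecd = runif(5, 0, 0.19))
  expect_true(all(group_accuracy(all_right)$accuracy$accuracy[1] == 100))
})

test_that("Bland-Altman limits are bias +/- 2 SD of the differences", {
  x <- c(0.1, 0.5, 0.9)
  expect_equal(bland_altman(x, x)[1:3],
               tibble::tibble(bias = 0, lower = 0, upper = 0))
  const <- bland_altman(x + 0.05, x)
  expect_equal(c(const$bias, const$lower, const$upper),
               c(0.05, 0.05, 0.05))
  set.seed(22)
  e <- runif(30); o <- runif(30)
  ba <- bland_altman(e, o)
  d <- e - o
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$lower, mean(d) - 2 * sd(d))
  expect_equal(ba$upper, mean(d) + 2 * sd(d))
})

test_that("independent t-test matches the closed form and flags correctly", {
  a <- c(0.9, 0.92, 0.95, 0.88)
  expect_equal(independent_t_test(a, a)$t, 0)
  expect_equal(independent_t_test(a, a)$p_value, 1, tolerance = 1e-12)
  expect_false(independent_t_test(a, a)$significant)

  b <- c(0.85, 0.9, 0.8, 0.95, 0.87)
  got <- independent_t_test(a, b)
  want <- oracle_t_test(a, b)
  expect_equal(got$t, want[["t"]], tolerance = 1e-12)
  expect_equal(got$p_value, want[["p"]], tolerance = 1e-12)

  # degenerate equal-constant groups
  z <- independent_t_test(rep(1, 3), rep(1, 4))
  expect_equal(c(z$t, z$p_value), c(0, 1))
  # the flag respects the chosen level
  expect_false(independent_t_test(a, b, alpha = 1e-6)$significant)
})

test_that("aggregate_report reproduces the reference cohort summaries", {
  ref <- reference_loso_results()
  overall <- aggregate_report(ref, r_squared)
  expect_equal(round(overall$mean, 3), 0.930)
  expect_equal(round(overall$sd, 3), 0.053)

  by_sex <- aggregate_report(ref, r_squared, by = sex,
                             exclude = c(4, 7, 11, 13, 15))
  expect_equal(round(by_sex$mean[by_sex$stratum == "M"], 3), 0.928)
  expect_equal(round(by_sex$mean[by_sex$stratum == "F"], 3), 0.909)

  by_day <- aggregate_report(ref, r_squared, by = daylight)
  expect_equal(round(by_day$mean[by_day$stratum == "daytime"], 3), 0.948)
  expect_equal(round(by_day$mean[by_day$stratum == "nighttime"], 3), 0.911)
})

test_that("LOSO recovers a shared noise-free law perfectly", {
  f <- c(25, 40, 55, 70, 85)
  law <- function(a) (a - 20) / 70
  d <- tibble::tibble(
    subject = rep(1:2, each = 5),
    group = rep(c("FO", "SC", "HC", "AC", "FC"), 2),
    alpha_per = rep(f, 2),
    observed_ecd = law(rep(f, 2)))
  rep_out <- loso_evaluate(d, model = "svr_linear", cost = 100,
                           epsilon = 1e-4)
  expect_equal(nrow(rep_out$folds), 2)
  expect_true(all(abs(rep_out$folds$r_squared - 1) < 1e-9))
  expect_true(all(rep_out$folds$mse < 1e-6))
})

test_that("LOSO on the synthetic cohort recovers the generator law", {
  cfg <- synth_config(seed = 11)
  coh <- gen_cohort_features(20, cfg)
  rep_out <- loso_evaluate(coh, model = "svr_linear")
  expect_equal(nrow(rep_out$folds), 20)
  expect_setequal(rep_out$folds$subject, 1:20)
  g <- glance(rep_out)
  expect_gte(g$mean_r_squared, 0.9)
  # aggregates exist for sex and daylight strata
  expect_true(all(c("M", "F", "daytime", "nighttime", "overall") %in%
                    rep_out$aggregates$stratum))
  # tidy() returns the fold table
  expect_identical(tidy(rep_out), rep_out$folds)
})

test_that("LOSO flags subjects with too few pairs as non-comparable", {
  cfg <- synth_config(seed = 16, subject_sd = c(0, 0))
  coh <- gen_cohort_features(6, cfg)
  # cripple subject 3 down to two pairs, like a driver who never dozed
  coh2 <- coh[!(coh$subject == 3 & coh$group %in% c("HC", "AC", "FC")), ]
  rep_out <- loso_evaluate(coh2, model = "simple_lr")
  f3 <- rep_out$folds[rep_out$folds$subject == 3, ]
  expect_false(f3$comparable)
  expect_equal(f3$n_pairs, 2L)
  expect_equal(f3$r_squared, 1, tolerance = 1e-9)  # 2 points: always exact
  ov <- rep_out$aggregates[rep_out$aggregates$stratum == "overall" &
                             rep_out$aggregates$metric == "r_squared", ]
  expect_equal(ov$n, 5L)  # excluded from the comparative aggregate
})

test_that("fold r^2 approaches 1 monotonically as cohort noise shrinks", {
  r2 <- vapply(c(3.2, 1.0, 0), function(ns) {
    cfg <- synth_config(seed = 11, cohort_noise_sd = ns,
                        subject_sd = c(0, 0), missing_rate = 0)
    glance(loso_evaluate(gen_cohort_features(12, cfg),
                         model = "svr_linear"))$mean_r_squared
  }, numeric(1))
  expect_true(all(diff(r2) > 0))
  expect_equal(r2[3], 1, tolerance = 1e-6)
})
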