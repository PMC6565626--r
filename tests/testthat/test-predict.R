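test_that("fit_logistic recovers known coefficients at n = 2000", {
  set.seed(77)
  n <- 2000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 - 3 * x))
  m <- fit_logistic(data.frame(x = x), y)
  expect_false(m$separation)
  expect_lt(abs(m$coefficients[["(Intercept)"]] - 2),
            3 * m$standard_errors[["(Intercept)"]])
  expect_lt(abs(m$coefficients[["x"]] - (-3)), 3 * m$standard_errors[["x"]])
})

test_that("null predictors are rarely significant (type-I control)", {
  set.seed(5150)
  sig <- 0
  for (i in 1:100) {
    x <- rnorm(200)
    y <- rbinom(200, 1, 0.3)
    m <- fit_logistic(data.frame(x = x), y)
    if (wald_chi2(m, "x")$p_value < 0.05) sig <- sig + 1
  }
  expect_lte(sig, 10)   # ~5% expected; <=10/100 with slack
})

test_that("separation triggers the flagged ridge fallback", {
  x <- c(1:5, 11:15)
  y <- rep(c(0, 1), each = 5)
  m <- fit_logistic(data.frame(x = x), y)
  expect_true(m$separation)
  expect_true(all(is.finite(m$coefficients)))
  expect_true(all(is.finite(m$standard_errors)))
  # the penalized fit still classifies the training data perfectly
  expect_equal(evaluate_transfer(m, data.frame(x = x), y)$accuracy, 1)
  expect_error(fit_logistic(data.frame(x = 1:6), rep(1, 6)), "single class")
})

test_that("slope rescales inversely under predictor rescaling", {
  set.seed(8)
  x <- rnorm(300)
  y <- rbinom(300, 1, plogis(1 - 2 * x))
  m1 <- fit_logistic(data.frame(x = x), y)
  m2 <- fit_logistic(data.frame(x = 2 * x), y)
  expect_equal(m2$coefficients[["x"]], m1$coefficients[["x"]] / 2,
               tolerance = 1e-6)
})

test_that("wald_chi2 is (beta/se)^2 with a chi-square(1) p-value", {
  m <- logistic_model(c(`(Intercept)` = 1, x = 3), c(0.5, 1.5))
  w <- wald_chi2(m, "x")
  expect_equal(w$statistic, 4)
  expect_equal(w$p_value, pchisq(4, 1, lower.tail = FALSE))
  m0 <- logistic_model(c(`(Intercept)` = 1, x = 0), c(0.5, 1.5))
  w0 <- wald_chi2(m0)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p_value, 1)
  # oracle: explicit square and survival function on a fitted model
  set.seed(12)
  x <- rnorm(200); y <- rbinom(200, 1, plogis(x))
  mf <- fit_logistic(data.frame(x = x), y)
  wf <- wald_chi2(mf, "x")
  expect_equal(wf$statistic,
               (mf$coefficients[["x"]] / mf$standard_errors[["x"]])^2)
  expect_error(wald_chi2(logistic_model(c(1, x = 2), c(1, 0)), "x"), "zero")
})

test_that("decision_boundary solves p = 0.5 and matches a bisection oracle", {
  m <- logistic_model(c(`(Intercept)` = 0, x = 1))
  expect_equal(decision_boundary(m), 0)
  set.seed(21)
  for (i in 1:10) {
    b0 <- runif(1, -10, 10); b1 <- runif(1, 0.5, 5) * sample(c(-1, 1), 1)
    m <- logistic_model(c(`(Intercept)` = b0, x = b1))
    b <- decision_boundary(m)
    # boundary maps back to probability 0.5
    expect_equal(plogis(b0 + b1 * b), 0.5, tolerance = 1e-9)
    # bisection oracle on p(x) - 0.5
    root <- uniroot(function(x) plogis(b0 + b1 * x) - 0.5, c(-1e3, 1e3),
                    tol = 1e-12)$root
    expect_equal(b, root, tolerance = 1e-6)
  }
  expect_error(decision_boundary(logistic_model(c(1, x = 0))), "zero slope")
})

test_that("confusion_metrics matches hand counts and identities", {
  lab <- counts_to_labels(tp = 3, fp = 0, tn = 23, fn = 4)
  cm <- confusion_metrics(lab$predicted, lab$actual)
  expect_equal(cm$accuracy, 26 / 30)
  expect_equal(cm$precision, 1)
  expect_equal(cm$recall, 3 / 7)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$f1, 0.6)

  all_right <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$f1, 1)

  # undefined ratios are NA, not 0
  none_pos <- confusion_metrics(c(0, 0), c(0, 1))
  expect_true(is.na(none_pos$precision))
  expect_error(confusion_metrics(c(1, 0), c(1)), "length")
})

test_that("confusion metric identities hold for random label pairs (property)", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    p <- rbinom(n, 1, runif(1, 0.2, 0.8))
    a <- rbinom(n, 1, runif(1, 0.2, 0.8))
    cm <- confusion_metrics(p, a)
    expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, n)
    expect_equal(cm$accuracy * n, cm$tp + cm$tn)
    if (cm$tp + cm$fp + cm$fn > 0)
      expect_equal(cm$f1, 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
    # brute-force recount
    expect_equal(cm$tp, sum(p & a))
    expect_equal(cm$tn, sum(!p & !a))
  }
})

test_that("evaluate_transfer applies training coefficients to holdout data", {
  set.seed(41)
  x <- rnorm(120)
  y <- rbinom(120, 1, plogis(1 - 2 * x))
  m <- fit_logistic(data.frame(x = x), y)
  # holdout identical to training -> metrics equal training metrics
  tr <- evaluate_transfer(m, data.frame(x = x), y)
  ho <- evaluate_transfer(m, data.frame(x = x), y)
  expect_identical(tr, ho)
  # threshold 0 classifies everything positive
  t0 <- evaluate_transfer(m, data.frame(x = x), y, threshold = 0)
  expect_equal(t0$fp + t0$tp, 120)
  expect_equal(t0$specificity, 0)
  expect_error(evaluate_transfer(m, data.frame(z = x), y), "lack predictor")
})

test_that("train/holdout accuracy agree within binomial error (simulation)", {
  set.seed(55)
  diffs <- replicate(50, {
    x <- rnorm(100); y <- rbinom(100, 1, plogis(1 - 2 * x))
    xh <- rnorm(100); yh <- rbinom(100, 1, plogis(1 - 2 * xh))
    m <- fit_logistic(data.frame(x = x), y)
    a_tr <- evaluate_transfer(m, data.frame(x = x), y)$accuracy
    a_ho <- evaluate_transfer(m, data.frame(x = xh), yh)$accuracy
    se <- sqrt(a_tr * (1 - a_tr) / 100)
    abs(a_ho - a_tr) <= 2 * pmax(se, 0.02)
  })
  expect_gte(mean(diffs), 0.8)
})

test_that("pearson_r matches the closed form and flags degenerate input", {
  x <- rnorm(30)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -2 * x)$r, -1)
  set.seed(61)
  y <- rnorm(30)
  pr <- pearson_r(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pr$r, r_hand)
  expect_error(pearson_r(x, rep(1, 30)), "zero variance")
})
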