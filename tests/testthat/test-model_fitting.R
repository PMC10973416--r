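test_that("exact data are interpolated exactly", {
  x <- seq(1, 10)
  fit <- fit_polynomial(x, 2 * x + 1, degree = 1)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_lt(fit$rss, 1e-18)
  expect_equal(fit$adj_r2, 1)

  y <- -0.1 * x^2 + 1.198 * x - 2.537
  fq <- fit_polynomial(x, y, degree = 2)
  expect_equal(unname(fq$coefficients), c(-2.537, 1.198, -0.1),
               tolerance = 1e-9)
})

test_that("least-squares coefficients match a normal-equations oracle", {
  set.seed(5)
  for (i in 1:20) {
    x <- runif(10, 3, 9)
    y <- -0.1 * x^2 + 1.2 * x - 2.6 + rnorm(10, 0, 0.3)
    for (deg in 1:2) {
      oracle <- normal_equations_fit(x, y, deg)
      fit <- fit_polynomial(x, y, degree = deg)
      expect_equal(unname(fit$coefficients), unname(oracle),
                   tolerance = 1e-8)
    }
    # weighted case
    w <- runif(10, 0.5, 3)
    oracle_w <- normal_equations_fit(x, y, 2, weights = w)
    fit_w <- fit_polynomial(x, y, degree = 2, weights = w)
    expect_equal(unname(fit_w$coefficients), unname(oracle_w),
                 tolerance = 1e-8)
  }
})

test_that("residuals are orthogonal to the design columns", {
  set.seed(6)
  x <- runif(50, 2, 10)
  y <- 0.5 * x + rnorm(50)
  w <- runif(50, 0.5, 2)
  fit <- fit_polynomial(x, y, degree = 2, weights = w)
  r <- stats::residuals(fit$lm)
  for (col in list(rep(1, 50), x, x^2)) {
    expect_lt(abs(sum(w * r * col)) / sqrt(sum((w * col)^2) * sum(r^2)),
              1e-8)
  }
})

test_that("degenerate designs and length mismatches error", {
  expect_error(fit_polynomial(rep(2, 10), rnorm(10), degree = 1),
               "rank deficient")
  expect_error(fit_polynomial(1:3, 1:3, degree = 2), "at least")
  expect_error(fit_polynomial(1:10, rnorm(10), degree = 2,
                              weights = c(-1, rep(1, 9))), "positive")
})

test_that("AICc matches hand arithmetic and its closed-form identities", {
  # linear fit: k = 3
  expect_equal(aicc(10, 20, 2),
               20 * log(10 / 20) + 2 * 3 + 2 * 3 * 4 / (20 - 3 - 1))
  # penalty is monotone in k
  expect_gt(aicc(10, 20, 3), aicc(10, 20, 2))
  # halving rss at fixed n, k lowers AICc by n log 2
  expect_equal(aicc(10, 50, 3) - aicc(5, 50, 3), 50 * log(2))
  expect_error(aicc(10, 4, 2), "AICc undefined")
  expect_error(aicc(0, 20, 2))
})

test_that("AICc approaches AIC for large n", {
  # correction term 2k(k+1)/(n-k-1) for k = 4
  n <- 5000
  expect_lt(abs(aicc(100, n, 3) - (n * log(100 / n) + 2 * 4)), 0.01)
})

test_that("model selection follows the AICc-difference rule with parsimony ties", {
  set.seed(9)
  x <- runif(200, 3, 9)
  # strongly curved truth: quadratic wins by a wide margin
  y_curved <- -0.5 * x^2 + 6 * x + rnorm(200, 0, 0.3)
  lin <- fit_polynomial(x, y_curved, 1)
  quad <- fit_polynomial(x, y_curved, 2)
  sel <- select_model(lin, quad)
  expect_equal(sel$chosen, "quadratic")
  expect_gt(sel$delta_aicc, 2)
  expect_false(sel$tie)

  # linear truth: the quadratic gains < 2 AICc and parsimony keeps the line
  y_line <- 2 * x + rnorm(200, 0, 0.5)
  sel2 <- select_model(fit_polynomial(x, y_line, 1),
                       fit_polynomial(x, y_line, 2))
  expect_equal(sel2$chosen, "linear")

  expect_error(select_model(fit_polynomial(x, y_line, 1),
                            fit_polynomial(x[1:50], y_line[1:50], 2)),
               "same data")
  expect_error(select_model(quad, quad), "in that order")
})

test_that("vertex reproduces every printed quadratic peak to one decimal", {
  printed <- list(
    list(c(-1.826, 1.030, -0.0913), 5.6),   # coarse EF vs pH
    list(c(-2.537, 1.198, -0.1000), 6.0),   # bin-averaged EF vs pH
    list(c(-2.204, 0.871, -0.072), 6.0),    # field gene ratio vs pH
    list(c(-9.560, 4.273, -0.357), 6.0),    # field N2O flux vs pH
    list(c(-1.304, 0.446, -0.0334), 6.7),   # potential denitrification
    list(c(2.782, 1.546, -0.129), 6.0),     # log nirK, coarse
    list(c(-1.956, 3.481, -0.276), 6.3),    # log nirK, averaged
    list(c(2.833, 1.429, -0.114), 6.3),     # log nirS, coarse
    list(c(-4.026, 3.816, -0.281), 6.8),    # log nirS, averaged
    list(c(-3.442, 1.398, -0.115), 6.1),    # log gene ratio, coarse
    list(c(-5.838, 2.627, -0.220), 6.0)     # log gene ratio, averaged
  )
  for (case in printed) {
    cf <- case[[1]]
    v <- vertex(fit_from_coefficients(cf[1], cf[2], cf[3]))
    expect_equal(round(v$peak_x, 1), case[[2]])
    # the vertex is -c1 / (2 c2) exactly
    expect_equal(v$peak_x, -cf[2] / (2 * cf[3]))
  }
})

test_that("vertex handles convex and linear fits", {
  expect_null(vertex(fit_from_coefficients(0, 1, 0.1)))
  expect_error(vertex(fit_from_coefficients(0, 1)), "quadratic")
  # out-of-range peaks are flagged when the fit has an x range
  x <- seq(1, 3, length.out = 20)
  fit <- fit_polynomial(x, -0.1 * (x - 10)^2 + rnorm(20, 0, 1e-6), 2)
  v <- vertex(fit)
  expect_false(v$in_range)
})

test_that("confidence bands behave as t-theory predicts", {
  x <- seq(1, 10)
  # zero-residual fit: band collapses onto the line
  fit0 <- fit_polynomial(x, 2 * x + 1, degree = 1)
  band0 <- confidence_band(fit0, x)
  expect_equal(band0$lower, band0$fit, tolerance = 1e-8)
  expect_equal(band0$upper, band0$fit, tolerance = 1e-8)

  # band is narrowest at the mean of symmetric x (leverage)
  set.seed(10)
  xs <- seq(-5, 5, length.out = 51)
  fit <- fit_polynomial(xs, xs + rnorm(51), degree = 1)
  band <- confidence_band(fit, xs)
  widths <- band$upper - band$lower
  expect_equal(unname(which.min(widths)), 26L)

  expect_error(confidence_band(fit, xs, level = 1.5), "level")
  expect_error(confidence_band(fit_from_coefficients(0, 1), xs),
               "fit_polynomial")
})

test_that("band coverage of the true mean response is near nominal", {
  set.seed(12)
  x <- seq(2, 9, length.out = 30)
  truth <- -0.1 * x^2 + 1.2 * x - 2.6
  x0 <- 5.5
  truth0 <- -0.1 * x0^2 + 1.2 * x0 - 2.6
  hits <- replicate(500, {
    y <- truth + rnorm(30, 0, 0.5)
    band <- confidence_band(fit_polynomial(x, y, 2), x0)
    band$lower <= truth0 && truth0 <= band$upper
  })
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})

test_that("linear and quadratic adjusted R2 coincide on noise-free linear truth", {
  x <- seq(1, 20)
  y <- 3 * x - 4
  expect_equal(fit_polynomial(x, y, 1)$adj_r2,
               fit_polynomial(x, y, 2)$adj_r2)
})
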