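test_that("headspace flux matches the dimensional-analysis oracle", {
  got <- headspace_flux(1, volume = 0.125, temperature_c = 20,
                        soil_mass = 0.020, interval_h = 6)
  want <- flux_oracle(1, 0.125, 20, 0.020, 6)
  expect_lt(abs(got - want) / want, 1e-9)
  # a spread of conditions
  set.seed(14)
  for (i in 1:20) {
    dc <- runif(1, -3, 3); v <- runif(1, 0.05, 1); t <- runif(1, 5, 35)
    w <- runif(1, 0.002, 0.1); h <- runif(1, 1, 24)
    got <- headspace_flux(dc, v, t, w, h)
    want <- flux_oracle(dc, v, t, w, h)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("headspace flux is linear in delta C and inverse in soil mass", {
  base <- headspace_flux(1, 0.1, 25, 0.005)
  expect_equal(headspace_flux(0, 0.1, 25, 0.005), 0)
  expect_equal(headspace_flux(2, 0.1, 25, 0.005), 2 * base)
  expect_equal(headspace_flux(1, 0.1, 25, 0.010), base / 2)
  expect_equal(headspace_flux(-1, 0.1, 25, 0.005), -base)
  # temperature factor strictly decreasing
  temps <- seq(0, 40, by = 5)
  fluxes <- vapply(temps, function(t) headspace_flux(1, 0.1, t, 0.005),
                   numeric(1))
  expect_true(all(diff(fluxes) < 0))
  expect_error(headspace_flux(1, 0.1, 25, 0.005, interval_h = 0), "positive")
  expect_error(headspace_flux(1, -0.1, 25, 0.005), "positive")
})

test_that("slope_rate recovers slopes and inverts a known rate", {
  s <- list(sample_id = "x", timepoints = c(2, 4, 6),
            headspace_ppm = c(1, 2, 3), bottle_volume = 0.1,
            temperature_c = 25, soil_dry_mass = 0.005)
  est <- slope_rate(s)
  expect_equal(est$slope_ppm_h, 0.5)
  expect_equal(est$method, "regression")
  expect_equal(est$r2_of_slope, 1)

  # noiseless inversion: rate -> ppm series -> rate
  true_rate <- 120
  per_ppm <- headspace_flux(1, 0.1, 25, 0.005, interval_h = 1)
  slope <- true_rate / per_ppm
  s$headspace_ppm <- 0.33 + slope * s$timepoints
  expect_equal(slope_rate(s)$rate, true_rate, tolerance = 1e-9)

  # two points: finite difference
  s2 <- s
  s2$timepoints <- c(0, 6)
  s2$headspace_ppm <- c(0.33, 0.33 + slope * 6)
  est2 <- slope_rate(s2)
  expect_equal(est2$method, "two_point")
  expect_equal(est2$rate, true_rate, tolerance = 1e-9)

  s3 <- s
  s3$timepoints <- c(2, 2, 6)
  expect_error(slope_rate(s3), "duplicate")
})

test_that("ppm rescaling rescales the rate proportionally", {
  s <- list(sample_id = "x", timepoints = c(2, 4, 6),
            headspace_ppm = c(0.4, 0.9, 1.3), bottle_volume = 0.1,
            temperature_c = 25, soil_dry_mass = 0.005)
  r1 <- slope_rate(s)$rate
  s$headspace_ppm <- s$headspace_ppm * 3
  expect_equal(slope_rate(s)$rate, 3 * r1, tolerance = 1e-12)
})

test_that("noisy series keep the median relative rate error below 5%", {
  set.seed(15)
  per_ppm <- headspace_flux(1, 0.1, 25, 0.005, interval_h = 1)
  errs <- replicate(200, {
    true_rate <- runif(1, 50, 300)
    slope <- true_rate / per_ppm
    tp <- c(2, 4, 6)
    ppm <- (0.33 + slope * tp) * (1 + rnorm(3, 0, 0.02))
    s <- list(sample_id = "x", timepoints = tp, headspace_ppm = ppm,
              bottle_volume = 0.1, temperature_c = 25,
              soil_dry_mass = 0.005)
    abs(slope_rate(s)$rate - true_rate) / true_rate
  })
  expect_lt(median(errs), 0.05)
})

test_that("product ratio divides net N2O by total denitrification and clamps", {
  pr <- product_ratio(5, 10)
  expect_equal(pr$ratio, 0.5)
  expect_false(pr$clamped)
  pr2 <- product_ratio(12, 10)
  expect_equal(pr2$ratio, 1)
  expect_equal(pr2$raw_ratio, 1.2)
  expect_true(pr2$clamped)
  pr3 <- product_ratio(-0.5, 10)
  expect_equal(pr3$ratio, 0)
  expect_true(pr3$clamped)
  expect_error(product_ratio(5, 0), "positive")
})

test_that("PDA requires acetylene and reports mg N kg-1 h-1", {
  per_ppm <- headspace_flux(1, 0.1, 25, 0.005, interval_h = 1)
  slope <- 200 / per_ppm
  s <- list(sample_id = "p", acetylene = TRUE, timepoints = c(2, 4, 6),
            headspace_ppm = 0.33 + slope * c(2, 4, 6), bottle_volume = 0.1,
            temperature_c = 25, soil_dry_mass = 0.005)
  est <- pda(s)
  expect_equal(est$rate, 0.2, tolerance = 1e-9)   # 200 ug = 0.2 mg
  expect_equal(est$unit, "mg N kg-1 h-1")
  # microgram / milligram conversion is exact
  expect_equal(est$rate * 1000, slope_rate(s)$rate, tolerance = 1e-12)
  s$acetylene <- FALSE
  expect_error(pda(s), "acetylene")
})

test_that("paired synthetic bottles recover the product-ratio law at zero noise", {
  cfg <- synthetic_config(seed = 3, ppm_noise_sd = 0)
  gen <- generate_incubation_pairs(cfg)
  rep <- run_field(run_config(), series = gen$series)
  # refit the linear ratio-pH law: slope within 0.005 of the truth -0.082
  slope <- rep$fits$c1[rep$fits$response == "product_ratio"]
  expect_lt(abs(slope - (-0.082)), 0.005)
  intercept <- rep$fits$c0[rep$fits$response == "product_ratio"]
  expect_lt(abs(intercept - 1.265), 0.02)
})

test_that("noisy paired bottles recover per-sample ratios within 0.03 median error", {
  cfg <- synthetic_config(seed = 16, n_incubation_samples = 200,
                          ppm_noise_sd = 0.02)
  gen <- generate_incubation_pairs(cfg)
  rep <- run_field(run_config(), series = gen$series)
  merged <- merge(rep$samples[, c("sample_id", "ratio")],
                  gen$truth[, c("sample_id", "ratio")],
                  by = "sample_id", suffixes = c("_est", "_true"))
  expect_lt(median(abs(merged$ratio_est - merged$ratio_true)), 0.03)
})
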