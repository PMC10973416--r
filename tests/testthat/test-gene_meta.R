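test_that("gene ratio is (nirK + nirS) / nosZI and scale invariant", {
  expect_equal(compute_gene_ratio(1e6, 1e6, 1e6)$ratio, 2)
  expect_equal(compute_gene_ratio(3e5, 1e5, 2e5)$ratio, 2)
  expect_equal(compute_gene_ratio(3e5, 1e5, 2e5)$log10_ratio, log10(2))
  expect_error(compute_gene_ratio(0, 1e5, 2e5), "positive")
  expect_error(compute_gene_ratio(1e5, 1e5, 0), "positive")
  set.seed(2)
  for (i in 1:20) {
    abn <- 10^runif(3, 4, 9)
    c <- runif(1, 0.01, 100)
    expect_equal(compute_gene_ratio(abn[1] * c, abn[2] * c, abn[3] * c)$ratio,
                 compute_gene_ratio(abn[1], abn[2], abn[3])$ratio)
  }
})

test_that("ratio records require all three genes and set nosZII aside", {
  genes <- tibble::tibble(
    study_id = c("a", "a", "a", "b", "b", "c"),
    sample_id = c("a", "a", "a", "b", "b", "c"),
    gene = c("nirK", "nirS", "nosZI", "nirK", "nirS", "nosZII"),
    copies_per_g = c(3e5, 1e5, 2e5, 1e6, 1e6, 5e4),
    ph_h2o = c(6, 6, 6, 7, 7, 5),
    n2o_flux = NA_real_
  )
  rr <- gene_ratio_records(genes)
  expect_equal(sum(!is.na(rr$records$ratio)), 1)
  expect_equal(rr$records$ratio[rr$records$sample_id == "a"], 2)
  expect_equal(rr$n_incomplete, 1)
  expect_equal(rr$n_noszii_set_aside, 1)
})

test_that("bin averages are linear-then-log, not means of logs", {
  genes <- tibble::tibble(
    study_id = "s", sample_id = c("x", "y"),
    gene = "nirK", copies_per_g = c(1e4, 1e6), ph_h2o = c(6.11, 6.14)
  )
  avg <- bin_average_log_abundance(genes, "nirK")
  expect_equal(nrow(avg), 1)
  expect_equal(avg$mean_log10_abundance, log10(505000), tolerance = 1e-12)
  # single member and all-equal bins reduce to the member's log10
  one <- bin_average_log_abundance(genes[1, ], "nirK")
  expect_equal(one$mean_log10_abundance, 4)
})

test_that("linear-then-log dominates the mean of logs (Jensen)", {
  set.seed(4)
  for (i in 1:30) {
    n <- sample(2:8, 1)
    vals <- 10^runif(n, 3, 8)
    genes <- tibble::tibble(study_id = "s", sample_id = as.character(seq_len(n)),
                            gene = "nirS", copies_per_g = vals,
                            ph_h2o = rep(5.55, n))
    avg <- bin_average_log_abundance(genes, "nirS")
    expect_gte(avg$mean_log10_abundance, mean(log10(vals)) - 1e-12)
  }
  # equality iff all members are equal
  genes_eq <- tibble::tibble(study_id = "s", sample_id = c("1", "2"),
                             gene = "nirS", copies_per_g = c(2e5, 2e5),
                             ph_h2o = c(6.3, 6.32))
  avg_eq <- bin_average_log_abundance(genes_eq, "nirS")
  expect_equal(avg_eq$mean_log10_abundance, log10(2e5), tolerance = 1e-12)
})

test_that("pH response fitting recovers a synthetic abundance peak", {
  set.seed(8)
  n <- 500
  ph <- runif(n, 3.5, 9)
  y <- -0.13 * (ph - 6)^2 + 7 + rnorm(n, 0, 0.3)   # true peak at pH 6
  genes <- tibble::tibble(study_id = "s", sample_id = as.character(1:n),
                          gene = "nirK", copies_per_g = 10^y, ph_h2o = ph)
  res <- fit_gene_ph(genes, "nirK")
  expect_equal(res$selection$chosen, "quadratic")
  expect_lt(abs(res$peak$peak_x - 6), 0.15)
})

test_that("a flat nosZI response selects the linear model with no peak", {
  ph <- seq(3.5, 9, length.out = 60)
  genes <- tibble::tibble(study_id = "s", sample_id = as.character(1:60),
                          gene = "nosZI", copies_per_g = 10^7.3, ph_h2o = ph)
  res <- fit_gene_ph(genes, "nosZI")
  expect_equal(res$selection$chosen, "linear")
  expect_null(res$peak)
})

test_that("noise-free data reproduce printed-style coefficients exactly", {
  ph <- seq(3, 9.5, length.out = 40)
  y <- -0.129 * ph^2 + 1.546 * ph + 2.782
  genes <- tibble::tibble(study_id = "s", sample_id = as.character(1:40),
                          gene = "nirK", copies_per_g = 10^y, ph_h2o = ph)
  res <- fit_gene_ph(genes, "nirK")
  expect_equal(unname(res$quadratic$coefficients), c(2.782, 1.546, -0.129),
               tolerance = 1e-9)
  expect_equal(round(res$peak$peak_x, 1), 6.0)
})

test_that("median synthetic peak-recovery error stays below 0.1 pH units", {
  set.seed(21)
  errs <- replicate(200, {
    ph <- runif(300, 3.5, 9)
    y <- -0.13 * (ph - 6)^2 + 7 + rnorm(300, 0, 0.3)
    fit <- fit_polynomial(ph, y, degree = 2)
    abs(vertex(fit)$peak_x - 6)
  })
  expect_lt(median(errs), 0.1)
})

test_that("flux-ratio fit recovers a known positive slope", {
  set.seed(13)
  n <- 200
  lr <- runif(n, -1, 1.5)
  flux <- 10 + 2 * lr + rnorm(n, 0, 1)
  rec <- tibble::tibble(log10_ratio = lr, n2o_flux = flux)
  res <- fit_flux_vs_ratio(rec)
  se <- summary(res$fit$lm)$coefficients["x", "Std. Error"]
  expect_equal(res$slope_sign, "positive")
  expect_lt(abs(res$slope - 2), 2 * se)

  # constant flux: slope indistinguishable from zero
  rec0 <- tibble::tibble(log10_ratio = lr, n2o_flux = rep(5, n))
  expect_lt(abs(fit_flux_vs_ratio(rec0)$slope), 1e-10)

  expect_error(fit_flux_vs_ratio(rec[1:2, ]), "at least 3")
})
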