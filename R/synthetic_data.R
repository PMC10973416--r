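#' Configuration for the synthetic-data generators
#'
#' Defines the ground truth from which [generate_field_dataset()],
#' [generate_gene_dataset()] and [generate_incubation_pairs()] simulate
#' datasets with the structure of compiled field-study tables. The
#' defaults emulate the global-synthesis conditions: soil pH drawn from a
#' three-component normal mixture concentrated between 5.5 and 7.5, a
#' concave (hump-shaped) true EF-pH response peaking at pH 6.0 with a peak
#' EF of 1 percent, study replicate counts of 3-6, N rates up to
#' 600 kg N ha-1, log10 gene abundances quadratic in pH with a flat nosZI
#' response, and a product-ratio law decreasing linearly in pH.
#'
#' All curve vectors are ordered `(c0, c1, c2)` = intercept, slope,
#' curvature.
#'
#' @param seed Integer seed; identical configurations generate identical
#'   datasets.
#' @param n_studies,obs_per_study Number of simulated studies and
#'   observations per study (field dataset size = product).
#' @param ph_mixture List with numeric `means`, `sds`, `weights` of the pH
#'   mixture components; draws are truncated to `ph_range`.
#' @param ph_range Admissible pH interval, default `c(2.8, 9.7)`.
#' @param ef_curve True EF(pH) quadratic, percent units; curvature must be
#'   negative so a peak exists.
#' @param ef_noise_sd Additive Gaussian noise on EF, percent units.
#' @param replicate_range Integer range replicate counts are drawn from.
#' @param n_rate_range N fertilization rate range, kg N ha-1.
#' @param control_emission_meanlog,control_emission_sdlog Lognormal
#'   parameters of the control-plot cumulative emission (kg N ha-1).
#' @param gene_curves Named list of `(c0, c1, c2)` quadratics for log10
#'   copies per g as a function of pH.
#' @param gene_noise_sd Gaussian noise on log10 abundance.
#' @param nosZI_flat If `TRUE` (default) the nosZI response to pH is flat,
#'   the behaviour seen in global compilations.
#' @param n_gene_samples Samples in the gene dataset (each carries all
#'   genes).
#' @param flux_law `(intercept, slope)` of the linear dependence of N2O
#'   flux (ug N m-2 h-1) on the true log10 gene ratio.
#' @param flux_noise_sd Gaussian noise on the flux.
#' @param n_incubation_samples Soil samples, each incubated as a
#'   with/without-acetylene bottle pair.
#' @param incubation_ph_range pH interval covered by the incubation
#'   samples, default `c(4.7, 8.0)` (the span of the acid-gradient field
#'   soils).
#' @param pda_curve True total-denitrification quadratic, mg N kg-1 h-1
#'   as a function of pH.
#' @param ratio_law `(intercept, slope)` of the true product-ratio line
#'   `N2O/(N2O+N2) = intercept + slope * pH`; must stay inside \[0, 1\]
#'   over `incubation_ph_range`.
#' @param ppm_noise_sd Multiplicative Gaussian noise on each headspace ppm
#'   reading (relative sd).
#' @param timepoints_h Headspace sampling times in hours.
#' @return A validated list of class `n2o_synth_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_studies = 400L,
    obs_per_study = 5L,
    ph_mixture = list(means = c(5.0, 6.5, 8.0), sds = c(0.9, 0.7, 0.6),
                      weights = c(0.3, 0.5, 0.2)),
    ph_range = c(2.8, 9.7),
    ef_curve = c(c0 = -2.6, c1 = 1.2, c2 = -0.1),
    ef_noise_sd = 0.2,
    replicate_range = c(3L, 6L),
    n_rate_range = c(50, 600),
    control_emission_meanlog = log(0.5),
    control_emission_sdlog = 0.5,
    gene_curves = list(
      nirK = c(c0 = 2.782, c1 = 1.546, c2 = -0.129),
      nirS = c(c0 = 2.833, c1 = 1.429, c2 = -0.114),
      nosZI = c(c0 = 7.3, c1 = 0, c2 = 0)
    ),
    gene_noise_sd = 0.3,
    nosZI_flat = TRUE,
    n_gene_samples = 500L,
    flux_law = c(intercept = 40, slope = 25),
    flux_noise_sd = 8,
    n_incubation_samples = 70L,
    incubation_ph_range = c(4.7, 8.0),
    pda_curve = c(c0 = -1.304, c1 = 0.446, c2 = -0.0334),
    ratio_law = c(intercept = 1.265, slope = -0.082),
    ppm_noise_sd = 0.02,
    timepoints_h = c(2, 4, 6)) {
  cfg <- list(
    seed = as.integer(seed), n_studies = as.integer(n_studies),
    obs_per_study = as.integer(obs_per_study), ph_mixture = ph_mixture,
    ph_range = ph_range, ef_curve = ef_curve, ef_noise_sd = ef_noise_sd,
    replicate_range = as.integer(replicate_range),
    n_rate_range = n_rate_range,
    control_emission_meanlog = control_emission_meanlog,
    control_emission_sdlog = control_emission_sdlog,
    gene_curves = gene_curves, gene_noise_sd = gene_noise_sd,
    nosZI_flat = isTRUE(nosZI_flat),
    n_gene_samples = as.integer(n_gene_samples), flux_law = flux_law,
    flux_noise_sd = flux_noise_sd,
    n_incubation_samples = as.integer(n_incubation_samples),
    incubation_ph_range = incubation_ph_range, pda_curve = pda_curve,
    ratio_law = ratio_law, ppm_noise_sd = ppm_noise_sd,
    timepoints_h = timepoints_h
  )
  with(cfg, {
    stopifnot(
      length(seed) == 1, !is.na(seed),
      n_studies >= 1, obs_per_study >= 1,
      length(ph_mixture$means) == length(ph_mixture$sds),
      length(ph_mixture$means) == length(ph_mixture$weights),
      all(ph_mixture$sds >= 0), all(ph_mixture$weights > 0),
      ph_range[1] < ph_range[2],
      ef_noise_sd >= 0, gene_noise_sd >= 0, ppm_noise_sd >= 0,
      replicate_range[1] >= 1, replicate_range[1] <= replicate_range[2],
      n_rate_range[1] > 0, n_rate_range[1] <= n_rate_range[2],
      length(timepoints_h) >= 2, all(diff(timepoints_h) > 0)
    )
  })
  if (cfg$ef_curve[["c2"]] >= 0) {
    stop("ef_curve curvature must be negative (a peaked response)",
         call. = FALSE)
  }
  ratio_ends <- cfg$ratio_law[["intercept"]] +
    cfg$ratio_law[["slope"]] * cfg$incubation_ph_range
  if (any(ratio_ends < 0 | ratio_ends > 1)) {
    stop("ratio_law leaves [0, 1] over incubation_ph_range", call. = FALSE)
  }
  structure(cfg, class = "n2o_synth_config")
}

.eval_quadratic <- function(coefs, x) {
  coefs[[1]] + coefs[[2]] * x + coefs[[3]] * x^2
}

.draw_ph <- function(n, mixture, range) {
  comp <- sample.int(length(mixture$weights), n, replace = TRUE,
                     prob = mixture$weights)
  ph <- stats::rnorm(n, mixture$means[comp], mixture$sds[comp])
  # redraw out-of-range values rather than clamping, so no mass piles up
  # at the interval edges
  bad <- which(ph < range[1] | ph > range[2])
  while (length(bad) > 0) {
    comp2 <- sample.int(length(mixture$weights), length(bad), replace = TRUE,
                        prob = mixture$weights)
    ph[bad] <- stats::rnorm(length(bad), mixture$means[comp2],
                            mixture$sds[comp2])
    bad <- bad[ph[bad] < range[1] | ph[bad] > range[2]]
  }
  ph
}

#' Simulate a field fertilization-experiment dataset with known truth
#'
#' Draws per-observation soil pH from the configured mixture, N rates
#' uniformly, control-plot emissions lognormally, and sets the fertilized
#' emission to `E_N = E_O + (trueEF + noise)/100 * N` so that
#' [compute_ef()] applied to the noiseless columns inverts the generator
#' exactly. The true EF is the configured quadratic evaluated at the
#' observation's pH.
#'
#' @param config An [synthetic_config()] object.
#' @return A list with `observations` (a tibble in the field-observation
#'   schema, pH medium `"H2O"`) and `truth` (the generating curve, its
#'   peak, and per-observation true EFs).
#' @export
generate_field_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "n2o_synth_config"))
  set.seed(config$seed)
  n <- config$n_studies * config$obs_per_study
  study <- rep(sprintf("S%04d", seq_len(config$n_studies)),
               each = config$obs_per_study)
  ph <- .draw_ph(n, config$ph_mixture, config$ph_range)
  true_ef <- .eval_quadratic(config$ef_curve, ph)
  noisy_ef <- true_ef + stats::rnorm(n, 0, config$ef_noise_sd)
  n_rate <- stats::runif(n, config$n_rate_range[1], config$n_rate_range[2])
  e_o <- stats::rlnorm(n, config$control_emission_meanlog,
                       config$control_emission_sdlog)
  replicates <- rep(
    sample(seq(config$replicate_range[1], config$replicate_range[2]),
           config$n_studies, replace = TRUE),
    each = config$obs_per_study
  )
  latitude <- rep(stats::runif(config$n_studies, -60, 60),
                  each = config$obs_per_study)
  ecosystem <- rep(sample(c("cropland", "grassland", "forest"),
                          config$n_studies, replace = TRUE,
                          prob = c(0.6, 0.25, 0.15)),
                   each = config$obs_per_study)
  obs <- tibble::tibble(
    study_id = study,
    site_id = study,
    latitude = latitude,
    ecosystem = ecosystem,
    ph_reported = ph,
    ph_medium = "H2O",
    n_rate = n_rate,
    emission_control = e_o,
    emission_fertilized = e_o + noisy_ef / 100 * n_rate,
    replicates = replicates
  )
  peak <- -config$ef_curve[["c1"]] / (2 * config$ef_curve[["c2"]])
  list(
    observations = obs,
    truth = list(
      ef_curve = config$ef_curve,
      peak_ph = peak,
      peak_ef = .eval_quadratic(config$ef_curve, peak),
      true_ef = true_ef
    )
  )
}

#' Simulate a functional-gene abundance dataset with known truth
#'
#' Each sample carries nirK, nirS and nosZI abundances whose log10 values
#' follow the configured quadratics in pH plus Gaussian noise (the nosZI
#' curve is flat by default). The paired N2O flux follows a linear law in
#' the sample's true log10 (nirK+nirS)/nosZI ratio.
#'
#' @param config An [synthetic_config()] object.
#' @return A list with `observations` (long-format gene tibble) and
#'   `truth` (curves, per-sample true log ratio and flux law).
#' @export
generate_gene_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "n2o_synth_config"))
  set.seed(config$seed + 1L)
  n <- config$n_gene_samples
  ph <- .draw_ph(n, config$ph_mixture, config$ph_range)
  curves <- config$gene_curves
  if (config$nosZI_flat) curves$nosZI[c("c1", "c2")] <- c(0, 0)
  true_log <- lapply(curves, .eval_quadratic, x = ph)
  true_ratio <- (10^true_log$nirK + 10^true_log$nirS) / 10^true_log$nosZI
  flux <- config$flux_law[["intercept"]] +
    config$flux_law[["slope"]] * log10(true_ratio) +
    stats::rnorm(n, 0, config$flux_noise_sd)
  sample_id <- sprintf("G%04d", seq_len(n))
  obs <- dplyr::bind_rows(lapply(names(curves), function(g) {
    tibble::tibble(
      study_id = sample_id,
      sample_id = sample_id,
      gene = factor(g, levels = .gene_levels),
      copies_per_g = 10^(true_log[[g]] + stats::rnorm(n, 0, config$gene_noise_sd)),
      ph_h2o = ph,
      n2o_flux = flux
    )
  }))
  list(
    observations = obs,
    truth = list(
      gene_curves = curves,
      true_log10 = true_log,
      true_log10_ratio = log10(true_ratio),
      flux_law = config$flux_law
    )
  )
}

#' Simulate paired with/without-acetylene incubation bottles
#'
#' For each soil sample the total denitrification rate follows the
#' configured PDA quadratic in pH (converted from mg to ug N kg-1 h-1) and
#' the N2O/(N2O+N2) product ratio follows the configured linear law. The
#' with-acetylene bottle accumulates headspace N2O at the ppm slope
#' implied by the total rate; the without-acetylene bottle at that slope
#' times the ratio. Multiplicative Gaussian noise is applied per reading.
#'
#' @param config An [synthetic_config()] object.
#' @param bottle_volume Bottle volume, litres.
#' @param soil_dry_mass Dry soil mass per bottle, kg.
#' @param temperature_c Incubation temperature.
#' @return A list with `series` (tibble, two rows per sample with
#'   list-columns `timepoints`/`headspace_ppm`) and `truth` (per-sample
#'   pH, true total rate in ug N kg-1 h-1, true ratio and net rate).
#' @export
generate_incubation_pairs <- function(config = synthetic_config(),
                                      bottle_volume = 0.1,
                                      soil_dry_mass = 0.005,
                                      temperature_c = 25) {
  stopifnot(inherits(config, "n2o_synth_config"))
  set.seed(config$seed + 2L)
  n <- config$n_incubation_samples
  ph <- stats::runif(n, config$incubation_ph_range[1],
                     config$incubation_ph_range[2])
  total_ug <- .eval_quadratic(config$pda_curve, ph) * 1000
  if (any(total_ug <= 0)) {
    stop("pda_curve must be positive over incubation_ph_range", call. = FALSE)
  }
  ratio <- config$ratio_law[["intercept"]] + config$ratio_law[["slope"]] * ph
  if (any(ratio < 0 | ratio > 1)) {
    stop("true product ratio outside [0, 1]", call. = FALSE)
  }
  # ppm accumulation slope that makes slope_rate() return the target rate
  per_ppm <- headspace_flux(1, bottle_volume, temperature_c, soil_dry_mass,
                            interval_h = 1)
  sample_id <- sprintf("I%03d", seq_len(n))
  tp <- config$timepoints_h
  one_series <- function(id, rate, with_c2h2) {
    slope <- rate / per_ppm
    ppm <- (0.33 + slope * tp) *
      (1 + stats::rnorm(length(tp), 0, config$ppm_noise_sd))
    tibble::tibble(
      sample_id = id, acetylene = with_c2h2,
      soil_dry_mass = soil_dry_mass, bottle_volume = bottle_volume,
      temperature_c = temperature_c, ph_h2o = NA_real_,
      timepoints = list(tp), headspace_ppm = list(pmax(ppm, 0))
    )
  }
  series <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    dplyr::bind_rows(
      one_series(sample_id[i], total_ug[i], TRUE),
      one_series(sample_id[i], total_ug[i] * ratio[i], FALSE)
    )
  }))
  series$ph_h2o <- rep(ph, each = 2)
  list(
    series = series,
    truth = tibble::tibble(
      sample_id = sample_id, ph_h2o = ph,
      total_rate = total_ug, ratio = ratio,
      net_rate = total_ug * ratio
    )
  )
}
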