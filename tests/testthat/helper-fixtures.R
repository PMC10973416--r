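# In-code fixtures: small CSV writers used across the reader tests.

write_field_csv <- function(df, path = withr::local_tempfile(fileext = ".csv",
                                                             .local_envir = parent.frame())) {
  readr::write_csv(df, path)
  path
}

field_rows <- function(n = 3) {
  tibble::tibble(
    study_id = sprintf("S%02d", seq_len(n)),
    latitude = seq(5, 50, length.out = n),
    ecosystem = rep_len(c("cropland", "grassland", "forest"), n),
    ph_reported = seq(5.0, 7.0, length.out = n),
    ph_medium = "H2O",
    n_rate = rep_len(c(100, 200, 150), n),
    emission_fertilized = rep_len(c(2.0, 1.5, 1.2), n),
    emission_control = rep_len(c(1.0, 0.5, 0.4), n),
    replicates = rep_len(3:5, n)
  )
}

gene_rows <- function() {
  tibble::tibble(
    study_id = c("G1", "G1", "G1", "G2"),
    sample_id = c("G1", "G1", "G1", "G2"),
    gene = c("nirK", "nirS", "nosZ clade I", "nirK"),
    copies_per_g = c(3e5, 1e5, 2e5, 5e6),
    ph_h2o = c(6.1, 6.1, 6.1, 5.4),
    n2o_flux = c(55, 55, 55, 40)
  )
}

incubation_rows <- function() {
  base <- tidyr::expand_grid(
    sample_id = c("A", "B"),
    acetylene = c(0, 1),
    time_h = c(2, 4, 6)
  )
  base$ppm <- 0.33 + 0.5 * base$time_h * ifelse(base$acetylene == 1, 2, 1)
  base$soil_dry_mass <- 0.005
  base$bottle_volume <- 0.1
  base$temperature_c <- 25
  base$ph_h2o <- ifelse(base$sample_id == "A", 5.5, 7.0)
  base
}

# independent normal-equations oracle for polynomial least squares
normal_equations_fit <- function(x, y, degree, weights = NULL) {
  X <- outer(x, 0:degree, `^`)
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)[, 1]
}

# independent dimensional-analysis oracle for the headspace flux:
# kg gas = rho[kg/m3] * headspace volume[m3] * ppm*1e-6 * (273/(273+T));
# N mass fraction; kg -> ug; per kg soil per hour.
flux_oracle <- function(delta_c_ppm, volume_l, temp_c, soil_kg, hours,
                        rho = 1.964, n_frac = 28 / 44) {
  gas_kg <- rho * (volume_l * 1e-3) * (delta_c_ppm * 1e-6) * 273 / (273 + temp_c)
  n_ug <- gas_kg * n_frac * 1e9
  n_ug / soil_kg / hours
}
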