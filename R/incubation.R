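#' Default gas constants for headspace flux calculation
#'
#' N2O density at standard state (0 C, 1 atm) is 1.964 kg m-3; the
#' molecular N fraction of N2O is 28/44 (two N atoms of 14 g mol-1 in a
#' 44 g mol-1 molecule); the sealed-accumulation interval of the incubation
#' protocol is 6 h.
#'
#' @return Named list with `gas_density` (kg m-3), `n_fraction`
#'   (dimensionless) and `interval_h` (hours).
#' @export
gas_constants <- function() {
  list(gas_density = 1.964, n_fraction = 28 / 44, interval_h = 6)
}

#' Headspace N2O accumulation to a soil-mass-specific flux
#'
#' Converts the rise in headspace N2O mixing ratio of a closed bottle over
#' an accumulation interval into a flux per kg of dry soil:
#'
#' `F = rho * V * dC * 273 / (273 + T) / (W * dt) * n_fraction`
#'
#' where `rho` is the standard-state gas density (kg m-3), `V` the bottle
#' volume (converted from litres to m3), `dC` the concentration change
#' (ppm, i.e. 1e-6 volume fraction), `273/(273+T)` the ideal-gas correction
#' of the density to the incubation temperature, `W` the dry soil mass (kg)
#' and `dt` the accumulation interval (h). `n_fraction` converts N2O mass
#' to N2O-N mass. The result is expressed in ug N per kg dry soil per hour
#' and is exactly linear in `dC`, so negative concentration changes (net
#' N2O uptake) yield negative fluxes.
#'
#' @param delta_c Concentration change over the interval (ppm), any sign.
#' @param volume Bottle volume in litres, > 0.
#' @param temperature_c Incubation temperature in degrees Celsius.
#' @param soil_mass Dry soil mass in kg, > 0.
#' @param interval_h Accumulation interval in hours, > 0 (default 6).
#' @param gas_density Standard-state N2O density in kg m-3.
#' @param n_fraction Mass fraction of N in the gas (default 28/44).
#' @return Flux in ug N kg-1 dry soil h-1.
#' @examples
#' headspace_flux(1, volume = 0.125, temperature_c = 20, soil_mass = 0.020)
#' @export
headspace_flux <- function(delta_c, volume, temperature_c, soil_mass,
                           interval_h = gas_constants()$interval_h,
                           gas_density = gas_constants()$gas_density,
                           n_fraction = gas_constants()$n_fraction) {
  stopifnot(is.numeric(delta_c))
  if (any(volume <= 0)) stop("bottle volume must be positive", call. = FALSE)
  if (any(soil_mass <= 0)) stop("soil mass must be positive", call. = FALSE)
  if (any(interval_h <= 0)) {
    stop("accumulation interval must be positive", call. = FALSE)
  }
  volume_m3 <- volume / 1000
  mass_kg <- gas_density * volume_m3 * (delta_c * 1e-6) *
    273 / (273 + temperature_c) * n_fraction
  mass_kg * 1e9 / (soil_mass * interval_h)
}

.series_fields <- function(series) {
  if (is.data.frame(series)) {
    stopifnot(nrow(series) == 1)
    series <- as.list(series)
    series$timepoints <- series$timepoints[[1]]
    series$headspace_ppm <- series$headspace_ppm[[1]]
  }
  stopifnot(is.list(series))
  series
}

#' Flux estimate from a timed headspace series
#'
#' Estimates the concentration accumulation rate (ppm h-1) as the
#' least-squares slope of headspace ppm against time, then converts it with
#' [headspace_flux()] using a 1-hour interval (the slope already is a
#' per-hour change). With exactly two timepoints the slope is the finite
#' difference (`method = "two_point"`); with three or more it is a
#' regression slope and its R2 is reported.
#'
#' @param series An incubation series: a one-row tibble from
#'   [read_incubations()] or a list with `sample_id`, `timepoints`,
#'   `headspace_ppm`, `bottle_volume`, `temperature_c`, `soil_dry_mass`
#'   and optionally `acetylene`.
#' @param gas_density,n_fraction Gas constants, see [gas_constants()].
#' @return A one-row tibble: `sample_id`, `rate` (ug N kg-1 h-1),
#'   `slope_ppm_h`, `r2_of_slope` (`NA` for two-point series), `method`.
#' @export
slope_rate <- function(series, gas_density = gas_constants()$gas_density,
                       n_fraction = gas_constants()$n_fraction) {
  s <- .series_fields(series)
  t <- s$timepoints
  p <- s$headspace_ppm
  if (length(t) < 2) stop("need at least two timepoints", call. = FALSE)
  if (length(p) != length(t)) {
    stop("timepoints and headspace_ppm differ in length", call. = FALSE)
  }
  if (any(duplicated(t))) stop("duplicate timepoints", call. = FALSE)
  if (length(t) == 2) {
    slope <- diff(p) / diff(t)
    r2 <- NA_real_
    method <- "two_point"
  } else {
    fit <- stats::lm(p ~ t)
    slope <- unname(stats::coef(fit)[2])
    # R2 computed directly: summary.lm warns on noise-free series
    tss <- sum((p - mean(p))^2)
    r2 <- if (tss == 0) 1 else max(0, 1 - sum(stats::residuals(fit)^2) / tss)
    method <- "regression"
  }
  tibble::tibble(
    sample_id = s$sample_id %||% NA_character_,
    rate = headspace_flux(slope, s$bottle_volume, s$temperature_c,
                          s$soil_dry_mass, interval_h = 1,
                          gas_density = gas_density,
                          n_fraction = n_fraction),
    slope_ppm_h = slope,
    r2_of_slope = r2,
    method = method
  )
}

#' Denitrification product ratio N2O / (N2O + N2)
#'
#' Acetylene blocks N2O reductase, so the flux measured with acetylene is
#' total denitrification (N2O + N2) while the flux without acetylene is net
#' N2O. Their quotient is the fraction of denitrification escaping as N2O.
#' Measurement noise can push the raw quotient outside \[0, 1\]; the
#' reported ratio is clamped to that interval and flagged.
#'
#' @param rate_without_c2h2 Net N2O flux without acetylene
#'   (ug N kg-1 h-1).
#' @param rate_with_c2h2 Total denitrification flux with acetylene, > 0.
#' @return A tibble with `raw_ratio`, `ratio` (clamped to \[0, 1\]) and
#'   `clamped`.
#' @examples
#' product_ratio(5, 10)
#' @export
product_ratio <- function(rate_without_c2h2, rate_with_c2h2) {
  stopifnot(is.numeric(rate_without_c2h2), is.numeric(rate_with_c2h2))
  if (any(rate_with_c2h2 <= 0)) {
    stop("rate with acetylene must be positive (no denitrification signal)",
         call. = FALSE)
  }
  raw <- rate_without_c2h2 / rate_with_c2h2
  ratio <- pmin(pmax(raw, 0), 1)
  tibble::tibble(raw_ratio = raw, ratio = ratio, clamped = raw != ratio)
}

#' Potential denitrification activity from an acetylene-blocked series
#'
#' Applies [slope_rate()] to a series incubated under acetylene (which
#' blocks the reduction of N2O to N2, so the N2O accumulation rate is the
#' total denitrification rate) and reports the rate in
#' mg N kg-1 dry soil h-1, the conventional PDA unit.
#'
#' @param series An incubation series with `acetylene = TRUE`; see
#'   [slope_rate()].
#' @param ... Passed to [slope_rate()].
#' @return A one-row tibble as from [slope_rate()] with `rate` in
#'   mg N kg-1 h-1 and an added `unit` column.
#' @export
pda <- function(series, ...) {
  s <- .series_fields(series)
  if (is.null(s$acetylene) || !isTRUE(as.logical(s$acetylene))) {
    stop("PDA requires an acetylene-amended series (acetylene = TRUE)",
         call. = FALSE)
  }
  est <- slope_rate(s, ...)
  est$rate <- est$rate / 1000
  est$unit <- "mg N kg-1 h-1"
  est
}
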