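#' Default soil pH medium-conversion coefficients
#'
#' Soil pH measured in salt solutions (CaCl2, KCl) reads systematically
#' lower than pH measured in water on the same sample. The package converts
#' salt-medium values to a water basis with a per-medium affine map
#' `ph_h2o = slope * ph_reported + intercept`. The shipped defaults
#' (CaCl2: +0.6 pH units, KCl: +1.0, both with slope 1) are typical offsets
#' from published pedotransfer comparisons; for publication-grade analyses
#' users should supply coefficients calibrated for their own soils.
#'
#' @return A tibble with columns `medium`, `slope`, `intercept`.
#' @export
default_ph_conversions <- function() {
  tibble::tibble(
    medium = c("CaCl2", "KCl"),
    slope = c(1.0, 1.0),
    intercept = c(0.6, 1.0)
  )
}

#' Convert soil pH to a water basis
#'
#' Values measured in water (or whose medium is unknown) pass through
#' unchanged; unknown media additionally raise a warning, since assuming
#' water is a judgement call. CaCl2/KCl values are mapped with the
#' configured affine coefficients and the result is kept inside (0, 14).
#'
#' @param value Numeric pH values in (0, 14).
#' @param medium Character vector (recycled) in
#'   `c("H2O", "CaCl2", "KCl", "unknown")`.
#' @param conversions Coefficient table as from [default_ph_conversions()].
#' @return Numeric vector of water-basis pH values.
#' @examples
#' convert_ph(5.5, "CaCl2")  # 6.1 with the default +0.6 offset
#' @export
convert_ph <- function(value, medium = "H2O",
                       conversions = default_ph_conversions()) {
  stopifnot(is.numeric(value))
  if (any(value <= 0 | value >= 14, na.rm = TRUE)) {
    stop("pH values must lie strictly between 0 and 14", call. = FALSE)
  }
  medium <- rep_len(as.character(medium), length(value))
  allowed <- c("H2O", "CaCl2", "KCl", "unknown")
  if (!all(medium %in% allowed)) {
    stop("unrecognised pH medium: ",
         paste(setdiff(unique(medium), allowed), collapse = ", "),
         call. = FALSE)
  }
  if (any(medium == "unknown")) {
    warning("pH medium unknown for ", sum(medium == "unknown"),
            " value(s); assuming water and leaving them unchanged",
            call. = FALSE)
  }
  out <- value
  for (m in intersect(unique(medium), conversions$medium)) {
    row <- conversions[conversions$medium == m, ]
    if (row$slope <= 0) stop("conversion slope must be positive", call. = FALSE)
    idx <- medium == m
    out[idx] <- row$slope * value[idx] + row$intercept
  }
  pmin(pmax(out, 1e-6), 14 - 1e-6)
}

#' Classify a latitude into a climate zone
#'
#' Zones are defined on absolute latitude: tropical up to 23.4 degrees,
#' subtropical in (23.4, 35.0], temperate beyond 35.0 degrees. Boundary
#' values belong to the zone whose interval closes at them.
#'
#' @param latitude Numeric degrees in \[-90, 90\].
#' @return Factor with levels `tropical`, `subtropical`, `temperate`.
#' @examples
#' classify_climate_zone(c(10, -30, 35, 50.2))
#' @export
classify_climate_zone <- function(latitude) {
  stopifnot(is.numeric(latitude))
  if (any(abs(latitude) > 90, na.rm = TRUE)) {
    stop("latitude must lie in [-90, 90]", call. = FALSE)
  }
  a <- abs(latitude)
  zone <- ifelse(a <= 23.4, "tropical",
                 ifelse(a <= 35.0, "subtropical", "temperate"))
  factor(zone, levels = c("tropical", "subtropical", "temperate"))
}

.acidity_classes <- c(
  "ultra-acidic", "extremely acidic", "very strongly acidic",
  "strongly acidic", "moderately acidic", "slightly acidic", "neutral",
  "slightly alkaline", "moderately alkaline", "strongly alkaline"
)

#' Classify soil pH into USDA acidity classes
#'
#' The standard ten-class soil-reaction scale: ultra-acidic below pH 3.5,
#' then classes 3.5-4.4, 4.5-5.0, 5.1-5.5, 5.6-6.0, 6.1-6.5, 6.6-7.3,
#' 7.4-7.8, 7.9-8.4 and 8.5-9.0 (strongly alkaline). The printed class
#' edges are closed at one-decimal resolution, so inputs are rounded to one
#' decimal before classification; values above 9.0 fall outside the
#' published table and are labelled strongly alkaline with an
#' `out_of_table` attribute marking them.
#'
#' @param ph Numeric pH values in (0, 14).
#' @return Factor of class labels with attribute `out_of_table`
#'   (logical vector).
#' @examples
#' classify_acidity(c(3.4, 5.8, 7.0, 9.5))
#' @export
classify_acidity <- function(ph) {
  stopifnot(is.numeric(ph))
  if (any(ph <= 0 | ph >= 14, na.rm = TRUE)) {
    stop("pH values must lie strictly between 0 and 14", call. = FALSE)
  }
  p <- round(ph, 1)
  upper <- c(3.4, 4.4, 5.0, 5.5, 6.0, 6.5, 7.3, 7.8, 8.4, Inf)
  cls <- .acidity_classes[findInterval(p, c(-Inf, upper), left.open = TRUE,
                                       rightmost.closed = TRUE)]
  out <- factor(cls, levels = .acidity_classes)
  attr(out, "out_of_table") <- !is.na(p) & p > 9.0
  out
}

#' Harmonize field observations to a common basis
#'
#' Fills `ph_h2o` from the reported pH and medium, and adds `climate_zone`
#' and `acidity_class` columns. Rows whose pH was converted from a salt
#' medium are flagged in `ph_converted`.
#'
#' @param observations Tibble of field observations as returned by
#'   [read_field_observations()].
#' @param conversions pH conversion table; see [default_ph_conversions()].
#' @return The input tibble with `ph_h2o`, `ph_converted`, `climate_zone`
#'   and `acidity_class` columns added or overwritten.
#' @export
harmonize_field_observations <- function(observations,
                                         conversions = default_ph_conversions()) {
  stopifnot(is.data.frame(observations))
  obs <- tibble::as_tibble(observations)
  medium <- if ("ph_medium" %in% names(obs)) obs$ph_medium else "unknown"
  obs$ph_h2o <- convert_ph(obs$ph_reported, medium, conversions)
  obs$ph_converted <- rep_len(medium, nrow(obs)) %in% conversions$medium
  obs$climate_zone <- if ("latitude" %in% names(obs)) {
    classify_climate_zone(obs$latitude)
  } else {
    factor(NA_character_, levels = levels(classify_climate_zone(0)))
  }
  obs$acidity_class <- classify_acidity(obs$ph_h2o)
  obs
}

#' Per-climate-zone summary of pH, emission factor and N rate
#'
#' Means with standard errors (sd / sqrt(n)) and counts for soil pH, the
#' N2O emission factor and the N fertilization rate, one row per climate
#' zone. Zones without observations appear with `n = 0` and `NA` means;
#' a single observation yields an `NA` standard error.
#'
#' @param observations Harmonized field observations (must carry `ph_h2o`
#'   and `latitude`; `ef_percent` is computed from the emission columns
#'   when absent).
#' @return A tibble with one row per zone and columns
#'   `climate_zone`, `n`, `ph_mean`, `ph_sem`, `ef_mean`, `ef_sem`,
#'   `n_rate_mean`, `n_rate_sem`.
#' @export
zone_summary <- function(observations) {
  stopifnot(is.data.frame(observations))
  obs <- tibble::as_tibble(observations)
  if (!"ph_h2o" %in% names(obs)) {
    stop("observations must be harmonized first (missing ph_h2o)",
         call. = FALSE)
  }
  if (!"climate_zone" %in% names(obs)) {
    obs$climate_zone <- classify_climate_zone(obs$latitude)
  }
  if (!"ef_percent" %in% names(obs)) {
    obs$ef_percent <- compute_ef(obs$emission_fertilized,
                                 obs$emission_control, obs$n_rate)
  }
  sem <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
  }
  mn <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  obs |>
    dplyr::group_by(climate_zone = factor(.data$climate_zone,
                                          levels = levels(classify_climate_zone(0)))) |>
    dplyr::summarise(
      n = dplyr::n(),
      ph_mean = mn(.data$ph_h2o), ph_sem = sem(.data$ph_h2o),
      ef_mean = mn(.data$ef_percent), ef_sem = sem(.data$ef_percent),
      n_rate_mean = mn(.data$n_rate), n_rate_sem = sem(.data$n_rate),
      .groups = "drop"
    ) |>
    tidyr::complete(climate_zone = factor(levels(classify_climate_zone(0)),
                                          levels = levels(classify_climate_zone(0))),
                    fill = list(n = 0L))
}
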