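#' N2O emission factor from paired fertilized/control emissions
#'
#' The emission factor is the fertilizer-induced N2O emission expressed as
#' a percentage of the N applied:
#' `EF (%) = 100 * (E_N - E_O) / N`, with `E_N` the cumulative emission of
#' the fertilized plot, `E_O` that of the unfertilized control and `N` the
#' fertilization rate, all in kg N per hectare. Negative values (apparent
#' net uptake relative to the control) are legitimate and are returned
#' unmodified.
#'
#' @param emission_fertilized,emission_control Cumulative N2O-N emissions
#'   (kg N ha-1) of fertilized and control plots.
#' @param n_rate N fertilization rate (kg N ha-1), strictly positive.
#' @return Numeric emission factors in percent.
#' @examples
#' compute_ef(2.0, 1.0, 100)  # 1 percent
#' @export
compute_ef <- function(emission_fertilized, emission_control, n_rate) {
  stopifnot(is.numeric(emission_fertilized), is.numeric(emission_control),
            is.numeric(n_rate))
  if (any(n_rate <= 0, na.rm = TRUE)) {
    stop("n_rate must be strictly positive: control plots yield no emission factor",
         call. = FALSE)
  }
  100 * (emission_fertilized - emission_control) / n_rate
}

#' Add emission-factor columns to a field-observation table
#'
#' @param observations Tibble with `emission_fertilized`,
#'   `emission_control` and `n_rate` columns.
#' @return The tibble with `ef_percent` and a logical `ef_negative` flag.
#' @export
add_ef <- function(observations) {
  stopifnot(is.data.frame(observations))
  obs <- tibble::as_tibble(observations)
  obs$ef_percent <- compute_ef(obs$emission_fertilized,
                               obs$emission_control, obs$n_rate)
  obs$ef_negative <- obs$ef_percent < 0
  obs
}

#' Assign observations to fixed-width pH bins
#'
#' Bins are half-open intervals `[anchor + k w, anchor + (k+1) w)` so every
#' value lands in exactly one bin; a value sitting exactly on an edge
#' belongs to the bin opening at that edge. The default width of 0.1 pH
#' units reproduces the increment used for the weighted-mean analysis.
#'
#' @param data Tibble carrying the binning variable.
#' @param var Name of the numeric column to bin (default `"ph_h2o"`).
#' @param width Bin width (> 0), default 0.1.
#' @param anchor Left edge of bin 0, default 0.
#' @return `data` with integer `bin_id` and numeric `bin_lower`,
#'   `bin_upper`, `bin_center` columns added.
#' @examples
#' assign_bins(tibble::tibble(ph_h2o = c(5.61, 5.64, 5.70)))
#' @export
assign_bins <- function(data, var = "ph_h2o", width = 0.1, anchor = 0) {
  stopifnot(is.data.frame(data))
  if (width <= 0) stop("bin width must be positive", call. = FALSE)
  if (!var %in% names(data)) {
    stop("column `", var, "` not found", call. = FALSE)
  }
  x <- data[[var]]
  if (anyNA(x)) stop("binning variable contains missing values", call. = FALSE)
  # round before floor so values printed at bin edges (e.g. 5.7 with
  # width 0.1) are not pushed into the lower bin by binary representation
  idx <- floor(round((x - anchor) / width, 9))
  out <- tibble::as_tibble(data)
  out$bin_id <- as.integer(idx)
  out$bin_lower <- anchor + idx * width
  out$bin_upper <- anchor + (idx + 1) * width
  out$bin_center <- out$bin_lower + width / 2
  out
}

#' Replicate-weighted mean of one bin of emission factors
#'
#' Within a bin of `o` observations each observation receives weight
#' `W_i = n_i / o`, with `n_i` its field-experiment replicate count, and the
#' bin mean is `M = sum(Y_i W_i) / sum(W_i)`. Well-replicated measurements
#' therefore count for more; with equal replication the weighted mean
#' reduces to the plain mean. Observations with unknown replication receive
#' the neutral weight `1 / o` and are flagged.
#'
#' @param ef Numeric vector of emission factors (one bin).
#' @param replicates Integer replicate counts, may contain `NA`.
#' @return A list with `weighted_mean`, `sum_weights`, `o` (member count)
#'   and `n_missing_replicates`.
#' @examples
#' weighted_mean_ef(c(1, 3), c(1, 3))  # 2.5
#' @export
weighted_mean_ef <- function(ef, replicates = rep(1, length(ef))) {
  stopifnot(is.numeric(ef), length(ef) >= 1)
  o <- length(ef)
  if (length(replicates) != o) {
    stop("`replicates` must match `ef` in length", call. = FALSE)
  }
  missing_n <- is.na(replicates)
  w <- ifelse(missing_n, 1, replicates) / o
  if (any(w <= 0)) stop("replicate counts must be positive", call. = FALSE)
  list(
    weighted_mean = sum(ef * w) / sum(w),
    sum_weights = sum(w),
    o = o,
    n_missing_replicates = sum(missing_n)
  )
}

#' Per-bin weighted mean table of emission factors
#'
#' Applies [weighted_mean_ef()] within each pH bin of a table produced by
#' [assign_bins()]. Only non-empty bins are returned, ordered by bin.
#'
#' @param binned Tibble with `bin_id`/`bin_lower`/`bin_upper`/`bin_center`,
#'   `ef_percent` and `replicates` columns.
#' @return A tibble with one row per non-empty bin: the bin edges and
#'   center, member count `o`, `sum_weights`, `weighted_mean_ef`,
#'   `min_ef`, `max_ef` and `n_missing_replicates`.
#' @export
bin_weighted_means <- function(binned) {
  stopifnot(is.data.frame(binned))
  need <- c("bin_id", "bin_lower", "bin_upper", "bin_center", "ef_percent")
  miss <- setdiff(need, names(binned))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  reps <- if ("replicates" %in% names(binned)) binned$replicates else
    rep(NA_integer_, nrow(binned))
  tibble::as_tibble(binned) |>
    dplyr::mutate(.reps = reps) |>
    dplyr::group_by(.data$bin_id, .data$bin_lower, .data$bin_upper,
                    .data$bin_center) |>
    dplyr::summarise(
      o = dplyr::n(),
      wm = list(weighted_mean_ef(.data$ef_percent, .data$.reps)),
      min_ef = min(.data$ef_percent),
      max_ef = max(.data$ef_percent),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sum_weights = vapply(.data$wm, `[[`, numeric(1), "sum_weights"),
      weighted_mean_ef = vapply(.data$wm, `[[`, numeric(1), "weighted_mean"),
      n_missing_replicates = vapply(.data$wm, `[[`, numeric(1),
                                    "n_missing_replicates")
    ) |>
    dplyr::select(-"wm") |>
    dplyr::arrange(.data$bin_id)
}

#' Weighted mean emission factor by N fertilization rate interval
#'
#' Groups observations into fixed-width N-rate intervals (default
#' 100 kg N ha-1) and applies the same replicate weighting as the pH bins.
#'
#' @param observations Tibble with `ef_percent`, `n_rate` and optionally
#'   `replicates`.
#' @param width Interval width in kg N ha-1, default 100.
#' @return A tibble with one row per non-empty interval: `rate_lower`,
#'   `rate_upper`, `o`, `sum_weights`, `weighted_mean_ef`.
#' @export
aggregate_by_n_rate <- function(observations, width = 100) {
  stopifnot(is.data.frame(observations))
  if (width <= 0) stop("interval width must be positive", call. = FALSE)
  obs <- tibble::as_tibble(observations)
  if (any(obs$n_rate <= 0)) {
    stop("n_rate must be strictly positive", call. = FALSE)
  }
  binned <- assign_bins(obs, var = "n_rate", width = width)
  reps <- if ("replicates" %in% names(binned)) binned$replicates else
    rep(NA_integer_, nrow(binned))
  binned |>
    dplyr::mutate(.reps = reps) |>
    dplyr::group_by(rate_lower = .data$bin_lower,
                    rate_upper = .data$bin_upper) |>
    dplyr::summarise(
      o = dplyr::n(),
      wm = list(weighted_mean_ef(.data$ef_percent, .data$.reps)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      sum_weights = vapply(.data$wm, `[[`, numeric(1), "sum_weights"),
      weighted_mean_ef = vapply(.data$wm, `[[`, numeric(1), "weighted_mean")
    ) |>
    dplyr::select(-"wm") |>
    dplyr::arrange(.data$rate_lower)
}
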