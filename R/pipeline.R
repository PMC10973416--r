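#' Run configuration for the end-to-end pipelines
#'
#' Collects every tunable of the three analyses in one validated object.
#' Defaults follow the published analysis choices where one exists: 0.1-pH
#' bins, an AICc difference of 2 as the model-selection threshold,
#' 100 kg N ha-1 rate intervals, and the gas constants of
#' [gas_constants()].
#'
#' @param field_csv,gene_csv,incubation_csv Input CSV paths (only the ones
#'   needed by the pipelines you run).
#' @param bin_width pH bin width.
#' @param nrate_width N-rate interval width, kg N ha-1.
#' @param aicc_threshold AICc difference treated as substantial.
#' @param weight_bins Weight the bin-averaged EF fit by bin total weight
#'   (default `FALSE`: every pH increment counts equally, the rationale
#'   for averaging in the first place).
#' @param ph_conversions pH medium conversion table,
#'   see [default_ph_conversions()].
#' @param gas Gas constants list, see [gas_constants()].
#' @param ratio_scale Scale of the gene-ratio response in `run_meta2`.
#' @param out_dir Optional directory; when set, reports are also written
#'   as TSV.
#' @param strict Upgrade reader rejects to errors.
#' @return A list of class `n2o_run_config`.
#' @export
run_config <- function(field_csv = NULL, gene_csv = NULL,
                       incubation_csv = NULL, bin_width = 0.1,
                       nrate_width = 100, aicc_threshold = 2,
                       weight_bins = FALSE,
                       ph_conversions = default_ph_conversions(),
                       gas = gas_constants(),
                       ratio_scale = c("log10", "linear"),
                       out_dir = NULL, strict = FALSE) {
  ratio_scale <- match.arg(ratio_scale)
  stopifnot(bin_width > 0, nrate_width > 0, aicc_threshold >= 0)
  structure(
    list(field_csv = field_csv, gene_csv = gene_csv,
         incubation_csv = incubation_csv, bin_width = bin_width,
         nrate_width = nrate_width, aicc_threshold = aicc_threshold,
         weight_bins = isTRUE(weight_bins), ph_conversions = ph_conversions,
         gas = gas, ratio_scale = ratio_scale, out_dir = out_dir,
         strict = isTRUE(strict)),
    class = "n2o_run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()];
#' `ph_conversions` may be given as a list of `{medium, slope, intercept}`
#' records.
#'
#' @param path YAML file path.
#' @return An `n2o_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  conv <- if (!is.null(raw$ph_conversions)) {
    dplyr::bind_rows(lapply(raw$ph_conversions, tibble::as_tibble))
  } else {
    default_ph_conversions()
  }
  gas <- utils::modifyList(gas_constants(), raw$gas %||% list())
  run_config(
    field_csv = raw$field_csv, gene_csv = raw$gene_csv,
    incubation_csv = raw$incubation_csv,
    bin_width = raw$bin_width %||% 0.1,
    nrate_width = raw$nrate_width %||% 100,
    aicc_threshold = raw$aicc_threshold %||% 2,
    weight_bins = raw$weight_bins %||% FALSE,
    ph_conversions = conv, gas = gas,
    ratio_scale = raw$ratio_scale %||% "log10",
    out_dir = raw$out_dir, strict = raw$strict %||% FALSE
  )
}

.provenance <- function(config, paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  sums <- if (length(paths)) {
    vapply(unlist(paths), function(p) unname(tools::md5sum(p)), character(1))
  } else {
    character(0)
  }
  cfg <- unclass(config)
  cfg$ph_conversions <- as.data.frame(cfg$ph_conversions)
  list(config = cfg, input_md5 = as.list(sums),
       generated = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

.fit_pair <- function(x, y, threshold, weights = NULL) {
  lin <- fit_polynomial(x, y, degree = 1, weights = weights)
  quad <- fit_polynomial(x, y, degree = 2, weights = weights)
  sel <- select_model(lin, quad, threshold = threshold)
  list(linear = lin, quadratic = quad, selection = sel,
       peak = if (sel$chosen == "quadratic") vertex(quad) else NULL)
}

.fit_row <- function(label, pair) {
  fit <- pair$selection$fit
  tibble::tibble(
    response = label,
    chosen = pair$selection$chosen,
    delta_aicc = pair$selection$delta_aicc,
    tie = pair$selection$tie,
    n = fit$n_obs,
    c0 = fit$coefficients[["c0"]],
    c1 = fit$coefficients[["c1"]],
    c2 = if (fit$model_kind == "quadratic") fit$coefficients[["c2"]] else NA_real_,
    adj_r2 = fit$adj_r2,
    peak_ph = if (!is.null(pair$peak)) pair$peak$peak_x else NA_real_,
    peak_y = if (!is.null(pair$peak)) pair$peak$peak_y else NA_real_
  )
}

#' Global EF meta-analysis: pH response of N2O emission factors
#'
#' Reads and harmonizes field observations, derives emission factors, and
#' fits the pH response twice: on every observation ("coarse") and on one
#' replicate-weighted mean per 0.1-pH bin ("averaged"), each with
#' linear/quadratic competition and AICc selection. Also reports the
#' climate-zone summary and the weighted mean EF by N-rate interval.
#'
#' @param config An [run_config()] with `field_csv` set, or a tibble of
#'   already-read field observations plus a config.
#' @param observations Optional pre-read observation tibble (bypasses the
#'   CSV reader; useful with [generate_field_dataset()]).
#' @return A list of class `n2o_report` with elements `fits` (tibble, one
#'   row per fitted response), `details` (the full fit objects), `bins`,
#'   `n_rate`, `zones`, `counts`, `provenance`.
#' @export
run_meta1 <- function(config = run_config(), observations = NULL) {
  stopifnot(inherits(config, "n2o_run_config"))
  if (is.null(observations)) {
    if (is.null(config$field_csv)) {
      stop("config$field_csv is not set and no observations were supplied",
           call. = FALSE)
    }
    rd <- read_field_observations(config$field_csv, strict = config$strict)
    obs <- rd$observations
    rejects <- rd$rejects
  } else {
    obs <- tibble::as_tibble(observations)
    rejects <- tibble::tibble(row = integer(), reason = character())
  }
  obs <- harmonize_field_observations(obs, config$ph_conversions)
  obs <- obs[obs$n_rate > 0, ]
  obs <- add_ef(obs)
  if (nrow(obs) < 10) {
    stop("fewer than 10 emission-factor observations; cannot fit a pH response",
         call. = FALSE)
  }
  binned <- assign_bins(obs, var = "ph_h2o", width = config$bin_width)
  bins <- bin_weighted_means(binned)
  coarse <- .fit_pair(obs$ph_h2o, obs$ef_percent, config$aicc_threshold)
  avg_w <- if (config$weight_bins) bins$sum_weights else NULL
  averaged <- .fit_pair(bins$bin_center, bins$weighted_mean_ef,
                        config$aicc_threshold, weights = avg_w)
  fits <- dplyr::bind_rows(.fit_row("ef_coarse", coarse),
                           .fit_row("ef_averaged", averaged))
  report <- structure(
    list(
      analysis = "meta1",
      fits = fits,
      details = list(coarse = coarse, averaged = averaged),
      bins = bins,
      n_rate = aggregate_by_n_rate(obs, width = config$nrate_width),
      zones = zone_summary(obs),
      counts = list(read = nrow(obs) + nrow(rejects),
                    rejected = nrow(rejects), used = nrow(obs),
                    negative_ef = sum(obs$ef_negative),
                    bins = nrow(bins)),
      provenance = .provenance(config, list(config$field_csv))
    ),
    class = "n2o_report"
  )
  .maybe_write(report, config, c("fits", "bins", "n_rate", "zones"))
  report
}

#' Global gene meta-analysis: pH response of denitrifier gene abundances
#'
#' Fits coarse and bin-averaged pH responses of log10 nirK, nirS and nosZI
#' abundance, the (nirK+nirS)/nosZI ratio (coarse and averaged, on the
#' configured scale), and the linear flux-versus-log-ratio relationship.
#'
#' @inheritParams run_meta1
#' @param observations Optional pre-read long-format gene tibble.
#' @return An `n2o_report` with `fits`, `details`, `flux_ratio`, `counts`,
#'   `provenance`.
#' @export
run_meta2 <- function(config = run_config(), observations = NULL) {
  stopifnot(inherits(config, "n2o_run_config"))
  if (is.null(observations)) {
    if (is.null(config$gene_csv)) {
      stop("config$gene_csv is not set and no observations were supplied",
           call. = FALSE)
    }
    rd <- read_gene_observations(config$gene_csv, strict = config$strict)
    obs <- rd$observations
    rejects <- rd$rejects
  } else {
    obs <- tibble::as_tibble(observations)
    rejects <- tibble::tibble(row = integer(), reason = character())
  }
  genes <- intersect(c("nirK", "nirS", "nosZI"), unique(as.character(obs$gene)))
  details <- list()
  rows <- list()
  for (g in genes) {
    for (avg in c(FALSE, TRUE)) {
      label <- paste0(g, if (avg) "_averaged" else "_coarse")
      pair <- fit_gene_ph(obs, g, use_averaged = avg,
                          width = config$bin_width,
                          aicc_threshold = config$aicc_threshold)
      details[[label]] <- pair
      rows[[label]] <- .fit_row(label, pair)
    }
  }
  rat <- gene_ratio_records(obs)
  for (avg in c(FALSE, TRUE)) {
    label <- paste0("ratio_", if (avg) "averaged" else "coarse")
    pair <- fit_gene_ph(obs, "ratio", use_averaged = avg,
                        ratio_scale = config$ratio_scale,
                        width = config$bin_width,
                        aicc_threshold = config$aicc_threshold)
    details[[label]] <- pair
    rows[[label]] <- .fit_row(label, pair)
  }
  flux_ratio <- tryCatch(fit_flux_vs_ratio(rat$records), error = function(e) NULL)
  report <- structure(
    list(
      analysis = "meta2",
      fits = dplyr::bind_rows(rows),
      details = details,
      flux_ratio = flux_ratio,
      counts = list(read = nrow(obs) + nrow(rejects),
                    rejected = nrow(rejects), used = nrow(obs),
                    ratio_records = sum(!is.na(rat$records$ratio)),
                    incomplete_ratio = rat$n_incomplete,
                    noszii_set_aside = rat$n_noszii_set_aside),
      provenance = .provenance(config, list(config$gene_csv))
    ),
    class = "n2o_report"
  )
  .maybe_write(report, config, "fits")
  report
}

#' Field-experiment analysis: fluxes, PDA and product ratios versus pH
#'
#' Computes per-bottle flux estimates from the headspace series, potential
#' denitrification activity from the acetylene bottles, pairs bottles per
#' sample into N2O/(N2O+N2) product ratios, and fits the pH responses of
#' the net N2O rate (quadratic competition), PDA (quadratic competition)
#' and the product ratio (linear).
#'
#' @inheritParams run_meta1
#' @param series Optional pre-read incubation series tibble (as from
#'   [read_incubations()] or [generate_incubation_pairs()]).
#' @return An `n2o_report` with `samples` (per-sample rates and ratios),
#'   `fits`, `details`, `counts`, `provenance`.
#' @export
run_field <- function(config = run_config(), series = NULL) {
  stopifnot(inherits(config, "n2o_run_config"))
  if (is.null(series)) {
    if (is.null(config$incubation_csv)) {
      stop("config$incubation_csv is not set and no series were supplied",
           call. = FALSE)
    }
    rd <- read_incubations(config$incubation_csv, strict = config$strict)
    ser <- rd$observations
    rejects <- rd$rejects
  } else {
    ser <- tibble::as_tibble(series)
    rejects <- tibble::tibble(row = integer(), reason = character())
  }
  if (nrow(ser) == 0) stop("no incubation series to analyse", call. = FALSE)
  est <- dplyr::bind_rows(lapply(seq_len(nrow(ser)), function(i) {
    e <- slope_rate(ser[i, ], gas_density = config$gas$gas_density,
                    n_fraction = config$gas$n_fraction)
    e$acetylene <- ser$acetylene[i]
    e$ph_h2o <- ser$ph_h2o[i]
    e
  }))
  with_c2h2 <- est[est$acetylene, c("sample_id", "ph_h2o", "rate")]
  names(with_c2h2)[3] <- "rate_with_c2h2"
  without <- est[!est$acetylene, c("sample_id", "rate")]
  names(without)[2] <- "rate_without_c2h2"
  samples <- dplyr::inner_join(with_c2h2, without, by = "sample_id")
  if (nrow(samples) > 0) {
    pr <- product_ratio(samples$rate_without_c2h2, samples$rate_with_c2h2)
    samples <- dplyr::bind_cols(samples, pr)
    samples$pda_mg <- samples$rate_with_c2h2 / 1000
  }
  details <- list()
  rows <- list()
  if (nrow(samples) >= 5 && !all(is.na(samples$ph_h2o))) {
    details$n2o <- .fit_pair(samples$ph_h2o, samples$rate_without_c2h2,
                             config$aicc_threshold)
    details$pda <- .fit_pair(samples$ph_h2o, samples$pda_mg,
                             config$aicc_threshold)
    ratio_lin <- fit_polynomial(samples$ph_h2o, samples$ratio, degree = 1)
    details$ratio <- list(linear = ratio_lin,
                          selection = list(fit = ratio_lin,
                                           chosen = "linear",
                                           delta_aicc = NA_real_, tie = NA),
                          peak = NULL)
    rows <- list(.fit_row("n2o_rate", details$n2o),
                 .fit_row("pda", details$pda),
                 .fit_row("product_ratio", details$ratio))
  }
  report <- structure(
    list(
      analysis = "field",
      samples = samples,
      fits = dplyr::bind_rows(rows),
      details = details,
      counts = list(series = nrow(ser) + nrow(rejects),
                    rejected = nrow(rejects), pairs = nrow(samples),
                    clamped_ratios = if (nrow(samples)) sum(samples$clamped) else 0L),
      provenance = .provenance(config, list(config$incubation_csv))
    ),
    class = "n2o_report"
  )
  .maybe_write(report, config, c("fits", "samples"))
  report
}

.maybe_write <- function(report, config, tables) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  present <- tables[vapply(tables, function(t) {
    is.data.frame(report[[t]]) && nrow(report[[t]]) > 0
  }, logical(1))]
  if (length(present) == 0) return(invisible(NULL))
  dir <- file.path(config$out_dir, report$analysis)
  write_report(stats::setNames(lapply(present, function(t) report[[t]]),
                               present),
               dir, format = "tsv")
  jsonlite::write_json(report$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' @export
print.n2o_report <- function(x, ...) {
  cat(sprintf("<n2o_report> analysis = %s\n", x$analysis))
  cat("  counts:", paste(names(x$counts), unlist(x$counts), sep = " = ",
                         collapse = ", "), "\n")
  if (!is.null(x$fits) && nrow(x$fits) > 0) {
    cat("  fits:\n")
    print(x$fits, n = nrow(x$fits))
  }
  invisible(x)
}
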