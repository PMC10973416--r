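#' Ratio of N2O-producing to N2O-consuming gene markers
#'
#' `(nirK + nirS) / nosZI` compares the abundance of the two nitrite
#' reductase genes (markers of N2O-producing denitrifiers) with the clade I
#' N2O reductase gene (the marker of N2O consumers). All three abundances
#' must be positive and from the same sample; the ratio is scale-invariant,
#' so the unit (copies per g soil) cancels.
#'
#' @param nirK,nirS,nosZI Gene abundances in copies per g soil, > 0.
#'   Vectors are processed elementwise; `NA`s yield an `NA` ratio with
#'   `complete = FALSE`.
#' @return A tibble with `ratio`, `log10_ratio` and `complete`.
#' @examples
#' compute_gene_ratio(1e6, 1e6, 1e6)  # ratio 2
#' @export
compute_gene_ratio <- function(nirK, nirS, nosZI) {
  stopifnot(is.numeric(nirK), is.numeric(nirS), is.numeric(nosZI))
  if (any(c(nirK, nirS, nosZI) <= 0, na.rm = TRUE)) {
    stop("gene abundances must be strictly positive", call. = FALSE)
  }
  ratio <- (nirK + nirS) / nosZI
  tibble::tibble(
    ratio = ratio,
    log10_ratio = log10(ratio),
    complete = !is.na(ratio)
  )
}

#' Build per-sample gene-ratio records from a long abundance table
#'
#' Pivots a long gene-observation table to one row per sample, computes the
#' (nirK+nirS)/nosZI ratio for samples carrying all three genes, and
#' reports how many records were set aside: samples missing one of the
#' three genes, and nosZII observations, which are stored but never enter
#' the ratio (clade II quantifications are too scarce in field datasets
#' paired with flux measurements to support one).
#'
#' @param genes Tibble from [read_gene_observations()]`$observations` with
#'   columns `sample_id`, `study_id`, `gene`, `copies_per_g`, `ph_h2o`
#'   and optionally `n2o_flux`.
#' @return A list with `records` (tibble: `sample_id`, `study_id`,
#'   `ph_h2o`, `n2o_flux`, `nirK`, `nirS`, `nosZI`, `ratio`,
#'   `log10_ratio`), `n_incomplete` and `n_noszii_set_aside`.
#' @export
gene_ratio_records <- function(genes) {
  stopifnot(is.data.frame(genes))
  genes <- tibble::as_tibble(genes)
  n_noszii <- sum(genes$gene == "nosZII", na.rm = TRUE)
  wide <- genes |>
    dplyr::filter(.data$gene %in% c("nirK", "nirS", "nosZI")) |>
    dplyr::group_by(.data$sample_id, .data$study_id, .data$gene) |>
    dplyr::summarise(copies_per_g = mean(.data$copies_per_g),
                     ph_h2o = .data$ph_h2o[1],
                     n2o_flux = .data$n2o_flux[1], .groups = "drop") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "copies_per_g",
                       id_cols = c("sample_id", "study_id", "ph_h2o",
                                   "n2o_flux"))
  for (g in c("nirK", "nirS", "nosZI")) {
    if (!g %in% names(wide)) wide[[g]] <- NA_real_
  }
  complete <- !is.na(wide$nirK) & !is.na(wide$nirS) & !is.na(wide$nosZI)
  wide$ratio <- NA_real_
  wide$log10_ratio <- NA_real_
  if (any(complete)) {
    rr <- compute_gene_ratio(wide$nirK[complete], wide$nirS[complete],
                             wide$nosZI[complete])
    wide$ratio[complete] <- rr$ratio
    wide$log10_ratio[complete] <- rr$log10_ratio
  }
  list(
    records = wide,
    n_incomplete = sum(!complete),
    n_noszii_set_aside = n_noszii
  )
}

#' Per-pH-bin average of gene abundance, computed on the linear scale
#'
#' Published gene abundances usually circulate as log10 values. Averaging
#' those directly would give the geometric mean; this pipeline instead
#' back-transforms to copy numbers, averages within each 0.1-unit pH bin on
#' the linear scale, and then takes log10 of the bin mean. By Jensen's
#' inequality this linear-then-log mean is never smaller than the mean of
#' logs, with equality only when all members of a bin are equal.
#'
#' @param genes Gene observation tibble (long format, `gene` column).
#' @param gene Which gene to average, e.g. `"nirK"`.
#' @param width,anchor Bin width and anchor, as in [assign_bins()].
#' @return A tibble with one row per non-empty bin: bin columns, `n`,
#'   `mean_abundance` (copies per g) and `mean_log10_abundance`.
#' @export
bin_average_log_abundance <- function(genes, gene, width = 0.1, anchor = 0) {
  stopifnot(is.data.frame(genes))
  sel <- tibble::as_tibble(genes) |>
    dplyr::filter(.data$gene == !!gene)
  if (nrow(sel) == 0) {
    return(tibble::tibble(bin_id = integer(), bin_lower = numeric(),
                          bin_upper = numeric(), bin_center = numeric(),
                          n = integer(), mean_abundance = numeric(),
                          mean_log10_abundance = numeric()))
  }
  assign_bins(sel, var = "ph_h2o", width = width, anchor = anchor) |>
    dplyr::group_by(.data$bin_id, .data$bin_lower, .data$bin_upper,
                    .data$bin_center) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_abundance = mean(.data$copies_per_g),
                     .groups = "drop") |>
    dplyr::mutate(mean_log10_abundance = log10(.data$mean_abundance)) |>
    dplyr::arrange(.data$bin_id)
}

#' Fit the pH response of a gene abundance or of the gene ratio
#'
#' Fits linear and quadratic models of log10 abundance (or of the gene
#' ratio) against water-basis soil pH and selects between them by AICc
#' ([select_model()]). `use_averaged = TRUE` first collapses the data to
#' one linear-scale mean per 0.1-pH bin (see
#' [bin_average_log_abundance()]); otherwise every observation enters the
#' fit ("coarse" mode).
#'
#' @param genes Gene observation tibble, long format.
#' @param gene Gene to fit (`"nirK"`, `"nirS"`, `"nosZI"`, ...), or
#'   `"ratio"` to fit the (nirK+nirS)/nosZI ratio from
#'   [gene_ratio_records()].
#' @param use_averaged Average per pH bin before fitting.
#' @param ratio_scale For `gene = "ratio"`: `"log10"` (the global
#'   meta-analysis convention) or `"linear"` (the field-experiment
#'   convention).
#' @param width Bin width for averaged mode.
#' @param aicc_threshold AICc difference treated as substantial.
#' @return A list: `linear`, `quadratic` (both `n2o_fit`), `selection`
#'   (from [select_model()]), `peak` (vertex of the quadratic or `NULL`)
#'   and `n` (points fitted).
#' @export
fit_gene_ph <- function(genes, gene, use_averaged = FALSE,
                        ratio_scale = c("log10", "linear"), width = 0.1,
                        aicc_threshold = 2) {
  ratio_scale <- match.arg(ratio_scale)
  if (identical(gene, "ratio")) {
    rec <- gene_ratio_records(genes)$records
    rec <- rec[!is.na(rec$ratio), ]
    y <- if (ratio_scale == "log10") rec$log10_ratio else rec$ratio
    dat <- tibble::tibble(ph_h2o = rec$ph_h2o, y = y)
    if (use_averaged) {
      dat <- assign_bins(dat, var = "ph_h2o", width = width) |>
        dplyr::group_by(.data$bin_center) |>
        dplyr::summarise(y = mean(.data$y), .groups = "drop") |>
        dplyr::rename(ph_h2o = "bin_center")
    }
  } else if (use_averaged) {
    avg <- bin_average_log_abundance(genes, gene, width = width)
    dat <- tibble::tibble(ph_h2o = avg$bin_center,
                          y = avg$mean_log10_abundance)
  } else {
    sel <- tibble::as_tibble(genes) |>
      dplyr::filter(.data$gene == !!gene)
    dat <- tibble::tibble(ph_h2o = sel$ph_h2o,
                          y = log10(sel$copies_per_g))
  }
  if (nrow(dat) < 5) {
    stop("need at least 5 points to fit a pH response", call. = FALSE)
  }
  lin <- fit_polynomial(dat$ph_h2o, dat$y, degree = 1)
  quad <- fit_polynomial(dat$ph_h2o, dat$y, degree = 2)
  sel_res <- select_model(lin, quad, threshold = aicc_threshold)
  list(
    linear = lin,
    quadratic = quad,
    selection = sel_res,
    peak = if (sel_res$chosen == "quadratic") vertex(quad) else NULL,
    n = nrow(dat)
  )
}

#' Linear relationship between N2O flux and the log gene ratio
#'
#' Fits flux (ug N m-2 h-1) against log10 of the (nirK+nirS)/nosZI ratio.
#' A positive slope indicates that soils whose denitrifier community is
#' tilted towards N2O producers emit more N2O.
#'
#' @param records Ratio records from [gene_ratio_records()] (needs paired
#'   `n2o_flux` and `log10_ratio`).
#' @return A list: `fit` (linear `n2o_fit`), `slope`, `slope_sign`
#'   (`"positive"`, `"negative"` or `"zero"`), `n`.
#' @export
fit_flux_vs_ratio <- function(records) {
  stopifnot(is.data.frame(records))
  rec <- tibble::as_tibble(records)
  rec <- rec[!is.na(rec$log10_ratio) & !is.na(rec$n2o_flux), ]
  if (nrow(rec) < 3) {
    stop("need at least 3 paired flux/ratio records", call. = FALSE)
  }
  fit <- fit_polynomial(rec$log10_ratio, rec$n2o_flux, degree = 1)
  slope <- unname(fit$coefficients[["c1"]])
  list(
    fit = fit,
    slope = slope,
    slope_sign = if (slope > 0) "positive" else if (slope < 0) "negative" else "zero",
    n = nrow(rec)
  )
}
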