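#' @importFrom rlang .data
NULL

.field_required <- c("study_id", "ph_reported", "n_rate",
                     "emission_fertilized", "emission_control", "replicates")
.field_numeric <- c("latitude", "ph_reported", "n_rate",
                    "emission_fertilized", "emission_control", "replicates",
                    "map_mm", "mat_c", "soc", "tn",
                    "sand_pct", "silt_pct", "clay_pct")
.ecosystems <- c("cropland", "grassland", "forest")
.ph_media <- c("H2O", "CaCl2", "KCl", "unknown")

.gene_levels <- c("AOA_amoA", "AOB_amoA", "nirK", "nirS", "nosZI", "nosZII")

# case-insensitive synonyms for gene names as they appear in compiled tables
.gene_synonyms <- c(
  "aoa_amoa" = "AOA_amoA", "aoa" = "AOA_amoA", "amoa_aoa" = "AOA_amoA",
  "aob_amoa" = "AOB_amoA", "aob" = "AOB_amoA", "amoa_aob" = "AOB_amoA",
  "nirk" = "nirK", "nirs" = "nirS",
  "noszi" = "nosZI", "nosz clade i" = "nosZI", "nosz_i" = "nosZI",
  "nosz-i" = "nosZI", "nosz1" = "nosZI", "noszclade1" = "nosZI",
  "nosz" = "nosZI",
  "noszii" = "nosZII", "nosz clade ii" = "nosZII", "nosz_ii" = "nosZII",
  "nosz-ii" = "nosZII", "nosz2" = "nosZII"
)

.apply_overrides <- function(tbl, schema_overrides) {
  if (is.null(schema_overrides)) return(tbl)
  stopifnot(is.character(schema_overrides) || is.list(schema_overrides))
  ov <- unlist(schema_overrides)
  for (canonical in names(ov)) {
    if (ov[[canonical]] %in% names(tbl)) {
      names(tbl)[names(tbl) == ov[[canonical]]] <- canonical
    }
  }
  tbl
}

.as_num <- function(x) suppressWarnings(as.numeric(x))

.finish_read <- function(tbl, keep, reasons, strict, what) {
  rejects <- tibble::tibble(
    row = which(!keep),
    reason = reasons[!keep]
  )
  if (strict && nrow(rejects) > 0) {
    stop(nrow(rejects), " invalid ", what, " row(s); first problem (row ",
         rejects$row[1], "): ", rejects$reason[1], call. = FALSE)
  }
  structure(
    list(observations = tbl[keep, , drop = FALSE], rejects = rejects),
    class = "n2o_read"
  )
}

#' @export
print.n2o_read <- function(x, ...) {
  cat(sprintf("<n2o_read> %d accepted, %d rejected\n",
              nrow(x$observations), nrow(x$rejects)))
  if (nrow(x$rejects) > 0) {
    cat("  first reject: row", x$rejects$row[1], "-", x$rejects$reason[1], "\n")
  }
  invisible(x)
}

#' Read field fertilization-experiment observations from CSV
#'
#' Reads one observation per row: study identifiers, soil pH and its
#' measurement medium, N fertilization rate, cumulative N2O-N emissions of
#' the fertilized and control plots, replicate count, and optional site
#' covariates (latitude, ecosystem, MAP, MAT, SOC, TN, texture fractions).
#' Malformed rows are collected in a rejects table with a reason instead of
#' aborting the read; `strict = TRUE` turns any reject into an error.
#'
#' Required columns: `study_id`, `ph_reported`, `n_rate`,
#' `emission_fertilized`, `emission_control`, `replicates`. A missing
#' `ph_medium` column is treated as medium unknown for every row.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param schema_overrides Optional named vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(ph_reported = "soil_pH")`.
#' @param strict Upgrade row-level rejects to an error.
#' @return An object of class `n2o_read`: list with `observations`
#'   (validated tibble, row order preserved) and `rejects`
#'   (tibble of `row`, `reason`).
#' @export
read_field_observations <- function(path, schema_overrides = NULL,
                                    strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  tbl <- .apply_overrides(tbl, schema_overrides)
  miss <- setdiff(.field_required, names(tbl))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(.field_numeric, names(tbl))) tbl[[col]] <- .as_num(tbl[[col]])
  if (!"ph_medium" %in% names(tbl)) tbl$ph_medium <- "unknown"
  tbl$ph_medium[is.na(tbl$ph_medium) | tbl$ph_medium == ""] <- "unknown"
  if (!"site_id" %in% names(tbl)) tbl$site_id <- NA_character_
  if (!"latitude" %in% names(tbl)) tbl$latitude <- NA_real_
  if (!"ecosystem" %in% names(tbl)) tbl$ecosystem <- NA_character_
  tbl$ecosystem[tbl$ecosystem == ""] <- NA_character_
  for (col in setdiff(.field_numeric, names(tbl))) tbl[[col]] <- NA_real_

  n <- nrow(tbl)
  keep <- rep(TRUE, n)
  reasons <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- which(bad & keep)
    keep[bad] <<- FALSE
    reasons[bad] <<- why
  }
  flag(is.na(tbl$ph_reported), "ph_reported is missing or non-numeric")
  flag(!is.na(tbl$ph_reported) & (tbl$ph_reported <= 0 | tbl$ph_reported >= 14),
       "ph_reported outside (0, 14)")
  flag(is.na(tbl$n_rate), "n_rate is missing or non-numeric")
  flag(!is.na(tbl$n_rate) & tbl$n_rate < 0, "n_rate must be >= 0")
  flag(is.na(tbl$emission_fertilized) | is.na(tbl$emission_control),
       "emission values missing or non-numeric")
  flag(is.na(tbl$replicates) | tbl$replicates < 1 |
         tbl$replicates != round(tbl$replicates),
       "replicates must be a positive integer (replicates >= 1)")
  flag(!tbl$ph_medium %in% .ph_media,
       paste0("ph_medium must be one of ", paste(.ph_media, collapse = ", ")))
  flag(!is.na(tbl$ecosystem) & !tbl$ecosystem %in% .ecosystems,
       paste0("ecosystem must be one of ", paste(.ecosystems, collapse = ", ")))
  flag(!is.na(tbl$latitude) & abs(tbl$latitude) > 90,
       "latitude outside [-90, 90]")
  tex <- tbl$sand_pct + tbl$silt_pct + tbl$clay_pct
  flag(!is.na(tex) & abs(tex - 100) > 2,
       "sand + silt + clay must be within 100 +/- 2")

  tbl$replicates <- as.integer(tbl$replicates)
  .finish_read(tbl, keep, reasons, strict, "field-observation")
}

#' Read functional-gene abundance observations from CSV
#'
#' One row per gene quantification: `study_id`, `gene`, `copies_per_g`
#' (copies per gram of soil, linear scale, strictly positive), `ph_h2o` and
#' optionally `n2o_flux` (ug N m-2 h-1) and `ecosystem`. Gene names are
#' matched case-insensitively against common synonyms; in particular a bare
#' `nosZ` (and "nosZ clade I") maps to `nosZI`, since clade I is the form
#' quantified alongside N2O fluxes in nearly all field studies.
#'
#' @inheritParams read_field_observations
#' @return An `n2o_read` object whose `observations` tibble has a `gene`
#'   factor with levels AOA_amoA, AOB_amoA, nirK, nirS, nosZI, nosZII.
#' @export
read_gene_observations <- function(path, schema_overrides = NULL,
                                   strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  tbl <- .apply_overrides(tbl, schema_overrides)
  miss <- setdiff(c("study_id", "gene", "copies_per_g", "ph_h2o"), names(tbl))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(c("copies_per_g", "ph_h2o", "n2o_flux"), names(tbl))) {
    tbl[[col]] <- .as_num(tbl[[col]])
  }
  if (!"n2o_flux" %in% names(tbl)) tbl$n2o_flux <- NA_real_
  if (!"sample_id" %in% names(tbl)) tbl$sample_id <- tbl$study_id
  if (!"ecosystem" %in% names(tbl)) tbl$ecosystem <- NA_character_

  canon <- unname(.gene_synonyms[tolower(trimws(tbl$gene))])
  n <- nrow(tbl)
  keep <- rep(TRUE, n)
  reasons <- rep(NA_character_, n)
  flag <- function(bad, why) {
    bad <- which(bad & keep)
    keep[bad] <<- FALSE
    reasons[bad] <<- why
  }
  flag(is.na(canon), "unrecognised gene name")
  flag(is.na(tbl$copies_per_g) | tbl$copies_per_g <= 0,
       "copies_per_g must be a positive number")
  flag(is.na(tbl$ph_h2o) | tbl$ph_h2o <= 0 | tbl$ph_h2o >= 14,
       "ph_h2o missing or outside (0, 14)")
  tbl$gene <- factor(canon, levels = .gene_levels)
  .finish_read(tbl, keep, reasons, strict, "gene-observation")
}

#' Read closed-bottle incubation series from long-format CSV
#'
#' Expects one row per headspace sampling with columns `sample_id`,
#' `acetylene` (0/1 or logical), `time_h`, `ppm`, plus the per-bottle
#' constants `soil_dry_mass` (kg), `bottle_volume` (L) and `temperature_c`.
#' Optional `ph_h2o` is carried through. Rows are nested into one series
#' per (sample, acetylene) bottle with list-columns `timepoints` and
#' `headspace_ppm`.
#'
#' @inheritParams read_field_observations
#' @return An `n2o_read` object; `observations` has one row per bottle.
#'   Series-level problems (fewer than two timepoints, non-increasing
#'   times, negative ppm) reject the whole series.
#' @export
read_incubations <- function(path, schema_overrides = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  tbl <- .apply_overrides(tbl, schema_overrides)
  need <- c("sample_id", "acetylene", "time_h", "ppm", "soil_dry_mass",
            "bottle_volume", "temperature_c")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("time_h", "ppm", "soil_dry_mass", "bottle_volume",
                "temperature_c", if ("ph_h2o" %in% names(tbl)) "ph_h2o")) {
    tbl[[col]] <- .as_num(tbl[[col]])
  }
  if (!"ph_h2o" %in% names(tbl)) tbl$ph_h2o <- NA_real_
  tbl$acetylene <- tolower(trimws(tbl$acetylene)) %in% c("1", "true", "yes")

  nested <- tbl |>
    dplyr::group_by(.data$sample_id, .data$acetylene) |>
    dplyr::summarise(
      soil_dry_mass = .data$soil_dry_mass[1],
      bottle_volume = .data$bottle_volume[1],
      temperature_c = .data$temperature_c[1],
      ph_h2o = .data$ph_h2o[1],
      timepoints = list(.data$time_h[order(.data$time_h)]),
      headspace_ppm = list(.data$ppm[order(.data$time_h)]),
      .groups = "drop"
    )
  n <- nrow(nested)
  keep <- rep(TRUE, n)
  reasons <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tp <- nested$timepoints[[i]]
    pp <- nested$headspace_ppm[[i]]
    bad <- if (length(tp) < 2) {
      "a series needs at least two timepoints"
    } else if (anyNA(tp) || anyNA(pp)) {
      "non-numeric time or ppm value"
    } else if (any(diff(tp) <= 0)) {
      "timepoints must be strictly increasing (no duplicates)"
    } else if (any(pp < 0)) {
      "headspace ppm must be non-negative"
    } else if (is.na(nested$soil_dry_mass[i]) || nested$soil_dry_mass[i] <= 0) {
      "soil_dry_mass must be positive"
    } else if (is.na(nested$bottle_volume[i]) || nested$bottle_volume[i] <= 0) {
      "bottle_volume must be positive"
    } else {
      NA_character_
    }
    if (!is.na(bad)) {
      keep[i] <- FALSE
      reasons[i] <- bad
    }
  }
  .finish_read(nested, keep, reasons, strict, "incubation")
}

#' Write result tables to TSV files or a single JSON document
#'
#' TSV output writes one `<name>.tsv` per table into the directory `path`
#' (created if needed) with full-precision doubles, so a re-read reproduces
#' every numeric field. JSON output writes all tables into one document.
#'
#' @param tables Non-empty named list of data frames.
#' @param path Output directory (tsv) or file path (json).
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, the paths written.
#' @seealso [read_report()] for the inverse.
#' @export
write_report <- function(tables, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!is.list(tables) || length(tables) == 0 ||
      is.null(names(tables)) || any(names(tables) == "")) {
    stop("`tables` must be a non-empty named list of data frames",
         call. = FALSE)
  }
  stopifnot(all(vapply(tables, is.data.frame, logical(1))))
  if (format == "tsv") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- file.path(path, paste0(names(tables), ".tsv"))
    for (i in seq_along(tables)) {
      readr::write_tsv(tables[[i]], files[i])
    }
    invisible(files)
  } else {
    jsonlite::write_json(tables, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
    invisible(path)
  }
}

#' Read back a report written by [write_report()]
#'
#' @param path Directory of TSV files or a JSON file.
#' @param format `"tsv"` or `"json"`.
#' @return Named list of tibbles.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
    if (length(files) == 0) stop("no .tsv files in ", path, call. = FALSE)
    out <- lapply(files, readr::read_tsv, show_col_types = FALSE,
                  progress = FALSE)
    names(out) <- sub("\\.tsv$", "", basename(files))
    out
  } else {
    lapply(jsonlite::read_json(path, simplifyVector = TRUE),
           tibble::as_tibble)
  }
}
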