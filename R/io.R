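#' Read a bioreactor time series
#'
#' Reads `timeseries.csv` (columns `time_d`, `location`, `species`,
#' `value`, `unit`) and normalises every record to a COD basis:
#' `gCOD_L` and `gCOD` pass through, `g_L` is converted with the species'
#' molar mass and COD factor, and `mM` with the COD factor.  Species names
#' are resolved (and canonicalised) against the registry.
#'
#' @param path CSV file path.
#' @param registry Species registry for name resolution and unit
#'   conversion.
#' @return A tibble `(time_d, location, species, value, unit)` with
#'   `unit` in `{"gCOD_L", "gCOD"}` and canonical species names.
#' @export
read_timeseries <- function(path, registry = species_registry()) {
  ts <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          time_d = readr::col_double(),
                          location = readr::col_character(),
                          species = readr::col_character(),
                          value = readr::col_double(),
                          unit = readr::col_character()
                        ))
  if (nrow(ts) == 0) stop("empty input: ", path, call. = FALSE)
  needed <- c("time_d", "location", "species", "value", "unit")
  missing <- setdiff(needed, names(ts))
  if (length(missing) > 0) {
    stop("timeseries file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_loc <- !ts$location %in% c("broth", "extract_solution", "effluent")
  if (any(bad_loc)) {
    stop("unknown location in row(s) ",
         paste(utils::head(which(bad_loc), 5), collapse = ", "), call. = FALSE)
  }
  bad_unit <- !ts$unit %in% c("gCOD_L", "gCOD", "g_L", "mM")
  if (any(bad_unit)) {
    stop("unknown unit in row(s) ",
         paste(utils::head(which(bad_unit), 5), collapse = ", "), call. = FALSE)
  }
  known <- tryCatch(lookup_species(ts$species, registry),
                    error = function(e) stop(conditionMessage(e), call. = FALSE))
  ts$species <- known$name

  dup <- duplicated(ts[c("time_d", "location", "species")])
  if (any(dup)) {
    stop("duplicate timestamp for the same (location, species) in row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)
  }

  is_gl <- ts$unit == "g_L"
  if (any(is_gl)) {
    ts$value[is_gl] <- to_cod(ts$value[is_gl], "g_L", ts$species[is_gl], registry)
    ts$unit[is_gl] <- "gCOD_L"
  }
  is_mm <- ts$unit == "mM"
  if (any(is_mm)) {
    ts$value[is_mm] <- to_cod(ts$value[is_mm] / 1000, "mol_L",
                              ts$species[is_mm], registry)
    ts$unit[is_mm] <- "gCOD_L"
  }
  ts
}

#' Read an operating-period table
#'
#' Reads `periods.csv` (one row per operating period) and sanity-checks
#' the hydraulics: where both are given, `HRT * Q_feed` should equal the
#' working volume within 10% (a warning, not an error, since reported
#' HRTs are rounded).
#'
#' @param path CSV file path.
#' @return A tibble in the `periods.csv` schema.
#' @export
read_periods <- function(path) {
  per <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("period_id", "t_start_d", "t_end_d", "V_L")
  missing <- setdiff(needed, names(per))
  if (length(missing) > 0) {
    stop("periods file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(per$t_end_d <= per$t_start_d)) {
    stop("period t_end_d must exceed t_start_d", call. = FALSE)
  }
  if (all(c("HRT_d", "Q_feed_L_d") %in% names(per))) {
    implied <- per$HRT_d * per$Q_feed_L_d
    ok <- is.na(implied) | per$V_L == 0 |
      abs(implied - per$V_L) / per$V_L <= 0.10
    if (any(!ok)) {
      warning("HRT * Q_feed deviates from V by more than 10% for period(s) ",
              paste(per$period_id[!ok], collapse = ", "), call. = FALSE)
    }
  }
  per
}

#' Read a cross-study record table
#'
#' Reads `studies.csv`, the input to [predict_flux()].
#'
#' @param path CSV file path.
#' @return A tibble of study records.
#' @export
read_studies <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read an OTU count table and sample metadata
#'
#' `read_otu_counts()` reads a TSV with OTUs as rows: first column
#' `otu_id`, one column per sample.  `read_sample_metadata()` reads the
#' matching `(sample_id, day, productivity)` TSV; missing productivity
#' (inoculum, substrate samples) is allowed.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_otu_counts <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(counts)[1] != "otu_id") {
    stop("first column of an OTU count table must be otu_id", call. = FALSE)
  }
  m <- as.matrix(counts[-1])
  if (any(m < 0) || any(m != round(m))) {
    stop("OTU counts must be non-negative integers", call. = FALSE)
  }
  counts
}

#' @rdname read_otu_counts
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  missing <- setdiff(c("sample_id", "productivity"), names(meta))
  if (length(missing) > 0) {
    stop("metadata file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta
}

#' Write package tables
#'
#' Plain-CSV/TSV writers with fixed column order, `.` decimal separator,
#' UTF-8 and Unix newlines, so outputs are byte-identical across runs.
#'
#' @param x The table to write.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  readr::write_csv(x[c("time_d", "location", "species", "value", "unit")],
                   path, eol = "\n")
  invisible(path)
}

#' @rdname write_timeseries
#' @export
write_performance <- function(x, path) {
  cols <- c("period_id", "species", "extraction_rate_gCOD_d",
            "washout_rate_gCOD_d", "production_rate_gCOD_d",
            "productivity_gCOD_L_d", "flux_gCOD_m2_d", "specificity",
            "yield", "product_ratio_c8_c6")
  readr::write_csv(x[intersect(cols, names(x))], path, eol = "\n")
  invisible(path)
}

#' Render a period performance report
#'
#' Formats a [period_performance()] table the way operating summaries are
#' conventionally printed: rates and productivities to 1 decimal place,
#' product ratios to 1 decimal place, yields and specificities as integer
#' percentages; rows sorted by period then species, the lumped MCC row
#' last within each period.  Full precision is retained in the input; the
#' report is for humans and regression-stable files.
#'
#' @param performances A [period_performance()] tibble (at least one row).
#' @return A list with `table` (the rounded tibble, deterministic column
#'   order) and `text` (a character vector, one summary line per period).
#' @export
render_period_report <- function(performances) {
  stopifnot(is.data.frame(performances))
  if (nrow(performances) == 0) {
    cols <- c("period_id", "species", "extraction_rate_gCOD_d",
              "washout_rate_gCOD_d", "production_rate_gCOD_d",
              "productivity_gCOD_L_d", "flux_gCOD_m2_d", "specificity_pct",
              "yield_pct", "product_ratio_c8_c6")
    empty <- tibble::as_tibble(stats::setNames(rep(list(numeric(0)), length(cols)),
                                               cols))
    empty$species <- character(0)
    return(list(table = empty, text = character(0)))
  }
  tab <- performances |>
    dplyr::mutate(is_mcc = .data$species == "MCC") |>
    dplyr::arrange(.data$period_id, .data$is_mcc, .data$species) |>
    dplyr::mutate(
      extraction_rate_gCOD_d = round(.data$extraction_rate_gCOD_d, 1),
      washout_rate_gCOD_d = round(.data$washout_rate_gCOD_d, 1),
      production_rate_gCOD_d = round(.data$production_rate_gCOD_d, 1),
      productivity_gCOD_L_d = round(.data$productivity_gCOD_L_d, 1),
      flux_gCOD_m2_d = round(.data$flux_gCOD_m2_d, 1),
      specificity_pct = round(100 * .data$specificity),
      yield_pct = round(100 * .data$yield),
      product_ratio_c8_c6 = round(.data$product_ratio_c8_c6, 1)
    ) |>
    dplyr::select("period_id", "species", "extraction_rate_gCOD_d",
                  "washout_rate_gCOD_d", "production_rate_gCOD_d",
                  "productivity_gCOD_L_d", "flux_gCOD_m2_d",
                  "specificity_pct", "yield_pct", "product_ratio_c8_c6")

  mcc <- tab[tab$species == "MCC", ]
  text <- sprintf(
    "Period %s: MCC productivity %.1f g COD/L-d, yield %s%%, C8:C6 ratio %s",
    mcc$period_id, mcc$productivity_gCOD_L_d,
    ifelse(is.na(mcc$yield_pct), "-", mcc$yield_pct),
    ifelse(is.na(mcc$product_ratio_c8_c6), "-",
           format(mcc$product_ratio_c8_c6, nsmall = 1))
  )
  list(table = tab, text = text)
}
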