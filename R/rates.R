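#' Fit an extraction rate from cumulative trap amounts
#'
#' The in-line pertraction system accumulates extracted carboxylates in an
#' alkaline extraction solution.  Plotting the cumulative amount (g COD)
#' against time and taking the ordinary least-squares slope gives the
#' extraction rate M (g COD/d); the slope standard error and a 95%
#' t-based confidence interval quantify its uncertainty.
#'
#' A negative fitted slope is physically impossible for an accumulating
#' trap; it is returned as-is with a warning and `negative_slope = TRUE`
#' so upstream sampling problems stay diagnosable, never silently clamped.
#'
#' @param times Sampling times in days, strictly increasing.
#' @param amounts Cumulative amounts in the extraction solution, g COD.
#' @param species Optional species label carried into the result.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return An object of class `extraction_fit`: a list with `slope` (g
#'   COD/d), `slope_se`, `intercept`, `n`, `ci_half` (half-width of the
#'   confidence interval), `conf_level`, `negative_slope`, and `species`.
#'   `slope_se` is `NA` when fewer than 3 points leave no residual degrees
#'   of freedom.
#' @examples
#' fit_extraction_rate(c(0, 1, 2), c(0, 5, 10))
#' @export
fit_extraction_rate <- function(times, amounts, species = NULL,
                                conf_level = 0.95) {
  if (length(times) != length(amounts)) {
    stop("times and amounts must have equal length", call. = FALSE)
  }
  if (length(times) < 2) {
    stop("insufficient data: at least 2 points are required to fit an extraction rate",
         call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  fit <- stats::lm(amounts ~ times)
  cf <- stats::coef(fit)
  n <- length(times)
  if (n >= 3) {
    # closed-form slope SE (avoids summary.lm's perfect-fit warning on
    # noiseless synthetic series)
    s2 <- sum(stats::residuals(fit)^2) / (n - 2)
    se <- sqrt(s2 / sum((times - mean(times))^2))
    ci_half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2) * se
  } else {
    se <- NA_real_
    ci_half <- NA_real_
  }
  slope <- unname(cf["times"])
  if (slope < 0) {
    warning("fitted extraction slope is negative (", signif(slope, 4),
            " g COD/d); returned unclamped", call. = FALSE)
  }
  structure(
    list(
      species = species,
      slope = slope,
      slope_se = unname(se),
      intercept = unname(cf["(Intercept)"]),
      n = n,
      ci_half = unname(ci_half),
      conf_level = conf_level,
      negative_slope = slope < 0
    ),
    class = "extraction_fit"
  )
}

#' @export
print.extraction_fit <- function(x, ...) {
  cat("Extraction rate fit",
      if (!is.null(x$species)) paste0(" (", x$species, ")"), "\n", sep = "")
  cat(sprintf("  slope: %.4g g COD/d (SE %.3g, n = %d)\n",
              x$slope, x$slope_se, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.extraction_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se),
    conf.low = c(NA_real_, x$slope - x$ci_half),
    conf.high = c(NA_real_, x$slope + x$ci_half)
  )
}

#' @export
glance.extraction_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, slope_se = x$slope_se, intercept = x$intercept,
    n = x$n, ci_half = x$ci_half, conf_level = x$conf_level,
    negative_slope = x$negative_slope
  )
}

#' Carboxylate washout rate through the effluent
#'
#' Carboxylates leave the bioreactor by two routes: membrane extraction and
#' washout in the effluent.  The washout rate is the period-average broth
#' concentration multiplied by the effluent flow.
#'
#' @param mean_broth_concentration Average broth concentration, g COD/L.
#' @param Q_effluent Effluent flow rate, L/d.
#' @return Washout rate, g COD/d.
#' @examples
#' washout_rate(2.0, 4.0) # 8 g COD/d
#' @export
washout_rate <- function(mean_broth_concentration, Q_effluent) {
  if (any(mean_broth_concentration < 0) || any(Q_effluent < 0)) {
    stop("concentration and flow must be non-negative", call. = FALSE)
  }
  mean_broth_concentration * Q_effluent
}

#' Ethanol-to-non-ethanol substrate ratio
#'
#' Given the ethanol share of the substrate COD, returns the ratio of
#' ethanol COD to non-ethanol COD, `f / (1 - f)`.
#'
#' @param ethanol_cod_fraction Fraction of substrate COD that is ethanol,
#'   in `[0, 1)`.
#' @return Dimensionless COD ratio.
#' @examples
#' ethanol_substrate_ratio(0.40) # ~0.67, rounds to 0.7
#' @export
ethanol_substrate_ratio <- function(ethanol_cod_fraction) {
  if (any(ethanol_cod_fraction < 0 | ethanol_cod_fraction >= 1)) {
    stop("ethanol_cod_fraction must lie in [0, 1)", call. = FALSE)
  }
  ethanol_cod_fraction / (1 - ethanol_cod_fraction)
}

#' Volumetric COD rate of reduced gases
#'
#' Converts methane and hydrogen production (mol/d) into a volumetric COD
#' rate using their ThOD factors (CH4: 64, H2: 16 g COD/mol, both from
#' [thod()]).
#'
#' @param CH4_rate,H2_rate Gas production rates, mol/d.
#' @param V Working volume, L.
#' @return Gas COD rate, g COD/L-d.
#' @examples
#' gas_cod_rate(0.02, 0.08, 4.1)
#' @export
gas_cod_rate <- function(CH4_rate, H2_rate, V) {
  if (any(CH4_rate < 0) || any(H2_rate < 0)) {
    stop("gas rates must be non-negative", call. = FALSE)
  }
  if (any(V <= 0)) stop("V must be positive", call. = FALSE)
  (thod(1, 4, 0) * CH4_rate + thod(0, 2, 0) * H2_rate) / V
}

#' Upflow hydraulic velocity in the reactor column
#'
#' Volumetric flow through the column cross-section, converted to m/h for
#' comparison with typical upflow anaerobic sludge blanket operation
#' (0.7-1.0 m/h).
#'
#' @param Q Upward flow through the column, L/d.
#' @param inner_diameter Column inner diameter, m.
#' @return Upflow velocity, m/h.
#' @examples
#' upflow_velocity(323, 0.12) # ~1.2 m/h
#' @export
upflow_velocity <- function(Q, inner_diameter) {
  if (any(Q < 0)) stop("Q must be non-negative", call. = FALSE)
  if (any(inner_diameter <= 0)) stop("inner_diameter must be positive", call. = FALSE)
  area_m2 <- pi * (inner_diameter / 2)^2
  (Q / 1000) / area_m2 / 24
}

#' Period-level production mass balance
#'
#' For one operating period, combines per-species extraction rates (from
#' [fit_extraction_rate()] on the alkaline-trap series) with washout rates
#' (period-mean broth concentration times effluent flow) into the full
#' performance sheet:
#' production = extraction + washout (g COD/d), productivity = production /
#' V (g COD/L-d), flux = production / membrane area (g COD/m2-d),
#' specificity = production of a product over total product production,
#' MCC yield = lumped medium-chain productivity over the organic loading
#' rate, and the n-caprylate-to-n-caproate product ratio (COD basis).
#'
#' @param period A one-row data frame (or list) with at least `period_id`,
#'   `V_L`, `Q_effluent_L_d`, and `OLR_gCOD_L_d`.
#' @param fits A data frame with columns `species` and `extraction_rate`
#'   (g COD/d), or a list of `extraction_fit` objects.
#' @param mean_broth A data frame with columns `species` and
#'   `concentration` (period-mean broth concentration, g COD/L).
#' @param geometry A [contactor_geometry()] list (membrane area used for
#'   fluxes).
#' @param mcc_species Species lumped as "MCC" (default n-caproate +
#'   n-caprylate, COD basis; pass C7 explicitly if wanted).
#' @param registry Species registry, used to resolve species aliases.
#' @return A tibble with one row per species plus one lumped `"MCC"` row:
#'   `period_id`, `species`, `extraction_rate_gCOD_d`,
#'   `washout_rate_gCOD_d`, `production_rate_gCOD_d`,
#'   `productivity_gCOD_L_d`, `flux_gCOD_m2_d`, `specificity`, `yield`
#'   (MCC row only), `product_ratio_c8_c6` (MCC row only).  Species present
#'   in only one of `fits`/`mean_broth` get a zero for the missing route;
#'   species requested but absent everywhere are reported in the
#'   `missing_species` attribute rather than silently zeroed.
#' @examples
#' per <- list(period_id = 4L, V_L = 4.8, Q_effluent_L_d = 0.53,
#'             OLR_gCOD_L_d = 5.8)
#' fits <- data.frame(species = c("n-caproate", "n-caprylate"),
#'                    extraction_rate = c(8.7, 8.7))
#' broth <- data.frame(species = c("n-caproate", "n-caprylate"),
#'                     concentration = c(0.9, 0.25))
#' production_summary(per, fits, broth)
#' @export
production_summary <- function(period, fits, mean_broth,
                               geometry = contactor_geometry(),
                               mcc_species = c("n-caproate", "n-caprylate"),
                               registry = species_registry()) {
  if (is.data.frame(period)) period <- as.list(period[1, ])
  V <- period$V_L
  if (is.null(V) || !is.finite(V) || V <= 0) {
    stop("period must carry a positive working volume V_L", call. = FALSE)
  }
  Q_eff <- period$Q_effluent_L_d %||% 0
  olr <- period$OLR_gCOD_L_d %||% NA_real_

  if (!is.data.frame(fits)) {
    fits <- purrr::map_dfr(fits, function(f) {
      tibble::tibble(species = f$species %||% NA_character_,
                     extraction_rate = f$slope)
    })
  }
  canon <- function(x) lookup_species(x, registry)$name
  ext <- tibble::tibble(species = canon(fits$species),
                        extraction = fits$extraction_rate)
  wash <- tibble::tibble(species = canon(mean_broth$species),
                         washout = washout_rate(mean_broth$concentration, Q_eff))

  tab <- dplyr::full_join(ext, wash, by = "species") |>
    dplyr::mutate(
      extraction = dplyr::coalesce(.data$extraction, 0),
      washout = dplyr::coalesce(.data$washout, 0),
      production = .data$extraction + .data$washout
    )

  mcc_species <- canon(mcc_species)
  missing <- setdiff(mcc_species, tab$species)

  # ethanol is the substrate, not a fermentation product
  products <- tab[tab$species != "ethanol", , drop = FALSE]
  total_production <- sum(products$production)

  lumped <- tab[tab$species %in% mcc_species, , drop = FALSE]
  mcc <- tibble::tibble(
    species = "MCC",
    extraction = sum(lumped$extraction),
    washout = sum(lumped$washout),
    production = sum(lumped$production)
  )

  out <- dplyr::bind_rows(tab, mcc) |>
    dplyr::mutate(
      period_id = period$period_id %||% NA,
      productivity = .data$production / V,
      flux = .data$production / geometry$A_transfer,
      specificity = dplyr::if_else(
        .data$species == "ethanol", NA_real_,
        .data$production / total_production
      )
    )

  mcc_yield <- if (is.finite(olr)) {
    if (olr == 0 && mcc$production > 0) {
      stop("OLR is zero: MCC yield is undefined for period ",
           period$period_id %||% "?", call. = FALSE)
    }
    (mcc$production / V) / olr
  } else {
    NA_real_
  }
  c8 <- tab$production[tab$species == "n-caprylate"]
  c6 <- tab$production[tab$species == "n-caproate"]
  ratio <- if (length(c8) == 1 && length(c6) == 1 && c6 > 0) c8 / c6 else NA_real_

  out <- out |>
    dplyr::mutate(
      yield = dplyr::if_else(.data$species == "MCC", mcc_yield, NA_real_),
      product_ratio_c8_c6 = dplyr::if_else(.data$species == "MCC", ratio, NA_real_)
    ) |>
    dplyr::select("period_id", "species",
                  extraction_rate_gCOD_d = "extraction",
                  washout_rate_gCOD_d = "washout",
                  production_rate_gCOD_d = "production",
                  productivity_gCOD_L_d = "productivity",
                  flux_gCOD_m2_d = "flux",
                  "specificity", "yield", "product_ratio_c8_c6")
  attr(out, "missing_species") <- missing
  out
}

#' Period performance from raw time series
#'
#' High-level driver: for every operating period, fits per-species
#' extraction rates from the cumulative alkaline-trap series, averages the
#' broth concentrations over the period window, and assembles the
#' [production_summary()] mass balance.  Period windows are
#' `[t_start, t_end]` inclusive of boundary samples.
#'
#' @param timeseries A tibble in the `timeseries.csv` schema: columns
#'   `time_d`, `location` (`"broth"`, `"extract_solution"`, or
#'   `"effluent"`), `species`, `value` (g COD/L for broth/effluent,
#'   cumulative g COD for the extraction solution).
#' @param periods A tibble in the `periods.csv` schema (one row per
#'   period; see [read_periods()]).
#' @inheritParams production_summary
#' @return A tibble of per-(period, species) performance rows (see
#'   [production_summary()]), sorted by period start time.
#' @examples
#' sim <- simulate_reactor(simulation_config(noise_cv = 0, seed = 1))
#' period_performance(sim$timeseries, sim$periods)
#' @export
period_performance <- function(timeseries, periods,
                               geometry = contactor_geometry(),
                               mcc_species = c("n-caproate", "n-caprylate"),
                               registry = species_registry()) {
  stopifnot(is.data.frame(timeseries), is.data.frame(periods))
  periods <- dplyr::arrange(periods, .data$t_start_d)
  purrr::map_dfr(seq_len(nrow(periods)), function(i) {
    per <- periods[i, ]
    win <- timeseries[timeseries$time_d >= per$t_start_d &
                        timeseries$time_d <= per$t_end_d, ]
    trap <- win[win$location == "extract_solution", ]
    fits <- trap |>
      dplyr::group_by(.data$species) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::summarise(
        extraction_rate = fit_extraction_rate(.data$time_d, .data$value)$slope,
        .groups = "drop"
      )
    broth <- win[win$location == "broth", ] |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(concentration = mean(.data$value), .groups = "drop")
    production_summary(per, fits, broth, geometry = geometry,
                       mcc_species = mcc_species, registry = registry)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
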