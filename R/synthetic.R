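# run code under a dedicated RNG stream without disturbing the caller's RNG
with_stream_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default operating-period schedule for the simulator
#'
#' Four semi-continuously fed periods with continuous in-line extraction,
#' spanning days 17-84: working volume 4.8 L, HRT 9 d, organic loading
#' rate 6 g COD/L-d, and broth-recycle rates stepped 9 -> 86 -> 323 -> 228
#' L/d so the superficial velocity sweeps the range over which the k-u
#' correlation is identifiable.
#'
#' @return A tibble in the `periods.csv` schema.
#' @export
default_period_schedule <- function() {
  tibble::tibble(
    period_id = 2:5,
    phase = "II",
    t_start_d = c(17, 38, 58, 74),
    t_end_d = c(38, 58, 74, 84),
    V_L = 4.8,
    HRT_d = 9,
    OLR_gCOD_L_d = 6,
    Q_feed_L_d = 4.8 / 9,
    Q_effluent_L_d = 4.8 / 9,
    Q_recycle_L_d = c(9, 86, 323, 228),
    ethanol_cod_fraction = 0.4,
    inner_diameter_m = 0.12
  )
}

#' Default planted production rates
#'
#' Piecewise-constant true production rates per period and species
#' (g COD/d).  Medium-chain production rises with the broth-recycle rate
#' and the n-caprylate share grows with it, peaking at a 1:1 C8:C6 split;
#' minor acetate and n-butyrate production is included so specificities
#' are non-trivial.
#'
#' @param periods A period schedule (used for ids and volumes).
#' @return A tibble `(period_id, species, rate_gCOD_d)`.
#' @export
default_production_rates <- function(periods = default_period_schedule()) {
  v <- periods$V_L
  mcc_prod <- c(0.6, 1.6, 3.9, 3.3)     # g COD/L-d, lumped C6 + C8
  ratio <- c(0.3, 0.5, 1.0, 0.8)        # C8:C6, COD basis
  c6 <- mcc_prod / (1 + ratio) * v
  c8 <- mcc_prod * ratio / (1 + ratio) * v
  tibble::tibble(
    period_id = rep(periods$period_id, each = 4),
    species = rep(c("n-caproate", "n-caprylate", "acetate", "n-butyrate"),
                  times = nrow(periods)),
    rate_gCOD_d = as.numeric(rbind(c6, c8, 1.0 * v, 0.5 * v))
  )
}

#' Simulation configuration
#'
#' Bundles everything the reactor simulator needs: the period schedule,
#' planted per-period production rates, the true k-u line, contactor
#' geometry, broth pH, measurement noise, and the sampling interval.
#' A fixed seed makes the output byte-identical across runs.
#'
#' @param periods Period schedule tibble ([default_period_schedule()]).
#' @param production_rates Planted rates tibble
#'   ([default_production_rates()]).
#' @param ku Named vector `c(slope =, intercept =)` of the true k-u line
#'   (k mm/d, u m/d).
#' @param geometry A [contactor_geometry()].
#' @param pH Broth pH (default 5.2, the controlled set point).
#' @param extract_species Species subject to membrane extraction (default
#'   the medium-chain acids n-caproate and n-caprylate; the hydrophobic
#'   solvent extracts short-chain acids far more slowly, approximated here
#'   as not at all).
#' @param noise_cv Multiplicative measurement noise CV (default 0.05,
#'   GC-like relative error; 0 for noiseless truth).
#' @param dt Sampling interval, d (default 2: samples are placed at
#'   midpoints `t_start + dt/2, t_start + 3 dt/2, ...` so every sample
#'   lies strictly inside one period window).
#' @param init `"steady_state"` (default) starts each period at its own
#'   steady state, emulating the quasi-steady per-period operation that
#'   period-average rate estimates assume; `"continue"` carries the broth
#'   state across period boundaries; `"zero"` starts the run empty.
#' @param seed Master seed; per-stream seeds are derived from it by fixed
#'   offsets (broth +11, trap +23) so regenerating one stream never
#'   perturbs another.
#' @param registry Species registry.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(periods = default_period_schedule(),
                              production_rates = default_production_rates(periods),
                              ku = c(slope = 0.24, intercept = 1.31),
                              geometry = contactor_geometry(),
                              pH = 5.2,
                              extract_species = c("n-caproate", "n-caprylate"),
                              noise_cv = 0.05,
                              dt = 2,
                              init = c("steady_state", "continue", "zero"),
                              seed = 1L,
                              registry = species_registry()) {
  init <- match.arg(init)
  stopifnot(noise_cv >= 0, dt > 0, all(c("slope", "intercept") %in% names(ku)))
  structure(
    list(periods = periods, production_rates = production_rates,
         ku = ku, geometry = geometry, pH = pH,
         extract_species = lookup_species(extract_species, registry)$name,
         noise_cv = noise_cv, dt = dt, init = init, seed = as.integer(seed),
         registry = registry),
    class = "simulation_config"
  )
}

#' Simulate a chain-elongation bioreactor with in-line pertraction
#'
#' Integrates, per species, the broth COD balance
#' `V dC/dt = production - extraction - washout` with
#' `extraction = k(u) * A_transfer * f_undiss * C` (k from the planted k-u
#' line; f_undiss the Henderson-Hasselbalch undissociated fraction at the
#' broth pH) and `washout = Q_effluent * C`, by explicit forward Euler
#' with automatic sub-stepping; the alkaline trap accumulates every
#' extracted gram of COD.  Multiplicative Gaussian measurement noise
#' (truncated at zero) is applied to the emitted broth and trap series;
#' the returned truth record and COD balance are noiseless.
#'
#' @param config A [simulation_config()].
#' @return A list of class `reactor_simulation`:
#'   * `timeseries`: tibble in the `timeseries.csv` schema (`time_d`,
#'     `location` (`broth` / `extract_solution`), `species`, `value`,
#'     `unit`),
#'   * `periods`: the period schedule used,
#'   * `truth`: per-period planted values (`u`, `k`, steady-state
#'     concentrations, extraction/washout/production rates) and the
#'     planted k-u line,
#'   * `balance`: per-period COD balance (fed = delta broth + extracted +
#'     washed out) from the noiseless integrator.
#' @examples
#' sim <- simulate_reactor(simulation_config(noise_cv = 0, seed = 1))
#' head(sim$timeseries)
#' sim$balance
#' @export
simulate_reactor <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  periods <- dplyr::arrange(config$periods, .data$t_start_d)
  species <- unique(config$production_rates$species)
  sp_info <- lookup_species(species, config$registry)
  f_undiss <- ifelse(is.na(sp_info$pKa), 1,
                     undissociated_fraction(config$pH, sp_info$pKa))
  names(f_undiss) <- sp_info$name
  extract_on <- stats::setNames(sp_info$name %in% config$extract_species,
                                sp_info$name)
  A <- config$geometry$A_transfer

  C <- stats::setNames(rep(0, length(species)), sp_info$name)
  trap <- stats::setNames(rep(0, length(species)), sp_info$name)
  rows <- list()
  truth_rows <- list()
  balance_rows <- list()
  substeps_used <- integer(0)

  for (i in seq_len(nrow(periods))) {
    per <- periods[i, ]
    u <- superficial_velocity(per$Q_recycle_L_d, config$geometry$A_cross)
    k <- max(0, config$ku[["slope"]] * u + config$ku[["intercept"]])
    P <- stats::setNames(rep(0, length(species)), sp_info$name)
    pr <- config$production_rates[config$production_rates$period_id == per$period_id, ]
    P[lookup_species(pr$species, config$registry)$name] <- pr$rate_gCOD_d

    lambda <- (k * A * f_undiss * extract_on + per$Q_effluent_L_d) / per$V_L
    if (config$init == "steady_state") {
      C <- ifelse(lambda > 0, P / (lambda * per$V_L), 0)
    } else if (config$init == "zero" && i == 1) {
      C <- C * 0
    }

    # forward Euler with sub-stepping: keep the per-step loss below 20%
    sample_times <- seq(per$t_start_d + config$dt / 2, per$t_end_d,
                        by = config$dt)
    # keep every sample strictly inside the period window so each sample
    # belongs to exactly one period
    sample_times <- sample_times[sample_times < per$t_end_d - 1e-9]
    n_sub <- max(1L, ceiling(config$dt * max(lambda) * 5))
    substeps_used <- c(substeps_used, n_sub)
    fed <- ext <- wash <- 0
    C_start <- C
    t <- per$t_start_d
    for (ts in c(sample_times, per$t_end_d)) {
      while (t < ts - 1e-12) {
        h <- min(config$dt / n_sub, ts - t)
        repeat {
          E <- k * A * f_undiss * extract_on * C
          W <- per$Q_effluent_L_d * C
          C_new <- C + h * (P - E - W) / per$V_L
          if (all(C_new >= 0)) break
          h <- h / 2 # automatic sub-stepping near depletion
        }
        fed <- fed + sum(P) * h
        ext <- ext + sum(E) * h
        wash <- wash + sum(W) * h
        trap <- trap + E * h
        C <- C_new
        t <- t + h
      }
      if (ts %in% sample_times) {
        rows[[length(rows) + 1]] <- dplyr::bind_rows(
          tibble::tibble(time_d = ts, location = "broth",
                         species = names(C), value = unname(C),
                         unit = "gCOD_L"),
          tibble::tibble(time_d = ts, location = "extract_solution",
                         species = names(trap)[extract_on],
                         value = unname(trap[extract_on]), unit = "gCOD")
        )
      }
    }
    balance_rows[[i]] <- tibble::tibble(
      period_id = per$period_id,
      fed_gCOD = fed,
      delta_broth_gCOD = sum((C - C_start) * per$V_L),
      extracted_gCOD = ext,
      washed_out_gCOD = wash
    )
    truth_rows[[i]] <- tibble::tibble(
      period_id = per$period_id, u_m_d = u, k_mm_d = k,
      species = names(P), production_gCOD_d = unname(P),
      steady_state_gCOD_L = unname(ifelse(lambda > 0, P / (lambda * per$V_L), NA)),
      extraction_gCOD_d = unname(k * A * f_undiss * extract_on *
                                   ifelse(lambda > 0, P / (lambda * per$V_L), 0)),
      washout_gCOD_d = unname(per$Q_effluent_L_d *
                                ifelse(lambda > 0, P / (lambda * per$V_L), 0))
    )
  }

  timeseries <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$time_d, .data$location, .data$species)

  if (config$noise_cv > 0) {
    is_broth <- timeseries$location == "broth"
    timeseries$value[is_broth] <- with_stream_seed(config$seed + 11L, {
      timeseries$value[is_broth] *
        pmax(0, 1 + config$noise_cv * stats::rnorm(sum(is_broth)))
    })
    is_trap <- !is_broth
    timeseries$value[is_trap] <- with_stream_seed(config$seed + 23L, {
      timeseries$value[is_trap] *
        pmax(0, 1 + config$noise_cv * stats::rnorm(sum(is_trap)))
    })
  }

  structure(
    list(
      timeseries = timeseries,
      periods = periods,
      truth = list(
        ku = config$ku, pH = config$pH,
        per_period = dplyr::bind_rows(truth_rows),
        config = config
      ),
      balance = dplyr::bind_rows(balance_rows),
      substeps = substeps_used
    ),
    class = "reactor_simulation"
  )
}

#' @export
print.reactor_simulation <- function(x, ...) {
  cat("Simulated pertraction bioreactor:", nrow(x$periods), "periods,",
      nrow(x$timeseries), "measurements\n")
  cat(sprintf("  planted k-u line: k = %.3g u + %.3g\n",
              x$truth$ku[["slope"]], x$truth$ku[["intercept"]]))
  invisible(x)
}

#' OTU-table simulation configuration
#'
#' @param n_samples Number of bioreactor samples with productivity
#'   metadata (default 7, one per semi-continuous sampling point).
#' @param n_otus Number of OTUs (default 50).
#' @param productivity Per-sample MCC productivity, g COD/L-d (default: a
#'   rising trajectory peaking with the highest broth-recycle rate).
#' @param days Collection days for the metadata (same length as
#'   `productivity`).
#' @param planted_otu Index of the OTU whose abundance tracks
#'   productivity (default 1).
#' @param rho Target Pearson correlation between the planted OTU's
#'   relative abundance and productivity, in `[-1, 1]` (default 0.9).
#' @param depth Sequencing depth per sample (default 1e4).
#' @param dirichlet_conc Concentration vector for the background
#'   community (default: a power-law ranked profile summing to 100; larger
#'   totals mean less compositional noise).
#' @param planted_mean,planted_cv Mean relative abundance of the planted
#'   OTU and the relative spread of its productivity-tracking signal.
#' @param seed Master seed (streams: signal +31, background +47,
#'   counts +59).
#' @return A list of class `otu_sim_config`.
#' @export
otu_sim_config <- function(n_samples = 7, n_otus = 50,
                           productivity = c(0.4, 0.7, 1.2, 2.0, 2.8, 3.9, 3.2),
                           days = c(20, 31, 45, 56, 64, 74, 84),
                           planted_otu = 1L, rho = 0.9, depth = 1e4,
                           dirichlet_conc = NULL,
                           planted_mean = 0.1, planted_cv = 0.5,
                           seed = 1L) {
  stopifnot(rho >= -1, rho <= 1, depth > 0, n_otus >= 2)
  if (length(productivity) != n_samples || length(days) != n_samples) {
    stop("productivity and days must have length n_samples", call. = FALSE)
  }
  if (is.null(dirichlet_conc)) {
    dirichlet_conc <- 100 * (1 / seq_len(n_otus - 1)) / sum(1 / seq_len(n_otus - 1))
  }
  structure(
    list(n_samples = n_samples, n_otus = n_otus, productivity = productivity,
         days = days, planted_otu = as.integer(planted_otu), rho = rho,
         depth = depth, dirichlet_conc = dirichlet_conc,
         planted_mean = planted_mean, planted_cv = planted_cv,
         seed = as.integer(seed)),
    class = "otu_sim_config"
  )
}

#' Simulate an OTU count table with a planted productivity signal
#'
#' The planted OTU's expected relative abundance is an increasing affine
#' function of the standardised productivity, mixed with independent
#' Gaussian noise in the ratio `rho : sqrt(1 - rho^2)` so its latent
#' correlation with productivity equals the target `rho`; the background
#' community is an independent Dirichlet draw per sample; counts are a
#' multinomial draw at the configured depth.  Expected proportions are
#' truncated into `[1e-6, 0.95]`; when truncation bites, the achievable
#' correlation actually realised is reported in the truth record
#' (`achieved_latent_rho`) rather than failing silently.
#'
#' @param config An [otu_sim_config()].
#' @return A list of class `otu_simulation`: `counts` (tibble, `otu_id` +
#'   one column per sample), `metadata` (`sample_id`, `day`,
#'   `productivity`), and `truth` (planted OTU id, target and achieved
#'   latent correlation, expected proportions, truncated-sample count).
#' @examples
#' sim <- simulate_otu_table(otu_sim_config(seed = 42))
#' correlate_otus(sim$counts, sim$metadata)
#' @export
simulate_otu_table <- function(config) {
  stopifnot(inherits(config, "otu_sim_config"))
  n <- config$n_samples
  z <- as.numeric(scale(config$productivity))
  eps <- with_stream_seed(config$seed + 31L, stats::rnorm(n))
  latent <- config$rho * z + sqrt(1 - config$rho^2) * eps
  p_raw <- config$planted_mean * (1 + config$planted_cv * latent)
  p_planted <- pmin(pmax(p_raw, 1e-6), 0.95)
  n_truncated <- sum(p_planted != p_raw)

  others <- with_stream_seed(config$seed + 47L, {
    g <- matrix(stats::rgamma(n * (config$n_otus - 1),
                              shape = rep(config$dirichlet_conc, each = n)),
                nrow = n)
    g / rowSums(g)
  })

  probs <- matrix(0, nrow = n, ncol = config$n_otus)
  probs[, config$planted_otu] <- p_planted
  probs[, -config$planted_otu] <- others * (1 - p_planted)

  counts_m <- with_stream_seed(config$seed + 59L, {
    t(apply(probs, 1, function(p) stats::rmultinom(1, size = config$depth, prob = p)))
  })

  otu_ids <- sprintf("OTU_%03d", seq_len(config$n_otus))
  sample_ids <- sprintf("BR_d%02d", config$days)
  counts <- tibble::as_tibble(stats::setNames(as.data.frame(t(counts_m)),
                                              sample_ids))
  counts <- dplyr::bind_cols(tibble::tibble(otu_id = otu_ids), counts)

  structure(
    list(
      counts = counts,
      metadata = tibble::tibble(sample_id = sample_ids, day = config$days,
                                productivity = config$productivity),
      truth = list(
        planted_otu = otu_ids[config$planted_otu],
        target_rho = config$rho,
        achieved_latent_rho = if (stats::sd(p_planted) > 0) {
          stats::cor(p_planted, config$productivity)
        } else {
          NA_real_
        },
        expected_proportion = p_planted,
        n_truncated = n_truncated
      )
    ),
    class = "otu_simulation"
  )
}

#' Re-estimate the k-u line from a simulated or measured time series
#'
#' The full analysis pipeline in one call: per period, fit the extraction
#' rate of the lumped medium-chain acids from the cumulative trap series,
#' average the broth concentrations, convert them to undissociated
#' concentrations at the broth pH (the trap-side concentration is taken as
#' zero, the high-pH approximation), form the overall mass transfer
#' coefficient `k = M / (A_transfer * C_undiss)`, and regress k on the
#' superficial velocity.
#'
#' @param timeseries Tibble in the `timeseries.csv` schema.
#' @param periods Period schedule tibble.
#' @param geometry A [contactor_geometry()].
#' @param pH Broth pH used for speciation (default 5.2).
#' @param mcc_species Lumped extracted species (default C6 + C8).
#' @param registry Species registry.
#' @return A list: `period_estimates` (tibble with `period_id`, `u_m_d`,
#'   `M_gCOD_d`, `M_se`, `C_undiss_gCOD_L`, `k_mm_d`) and `model` (the
#'   fitted [fit_ku()] line).
#' @examples
#' sim <- simulate_reactor(simulation_config(noise_cv = 0))
#' estimate_ku(sim$timeseries, sim$periods)$model
#' @export
estimate_ku <- function(timeseries, periods,
                        geometry = contactor_geometry(), pH = 5.2,
                        mcc_species = c("n-caproate", "n-caprylate"),
                        registry = species_registry()) {
  mcc_species <- lookup_species(mcc_species, registry)$name
  sp <- lookup_species(mcc_species, registry)
  fu <- undissociated_fraction(pH, sp$pKa)
  names(fu) <- sp$name

  est <- purrr::map_dfr(seq_len(nrow(periods)), function(i) {
    per <- periods[i, ]
    win <- timeseries[timeseries$time_d >= per$t_start_d &
                        timeseries$time_d <= per$t_end_d, ]
    trap <- win[win$location == "extract_solution" &
                  win$species %in% mcc_species, ] |>
      dplyr::group_by(.data$time_d) |>
      dplyr::summarise(amount = sum(.data$value), .groups = "drop")
    fit <- fit_extraction_rate(trap$time_d, trap$amount, species = "MCCA")
    broth <- win[win$location == "broth" & win$species %in% mcc_species, ] |>
      dplyr::group_by(.data$species) |>
      dplyr::summarise(concentration = mean(.data$value), .groups = "drop")
    c_undiss <- sum(broth$concentration * fu[broth$species])
    tibble::tibble(
      period_id = per$period_id,
      u_m_d = superficial_velocity(per$Q_recycle_L_d, geometry$A_cross),
      M_gCOD_d = fit$slope,
      M_se = fit$slope_se,
      C_undiss_gCOD_L = c_undiss,
      k_mm_d = mass_transfer_coefficient(fit$slope, geometry$A_transfer,
                                         gradient_approximation(c_undiss,
                                                                approximate = TRUE))
    )
  })
  list(period_estimates = est,
       model = fit_ku(data.frame(u = est$u_m_d, k = est$k_mm_d)))
}
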