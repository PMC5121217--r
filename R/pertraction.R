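#' Membrane contactor geometry
#'
#' Defaults are the hollow-fiber forward membrane contactor used for
#' in-line pertraction: 1.4 m2 of membrane transfer area and a shell
#' cross-sectional area of 1.56e-3 m2.
#'
#' @param A_transfer Membrane surface area, m2.
#' @param A_cross Shell cross-sectional area, m2.
#' @return A list with class `contactor_geometry`.
#' @examples
#' contactor_geometry()
#' @export
contactor_geometry <- function(A_transfer = 1.4, A_cross = 1.56e-3) {
  if (A_transfer <= 0 || A_cross <= 0) {
    stop("contactor areas must be positive", call. = FALSE)
  }
  structure(list(A_transfer = A_transfer, A_cross = A_cross),
            class = "contactor_geometry")
}

#' Broth-recycle superficial velocity through the contactor shell
#'
#' The broth-recycle flow divided by the shell cross-sectional area.  This
#' is the speed at which broth sweeps past the membrane surface; higher
#' velocities increase turbulence and lower the resistance to carboxylic
#' acid transfer across the membrane.
#'
#' @param Q_recycle Broth-recycle flow rate, L/d.
#' @param A_cross Shell cross-sectional area, m2 (default 1.56e-3).
#' @return Superficial velocity, m/d.
#' @examples
#' superficial_velocity(323) # ~207 m/d
#' @export
superficial_velocity <- function(Q_recycle, A_cross = 1.56e-3) {
  if (any(Q_recycle < 0)) stop("Q_recycle must be non-negative", call. = FALSE)
  if (any(A_cross <= 0)) stop("A_cross must be positive", call. = FALSE)
  (Q_recycle / 1000) / A_cross
}

#' Overall mass transfer coefficient
#'
#' `k = M / (A_transfer * delta_C)`: the extraction rate per unit membrane
#' area per unit concentration gradient of undissociated medium-chain
#' carboxylic acids.  The resulting unit, L m-2 d-1, is numerically
#' identical to mm/d (1 L spread over 1 m2 is a 1-mm film), which is how k
#' is reported.
#'
#' @param M Extraction rate, g COD/d.
#' @param A_transfer Membrane surface area, m2.
#' @param delta_C Concentration gradient of undissociated acids across the
#'   membrane, g COD/L.  Must be positive; a zero gradient leaves k
#'   undefined.
#' @return k in mm/d.
#' @examples
#' mass_transfer_coefficient(17.85, 1.4, 0.25) # 51 mm/d
#' @export
mass_transfer_coefficient <- function(M, A_transfer = 1.4, delta_C) {
  if (any(A_transfer <= 0)) stop("A_transfer must be positive", call. = FALSE)
  if (any(delta_C <= 0)) {
    stop("undefined coefficient: concentration gradient must be positive",
         call. = FALSE)
  }
  M / (A_transfer * delta_C)
}

#' Concentration gradient across the forward membrane
#'
#' The driving force for extraction is the difference between undissociated
#' acid concentrations in the broth and in the alkaline extraction
#' solution.  Because the alkaline solution (pH 9) holds essentially no
#' undissociated acid, the gradient is conventionally approximated by the
#' broth concentration alone; set `approximate = TRUE` for that convention.
#'
#' @param C_broth_undiss Undissociated acid concentration in the broth,
#'   g COD/L.
#' @param C_extract_undiss Undissociated acid concentration in the
#'   extraction solution, g COD/L (default 0).
#' @param approximate If `TRUE`, return `C_broth_undiss` (the high-pH trap
#'   approximation); if `FALSE` (default), the exact difference.
#' @return Gradient, g COD/L.
#' @examples
#' gradient_approximation(0.25, 0.01)                     # 0.24
#' gradient_approximation(0.25, 0.01, approximate = TRUE) # 0.25
#' @export
gradient_approximation <- function(C_broth_undiss, C_extract_undiss = 0,
                                   approximate = FALSE) {
  if (any(C_broth_undiss < 0) || any(C_extract_undiss < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (approximate) C_broth_undiss else C_broth_undiss - C_extract_undiss
}

#' Fit the linear k-u mass-transfer correlation
#'
#' Ordinary least-squares fit of the overall mass transfer coefficient
#' (mm/d) against the broth-recycle superficial velocity (m/d), the
#' operating relationship that governs how much recycle pumping improves
#' in-line extraction.  The fit is unweighted and includes an intercept.
#'
#' @param points A data frame with columns `u` (m/d) and `k` (mm/d), e.g.
#'   one row per operating period.
#' @return An object of class `ku_model` with `slope` (mm/d per m/d),
#'   `intercept` (mm/d), `r_squared`, `n`, the fitted-u range, and the
#'   underlying `lm` fit.
#' @examples
#' pts <- data.frame(u = c(6, 55, 207, 146), k = 0.24 * c(6, 55, 207, 146) + 1.31)
#' fit_ku(pts)
#' @export
fit_ku <- function(points) {
  stopifnot(is.data.frame(points), all(c("u", "k") %in% names(points)))
  if (nrow(points) < 2 || length(unique(points$u)) < 2) {
    stop("singular fit: at least 2 distinct superficial velocities are required",
         call. = FALSE)
  }
  if (any(points$u < 0) || any(points$k < 0)) {
    stop("u and k must be non-negative", call. = FALSE)
  }
  fit <- stats::lm(k ~ u, data = points)
  cf <- stats::coef(fit)
  ss_tot <- sum((points$k - mean(points$k))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  new_ku_model(
    slope = unname(cf["u"]), intercept = unname(cf["(Intercept)"]),
    r_squared = r2, n = nrow(points),
    u_range = range(points$u), fit = fit, source = "fitted"
  )
}

new_ku_model <- function(slope, intercept, r_squared = NA_real_, n = NA_integer_,
                         u_range = c(NA_real_, NA_real_), fit = NULL,
                         source = "fitted") {
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         n = n, u_range = u_range, fit = fit, source = source),
    class = "ku_model"
  )
}

#' The published k-u correlation
#'
#' The linear correlation `k = 0.24 u + 1.31` (k in mm/d, u in m/d)
#' established over broth-recycle superficial velocities of roughly 6-207
#' m/d for lumped n-caproic + n-caprylic acid extraction on a COD basis.
#' Ships as a packaged constant so fluxes can be predicted for external
#' study records when no local fit is available.
#'
#' @return A `ku_model` with slope 0.24 and intercept 1.31.
#' @examples
#' predict_k(published_ku_model(), 207) # ~51 mm/d
#' @export
published_ku_model <- function() {
  new_ku_model(slope = 0.24, intercept = 1.31, n = 4L,
               u_range = c(5.77, 207.05), source = "published")
}

#' @export
print.ku_model <- function(x, ...) {
  cat(sprintf("k-u mass-transfer model (%s): k = %.4g u + %.4g  [k mm/d, u m/d]\n",
              x$source, x$slope, x$intercept))
  if (is.finite(x$r_squared)) cat(sprintf("  R-squared: %.3f (n = %d)\n", x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.ku_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    cf <- suppressWarnings(summary(x$fit))$coefficients
    tibble::tibble(
      term = c("intercept", "slope"),
      estimate = cf[, "Estimate"],
      std.error = cf[, "Std. Error"],
      statistic = cf[, "t value"],
      p.value = cf[, "Pr(>|t|)"]
    )
  } else {
    tibble::tibble(term = c("intercept", "slope"),
                   estimate = c(x$intercept, x$slope),
                   std.error = NA_real_, statistic = NA_real_,
                   p.value = NA_real_)
  }
}

#' @export
glance.ku_model <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, n = x$n,
                 u_min = x$u_range[1], u_max = x$u_range[2],
                 source = x$source)
}

#' Predict the overall mass transfer coefficient at a velocity
#'
#' Evaluates the linear k-u correlation, floored at zero.  Predictions
#' beyond the fitted velocity range are permitted (the model is routinely
#' extrapolated to velocities abiotic contactors can sustain) but flagged
#' via the `"extrapolated"` attribute.
#'
#' @param model A `ku_model`.
#' @param u Superficial velocity, m/d (vectorised, non-negative).
#' @return Predicted k, mm/d, with a logical `"extrapolated"` attribute.
#' @examples
#' predict_k(published_ku_model(), 6000) # > 1400 mm/d
#' @export
predict_k <- function(model, u) {
  stopifnot(inherits(model, "ku_model"))
  if (any(u < 0)) stop("u must be non-negative", call. = FALSE)
  k <- pmax(0, model$slope * u + model$intercept)
  extrap <- if (all(is.finite(model$u_range))) {
    u < model$u_range[1] | u > model$u_range[2]
  } else {
    rep(NA, length(u))
  }
  attr(k, "extrapolated") <- extrap
  k
}

#' Washout rate from volume, broth concentration, and HRT
#'
#' `V * C / HRT`: the broth inventory divided by the hydraulic retention
#' time.  Algebraically identical to [washout_rate()] with
#' `Q_effluent = V / HRT`; this form uses only quantities routinely
#' reported by external studies, so it backs the cross-study flux
#' prediction.
#'
#' @param V Working volume, L.
#' @param C_MCC Broth concentration of medium-chain carboxylates, g COD/L.
#' @param HRT Hydraulic retention time, d (positive).
#' @return Washout rate, g COD/d.
#' @examples
#' predict_washout(4.8, 1.0, 9.5)
#' @export
predict_washout <- function(V, C_MCC, HRT) {
  if (any(HRT <= 0)) stop("HRT must be positive", call. = FALSE)
  if (any(V < 0) || any(C_MCC < 0)) {
    stop("V and C_MCC must be non-negative", call. = FALSE)
  }
  V * C_MCC / HRT
}

#' Predict cross-study MCC production fluxes
#'
#' For each study record, predicts the medium-chain carboxylate production
#' flux through a forward membrane contactor from reported operating data
#' alone: the extraction rate is `predict_k(u) * A_transfer *
#' C_MCCA_undiss` (k in mm/d equals L m-2 d-1, so the product is g COD/d),
#' the washout rate is `V * C_MCC / HRT`, and the flux is their sum per
#' unit membrane area.
#'
#' @param model A `ku_model` (e.g. [published_ku_model()]).
#' @param studies A data frame with columns `label`, `u_m_d`,
#'   `A_transfer_m2`, `C_MCCA_undiss_gCOD_L`, `V_L`, `C_MCC_broth_gCOD_L`,
#'   `HRT_d`, and optionally `observed_flux_gCOD_m2_d`.
#' @return The input tibble with `predicted_k_mm_d`,
#'   `extraction_rate_gCOD_d`, `washout_rate_gCOD_d`,
#'   `predicted_flux_gCOD_m2_d`, `extrapolated`, and (when observations are
#'   present) `residual_gCOD_m2_d` appended.
#' @examples
#' studies <- data.frame(label = "Period 4", u_m_d = 207, A_transfer_m2 = 1.4,
#'                       C_MCCA_undiss_gCOD_L = 0.25, V_L = 4.8,
#'                       C_MCC_broth_gCOD_L = 1.0, HRT_d = 9.5)
#' predict_flux(published_ku_model(), studies)
#' @export
predict_flux <- function(model, studies) {
  stopifnot(inherits(model, "ku_model"), is.data.frame(studies))
  required <- c("label", "u_m_d", "A_transfer_m2", "C_MCCA_undiss_gCOD_L",
                "V_L", "C_MCC_broth_gCOD_L", "HRT_d")
  missing_cols <- setdiff(required, names(studies))
  if (length(missing_cols) > 0) {
    stop("incomplete study records: missing field(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  na_rows <- !stats::complete.cases(studies[required])
  if (any(na_rows)) {
    stop("incomplete study records (NA in required fields): ",
         paste(studies$label[na_rows], collapse = ", "), call. = FALSE)
  }
  k <- predict_k(model, studies$u_m_d)
  extraction <- as.numeric(k) * studies$A_transfer_m2 * studies$C_MCCA_undiss_gCOD_L
  washout <- predict_washout(studies$V_L, studies$C_MCC_broth_gCOD_L, studies$HRT_d)
  out <- tibble::as_tibble(studies) |>
    dplyr::mutate(
      predicted_k_mm_d = as.numeric(k),
      extraction_rate_gCOD_d = extraction,
      washout_rate_gCOD_d = washout,
      predicted_flux_gCOD_m2_d = (extraction + washout) / .data$A_transfer_m2,
      extrapolated = attr(k, "extrapolated")
    )
  if ("observed_flux_gCOD_m2_d" %in% names(out)) {
    out$residual_gCOD_m2_d <- out$observed_flux_gCOD_m2_d - out$predicted_flux_gCOD_m2_d
  }
  out
}

#' Coefficient of determination (squared Pearson convention)
#'
#' `r_squared(observed, predicted)` is the squared Pearson correlation
#' between the two vectors.  Under this convention a constant prediction
#' has no explanatory power and returns 0.
#'
#' @param observed,predicted Equal-length numeric vectors, `n >= 2`.
#' @return R-squared in `[0, 1]`.
#' @examples
#' r_squared(1:5, c(1.1, 2.2, 2.9, 4.2, 4.8))
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("observed and predicted must be equal-length vectors with n >= 2",
         call. = FALSE)
  }
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    return(0)
  }
  stats::cor(observed, predicted)^2
}
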