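test_that("extraction-rate fit recovers exact and hand-computed OLS lines", {
  exact <- fit_extraction_rate(c(0, 1, 2), c(0, 5, 10))
  expect_equal(exact$slope, 5, tolerance = 1e-12)
  expect_equal(exact$slope_se, 0, tolerance = 1e-9)
  # closed-form OLS on 3 points by hand: slope 5, intercept -1/3
  by_hand <- fit_extraction_rate(c(0, 1, 2), c(0, 4, 10))
  expect_equal(by_hand$slope, 5, tolerance = 1e-12)
  expect_equal(by_hand$intercept, -1 / 3, tolerance = 1e-12)
  expect_equal(by_hand$n, 3L)
  expect_error(fit_extraction_rate(1, 2), "insufficient data")
  expect_error(fit_extraction_rate(c(0, 1, 1), c(0, 1, 2)), "strictly increasing")
  expect_warning(f <- fit_extraction_rate(c(0, 1, 2), c(10, 5, 0)), "negative")
  expect_true(f$negative_slope)
  expect_equal(f$slope, -5, tolerance = 1e-12) # reported as-is, never clamped
})

test_that("slope confidence interval covers a planted rate at nominal level", {
  # simulation oracle: planted slope 7, CV-5% noise, n = 20 per replicate
  set.seed(401)
  times <- seq(0, 9.5, by = 0.5)
  truth <- 7
  covered <- vapply(1:200, function(i) {
    amounts <- truth * times * (1 + 0.05 * rnorm(length(times)))
    f <- fit_extraction_rate(times, amounts)
    abs(f$slope - truth) <= f$ci_half
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("tidy and glance expose the extraction fit as tibbles", {
  f <- fit_extraction_rate(c(0, 1, 2, 3), c(0.1, 5.2, 9.9, 15.1))
  td <- generics::tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_identical(td$term, c("intercept", "slope"))
  expect_true(td$conf.low[2] < f$slope && f$slope < td$conf.high[2])
  gl <- generics::glance(f)
  expect_identical(gl$n, 4L)
})

test_that("washout rate is concentration times effluent flow", {
  expect_identical(washout_rate(2.0, 4.0), 8.0)
  expect_identical(washout_rate(0, 100), 0)
  # V*C/HRT form agrees when Q_effluent = V/HRT
  V <- 4.8; HRT <- 9; C <- 1.3
  expect_equal(washout_rate(C, V / HRT), predict_washout(V, C, HRT),
               tolerance = 1e-15)
  expect_error(washout_rate(-1, 1), "non-negative")
})

test_that("ethanol substrate ratio is f/(1-f)", {
  expect_equal(round(ethanol_substrate_ratio(0.40), 1), 0.7)
  expect_identical(ethanol_substrate_ratio(0.5), 1)
  expect_identical(ethanol_substrate_ratio(0), 0)
  expect_error(ethanol_substrate_ratio(1), "\\[0, 1\\)")
})

test_that("gas COD rate uses ThOD factors for methane and hydrogen", {
  expect_identical(gas_cod_rate(0, 0, 4.1), 0)
  # (64*0.02 + 16*0.08)/4.1 by hand
  expect_equal(gas_cod_rate(0.02, 0.08, 4.1), 2.56 / 4.1, tolerance = 1e-12)
  expect_identical(thod(1, 4, 0), 64) # the methane factor itself
})

test_that("upflow velocity reproduces the reactor-column operating range", {
  expect_equal(upflow_velocity(323, 0.12), 1.19, tolerance = 5e-3)
  # 9 + 140 L/d augmented recycle, by hand
  expect_equal(upflow_velocity(149, 0.12), 0.55, tolerance = 5e-3)
  expect_identical(upflow_velocity(0, 0.12), 0)
})

test_that("production summary reproduces headline yield and specificities", {
  # MCC productivity 3.9 g COD/L-d at OLR 5.8 -> yield 67%
  V <- 4.8
  per <- list(period_id = 4L, V_L = V, Q_effluent_L_d = 0, OLR_gCOD_L_d = 5.8)
  # total product productivity 5.42 back-calculated from 72% combined
  # specificity; MCC split 1:1
  fits <- data.frame(
    species = c("n-caproate", "n-caprylate", "acetate"),
    extraction_rate = c(1.95 * V, 1.95 * V, (5.42 - 3.9) * V)
  )
  broth <- data.frame(species = "n-caproate", concentration = 0)
  out <- production_summary(per, fits, broth)
  mcc <- out[out$species == "MCC", ]
  expect_equal(round(100 * mcc$yield), 67)
  expect_equal(mcc$product_ratio_c8_c6, 1.0, tolerance = 1e-12)
  each <- out[out$species %in% c("n-caproate", "n-caprylate"), ]
  expect_equal(round(100 * each$specificity), c(36, 36))
  expect_equal(round(100 * mcc$specificity), 72)
})

test_that("production equals extraction plus washout, per species", {
  per <- list(period_id = 1L, V_L = 4.8, Q_effluent_L_d = 0.53,
              OLR_gCOD_L_d = 6)
  fits <- data.frame(species = c("n-caproate", "n-caprylate"),
                     extraction_rate = c(8.2, 7.9))
  broth <- data.frame(species = c("n-caproate", "n-caprylate", "acetate"),
                      concentration = c(0.9, 0.25, 2.1))
  out <- production_summary(per, fits, broth)
  expect_equal(out$production_rate_gCOD_d,
               out$extraction_rate_gCOD_d + out$washout_rate_gCOD_d,
               tolerance = 1e-15)
})

test_that("yield and specificity are invariant under global rate rescaling", {
  per <- list(period_id = 1L, V_L = 4.8, Q_effluent_L_d = 0.5,
              OLR_gCOD_L_d = 6)
  fits <- data.frame(species = c("n-caproate", "n-caprylate", "acetate"),
                     extraction_rate = c(5, 4, 0.5))
  broth <- data.frame(species = c("n-caproate", "n-caprylate", "acetate"),
                      concentration = c(1.1, 0.3, 2.0))
  base <- production_summary(per, fits, broth)
  for (s in c(0.5, 3)) {
    per2 <- per; per2$OLR_gCOD_L_d <- per$OLR_gCOD_L_d * s
    fits2 <- fits; fits2$extraction_rate <- fits$extraction_rate * s
    broth2 <- broth; broth2$concentration <- broth$concentration * s
    scaled <- production_summary(per2, fits2, broth2)
    expect_equal(scaled$specificity, base$specificity, tolerance = 1e-12)
    expect_equal(scaled$yield, base$yield, tolerance = 1e-12)
  }
})

test_that("zero OLR with nonzero MCC production is a division error", {
  per <- list(period_id = 1L, V_L = 4.8, Q_effluent_L_d = 0,
              OLR_gCOD_L_d = 0)
  fits <- data.frame(species = "n-caproate", extraction_rate = 5)
  broth <- data.frame(species = "n-caproate", concentration = 0)
  expect_error(production_summary(per, fits, broth), "OLR is zero")
})

test_that("species missing from both routes are reported, not zeroed", {
  per <- list(period_id = 1L, V_L = 4.8, Q_effluent_L_d = 0.5,
              OLR_gCOD_L_d = 6)
  fits <- data.frame(species = "n-caproate", extraction_rate = 5)
  broth <- data.frame(species = "n-caproate", concentration = 1)
  out <- production_summary(per, fits, broth)
  expect_identical(attr(out, "missing_species"), "n-caprylate")
})
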