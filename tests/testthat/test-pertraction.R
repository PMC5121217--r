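test_that("superficial velocity is recycle flow over shell cross-section", {
  expect_equal(superficial_velocity(323, 1.56e-3), 207, tolerance = 1e-3)
  expect_identical(superficial_velocity(0), 0)
  expect_equal(superficial_velocity(9, 1.56e-3), 5.77, tolerance = 1e-3)
  expect_error(superficial_velocity(-1), "non-negative")
})

test_that("mass transfer coefficient is M/(A*dC) with mm/d unit identity", {
  expect_equal(mass_transfer_coefficient(17.85, 1.4, 0.25), 51, tolerance = 1e-12)
  expect_identical(mass_transfer_coefficient(0, 1.4, 0.3), 0)
  # homogeneity: doubling both M and dC leaves k unchanged
  expect_equal(mass_transfer_coefficient(2 * 17.85, 1.4, 2 * 0.25),
               mass_transfer_coefficient(17.85, 1.4, 0.25), tolerance = 1e-15)
  expect_error(mass_transfer_coefficient(1, 1.4, 0), "undefined coefficient")
  # dimensional-analysis oracle on random inputs:
  # M [g/d] / (A [m2] * dC [g/L -> g/m3]) gives k in m/d; x1000 -> mm/d
  set.seed(7)
  for (i in 1:20) {
    M <- runif(1, 0.1, 50); A <- runif(1, 0.5, 10); dC <- runif(1, 0.01, 2)
    k_m_d <- M / (A * (dC * 1000))
    expect_equal(mass_transfer_coefficient(M, A, dC), k_m_d * 1000,
                 tolerance = 1e-12)
  }
})

test_that("gradient approximation: exact difference vs high-pH shortcut", {
  expect_identical(gradient_approximation(0.25, 0), 0.25)
  expect_equal(gradient_approximation(0.25, 0.01), 0.24, tolerance = 1e-15)
  expect_identical(gradient_approximation(0.25, 0.01, approximate = TRUE), 0.25)
  # approximation error is bounded by the trap-side concentration
  expect_lte(abs(gradient_approximation(0.25, 0.01, approximate = TRUE) -
                   gradient_approximation(0.25, 0.01)), 0.01 + 1e-12)
})

test_that("k-u fit recovers exact lines and is robust to noise", {
  u <- c(6, 55, 146, 207)
  exact <- fit_ku(data.frame(u = u, k = 0.24 * u + 1.31))
  expect_equal(exact$slope, 0.24, tolerance = 1e-12)
  expect_equal(exact$intercept, 1.31, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)

  two_pt <- fit_ku(data.frame(u = c(0, 100), k = c(1.31, 25.31)))
  expect_equal(two_pt$slope, 0.24, tolerance = 1e-12)
  expect_equal(two_pt$intercept, 1.31, tolerance = 1e-12)

  # planted line with SD-2 noise: slope within 3 SE of 0.24
  set.seed(12)
  u8 <- seq(10, 220, length.out = 8)
  noisy <- data.frame(u = u8, k = pmax(0, 0.24 * u8 + 1.31 + rnorm(8, sd = 2)))
  fit <- fit_ku(noisy)
  se <- generics::tidy(fit)$std.error[2]
  expect_lt(abs(fit$slope - 0.24), 3 * se)

  expect_error(fit_ku(data.frame(u = c(5, 5), k = c(1, 2))), "singular")
})

test_that("published k-u line reproduces the printed checkpoints", {
  m <- published_ku_model()
  k207 <- as.numeric(predict_k(m, 207))
  expect_equal(k207, 50, tolerance = 0.05)        # measured 50 mm/d, 5%
  k6000 <- as.numeric(predict_k(m, 6000))
  expect_equal(k6000, 1441.31, tolerance = 1e-12) # exact arithmetic
  expect_gte(k6000, 1400)
  expect_lte(k6000 / k207, 30)                    # "almost 30 times larger"
})

test_that("predict_k is affine, floored at zero, and flags extrapolation", {
  m <- published_ku_model()
  u1 <- 40; u2 <- 130
  expect_equal(as.numeric(predict_k(m, u1)) + as.numeric(predict_k(m, u2)),
               as.numeric(predict_k(m, u1 + u2)) + m$intercept,
               tolerance = 1e-12)
  falling <- fit_ku(data.frame(u = c(0, 10), k = c(5, 0)))
  expect_identical(as.numeric(predict_k(falling, 100)), 0)
  flags <- attr(predict_k(m, c(50, 6000)), "extrapolated")
  expect_identical(flags, c(FALSE, TRUE))
})

test_that("predicted washout is broth inventory over HRT", {
  expect_identical(predict_washout(4.1, 1.0, 1.0), 4.1)
  expect_identical(predict_washout(10, 0, 3), 0)
  expect_error(predict_washout(4, 1, 0), "HRT")
})

test_that("cross-study flux prediction composes extraction and washout", {
  m <- published_ku_model()
  zero <- data.frame(label = "null", u_m_d = 100, A_transfer_m2 = 1.4,
                     C_MCCA_undiss_gCOD_L = 0, V_L = 5,
                     C_MCC_broth_gCOD_L = 0, HRT_d = 2)
  expect_identical(predict_flux(m, zero)$predicted_flux_gCOD_m2_d, 0)

  p4 <- data.frame(label = "high-recycle period", u_m_d = 207,
                   A_transfer_m2 = 1.4, C_MCCA_undiss_gCOD_L = 0.25,
                   V_L = 4.8, C_MCC_broth_gCOD_L = 1.0, HRT_d = 9.5,
                   observed_flux_gCOD_m2_d = 13.3)
  out <- predict_flux(m, p4)
  expect_equal(out$predicted_flux_gCOD_m2_d, 13.3, tolerance = 0.05)
  expect_identical(out$residual_gCOD_m2_d,
                   13.3 - out$predicted_flux_gCOD_m2_d)

  # flux nondecreasing in u at fixed concentrations
  sweep <- data.frame(label = letters[1:5], u_m_d = c(10, 50, 150, 400, 6000),
                      A_transfer_m2 = 1.4, C_MCCA_undiss_gCOD_L = 0.2,
                      V_L = 4.8, C_MCC_broth_gCOD_L = 1, HRT_d = 9)
  expect_true(all(diff(predict_flux(m, sweep)$predicted_flux_gCOD_m2_d) >= 0))

  incomplete <- p4[, setdiff(names(p4), "HRT_d")]
  expect_error(predict_flux(m, incomplete), "HRT_d")
})

test_that("R-squared follows the squared-Pearson convention", {
  expect_equal(r_squared(1:5, 1:5), 1, tolerance = 1e-12)
  expect_identical(r_squared(1:5, rep(2, 5)), 0)
  # simulation oracle: planted correlation 0.86 gives R2 near 0.74
  set.seed(86)
  z <- rnorm(4000)
  obs <- 0.86 * z + sqrt(1 - 0.86^2) * rnorm(4000)
  expect_equal(r_squared(obs, z), 0.74, tolerance = 0.04)
  expect_error(r_squared(1:3, 1:4), "equal-length")
})
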