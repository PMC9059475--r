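test_that("Hertz fit inverts the forward model", {
  # point inversion
  expect_equal(hertz_modulus(4 / 3, 1, nu = 0, R = 1), 1)
  cv <- synth_indentation_curve(E = 5, nu = 0.3, R = 300, depth_max = 50,
                                noise_sd = 0)
  fit <- fit_hertz(cv)
  expect_lt(abs(fit$modulus_e / 5 - 1), 0.001)
  expect_lt(fit$residual_rms, 1e-9)
})

test_that("noisy replicate fits are unbiased within 5%", {
  errs <- vapply(1:50, function(i) {
    cv <- synth_indentation_curve(E = 5, nu = 0.3, R = 300, depth_max = 50,
                                  noise_sd = 0)
    set.seed(5000 + i)
    cv$force <- cv$force * (1 + rnorm(length(cv$force), 0, 0.02))
    fit_hertz(cv)$modulus_e / 5 - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.05)
  # no systematic sign bias: mean error small relative to its spread
  expect_lt(abs(mean(errs)), 3 * sd(errs) / sqrt(50) + 0.01)
})

test_that("fit scales exactly with force, nu and the depth grid", {
  cv <- synth_indentation_curve(E = 5, nu = 0.3, R = 300, depth_max = 50,
                                noise_sd = 0.2, seed = 4)
  e0 <- fit_hertz(cv)$modulus_e
  cv2 <- cv
  cv2$force <- 2 * cv$force
  expect_equal(fit_hertz(cv2)$modulus_e, 2 * e0, tolerance = 1e-12)
  cv3 <- cv
  cv3$poisson_ratio <- 0.45
  expect_equal(fit_hertz(cv3)$modulus_e,
               e0 * (1 - 0.45^2) / (1 - 0.3^2), tolerance = 1e-12)
  # denser sampling over the same window changes nothing systematic
  cvd <- synth_indentation_curve(E = 5, nu = 0.3, R = 300, depth_max = 50,
                                 n_points = 400, noise_sd = 0)
  expect_equal(fit_hertz(cvd)$modulus_e, 5, tolerance = 1e-9)
})

test_that("contact point detection recovers known offsets", {
  cv <- synth_indentation_curve(E = 5, nu = 0.3, R = 300, depth_max = 50,
                                contact_offset = 5, noise_sd = 0)
  step <- diff(cv$depth)[1]
  expect_lt(abs(detect_contact_point(cv) - 5), step + 1e-9)
  expect_lt(abs(fit_hertz(cv, detect = TRUE)$modulus_e / 5 - 1), 0.02)

  cv0 <- synth_indentation_curve(E = 5, nu = 0.3, R = 300, depth_max = 50,
                                 contact_offset = 0, noise_sd = 0)
  expect_lt(detect_contact_point(cv0), 2 * step)

  flat <- force_indentation_curve(seq(0, 50, length.out = 50),
                                  rep(0, 50))
  expect_error(detect_contact_point(flat), class = "osteomech_data_error")
})

test_that("fit guards its preconditions", {
  cv <- synth_indentation_curve(E = 5, depth_max = 50, n_points = 12,
                                noise_sd = 0)
  expect_error(fit_hertz(cv, depth_cap = 5),
               class = "osteomech_data_error")   # too few capped points
  neg <- force_indentation_curve(seq(0, 50, length.out = 50),
                                 seq(0, -5, length.out = 50))
  expect_error(fit_hertz(neg), class = "osteomech_data_error")
})

test_that("log-frequency fit is exact on exact points", {
  fl <- fit_log_frequency(c(1, 10, 100), 10 + 2 * log(c(1, 10, 100)))
  expect_equal(fl$intercept_a, 10, tolerance = 1e-10)
  expect_equal(fl$slope_b, 2, tolerance = 1e-10)
  expect_equal(fl$r_squared, 1)
  flat <- fit_log_frequency(c(1, 10, 100), c(4, 4, 4))
  expect_equal(flat$slope_b, 0, tolerance = 1e-12)
  expect_error(fit_log_frequency(c(1, 1, 1), c(1, 2, 3)),
               class = "osteomech_data_error")
  expect_error(fit_log_frequency(c(-1, 1, 10), c(1, 2, 3)),
               class = "osteomech_parameter_error")
})

test_that("modulus summary computes anisotropy ratios per group", {
  fits <- data.frame(
    modulus = c(2, 2, 1, 1, 4, 4, 2, 2),
    orientation = rep(c("longitudinal", "longitudinal", "transverse",
                        "transverse"), 2),
    compartment = rep(c("cortical", "trabecular"), each = 4))
  sm <- modulus_summary(fits)
  expect_equal(sm$anisotropy_ratio[sm$compartment == "cortical"], 2)
  expect_equal(sm$anisotropy_ratio[sm$compartment == "trabecular"], 2)
  same <- data.frame(modulus = c(3, 3, 3, 3),
                     orientation = c("longitudinal", "longitudinal",
                                     "transverse", "transverse"),
                     compartment = "cortical")
  expect_equal(modulus_summary(same)$anisotropy_ratio, 1)
})
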