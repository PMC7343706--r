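test_that("confocal PSF matches its analytic values and rejects bad zR", {
  expect_equal(confocal_psf(1.3, 1.3, 2), 1.0)
  expect_equal(confocal_psf(1.3 + 2, 1.3, 2), 1 / sqrt(2))
  expect_equal(confocal_psf(2, 0, 1), 5^(-1 / 2))
  expect_error(confocal_psf(1, 0, 0), "zR")
})

test_that("roll-off matches its analytic values, is symmetric, rejects bad zW", {
  expect_equal(rolloff(1.5, 1.5, 3), 1.0)
  expect_equal(rolloff(1.5 + 3, 1.5, 3), exp(-1))
  d <- runif(5, 0, 2)
  expect_equal(rolloff(1.5 + d, 1.5, 3), rolloff(1.5 - d, 1.5, 3))
  expect_error(rolloff(1, 0, -1), "zW")
})

test_that("compensation inverts the forward model to an exact line", {
  sys <- system_params(z0 = 0.8, zR = 1.4, zC = 1.0, zW = 2.2,
                       axial_spacing = 0.005, n_alines = 16)
  r <- (0:199) * sys$axial_spacing
  prof <- 2000 * confocal_psf(r, 0.8, 1.4) * rolloff(r, 1.0, 2.2) *
    exp(-4.2 * r)
  y <- compensate_log_signal(prof, sys)
  fit <- lm(y ~ r)
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_equal(unname(coef(fit)[2]), -4.2, tolerance = 1e-10)
  expect_equal(unname(coef(fit)[1]), log(2000), tolerance = 1e-10)
})

test_that("with neutral beam parameters compensation is the identity up to log", {
  sys <- neutral_sys()
  prof <- c(10, 20, 40)
  y <- compensate_log_signal(prof, sys)
  expect_equal(y, log(prof), tolerance = 1e-9)
})

test_that("masked pixels are excluded and all-masked input errors", {
  sys <- neutral_sys()
  prof <- c(100, 0, 50, 25)
  y <- compensate_log_signal(prof, sys)
  expect_true(is.na(y[2]) && !anyNA(y[-2]))
  fit <- fit_attenuation(y, c(0L, 4L), sys$axial_spacing)
  expect_equal(fit$n_points, 3L)
  expect_error(compensate_log_signal(c(0, 0), sys), "no fit support")
})

test_that("attenuation fit recovers truth to machine precision over a parameter grid", {
  # the central inversion oracle: noiseless forward model, exact recovery
  for (mu in c(0.5, 2, 4, 6, 8, 10)) {
    for (cfg in list(c(0.5, 1.0, 1.2, 2.0), c(1.0, 3.0, 0.3, 4.0))) {
      sys <- system_params(z0 = cfg[1], zR = cfg[2], zC = cfg[3], zW = cfg[4],
                           axial_spacing = 0.005, n_alines = 16)
      i0 <- 5000
      ray <- make_ray(0, 120)
      prof <- render_aline(ray, list(fibrous = tissue_optical_params(mu, i0)),
                           sys, looks = Inf)
      y <- compensate_log_signal(prof, sys)
      fit <- fit_attenuation(y, c(0L, 120L), sys$axial_spacing)
      expect_equal(fit$mu_t, mu, tolerance = 1e-9)
      expect_equal(fit$log_i0, log(i0), tolerance = 1e-9)
      expect_equal(fit$r2, 1, tolerance = 1e-9)
    }
  }
})

test_that("a constant corrected profile fits mu_t = 0", {
  fit <- fit_attenuation(rep(3.5, 20), c(0L, 20L), 0.005)
  expect_equal(fit$mu_t, 0)
  expect_equal(fit$r2, 1)
})

test_that("windows with fewer than 3 points are rejected", {
  expect_error(fit_attenuation(rep(1, 10), c(0L, 2L), 0.005), "3 columns")
  y <- c(1, NA, NA, NA, NA, 2)
  expect_error(fit_attenuation(y, c(0L, 6L), 0.005), "3 unmasked")
})

test_that("speckled estimates are nearly unbiased and tighten with window length", {
  sys <- neutral_sys(axial_spacing = 0.005)
  mu <- 3.0
  ests_short <- ests_long <- numeric(300)
  for (k in 1:300) {
    prof <- render_aline(make_ray(0, 200),
                         list(fibrous = tissue_optical_params(mu, 1e4)),
                         sys, looks = 4, seed = k)
    y <- compensate_log_signal(prof, sys)
    ests_short[k] <- fit_attenuation(y, c(0L, 50L), 0.005)$mu_t
    ests_long[k] <- fit_attenuation(y, c(0L, 200L), 0.005)$mu_t
  }
  expect_lt(abs(mean(ests_long) - mu) / mu, 0.05)
  # consistency: 4x the window points shrinks the SD roughly by 8 (n^{3/2}
  # scaling of slope-estimator variance); require at least a factor 2
  expect_lt(sd(ests_long), sd(ests_short) / 2)
})

test_that("backscatter coefficient follows I0 = I' * mu_b", {
  expect_equal(backscatter_coefficient(log(1000), 500)$mu_b, 2.0)
  expect_equal(backscatter_coefficient(log(77), 77)$mu_b, 1.0)
  b1 <- backscatter_coefficient(log(1000), 100)$mu_b
  b2 <- backscatter_coefficient(log(1000), 50)$mu_b
  expect_equal(b2, 2 * b1)
  expect_error(backscatter_coefficient(1, 0), "i_prime")
})

test_that("attenuation map recovers per-sector truth on a noiseless phantom", {
  sys <- system_params(n_alines = 60, axial_spacing = 0.01)
  pars <- list(fibrous = tissue_optical_params(2.0, 30000),
               lipid = tissue_optical_params(6.0, 30000))
  sp <- phantom_spec(mean_radius_mm = 0.8,
                     tissue_sectors = data.frame(
                       start_deg = c(0, 180), end_deg = c(180, 360),
                       label = c(1L, 3L), thickness_mm = 1.3),
                     looks = Inf, seed = 3)
  ph <- generate_phantom(sp, params_by_label = pars, sys = sys)
  opt <- attenuation_map(ph$image, ph$boundary, sys)
  med1 <- median(opt$mu_t[ph$labels$labels == 1L & opt$roi], na.rm = TRUE)
  med2 <- median(opt$mu_t[ph$labels$labels == 3L & opt$roi], na.rm = TRUE)
  expect_lt(abs(med1 - 2.0) / 2.0, 0.01)
  expect_lt(abs(med2 - 6.0) / 6.0, 0.01)
})

test_that("the ROI equals the band [boundary, boundary + depth)", {
  sys <- system_params(n_alines = 40, axial_spacing = 0.01)
  ph <- generate_phantom(phantom_spec(seed = 4), sys = sys)
  opt <- attenuation_map(ph$image, ph$boundary, sys, analysis_depth = 1.0)
  depth_px <- 100
  for (i in seq_len(40)) {
    expected <- rep(FALSE, ncol(ph$image$pixels))
    cols <- (ph$boundary[i]):(min(ph$boundary[i] + depth_px,
                                  ncol(ph$image$pixels)) - 1L)
    expected[cols + 1L] <- TRUE
    expect_identical(opt$roi[i, ], expected)
  }
  expect_error(attenuation_map(ph$image, NULL, sys), "boundary")
})
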