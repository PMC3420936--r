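test_that("anchor-only fit pins the half-maximal and relaxed points", {
  cv <- fit_calibration(pairs = NULL)
  expect_lt(abs(efficiency_at(cv, -0.030) - 0.5), 0.02)
  expect_equal(efficiency_at(cv, -0.004), 0)
  expect_equal(efficiency_at(cv, 0), 0)
  expect_gte(efficiency_at(cv, -0.041), efficiency_at(cv, -0.023))
})

test_that("fit to anchors plus survey pairs matches the published read-offs", {
  cv <- survey_curve()
  expect_true(efficiency_at(cv, -0.037) >= 0.70 && efficiency_at(cv, -0.037) <= 0.80)
  expect_lt(abs(efficiency_at(cv, -0.030) - 0.50), 0.02)
  expect_lte(cv$fit_residual, 0.05)
  expect_false(cv$monotone_conflict)
})

test_that("curve invariants hold: monotone, clamped, bounded", {
  cv <- survey_curve()
  grid <- seq(-0.05, 0, length.out = 500)
  eff <- efficiency_at(cv, grid)
  expect_true(all(diff(eff) <= 1e-12))
  expect_true(all(eff >= 0 & eff <= 1))
  expect_lte(efficiency_at(cv, cv$sigma_relaxed), 0.01)
  expect_gte(efficiency_at(cv, cv$sigma_saturation), 0.90)
  expect_error(efficiency_at(cv, 0.01), "positive")
})

test_that("inversion reproduces the printed apparent sigma_D values", {
  cv <- survey_curve()
  expect_lt(abs(sigma_from_efficiency(cv, 0.75)$value - -0.037), 0.003)
  expect_lt(abs(sigma_from_efficiency(cv, 0.28)$value - -0.023), 0.003)
  expect_lt(abs(sigma_from_efficiency(cv, 0.92)$value - -0.041), 0.003)
  low <- sigma_from_efficiency(cv, 0.005)
  expect_identical(low$kind, "magnitude_upper_bound")
  expect_lte(abs(low$value), 0.003)
  sat <- sigma_from_efficiency(cv, 0.999)
  expect_identical(sat$kind, "magnitude_lower_bound")
  expect_gte(abs(sat$value), 0.040)
  expect_error(sigma_from_efficiency(cv, 1.2), "\\[0, 1\\]")
})

test_that("forward and inverse maps are exact round-trips on the working range", {
  cv <- survey_curve()
  for (eff in seq(0.05, 0.90, by = 0.05)) {
    s <- sigma_from_efficiency(cv, eff)$value
    expect_equal(efficiency_at(cv, s), eff, tolerance = 1e-6)
  }
})

test_that("total sigma is the sum of constrained and diffusible parts", {
  expect_equal(total_sigma(-0.030, -0.030), -0.060)
  expect_equal(total_sigma(-0.030, 0), -0.030)
  expect_equal(total_sigma(0, 0), 0)
  expect_error(total_sigma(0.01, -0.03), "<= 0")
})

test_that("delta_sigma matches the rifampicin-rebound column", {
  cv <- survey_curve()
  expect_lt(abs(delta_sigma(cv, 0.08, 0.56) - -0.020), 0.003)
  expect_lt(abs(delta_sigma(cv, 0.005, 0.57) - -0.030), 0.003)
  expect_equal(delta_sigma(cv, 0.4, 0.4), 0)
})

test_that("non-monotone-compatible pairs are flagged but fitted", {
  bad <- data.frame(efficiency = c(0.2, 0.7), sigma_d = c(-0.030, -0.020))
  expect_warning(cv <- fit_calibration(bad), "monotone")
  expect_true(cv$monotone_conflict)
  expect_error(fit_calibration(data.frame(efficiency = 0.5, sigma_d = 0.01)),
               "sigma_d")
})

test_that("logistic method gives an analytic, invertible sigmoid", {
  cv <- fit_calibration(calibration_pairs_from_survey(), method = "logistic")
  expect_equal(efficiency_at(cv, cv$params[["sigma50"]]), 0.5, tolerance = 1e-9)
  s <- sigma_from_efficiency(cv, 0.3)$value
  expect_equal(efficiency_at(cv, s), 0.3, tolerance = 1e-6)
  grid <- seq(-0.05, -0.005, length.out = 200)
  expect_true(all(diff(efficiency_at(cv, grid)) < 0))
})

test_that("curve serialization round-trips bit-exactly", {
  cv <- survey_curve()
  f1 <- tempfile(); f2 <- tempfile()
  write_calibration(cv, f1)
  cv2 <- read_calibration(f1)
  write_calibration(cv2, f2)
  expect_identical(readLines(f1), readLines(f2))
  grid <- seq(-0.05, 0, length.out = 101)
  expect_equal(efficiency_at(cv2, grid), efficiency_at(cv, grid), tolerance = 1e-12)
})
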