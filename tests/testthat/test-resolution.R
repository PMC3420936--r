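test_that("efficiency from counts is the replicate mean with sample SD", {
  est <- efficiency_from_counts(c(162, 158, 166), c(200, 200, 200))
  expect_equal(est$mean, 0.810)
  expect_equal(est$sd, 0.020)
  zero <- efficiency_from_counts(c(0, 0, 0), c(200, 200, 200))
  expect_equal(zero$mean, 0)
  expect_equal(zero$sd, 0)
  expect_warning(one <- efficiency_from_counts(200, 200), "fewer than 3")
  expect_equal(one$mean, 1)
  expect_true(is.na(one$sd))
  expect_error(efficiency_from_counts(1, 0), "zero")
  expect_warning(efficiency_from_counts(c(10, 10, 10), c(150, 200, 200)), "200 colonies")
})

test_that("the efficiency estimator is unbiased under binomial sampling", {
  set.seed(42)
  means <- replicate(1000, mean(stats::rbinom(3, 600, 0.4) / 600))
  expect_lt(abs(mean(means) - 0.4), 0.01)
})

test_that("detection-limit censoring substitutes 0.5% and is idempotent", {
  expect_equal(censor_low(0.007)$value, 0.005)
  expect_true(censor_low(0.007)$censored)
  expect_equal(censor_low(0.02)$value, 0.02)
  expect_false(censor_low(0.02)$censored)
  expect_true(censor_low(0)$censored)
  once <- censor_low(c(0, 0.007, 0.02, 0.9))
  twice <- censor_low(once$value)
  expect_equal(twice$value, once$value)
})

test_that("MIF is the WT/mutant efficiency ratio with bounds below detection", {
  expect_equal(mif(0.81, 0.07)$display, "12")
  expect_equal(mif(0.81, 0.56)$display, "1.4")
  expect_equal(mif(0.5, 0.5)$value, 1)
  b <- mif(0.82, NA, mut_censored = TRUE)
  expect_true(b$bound)
  expect_equal(b$value, 82)
  expect_equal(b$display, ">82")
  expect_equal(mif(0.4, 0)$value, 40)
  expect_error(mif(0, 0.5), "positive")
})

test_that("MIF reciprocity holds before display rounding", {
  for (pair in list(c(0.81, 0.07), c(0.6, 0.45), c(0.92, 0.3)))
    expect_equal(mif(pair[1], pair[2])$value * mif(pair[2], pair[1])$value, 1)
})

test_that("genome-wide aggregates reproduce the printed genotype summaries", {
  t1 <- paper_fixture_tables()$table1
  cv <- survey_curve()

  wt <- aggregate_positions(t1[t1$genotype == "WT", ], cv)
  expect_equal(wt$n_positions, 7)
  expect_equal(round(100 * wt$mean_efficiency), 81)
  expect_equal(round(wt$mean_sigma, 3), -0.038)

  gyrB <- aggregate_positions(t1[t1$genotype == "gyrB652", ], cv, wt_summary = wt)
  expect_equal(round(100 * gyrB$mean_efficiency), 2)
  expect_equal(round(gyrB$mif$value), 40)  # 81% / 2%

  parE <- aggregate_positions(t1[t1$genotype == "parE206", ], cv, wt_summary = wt)
  expect_equal(round(100 * parE$mean_efficiency), 60)
  expect_equal(parE$mif$display, "1.3")

  expect_error(aggregate_positions(t1[t1$position == 33, , drop = FALSE], cv),
               "after exclusion")
})

test_that("aggregates work from raw efficiencies through the curve inversion", {
  t1 <- paper_fixture_tables()$table1
  wt <- t1[t1$genotype == "WT", ]
  wt$sigma_d <- NULL
  agg <- aggregate_positions(wt, survey_curve())
  expect_equal(round(agg$mean_sigma, 3), -0.038)
})

test_that("rifampicin rebound gives the printed fold change and delta sigma", {
  cv <- survey_curve()
  t3 <- paper_fixture_tables()$table3
  cs85 <- t3[t3$position == 85, ]
  res <- rif_rebound(
    no_rif = list(strain = cs85$strain, position = 85,
                  efficiency = cs85$efficiency, censored = cs85$censored),
    rif = list(strain = cs85$strain, position = 85,
               efficiency = cs85$efficiency_rif, censored = FALSE),
    curve = cv)
  expect_equal(res$fold, 7)
  expect_lt(abs(res$delta_sigma - -0.020), 0.003)

  same <- list(strain = "X", position = 1, efficiency = 0.4, censored = FALSE)
  id <- rif_rebound(same, same, cv)
  expect_equal(id$fold, 1)
  expect_equal(id$delta_sigma, 0)
  other <- same; other$position <- 2
  expect_error(rif_rebound(same, other, cv), "same strain")
})

test_that("the count pipeline renders a survey-style report", {
  counts <- wt_counts_sheet()
  f <- tempfile(); write_tsv_file(counts, f)
  meas <- measurements_from_counts(read_counts_tsv(f))
  expect_equal(nrow(meas), 8)
  rep <- resolution_report(meas, survey_curve())
  cs85 <- rep[rep$position_cs == 85, ]
  expect_equal(cs85$mif, "1")
  expect_match(cs85$efficiency_pct, "^81")
  expect_match(cs85$sigma_d, "^-0\\.038")
})
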