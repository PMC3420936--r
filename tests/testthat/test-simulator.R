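no_topo <- function() topoisomerase_params(k_gyrase = 0, k_topo1 = 0, k_topo4 = 0)

test_that("presets encode the allele-specific rate scalings", {
  wt <- build_model("wt")
  expect_equal(wt$n_domains, 450L)
  expect_equal(wt$topo$k_gyrase, 4.5)
  expect_equal(nrow(wt$units), 30)
  expect_equal(build_model("gyrB1820")$topo$k_gyrase, 0.45)
  expect_equal(build_model("gyrA209")$topo$k_gyrase, 2.25)
  expect_equal(build_model("parE206")$topo$k_topo4, 0.25)
  expect_equal(unique(build_model("rpoC")$units$elongation_rate), 31.5)
  rif <- build_model(list(preset = "gyrB1820", rif = TRUE))
  expect_true(all(rif$units$activity == 0))
  expect_true(all(!rif$units$is_barrier))
  expect_error(build_model("nosuch"), "available")
  expect_error(build_model(list(preset = "wt", n_domains = 2)), ">= 3")
})

test_that("a state with no forces does not move", {
  m <- chromosome_model(n_domains = 9, topo = no_topo(), diffusion_rate = 0)
  s0 <- sim_state(m, sigma = -0.02)
  s1 <- sim_step(m, s0, 0.01)
  expect_equal(s1$sigma, s0$sigma)
})

test_that("twin-domain flux moves 50 turns in 10 s at 52.5 nt/s", {
  u <- transcription_units(50, orientation = 1, elongation_rate = 52.5,
                           activity = 1, is_barrier = FALSE)
  m <- chromosome_model(n_domains = 5, units = u, topo = no_topo(),
                        diffusion_rate = 0)
  s <- run_to_steady_state(m, dt = 0.01, tol = 0, t_max = 10)
  dlk <- s$sigma * m$lk0_domain
  unit_dom <- 3  # floor(50/100*5)+1
  expect_lt(abs(dlk[unit_dom - 1] - -50), 1e-9)
  expect_lt(abs(dlk[unit_dom + 1] - 50), 1e-9)
  expect_lt(abs(sum(dlk)), 1e-9)
})

test_that("upstream and downstream linking differences are exact negatives", {
  u <- transcription_units(50, elongation_rate = 47.25, activity = 0.8,
                           is_barrier = FALSE)
  m <- chromosome_model(n_domains = 5, units = u, topo = no_topo(),
                        diffusion_rate = 0)
  s <- sim_state(m)
  for (i in 1:50) {
    s <- sim_step(m, s, 0.01)
    expect_equal(s$sigma[2], -s$sigma[4])
  }
})

test_that("linking difference is conserved with topoisomerases off", {
  m <- chromosome_model(n_domains = 45, units = default_units(5),
                        topo = no_topo(), diffusion_rate = 0.1)
  s <- sim_state(m, sigma = -0.038)
  lk0 <- total_linking_difference(m, s)
  s <- run_to_steady_state(m, dt = 0.01, tol = 0, t_max = 50, state = s)
  expect_lt(abs(total_linking_difference(m, s) - lk0) / abs(lk0), 1e-9)
})

test_that("without transcription the chromosome settles at the gyrase set point", {
  m <- chromosome_model(n_domains = 9)
  s <- run_to_steady_state(m, dt = 0.01)
  expect_true(s$converged)
  expect_lt(max(abs(s$sigma - m$topo$sigma_setpoint)), 1e-4)
})

test_that("one strong unit splits its flanks around the set point", {
  u <- transcription_units(50, elongation_rate = 52.5, activity = 1)
  m <- chromosome_model(n_domains = 45, units = u)
  s <- run_to_steady_state(m, dt = 0.01)
  d <- 23  # unit domain: floor(50/100*45)+1
  expect_lt(s$sigma[d - 1], m$topo$sigma_setpoint)  # upstream more negative
  expect_gt(s$sigma[d + 1], m$topo$sigma_setpoint)  # downstream relaxed
})

test_that("a rifampicin block is idempotent and returns to the set point", {
  u <- transcription_units(c(20, 60), elongation_rate = 52.5, activity = 1)
  m <- chromosome_model(n_domains = 45, units = u,
                        topo = topoisomerase_params(k_gyrase = 0.45))
  s <- run_to_steady_state(m, dt = 0.01)
  r1 <- rif_experiment(m, s, dt = 0.01)
  expect_lt(abs(mean(r1$sigma) - m$topo$sigma_setpoint), 1e-3)
  expect_lt(mean(r1$sigma), mean(s$sigma))  # rebound toward more negative
  r2 <- rif_experiment(attr(r1, "model"), r1, dt = 0.01)
  expect_lt(max(abs(r2$sigma - r1$sigma)), 1e-5)
})

test_that("instability and argument errors are reported", {
  u <- transcription_units(50, elongation_rate = 5000, activity = 1,
                           is_barrier = FALSE)
  m <- chromosome_model(n_domains = 5, units = u, topo = no_topo(),
                        diffusion_rate = 0)
  expect_error(run_to_steady_state(m, dt = 0.01, tol = 0, t_max = 2000),
               "instability")
  expect_error(sim_step(m, sim_state(m), 0), "positive")
})

test_that("sensor positions map through the state to the calibration curve", {
  cv <- survey_curve()
  m <- chromosome_model(n_domains = 10)
  s <- sim_state(m, sigma = -0.030)
  prof <- predicted_efficiency_profile(m, s, cv, positions = c(5, 50, 95))
  expect_lt(max(abs(prof - 0.5)), 0.02)
  s0 <- sim_state(m, sigma = 0)
  expect_equal(unname(predicted_efficiency_profile(m, s0, cv, 50)), 0)
  expect_error(predicted_efficiency_profile(m, s, cv, 100), "\\[0, 100\\)")
})
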