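#' Synthetic resolution-assay scenario
#'
#' Describes the ground truth of a simulated sensor assay: a true diffusible
#' supercoil density per position, the number of colonies scored per replicate
#' plate, and the replicate count. Defaults mirror the wet assay design
#' (at least 200 colonies counted, three independent experiments).
#'
#' @param true_sigma True sigma_D per position, in \[-0.05, 0\].
#' @param n_colonies Colonies scored per replicate (>= 200; default 600).
#' @param n_replicates Replicates per position (default 3).
#' @param seed Integer seed.
#' @return An `assay_scenario` list.
#' @export
assay_scenario <- function(true_sigma, n_colonies = 600, n_replicates = 3, seed = 1) {
  if (any(true_sigma < -0.05 | true_sigma > 0)) stop("true_sigma must lie in [-0.05, 0]")
  if (n_colonies < 200) stop("n_colonies must be >= 200")
  structure(list(true_sigma = true_sigma, n_colonies = n_colonies,
                 n_replicates = n_replicates, seed = as.integer(seed)),
            class = "assay_scenario")
}

#' Simulate replicate colony counts through the calibration curve
#'
#' White (sensor-deleted) colony counts are binomial draws at the resolution
#' efficiency the calibration curve assigns to each position's true sigma_D:
#' counting statistics are the only noise source, as in plate scoring.
#'
#' @param scenario An [assay_scenario()].
#' @param curve A `calibration_curve`.
#' @return data.frame with columns `position_index`, `true_sigma`,
#'   `replicate_id`, `white_count`, `total_count`. Reproducible for a fixed
#'   scenario seed.
#' @export
simulate_colony_counts <- function(scenario, curve) {
  stopifnot(inherits(scenario, "assay_scenario"), inherits(curve, "calibration_curve"))
  set.seed(scenario$seed)
  eff <- efficiency_at(curve, scenario$true_sigma)
  rows <- lapply(seq_along(scenario$true_sigma), function(i) {
    data.frame(position_index = i,
               true_sigma = scenario$true_sigma[i],
               replicate_id = seq_len(scenario$n_replicates),
               white_count = stats::rbinom(scenario$n_replicates,
                                           scenario$n_colonies, eff[i]),
               total_count = scenario$n_colonies)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic induction time-course scenario
#'
#' Flat baseline, then a linear rise in enzyme activity starting a hidden lag
#' after induction, with multiplicative Gaussian noise on the rise (pipetting
#' and assay error). Sampling every 10 s with three background samples before
#' induction mirrors the assay design.
#'
#' @param true_lag_s Hidden lag between induction and onset of the rise (> 0).
#' @param slope_mu_per_s Rise slope, Miller units per second.
#' @param baseline_mu Baseline activity, Miller units.
#' @param noise_fraction SD of the multiplicative noise (default 0.05).
#' @param sampling_interval_s Seconds between samples (default 10).
#' @param duration_s Total sampled time span.
#' @param induction_time_s IPTG addition time (default 30 s, after three
#'   background samples).
#' @param seed Integer seed.
#' @return A `timecourse_scenario` list.
#' @export
timecourse_scenario <- function(true_lag_s, slope_mu_per_s = 2, baseline_mu = 20,
                                noise_fraction = 0.05, sampling_interval_s = 10,
                                duration_s = 300, induction_time_s = 30, seed = 1) {
  if (true_lag_s <= 0) stop("true_lag_s must be positive")
  if (noise_fraction < 0) stop("noise_fraction must be >= 0")
  structure(list(true_lag_s = true_lag_s, slope_mu_per_s = slope_mu_per_s,
                 baseline_mu = baseline_mu, noise_fraction = noise_fraction,
                 sampling_interval_s = sampling_interval_s,
                 duration_s = duration_s, induction_time_s = induction_time_s,
                 seed = as.integer(seed)),
            class = "timecourse_scenario")
}

#' Simulate a beta-galactosidase induction time course
#'
#' Generates Miller-unit values
#' `MU(t) = baseline + slope * max(0, t - t0 - lag) * (1 + eps_t)` and
#' back-computes OD420 readings (at fixed OD600, OD550 and reaction time) so
#' that [miller_units()] reproduces the trace exactly.
#'
#' @param scenario A [timecourse_scenario()].
#' @return An `induction_timecourse` carrying attribute `true_lag_s`.
#' @export
simulate_timecourse <- function(scenario) {
  stopifnot(inherits(scenario, "timecourse_scenario"))
  t0 <- scenario$induction_time_s
  if (scenario$duration_s < t0 + scenario$true_lag_s + 2 * scenario$sampling_interval_s)
    stop("duration_s is shorter than the induction time plus the lag; no rise would be sampled")
  set.seed(scenario$seed)
  t <- seq(0, scenario$duration_s, by = scenario$sampling_interval_s)
  rise <- pmax(0, t - t0 - scenario$true_lag_s)
  eps <- stats::rnorm(length(t), 0, scenario$noise_fraction)
  mu <- scenario$baseline_mu + scenario$slope_mu_per_s * rise * (1 + eps)
  mu <- pmax(mu, 0)
  od600 <- 0.4; od550 <- 0; rt <- 120; vol <- 0.5
  od420 <- mu * (rt * vol * od600) / 1000
  tc <- induction_timecourse(t, od420, rep(od550, length(t)), rep(od600, length(t)),
                             rt, induction_time_s = t0, volume_ml = vol)
  attr(tc, "true_lag_s") <- scenario$true_lag_s
  tc
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "supercoilr", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  for (col in c("censored", "mif_bound", "sigma_bound"))
    if (col %in% names(df)) df[[col]] <- df[[col]] == 1
  if ("eff_pct" %in% names(df)) df$efficiency <- df$eff_pct / 100
  if ("eff_sd_pct" %in% names(df)) df$efficiency_sd <- df$eff_sd_pct / 100
  if ("eff_rif_pct" %in% names(df)) df$efficiency_rif <- df$eff_rif_pct / 100
  df
}

#' Published resolution measurements as structured fixtures
#'
#' The four printed measurement tables of the sensor survey, transcribed to
#' plain-text fixtures: (1) resolution efficiencies and apparent sigma_D for
#' WT and type II topoisomerase mutants at up to 10 chromosome positions;
#' (2) the Cs 85 allele comparison with doubling times; (3) the rifampicin
#' rebound series in gyrB1820 strains; (4) the slow-polymerase (rpoC
#' Delta215-220) series. Efficiencies are returned as fractions; censored
#' rows ("<1%") carry `censored = TRUE` and their sigma at the |0.003| bound;
#' printed MIF lower bounds carry `mif_bound = TRUE`.
#'
#' @return Named list of data.frames: `table1`, `table2`, `table3`, `table4`.
#' @export
paper_fixture_tables <- function() {
  list(table1 = read_fixture("table1_resolution.tsv"),
       table2 = read_fixture("table2_cs85.tsv"),
       table3 = read_fixture("table3_rif.tsv"),
       table4 = read_fixture("table4_rpoc.tsv"))
}

#' Calibration pairs from the published survey
#'
#' Point-valued (efficiency, sigma_D) pairs from the genome-wide survey table
#' for fitting the calibration curve. Censored rows carry no usable pair. The
#' terminus-region sensors (Cs 33) are excluded by default: resolvase binding
#' there is occluded by dif-region proteins, so those efficiencies
#' under-report the local supercoil density and distort the monotone fit.
#'
#' @param include_ter Keep the Cs 33 rows?
#' @return data.frame with columns `efficiency` and `sigma_d`.
#' @export
calibration_pairs_from_survey <- function(include_ter = FALSE) {
  t1 <- paper_fixture_tables()$table1
  t1 <- t1[!t1$censored, , drop = FALSE]
  if (!include_ter) t1 <- t1[t1$position != 33, , drop = FALSE]
  data.frame(efficiency = t1$efficiency, sigma_d = t1$sigma_d)
}
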