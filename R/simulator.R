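#' Topoisomerase rate parameters
#'
#' Linear-saturating rate laws for the three activities that set diffusible
#' supercoil density: gyrase introduces negative supercoils at up to
#' `k_gyrase` supercoils/s per domain, tapering to zero as sigma approaches
#' its set point; topoisomerase I removes negative supercoils (up to
#' `k_topo1`/s) only on hypernegative DNA below an engagement threshold; and
#' topoisomerase IV removes positive supercoils (up to `k_topo4`/s) only where
#' sigma > 0.
#'
#' @param k_gyrase Max gyrase rate, supercoils/s per domain (WT enzyme works
#'   processively at 4-5 sc/s at 30 C; default 4.5).
#' @param sigma_setpoint Density at which gyrase activity falls to zero.
#' @param k_topo1 Max topoisomerase I relaxation rate, sc/s (matches gyrase).
#' @param sigma_topo1_threshold Density below which Topo I engages.
#' @param k_topo4 Max topoisomerase IV (+)-relaxation rate, sc/s.
#' @return A `topo_params` list.
#' @export
topoisomerase_params <- function(k_gyrase = 4.5, sigma_setpoint = -0.038,
                                 k_topo1 = 4.5, sigma_topo1_threshold = -0.045,
                                 k_topo4 = 0.5) {
  if (k_gyrase < 0 || k_topo1 < 0 || k_topo4 < 0) stop("rates must be >= 0")
  if (sigma_setpoint >= 0) stop("sigma_setpoint must be negative")
  if (sigma_topo1_threshold >= sigma_setpoint)
    stop("sigma_topo1_threshold must be more negative than sigma_setpoint")
  structure(list(k_gyrase = k_gyrase, sigma_setpoint = sigma_setpoint,
                 k_topo1 = k_topo1, sigma_topo1_threshold = sigma_topo1_threshold,
                 k_topo4 = k_topo4),
            class = "topo_params")
}

#' Transcription units for the chromosome model
#'
#' @param position Centisome coordinate of each unit (in \[0, 100)).
#' @param orientation +1 (clockwise, increasing centisomes) or -1 per unit.
#' @param elongation_rate RNAP elongation rate, nt/s (>= 0).
#' @param activity Fraction of time each unit is elongating, in \[0, 1\].
#' @param is_barrier Do active units block supercoil diffusion across their
#'   span? Highly transcribed genes do.
#' @return data.frame of transcription units.
#' @export
transcription_units <- function(position, orientation = 1, elongation_rate = 52.5,
                                activity = 1, is_barrier = TRUE) {
  n <- length(position)
  df <- data.frame(position = position,
                   orientation = rep_len(orientation, n),
                   elongation_rate = rep_len(elongation_rate, n),
                   activity = rep_len(activity, n),
                   is_barrier = rep_len(is_barrier, n))
  if (any(df$position < 0 | df$position >= 100)) stop("positions must lie in [0, 100)")
  if (!all(df$orientation %in% c(-1, 1))) stop("orientation must be +1 or -1")
  if (any(df$activity < 0 | df$activity > 1)) stop("activity must lie in [0, 1]")
  if (any(df$elongation_rate < 0)) stop("elongation_rate must be >= 0")
  df
}

#' Circular domain-partitioned chromosome model
#'
#' The chromosome is a ring of equal supercoil domains (about 10 kb each,
#' 400-500 per genome) that exchange diffusible supercoil density with their
#' neighbours; transcription units pump linking difference from the domain
#' downstream of each unit into the domain upstream (twin-domain flux), and
#' the topoisomerase rate laws act per domain.
#'
#' @param n_domains Number of domains (>= 3; default 450).
#' @param domain_size_bp Domain size in bp (default 10000).
#' @param units data.frame from [transcription_units()] (may have 0 rows).
#' @param topo A `topo_params` list.
#' @param diffusion_rate Density equilibration rate between adjacent domains,
#'   1/s.
#' @param helical_repeat bp per duplex turn.
#' @return An object of class `chromosome_model`.
#' @export
chromosome_model <- function(n_domains = 450, domain_size_bp = 10000,
                             units = transcription_units(numeric(0)),
                             topo = topoisomerase_params(),
                             diffusion_rate = 0.1, helical_repeat = 10.5) {
  if (n_domains < 3) stop("n_domains must be >= 3 (circular adjacency)")
  if (diffusion_rate < 0) stop("diffusion_rate must be >= 0")
  structure(list(n_domains = as.integer(n_domains),
                 domain_size_bp = domain_size_bp,
                 units = units, topo = topo,
                 diffusion_rate = diffusion_rate,
                 helical_repeat = helical_repeat,
                 lk0_domain = domain_size_bp / helical_repeat),
            class = "chromosome_model")
}

#' @export
print.chromosome_model <- function(x, ...) {
  cat(sprintf("Chromosome model: %d x %.0f kb domains, %d transcription units\n",
              x$n_domains, x$domain_size_bp / 1000, nrow(x$units)))
  cat(sprintf("  gyrase %.2f sc/s to set point %.3f; Topo I %.2f sc/s below %.3f; Topo IV %.2f sc/s\n",
              x$topo$k_gyrase, x$topo$sigma_setpoint, x$topo$k_topo1,
              x$topo$sigma_topo1_threshold, x$topo$k_topo4))
  invisible(x)
}

sim_presets <- function() c("wt", "gyrA209", "gyrB652", "gyrB1820", "parE206", "rpoC", "rif")

# default highly-transcribed gene layout: n units evenly spaced around the
# ring, co-oriented with replication (oriC near Cs 84, terminus near Cs 34)
default_units <- function(n_units = 30, elongation_rate = 52.5, activity = 1) {
  pos <- seq(0, 100, length.out = n_units + 1)[seq_len(n_units)]
  orient <- ifelse(pos >= 34 & pos < 84, -1, 1)
  transcription_units(pos, orient, elongation_rate, activity, is_barrier = TRUE)
}

#' Build a chromosome model from a scenario preset or config
#'
#' Presets start from the WT parameterisation (450 domains, gyrase 4.5 sc/s to
#' a set point of -0.038, Topo I 4.5 sc/s below -0.045, Topo IV 0.5 sc/s,
#' diffusion 0.1/s, 30 co-oriented highly transcribed units at 52.5 nt/s,
#' activity 1) and scale the parameter the corresponding allele damages:
#' `gyrA209` halves the gyrase rate, `gyrB652`/`gyrB1820` cut it to 10%,
#' `parE206` halves the Topo IV rate, `rpoC` slows elongation to 60%, and
#' `rif` silences every unit (activity 0, barriers released).
#'
#' @param scenario A preset name, or a list with a `preset` element plus
#'   overrides: `rif` (logical), `n_domains`, `n_units`, `elongation_rate`,
#'   `activity`, `diffusion_rate`, `k_gyrase`, `k_topo1`, `k_topo4`,
#'   `sigma_setpoint`, `sigma_topo1_threshold`.
#' @return A `chromosome_model`.
#' @examples
#' m <- build_model("wt")
#' m$topo$k_gyrase   # 4.5
#' @export
build_model <- function(scenario = "wt") {
  if (is.character(scenario)) scenario <- list(preset = scenario)
  preset <- scenario$preset %||% "wt"
  if (!preset %in% sim_presets())
    stop("unknown preset '", preset, "'; available: ", paste(sim_presets(), collapse = ", "))
  rif <- isTRUE(scenario$rif) || preset == "rif"

  k_gyrase <- scenario$k_gyrase %||% switch(preset,
    gyrA209 = 4.5 * 0.5, gyrB652 = 4.5 * 0.1, gyrB1820 = 4.5 * 0.1, 4.5)
  k_topo4 <- scenario$k_topo4 %||% (if (preset == "parE206") 0.5 * 0.5 else 0.5)
  v_e <- scenario$elongation_rate %||% (if (preset == "rpoC") 52.5 * 0.6 else 52.5)
  units <- default_units(n_units = scenario$n_units %||% 30,
                         elongation_rate = v_e,
                         activity = scenario$activity %||% 1)
  if (rif) {
    units$activity <- 0
    units$is_barrier <- FALSE
  }
  chromosome_model(
    n_domains = scenario$n_domains %||% 450,
    units = units,
    topo = topoisomerase_params(
      k_gyrase = k_gyrase,
      sigma_setpoint = scenario$sigma_setpoint %||% -0.038,
      k_topo1 = scenario$k_topo1 %||% 4.5,
      sigma_topo1_threshold = scenario$sigma_topo1_threshold %||% -0.045,
      k_topo4 = k_topo4),
    diffusion_rate = scenario$diffusion_rate %||% 0.1)
}

#' Initial simulator state
#'
#' @param model A `chromosome_model`.
#' @param sigma Initial per-domain sigma (scalar recycled or full vector);
#'   default 0 (fully relaxed chromosome).
#' @return A `sim_state` with fields `sigma`, `time`, `converged`.
#' @export
sim_state <- function(model, sigma = 0) {
  structure(list(sigma = rep_len(sigma, model$n_domains), time = 0,
                 converged = NA),
            class = "sim_state")
}

#' Total linking difference of a state
#'
#' Sum over domains of sigma_i times the relaxed linking number of one domain.
#' Conserved exactly when all topoisomerase rates are zero, because the two
#' twin-domain fluxes of each unit are equal and opposite and diffusion only
#' moves density between equal-sized domains.
#'
#' @param model A `chromosome_model`.
#' @param state A `sim_state`.
#' @return Linking difference in turns.
#' @export
total_linking_difference <- function(model, state) {
  sum(state$sigma) * model$lk0_domain
}

# map centisome positions to domain indices (1-based)
domain_of_position <- function(model, position) {
  if (any(position < 0 | position >= 100)) stop("positions must lie in [0, 100)")
  (floor(position / 100 * model$n_domains) %% model$n_domains) + 1L
}

# Precompute the static pieces of the rate function: per-domain deposition
# from transcription (turns/s), and per-edge diffusion conductances with
# edges into/out of active barrier units zeroed. Edge i joins domain i to
# domain i + 1 (edge n wraps to domain 1).
sim_plan <- function(model) {
  n <- model$n_domains
  dep <- rep(0, n)
  u <- model$units
  if (nrow(u) > 0) {
    d <- domain_of_position(model, u$position)
    up <- ((d - 1L - u$orientation) %% n) + 1L
    dn <- ((d - 1L + u$orientation) %% n) + 1L
    phi <- u$activity * u$elongation_rate / model$helical_repeat
    for (k in seq_len(nrow(u))) {
      dep[up[k]] <- dep[up[k]] - phi[k]
      dep[dn[k]] <- dep[dn[k]] + phi[k]
    }
  }
  cond <- rep(model$diffusion_rate, n)
  if (nrow(u) > 0) {
    bar <- domain_of_position(model, u$position)[u$is_barrier & u$activity > 0]
    cond[bar] <- 0
    cond[((bar - 2L) %% n) + 1L] <- 0
  }
  list(n = n, dep = dep, cond = cond,
       nxt = c(2:n, 1L), prv = c(n, 1:(n - 1L)),
       ss = abs(model$topo$sigma_setpoint))
}

# dsigma/dt for the current state (1/s per domain)
sim_rates <- function(model, plan, sigma) {
  topo <- model$topo
  gyr <- -topo$k_gyrase * pmin(pmax((sigma - topo$sigma_setpoint) / plan$ss, 0), 1)
  t1 <- topo$k_topo1 * pmin(pmax((topo$sigma_topo1_threshold - sigma) / plan$ss, 0), 1)
  t4 <- -topo$k_topo4 * pmin(pmax(sigma / plan$ss, 0), 1)
  dif <- plan$cond * (sigma[plan$nxt] - sigma) +
    plan$cond[plan$prv] * (sigma[plan$prv] - sigma)
  (plan$dep + gyr + t1 + t4) / model$lk0_domain + dif
}

#' Advance the simulator by one forward-Euler step
#'
#' Per domain and per second, the linking difference changes by the
#' twin-domain transcription flux (activity x v_e / helical repeat out of the
#' upstream neighbour and into the downstream neighbour of each unit), the
#' gyrase, Topo I and Topo IV rate laws, and diffusive exchange with the two
#' neighbours (zeroed across active barrier units). The explicit step is
#' stable for dt <= 0.01 s at the default rates.
#'
#' @param model A `chromosome_model`.
#' @param state A `sim_state`.
#' @param dt Time step in seconds (> 0).
#' @return The advanced `sim_state`.
#' @export
sim_step <- function(model, state, dt) {
  if (dt <= 0) stop("dt must be positive")
  plan <- sim_plan(model)
  sigma <- state$sigma + dt * sim_rates(model, plan, state$sigma)
  if (max(abs(sigma)) > 0.5)
    stop("instability: |sigma| exceeded 0.5; reduce dt or the driving rates")
  structure(list(sigma = sigma, time = state$time + dt, converged = NA),
            class = "sim_state")
}

#' Run the simulator to steady state
#'
#' Iterates forward-Euler steps until the largest per-domain |dsigma/dt|
#' falls below `tol` or `t_max` is reached. Non-convergence is reported in
#' the returned state's `converged` flag, not as an error.
#'
#' @param model A `chromosome_model`.
#' @param dt Step size, seconds.
#' @param tol Convergence tolerance on max |dsigma/dt| (1/s).
#' @param t_max Time horizon, seconds.
#' @param state Optional starting `sim_state` (default: relaxed chromosome).
#' @param check_every Steps between convergence checks.
#' @return A `sim_state` with `converged` set.
#' @export
run_to_steady_state <- function(model, dt = 0.01, tol = 1e-6, t_max = 2000,
                                state = NULL, check_every = 100L) {
  if (dt <= 0) stop("dt must be positive")
  if (is.null(state)) state <- sim_state(model)
  plan <- sim_plan(model)
  sigma <- state$sigma
  t <- state$time
  steps <- ceiling(t_max / dt)
  converged <- FALSE
  for (i in seq_len(steps)) {
    r <- sim_rates(model, plan, sigma)
    sigma <- sigma + dt * r
    if (max(abs(sigma)) > 0.5)
      stop("instability: |sigma| exceeded 0.5; reduce dt or the driving rates")
    if (i %% check_every == 0L && max(abs(r)) < tol) {
      converged <- TRUE
      t <- t + i * dt
      break
    }
  }
  if (!converged) t <- t + steps * dt
  structure(list(sigma = sigma, time = t, converged = converged),
            class = "sim_state")
}

#' Rifampicin experiment: silence transcription and re-equilibrate
#'
#' Sets every unit's activity to zero, releases the diffusion barriers, and
#' runs the silenced model to steady state from the supplied state. This is
#' the in silico analogue of a transient rifampicin block of initiation: the
#' supercoil density rebounds toward the gyrase set point once the
#' transcription-driven flux stops.
#'
#' @param model A `chromosome_model`.
#' @param state Starting `sim_state` (typically a converged profile).
#' @param ... Passed to [run_to_steady_state()].
#' @return The rebound `sim_state`; the silenced model is attached as
#'   attribute `"model"`.
#' @export
rif_experiment <- function(model, state, ...) {
  m <- model
  if (nrow(m$units) > 0) {
    m$units$activity <- 0
    m$units$is_barrier <- FALSE
  }
  out <- run_to_steady_state(m, state = state, ...)
  attr(out, "model") <- m
  out
}

#' Predicted resolution efficiencies along the chromosome
#'
#' Maps centisome positions to their domains' sigma and pushes those through
#' the calibration curve, giving the resolution efficiency a supercoil sensor
#' at each position would report for the simulated state.
#'
#' @param model A `chromosome_model`.
#' @param state A `sim_state`.
#' @param curve A `calibration_curve`.
#' @param positions Centisome coordinates in \[0, 100).
#' @return Named numeric vector of efficiencies.
#' @export
predicted_efficiency_profile <- function(model, state, curve, positions) {
  idx <- domain_of_position(model, positions)
  sig <- pmin(state$sigma[idx], 0)
  stats::setNames(efficiency_at(curve, sig), format(positions))
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("Simulator state at t = %.1f s (converged: %s)\n", x$time, x$converged))
  cat(sprintf("  mean sigma %.4f, range [%.4f, %.4f]\n",
              mean(x$sigma), min(x$sigma), max(x$sigma)))
  invisible(x)
}
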