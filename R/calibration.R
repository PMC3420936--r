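#' Default calibration anchor points
#'
#' The three fixed anchors of the in vivo response curve relating diffusible
#' supercoil density (sigma_D) to gamma-delta resolution efficiency: resolution
#' falls to zero on relaxed DNA (sigma_D >= -0.004), is about 50% at
#' sigma_D = -0.030, and approaches saturation at sigma_D <= -0.040.
#'
#' @param saturation_efficiency Efficiency assigned to the saturation anchor
#'   (the curve "approaches 100%"; an exact 1.0 is unattainable in an endpoint
#'   assay, so 0.99 is used).
#' @return A data.frame with columns `efficiency` and `sigma_d`.
#' @export
calibration_anchors <- function(saturation_efficiency = 0.99) {
  data.frame(efficiency = c(0, 0.5, saturation_efficiency),
             sigma_d = c(-0.004, -0.030, -0.040))
}

# Weighted pool-adjacent-violators for a non-increasing fit of y over
# increasing x. Duplicated x are pooled by weighted mean first. Returns the
# unique x grid, the isotonic fit, and the largest adjustment made.
pava_decreasing <- function(x, y, w) {
  ux <- sort(unique(x))
  y0 <- vapply(ux, function(u) stats::weighted.mean(y[x == u], w[x == u]), 0)
  w0 <- vapply(ux, function(u) sum(w[x == u]), 0)
  # PAVA on -y (non-decreasing)
  v <- -y0; ww <- w0; n <- rep(1L, length(v))
  i <- 1L
  while (i < length(v)) {
    if (v[i + 1L] < v[i] - 1e-15) {
      v[i] <- (v[i] * ww[i] + v[i + 1L] * ww[i + 1L]) / (ww[i] + ww[i + 1L])
      ww[i] <- ww[i] + ww[i + 1L]
      n[i] <- n[i] + n[i + 1L]
      v <- v[-(i + 1L)]; ww <- ww[-(i + 1L)]; n <- n[-(i + 1L)]
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  fit <- -rep(v, n)
  list(x = ux, y = fit, max_adjustment = max(abs(fit - y0)))
}

#' Fit the sigma_D / resolution-efficiency calibration curve
#'
#' Fits a monotone non-increasing map from diffusible supercoil density
#' (sigma_D, dimensionless and non-positive) to in vivo resolution efficiency
#' (fraction of cells deleting the sensor). The default method pools the
#' anchors and observed pairs by weighted isotonic regression and interpolates
#' with a monotone Hermite spline, which tracks the asymmetric shape of the
#' in vivo response. A two-parameter logistic
#' `R(sigma) = 1 / (1 + exp((sigma - sigma50) / w))` is available via
#' `method = "logistic"` for a smooth parametric alternative.
#'
#' Efficiency is hard-clamped to 0 for `sigma >= sigma_relaxed` (relaxed DNA
#' cannot drive synapsis) and to the saturation plateau for `sigma` below the
#' most negative fitted point.
#'
#' @param pairs data.frame with columns `efficiency` (fraction in \[0, 1\]) and
#'   `sigma_d` (in \[-0.06, 0\]); may have zero rows when fitting anchors only.
#' @param anchors data.frame like [calibration_anchors()]; `NULL` to fit pairs
#'   alone.
#' @param method `"monotone"` (default) or `"logistic"`.
#' @param anchor_weight Weight given to each anchor relative to an observed
#'   pair. The anchors are stated exactly while table pairs are rounded, so
#'   they are up-weighted (default 5).
#' @param monotone_tolerance Largest efficiency adjustment the isotonic pooling
#'   may make before the input is flagged as monotone-incompatible (a pair
#'   demanding efficiency to increase as sigma rises toward 0).
#' @return An object of class `calibration_curve` with fields `method`,
#'   `sigma_relaxed`, `sigma_half`, `sigma_saturation`, `knots` (monotone) or
#'   `params` (logistic), `fitted_pairs`, `fit_residual` (RMS residual in
#'   efficiency units) and `monotone_conflict`.
#' @examples
#' cv <- fit_calibration(pairs = NULL)
#' efficiency_at(cv, -0.030)   # ~0.5 by construction
#' @export
fit_calibration <- function(pairs = NULL, anchors = calibration_anchors(),
                            method = c("monotone", "logistic"),
                            anchor_weight = 5, monotone_tolerance = 0.05) {
  method <- match.arg(method)
  if (is.null(pairs)) pairs <- data.frame(efficiency = numeric(), sigma_d = numeric())
  stopifnot(is.data.frame(pairs), all(c("efficiency", "sigma_d") %in% names(pairs)) ||
              nrow(pairs) == 0)
  if (nrow(pairs) > 0) {
    if (any(pairs$sigma_d > 0)) stop("sigma_d must be <= 0: positive supercoil density is not valid for this assay")
    if (any(pairs$efficiency < 0 | pairs$efficiency > 1)) stop("efficiencies must lie in [0, 1]")
    if (any(pairs$sigma_d < -0.06)) stop("sigma_d must lie in [-0.06, 0]")
  }
  eff <- c(if (!is.null(anchors)) anchors$efficiency, pairs$efficiency)
  sig <- c(if (!is.null(anchors)) anchors$sigma_d, pairs$sigma_d)
  w <- c(if (!is.null(anchors)) rep(anchor_weight, nrow(anchors)), rep(1, nrow(pairs)))
  if (length(eff) < 3) stop("need at least 3 (efficiency, sigma_d) points including anchors")

  curve <- list(method = method,
                sigma_relaxed = -0.004,
                sigma_saturation = -0.040,
                fitted_pairs = data.frame(efficiency = eff, sigma_d = sig, weight = w))

  if (method == "monotone") {
    iso <- pava_decreasing(sig, eff, w)
    curve$knots <- data.frame(sigma_d = iso$x, efficiency = iso$y)
    curve$monotone_conflict <- iso$max_adjustment > monotone_tolerance
    if (curve$monotone_conflict)
      warning(sprintf("input pairs conflict with a monotone response (max adjustment %.3f); fit proceeds on the pooled values",
                      iso$max_adjustment))
    curve$spline <- stats::splinefun(iso$x, iso$y, method = "monoH.FC")
  } else {
    f <- function(p) {
      r <- 1 / (1 + exp((sig - p[1]) / exp(p[2])))
      sum(w * (eff - r)^2)
    }
    opt <- stats::optim(c(-0.030, log(0.005)), f, method = "BFGS")
    curve$params <- c(sigma50 = opt$par[1], w = exp(opt$par[2]))
    curve$monotone_conflict <- FALSE
  }
  class(curve) <- "calibration_curve"
  fitted <- efficiency_at(curve, pmin(sig, 0))
  curve$fit_residual <- sqrt(mean((eff - fitted)^2))
  curve$sigma_half <- sigma_from_efficiency(curve, 0.5)$value
  curve
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Supercoil-sensor calibration curve (", x$method, " fit)\n", sep = "")
  cat(sprintf("  sigma at 50%% efficiency : %.4f\n", x$sigma_half))
  cat(sprintf("  relaxed cutoff          : sigma >= %.3f -> efficiency 0\n", x$sigma_relaxed))
  cat(sprintf("  fit RMS residual        : %.4f (efficiency units, %d points)\n",
              x$fit_residual, nrow(x$fitted_pairs)))
  if (isTRUE(x$monotone_conflict))
    cat("  note: input pairs conflicted with monotonicity; isotonic pooling applied\n")
  invisible(x)
}

#' Resolution efficiency expected at a given supercoil density
#'
#' Forward evaluation of the calibration curve. Efficiency is 0 at and above
#' the relaxed cutoff and plateaus at the saturation level below the most
#' negative fitted density.
#'
#' @param curve A `calibration_curve`.
#' @param sigma Diffusible supercoil density values (must be <= 0).
#' @return Efficiencies in \[0, 1\], same length as `sigma`.
#' @export
efficiency_at <- function(curve, sigma) {
  if (any(sigma > 0)) stop("sigma must be <= 0: positive supercoil density is not valid for this curve")
  if (curve$method == "monotone") {
    lo <- min(curve$knots$sigma_d)
    s <- pmin(pmax(sigma, lo), max(curve$knots$sigma_d))
    e <- curve$spline(s)
  } else {
    e <- 1 / (1 + exp((sigma - curve$params[["sigma50"]]) / curve$params[["w"]]))
  }
  e[sigma >= curve$sigma_relaxed] <- 0
  pmin(pmax(e, 0), 1)
}

# Point inversion of the monotone curve. Flat stretches of the isotonic fit
# map an efficiency to an interval; the interval midpoint is returned.
invert_monotone <- function(curve, eff) {
  kx <- curve$knots$sigma_d
  ky <- curve$knots$efficiency
  lo <- min(kx); hi <- curve$sigma_relaxed
  if (eff >= efficiency_at(curve, lo)) return(lo)
  if (eff <= efficiency_at(curve, hi)) return(hi)
  run <- which(abs(ky - eff) < 1e-12)
  if (length(run) > 1 && all(diff(run) == 1))
    return(mean(range(kx[run])))
  stats::uniroot(function(s) efficiency_at(curve, s) - eff, c(lo, hi),
                 tol = .Machine$double.eps^0.75)$root
}

#' Apparent sigma_D from an observed resolution efficiency
#'
#' Monotone inverse of [efficiency_at()]. Efficiencies below the 1% detection
#' limit cannot be placed on the curve and are returned as a magnitude upper
#' bound |sigma_D| <= 0.003; efficiencies at or beyond 95% sit on the
#' saturated shoulder, where point estimates are flagged and extrapolation is
#' capped at -0.045.
#'
#' @param curve A `calibration_curve`.
#' @param eff Single efficiency in \[0, 1\].
#' @param detection_limit Efficiency below which the estimate is censored.
#' @return A `sigma_estimate`: list with `value` (sigma_D, <= 0), `kind`
#'   (`"point"`, `"magnitude_upper_bound"` or `"magnitude_lower_bound"`),
#'   `source_efficiency` and `saturated`.
#' @examples
#' cv <- fit_calibration(pairs = NULL)
#' sigma_from_efficiency(cv, 0.5)$value   # -0.030 by construction
#' @export
sigma_from_efficiency <- function(curve, eff, detection_limit = 0.01) {
  if (length(eff) != 1 || is.na(eff) || eff < 0 || eff > 1)
    stop("eff must be a single value in [0, 1]")
  out <- list(source_efficiency = eff, saturated = FALSE)
  if (eff < detection_limit) {
    out$value <- -0.003
    out$kind <- "magnitude_upper_bound"
    class(out) <- "sigma_estimate"
    return(out)
  }
  raw <- if (curve$method == "monotone") invert_monotone(curve, eff)
         else curve$params[["sigma50"]] + curve$params[["w"]] * log(1 / eff - 1)
  if (eff >= 0.95) {
    out$saturated <- TRUE
    top <- if (curve$method == "monotone") max(curve$knots$efficiency) else 1
    if (eff >= top || raw < -0.045) {
      out$value <- -0.045
      out$kind <- "magnitude_lower_bound"
      class(out) <- "sigma_estimate"
      return(out)
    }
  }
  out$value <- min(max(raw, -0.06), 0)
  out$kind <- "point"
  class(out) <- "sigma_estimate"
  out
}

#' @export
print.sigma_estimate <- function(x, ...) {
  lab <- switch(x$kind,
                point = sprintf("sigma_D = %.4f", x$value),
                magnitude_upper_bound = sprintf("|sigma_D| <= %.3f (below detection)", abs(x$value)),
                magnitude_lower_bound = sprintf("|sigma_D| >= %.3f (saturated)", abs(x$value)))
  cat(lab, sprintf("[efficiency %.3f]\n", x$source_efficiency))
  invisible(x)
}

# Vectorised inversion returning bare sigma values (bounds enter at their
# bound value, mirroring how the printed tables are averaged).
sigma_values_from_efficiency <- function(curve, eff, detection_limit = 0.01) {
  vapply(eff, function(e) sigma_from_efficiency(curve, e, detection_limit)$value, 0)
}

#' Total supercoil density from constrained and diffusible parts
#'
#' Chromosomal supercoil density partitions as sigma = sigma_C + sigma_D,
#' with both parts negative in vivo.
#'
#' @param sigma_constrained Constrained density sigma_C (<= 0).
#' @param sigma_diffusible Diffusible density sigma_D (<= 0).
#' @return The arithmetic sum.
#' @export
total_sigma <- function(sigma_constrained, sigma_diffusible) {
  if (any(sigma_constrained > 0) || any(sigma_diffusible > 0))
    stop("both components of sigma must be <= 0")
  sigma_constrained + sigma_diffusible
}

#' Change in apparent sigma_D between two conditions
#'
#' Inverts both efficiencies through the calibration curve and returns the
#' difference after minus before. Before-values under the detection limit
#' enter at their bound magnitude (|sigma_D| = 0.003).
#'
#' @param curve A `calibration_curve`.
#' @param eff_before,eff_after Efficiencies in \[0, 1\].
#' @return Delta sigma_D (after minus before), a single number.
#' @export
delta_sigma <- function(curve, eff_before, eff_after) {
  if (eff_before < 0 || eff_before > 1 || eff_after < 0 || eff_after > 1)
    stop("efficiencies must lie in [0, 1]")
  sigma_from_efficiency(curve, eff_after)$value -
    sigma_from_efficiency(curve, eff_before)$value
}

#' Serialize a calibration curve to a plain-text file
#'
#' Writes the fitted form (method name plus parameters or knots) at full
#' precision so a re-read curve reproduces the original bit-exactly.
#'
#' @param curve A `calibration_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(curve, path) {
  lines <- c(paste0("method\t", curve$method),
             paste0("sigma_relaxed\t", format_full(curve$sigma_relaxed)),
             paste0("sigma_saturation\t", format_full(curve$sigma_saturation)),
             paste0("sigma_half\t", format_full(curve$sigma_half)),
             paste0("fit_residual\t", format_full(curve$fit_residual)))
  if (curve$method == "monotone") {
    lines <- c(lines, paste0("knot\t", format_full(curve$knots$sigma_d), "\t",
                             format_full(curve$knots$efficiency)))
  } else {
    lines <- c(lines,
               paste0("sigma50\t", format_full(curve$params[["sigma50"]])),
               paste0("w\t", format_full(curve$params[["w"]])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a calibration curve written by [write_calibration()]
#' @param path File path.
#' @return A `calibration_curve`.
#' @export
read_calibration <- function(path) {
  raw <- strsplit(readLines(path), "\t", fixed = TRUE)
  key <- vapply(raw, `[`, "", 1)
  val1 <- vapply(raw, `[`, "", 2)
  curve <- list(method = val1[key == "method"],
                sigma_relaxed = as.numeric(val1[key == "sigma_relaxed"]),
                sigma_saturation = as.numeric(val1[key == "sigma_saturation"]),
                fit_residual = as.numeric(val1[key == "fit_residual"]),
                monotone_conflict = FALSE,
                fitted_pairs = data.frame())
  if (curve$method == "monotone") {
    kx <- as.numeric(val1[key == "knot"])
    ky <- as.numeric(vapply(raw[key == "knot"], `[`, "", 3))
    curve$knots <- data.frame(sigma_d = kx, efficiency = ky)
    curve$spline <- stats::splinefun(kx, ky, method = "monoH.FC")
  } else {
    curve$params <- c(sigma50 = as.numeric(val1[key == "sigma50"]),
                      w = as.numeric(val1[key == "w"]))
  }
  class(curve) <- "calibration_curve"
  curve$sigma_half <- as.numeric(val1[key == "sigma_half"])
  curve
}
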