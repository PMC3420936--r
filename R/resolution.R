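#' Resolution efficiency from replicate colony counts
#'
#' Each replicate plate yields a deletion fraction white/total; the reported
#' efficiency is the unweighted mean over replicates with the sample standard
#' deviation (n - 1 denominator), matching how the assay reports "average
#' +/- 1 SD of at least three independent experiments".
#'
#' @param white_count Integer vector, colonies that deleted the sensor.
#' @param total_count Integer vector, colonies scored (same length).
#' @return List with `mean`, `sd` (NA for a single replicate), `n_replicates`,
#'   `fractions`, and logical flags `few_replicates` (n < 3) and `low_counts`
#'   (any plate with fewer than 200 colonies).
#' @examples
#' efficiency_from_counts(c(162, 158, 166), c(200, 200, 200))
#' @export
efficiency_from_counts <- function(white_count, total_count) {
  if (length(white_count) != length(total_count) || length(white_count) < 1)
    stop("white_count and total_count must be equal-length, non-empty vectors")
  if (any(total_count == 0)) stop("total_count of zero: no colonies were scored")
  if (any(white_count < 0) || any(white_count > total_count))
    stop("white_count must lie in [0, total_count]")
  frac <- white_count / total_count
  few <- length(frac) < 3
  low <- any(total_count < 200)
  if (few) warning("fewer than 3 replicates; SD is unreliable")
  if (low) warning("replicate with fewer than 200 colonies counted")
  list(mean = mean(frac),
       sd = if (length(frac) > 1) stats::sd(frac) else NA_real_,
       n_replicates = length(frac),
       fractions = frac,
       few_replicates = few,
       low_counts = low)
}

#' Censor an efficiency below the assay detection limit
#'
#' Efficiencies under the detection limit (1% by default) are replaced by a
#' fixed substitution value (0.5%) and flagged, mirroring how sub-detection
#' measurements enter genome-wide averages.
#'
#' @param eff Efficiency fractions in \[0, 1\] (vectorised).
#' @param detection_limit Censoring threshold (fraction).
#' @param substitution Value substituted for censored measurements.
#' @return data.frame with columns `value`, `censored`, `substitution`.
#' @export
censor_low <- function(eff, detection_limit = 0.01, substitution = 0.005) {
  if (any(eff < 0 | eff > 1)) stop("efficiencies must lie in [0, 1]")
  cen <- eff < detection_limit
  data.frame(value = ifelse(cen, substitution, eff),
             censored = cen,
             substitution = substitution)
}

#' Mutant Impact Factor
#'
#' The MIF is the resolution efficiency of the WT strain divided by the
#' efficiency of an isogenic mutant at the same position; a large MIF means a
#' dramatic supercoil loss in the mutant. When the mutant is below the
#' detection limit the ratio is a lower bound computed against the detection
#' limit itself.
#'
#' @param wt_eff WT efficiency (fraction, > 0).
#' @param mut_eff Mutant efficiency (fraction); ignored when
#'   `mut_censored = TRUE`.
#' @param mut_censored Is the mutant value below detection?
#' @param detection_limit Detection limit used for bounds.
#' @return List with `value` (unrounded ratio), `bound` (TRUE when the value
#'   is a ">" lower bound) and `display` (2 significant figures, prefixed
#'   with ">" for bounds).
#' @examples
#' mif(0.81, 0.07)$display   # "12"
#' mif(0.81, 0.56)$display   # "1.4"
#' @export
mif <- function(wt_eff, mut_eff, mut_censored = FALSE, detection_limit = 0.01) {
  if (wt_eff <= 0) stop("wt_eff must be positive")
  bound <- isTRUE(mut_censored) || mut_eff == 0
  value <- if (bound) wt_eff / detection_limit else wt_eff / mut_eff
  list(value = value,
       bound = bound,
       display = paste0(if (bound) ">" else "", format(signif(value, 2))))
}

#' Genome-wide aggregate of sensor measurements for one genotype
#'
#' Averages resolution efficiencies (censored values entering at the
#' substitution level) and apparent sigma_D across chromosome positions after
#' dropping excluded sites. The terminus-region sensor (Cs 33) is excluded by
#' default because resolvase binding there is occluded by dif-region proteins,
#' as are the rrnG-flanking pair (Cs 57.64 / 57.65), which probe a local twin
#' domain rather than the genome-wide level. The aggregate MIF against a WT
#' summary is the ratio of mean efficiencies (not the mean of per-site
#' ratios).
#'
#' @param measurements data.frame with columns `position`, `efficiency`
#'   (fraction; NA allowed when `censored`), `censored` (logical), and
#'   optionally `sigma_d` (apparent density already read off the curve, e.g.
#'   from a published table; censored rows at their bound value).
#' @param curve Optional `calibration_curve`; required when `measurements`
#'   lacks a usable `sigma_d` column, in which case each position's sigma is
#'   obtained by inverting its (censored-substituted) efficiency.
#' @param exclude_positions Centisome positions dropped before averaging.
#' @param wt_summary Optional summary of the matched WT genotype (as returned
#'   by this function) used for the aggregate MIF.
#' @param detection_limit,substitution Censoring parameters, see
#'   [censor_low()].
#' @return List with `n_positions`, `mean_efficiency`, `sd_efficiency`,
#'   `mean_sigma`, `sd_sigma`, `mif` (list as in [mif()], or NULL without
#'   `wt_summary`).
#' @export
aggregate_positions <- function(measurements, curve = NULL,
                                exclude_positions = c(33, 57.64, 57.65),
                                wt_summary = NULL,
                                detection_limit = 0.01, substitution = 0.005) {
  m <- measurements[!measurements$position %in% exclude_positions, , drop = FALSE]
  if (nrow(m) < 2) stop("fewer than 2 measurements left after exclusion")
  eff <- ifelse(m$censored, substitution, m$efficiency)
  if (any(is.na(eff))) stop("non-censored rows must carry an efficiency")
  if (!is.null(m$sigma_d) && !any(is.na(m$sigma_d))) {
    sig <- m$sigma_d
  } else {
    if (is.null(curve)) stop("need either a sigma_d column or a calibration curve")
    sig <- sigma_values_from_efficiency(curve, eff, detection_limit)
  }
  out <- list(n_positions = nrow(m),
              mean_efficiency = mean(eff),
              sd_efficiency = stats::sd(eff),
              mean_sigma = mean(sig),
              sd_sigma = stats::sd(sig),
              mif = NULL)
  if (!is.null(wt_summary))
    out$mif <- mif(wt_summary$mean_efficiency, out$mean_efficiency,
                   mut_censored = out$mean_efficiency < detection_limit,
                   detection_limit = detection_limit)
  out
}

#' Rifampicin rebound at one sensor position
#'
#' Compares a strain's resolution efficiency without and with a transient
#' rifampicin block of transcription initiation. Returns the fold change in
#' efficiency (censored before-values enter at the substitution level) and
#' the change in apparent sigma_D through the calibration curve (censored
#' before-values at their |sigma| = 0.003 bound).
#'
#' @param no_rif,rif Lists/rows with fields `strain`, `position`, `efficiency`
#'   and `censored`.
#' @param curve A `calibration_curve`.
#' @param substitution Efficiency substituted for censored before-values in
#'   the fold computation.
#' @return List with `fold` (unrounded), `fold_display` (2 significant
#'   figures) and `delta_sigma`.
#' @export
rif_rebound <- function(no_rif, rif, curve, substitution = 0.005) {
  if (!identical(no_rif$strain, rif$strain) ||
      !identical(no_rif$position, rif$position))
    stop("no_rif and rif measurements must come from the same strain and position")
  eff0 <- if (isTRUE(no_rif$censored)) substitution else no_rif$efficiency
  eff1 <- if (isTRUE(rif$censored)) substitution else rif$efficiency
  fold <- eff1 / eff0
  ds <- delta_sigma(curve,
                    eff_before = if (isTRUE(no_rif$censored)) 0 else no_rif$efficiency,
                    eff_after = if (isTRUE(rif$censored)) 0 else rif$efficiency)
  list(fold = fold, fold_display = format(signif(fold, 2)), delta_sigma = ds)
}

#' Read a replicate colony-count sheet
#'
#' Expected columns: `strain_id`, `position_cs`, `genotype`, `condition`,
#' `replicate_id`, `white_count`, `total_count`.
#'
#' @param path TSV file path.
#' @return data.frame as read.
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_file(path)
  need <- c("strain_id", "position_cs", "genotype", "condition",
            "replicate_id", "white_count", "total_count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("counts sheet is missing columns: ", paste(miss, collapse = ", "))
  df
}

# Collapse a counts sheet to one measurement row per strain/condition.
measurements_from_counts <- function(counts, detection_limit = 0.01) {
  key <- interaction(counts$strain_id, counts$condition, drop = TRUE)
  rows <- lapply(split(counts, key), function(d) {
    est <- suppressWarnings(efficiency_from_counts(d$white_count, d$total_count))
    data.frame(strain = d$strain_id[1],
               position = d$position_cs[1],
               genotype = d$genotype[1],
               condition = d$condition[1],
               efficiency = est$mean,
               efficiency_sd = est$sd,
               n_replicates = est$n_replicates,
               censored = est$mean < detection_limit,
               few_replicates = est$few_replicates,
               low_counts = est$low_counts)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$genotype, out$position, out$condition), , drop = FALSE]
}

#' Render a Table-1-style resolution report
#'
#' One row per strain with efficiency +/- SD (integer percent), MIF against
#' the matched WT at the same position and condition, and the apparent
#' sigma_D from the calibration curve (3 decimals; censored rows as bounds).
#'
#' @param measurements data.frame as produced by internal count collapsing
#'   (columns `strain`, `position`, `genotype`, `condition`, `efficiency`,
#'   `efficiency_sd`, `censored`).
#' @param curve A `calibration_curve`.
#' @param wt_genotype Genotype label of the reference strain set.
#' @return data.frame with display columns.
#' @export
resolution_report <- function(measurements, curve, wt_genotype = "WT") {
  wt <- measurements[measurements$genotype == wt_genotype &
                       measurements$condition == "none", , drop = FALSE]
  fmt_row <- function(r) {
    wt_ref <- wt$efficiency[match(r$position, wt$position)]
    m <- if (!is.na(wt_ref)) mif(wt_ref, r$efficiency, mut_censored = r$censored) else NULL
    if (is.null(m)) warning("no WT reference at position ", r$position, "; MIF left blank")
    est <- sigma_from_efficiency(curve, if (r$censored) 0 else r$efficiency)
    data.frame(strain = r$strain,
               position_cs = r$position,
               genotype = r$genotype,
               condition = r$condition,
               efficiency_pct = if (r$censored) "<1" else
                 sprintf("%.0f+/-%.0f", 100 * r$efficiency, 100 * r$efficiency_sd),
               mif = if (is.null(m)) NA_character_ else m$display,
               sigma_d = if (est$kind == "magnitude_upper_bound")
                 sprintf("<%.3f", est$value) else sprintf("%.3f", est$value))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(measurements)),
                               function(i) fmt_row(measurements[i, , drop = FALSE])))
  rownames(out) <- NULL
  out
}
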