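#' Pooled control statistics for one screening condition
#'
#' Pools all high-control (vehicle) and low-control (full-kill) wells across
#' the supplied plates and summarises each role: count, mean, SD (sample
#' denominator, n - 1) and CV (%). These are the statistics a control run
#' reports alongside S/N and Z'.
#'
#' @param plates `plate_data` rows for a single condition (one cell line, one
#'   effector concentration).
#' @return list of class `control_stats` with `n_high`, `n_low`, `mu_high`,
#'   `mu_low`, `sd_high`, `sd_low`, `cv_high`, `cv_low`.
#' @export
control_stats <- function(plates) {
  plates <- as.data.frame(plates)
  hi <- plates$signal[plates$role == "high_control" & !is.na(plates$signal)]
  lo <- plates$signal[plates$role == "low_control" & !is.na(plates$signal)]
  if (length(hi) < 2L) stop("fewer than 2 high_control wells", call. = FALSE)
  if (length(lo) < 2L) stop("fewer than 2 low_control wells", call. = FALSE)
  cv <- function(x) if (mean(x) > 0) 100 * stats::sd(x) / mean(x) else NA_real_
  structure(list(
    n_high = length(hi), n_low = length(lo),
    mu_high = mean(hi), mu_low = mean(lo),
    sd_high = stats::sd(hi), sd_low = stats::sd(lo),
    cv_high = cv(hi), cv_low = cv(lo)
  ), class = "control_stats")
}

#' Z'-factor
#'
#' Control-separation statistic
#' \eqn{Z' = 1 - 3(\sigma_{high} + \sigma_{low}) / |\mu_{high} - \mu_{low}|}.
#' Always at most 1, equal to 1 only when both SDs vanish, and invariant under
#' positive affine rescaling of all signals.
#'
#' @param stats a `control_stats` object (or any list with `mu_*`/`sd_*`).
#' @return Z' value (dimensionless).
#' @export
zprime <- function(stats) {
  if (stats$mu_high == stats$mu_low) {
    stop("Z' undefined: control means are equal (no separation)",
         call. = FALSE)
  }
  1 - 3 * (stats$sd_high + stats$sd_low) / abs(stats$mu_high - stats$mu_low)
}

#' Signal-to-noise ratio of control means
#'
#' The plain ratio of the high- to low-control mean. Assay reports round it
#' to the nearest integer "n:1" (so 9.73 prints as "10:1"); the computation
#' itself is unrounded.
#'
#' @inheritParams zprime
#' @return list with `ratio` (numeric) and `label` (e.g. `"10:1"`).
#' @export
signal_to_noise <- function(stats) {
  if (stats$mu_low <= 0) stop("S/N undefined: low-control mean <= 0",
                              call. = FALSE)
  r <- stats$mu_high / stats$mu_low
  list(ratio = r, label = paste0(round(r), ":1"))
}

#' Robustness gate on Z'
#'
#' An assay is screen-robust when Z' strictly exceeds the gate (default 0.5).
#' The narrative follows common HTS bands: "excellent" above 0.7, "good" in
#' (0.5, 0.7], "poor" at or below 0.5.
#'
#' @param zp Z' value.
#' @param gate robustness threshold (strict inequality).
#' @return list of class `qc_gate` with `zprime`, `threshold`, `robust`,
#'   `band` and a one-line `narrative`.
#' @export
qc_gate <- function(zp, gate = 0.5) {
  band <- if (zp > 0.7) "excellent" else if (zp > 0.5) "good" else "poor"
  structure(list(
    zprime = zp, threshold = gate, robust = zp > gate, band = band,
    narrative = sprintf(
      "Z' = %.2f: %s separation; assay %s for screening (gate %.2f)",
      zp, band, if (zp > gate) "robust" else "not robust", gate)
  ), class = "qc_gate")
}

#' Full QC report for one condition
#'
#' @param plates control wells for one condition (see [control_stats()]).
#' @param gate Z' robustness gate.
#' @return list of class `qc_report`: `stats`, `s_n`, `zprime`, `robust`,
#'   `band`, `threshold`.
#' @export
qc_report <- function(plates, gate = 0.5) {
  st <- control_stats(plates)
  zp <- zprime(st)
  g <- qc_gate(zp, gate)
  structure(list(stats = st, s_n = signal_to_noise(st), zprime = zp,
                 robust = g$robust, band = g$band, threshold = gate),
            class = "qc_report")
}

#' Growth-kinetics linearity and seeding-density selection
#'
#' Viability-dye conversion must grow linearly over the incubation window for
#' inhibition to be measured accurately. For each seeding density a
#' least-squares line of signal against time is fitted; a density is linear
#' when R-squared meets `r2_min` (default 0.95). Among linear densities the
#' selected one maximizes the signal window, the signal gain between the
#' first timepoint and the horizon (the last common timepoint).
#'
#' @param curves data.frame with columns `density` (cells/well), `time_h` and
#'   `signal`; at least 3 timepoints per density.
#' @param r2_min linearity threshold on R-squared.
#' @return list of class `linearity_result`: `per_density` (data.frame with
#'   `density`, `r2`, `linear`, `signal_window`), `selected_density`
#'   (NA if no density is linear, with `reason`), `selected_horizon` (hours).
#' @export
assess_growth <- function(curves, r2_min = 0.95) {
  curves <- as.data.frame(curves)
  stopifnot(all(c("density", "time_h", "signal") %in% names(curves)))
  per <- lapply(split(curves, curves$density), function(d) {
    d <- d[order(d$time_h), ]
    if (nrow(d) < 3L) stop("density ", d$density[1],
                           " has fewer than 3 timepoints", call. = FALSE)
    if (any(diff(d$time_h) <= 0)) stop("timepoints must be strictly increasing",
                                       call. = FALSE)
    if (stats::var(d$signal) == 0) {
      return(data.frame(density = d$density[1], r2 = NA_real_, linear = FALSE,
                        signal_window = 0, flat = TRUE))
    }
    fit <- stats::lm(signal ~ time_h, data = d)
    r2 <- 1 - sum(stats::resid(fit)^2) /
      sum((d$signal - mean(d$signal))^2)
    data.frame(density = d$density[1], r2 = r2, linear = r2 >= r2_min,
               signal_window = d$signal[nrow(d)] - d$signal[1], flat = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  horizon <- max(curves$time_h)
  lin <- per[per$linear, , drop = FALSE]
  if (nrow(lin) == 0L) {
    res <- list(per_density = per, selected_density = NA_real_,
                selected_horizon = horizon,
                reason = "no seeding density meets the linearity threshold")
  } else {
    res <- list(per_density = per,
                selected_density = lin$density[which.max(lin$signal_window)],
                selected_horizon = horizon, reason = "ok")
  }
  structure(res, class = "linearity_result")
}

#' Aqueous solubility limit from a nephelometry series
#'
#' Precipitation scatters laser light, so turbidity rises sharply above the
#' solubility limit. The threshold is the control-buffer baseline mean plus 3
#' baseline SDs; the limit is the lowest tested concentration whose turbidity
#' exceeds the threshold with every higher tested concentration also
#' exceeding it (a sustained crossing, guarding against single-well spikes).
#' If nothing crosses, the compound is soluble across the tested range.
#'
#' @param concentrations tested concentrations, micromolar (a doubling
#'   dilution series; any order accepted).
#' @param turbidity turbidity per concentration, NTU.
#' @param baseline_values at least 3 replicate control-buffer readings, NTU.
#' @return list of class `solubility_result`: `baseline_mean`, `baseline_sd`,
#'   `threshold` (NTU), `limit` (micromolar, or `NA` with
#'   `limit_label = "above tested range"`).
#' @export
solubility_limit <- function(concentrations, turbidity, baseline_values) {
  stopifnot(length(concentrations) == length(turbidity))
  if (any(concentrations <= 0)) stop("concentrations must be positive",
                                     call. = FALSE)
  if (any(turbidity < 0)) stop("turbidity must be non-negative", call. = FALSE)
  if (length(baseline_values) < 3L) {
    stop("baseline needs at least 3 readings", call. = FALSE)
  }
  o <- order(concentrations)
  conc <- concentrations[o]
  turb <- turbidity[o]
  bm <- mean(baseline_values)
  bs <- stats::sd(baseline_values)
  thr <- bm + 3 * bs
  above <- turb > thr
  # sustained crossing: exceeds here and at every higher concentration
  sustained <- rev(cumprod(rev(above))) == 1
  limit <- if (any(sustained)) conc[which(sustained)[1]] else NA_real_
  structure(list(
    baseline_mean = bm, baseline_sd = bs, threshold = thr, limit = limit,
    limit_label = if (is.na(limit)) "above tested range" else
      paste0(format(limit), " uM")
  ), class = "solubility_result")
}
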