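#' Doubling-dilution series
#'
#' `concentrations[i] = top_conc / 2^(i-1)`: each point half the previous,
#' the standard dose-response design here (12 points from 1, 10 or 100 uM in
#' confirmation studies; 22-24 points for effector characterization).
#'
#' @param top_conc top concentration, micromolar (> 0).
#' @param n_points number of dilutions (>= 2).
#' @return numeric vector of strictly decreasing concentrations.
#' @export
make_doubling_dilutions <- function(top_conc, n_points) {
  if (!is.finite(top_conc) || top_conc <= 0) {
    stop("top_conc must be positive", call. = FALSE)
  }
  if (n_points < 2) stop("n_points must be at least 2", call. = FALSE)
  top_conc / 2^(seq_len(n_points) - 1)
}

#' Four-parameter logistic response
#'
#' \eqn{y(c) = bottom + (top - bottom) / (1 + (ic50/c)^{hill})}; monotone
#' increasing in concentration for `hill > 0`, with `y(ic50)` exactly halfway
#' between bottom and top.
#'
#' @param conc concentration(s), micromolar.
#' @param bottom,top lower/upper asymptote (%I units).
#' @param ic50 midpoint concentration, micromolar.
#' @param hill slope.
#' @return response in %I units.
#' @export
four_pl <- function(conc, bottom, top, ic50, hill) {
  bottom + (top - bottom) / (1 + (ic50 / conc)^hill)
}

#' Censored potency value
#'
#' An IC50 is either exact (`qualifier "="`) or right-censored
#' (`qualifier ">"`, value pinned to the censor limit) when maximal observed
#' inhibition stayed below 50% within the tested range.
#'
#' @param qualifier `"="` or `">"`.
#' @param value micromolar; for `">"` this must equal `censor_limit`.
#' @param censor_limit top tested concentration, micromolar.
#' @return object of class `censored_value`.
#' @export
censored_value <- function(qualifier = "=", value, censor_limit = 100) {
  qualifier <- match.arg(qualifier, c("=", ">"))
  if (qualifier == ">") {
    value <- censor_limit
  } else if (!is.finite(value) || value <= 0) {
    stop("exact censored_value needs a positive value", call. = FALSE)
  }
  structure(list(qualifier = qualifier, value = value,
                 censor_limit = censor_limit),
            class = "censored_value")
}

#' @export
format.censored_value <- function(x, digits = 3, ...) {
  if (x$qualifier == ">") paste0(">", format(x$censor_limit, ...))
  else format(signif(x$value, digits), ...)
}

#' @export
print.censored_value <- function(x, ...) {
  cat("IC50 ", if (x$qualifier == ">") ">" else "= ", format(x), " uM\n",
      sep = "")
  invisible(x)
}

#' Parse a printed IC50 entry
#'
#' Published potency tables print exact values ("8.6"), censored values
#' (">100") and partial-curve flags (a trailing "*"). This parses that
#' notation back into a [censored_value()] plus a partial flag.
#'
#' @param text character vector of entries like `"24*"`, `">100"`, `"8.6"`.
#' @param censor_limit censor limit assumed for `">"` entries.
#' @return list of lists, each with `ic50` (censored_value) and `partial`.
#' @export
parse_ic50_entry <- function(text, censor_limit = 100) {
  lapply(as.character(text), function(s) {
    s <- trimws(s)
    partial <- grepl("\\*$", s)
    s <- sub("\\*+$", "", s)
    if (grepl("^>", s)) {
      lim <- as.numeric(sub("^>", "", s))
      list(ic50 = censored_value(">", censor_limit = lim), partial = partial)
    } else {
      list(ic50 = censored_value("=", as.numeric(s), censor_limit),
           partial = partial)
    }
  })
}

#' Partial-curve rule
#'
#' A dose-response curve is partial when its maximum observed inhibition is
#' below 65%, or when it fails to reach an asymptote at the top tested
#' concentrations -- operationalized as the observed %I at the top dose
#' lying more than `plateau_tol` percentage points below the fitted top.
#'
#' @param max_observed_pct maximum mean %I over the series.
#' @param top_dose_pct observed mean %I at the top concentration.
#' @param fitted_top fitted upper asymptote (`NA` skips the asymptote branch).
#' @param plateau_tol plateau tolerance, percentage points.
#' @return logical.
#' @export
flag_partial <- function(max_observed_pct, top_dose_pct = NA,
                         fitted_top = NA, plateau_tol = 5) {
  if (max_observed_pct < 65) return(TRUE)
  if (!is.na(top_dose_pct) && !is.na(fitted_top)) {
    return(abs(top_dose_pct - fitted_top) > plateau_tol)
  }
  FALSE
}

#' IC50 censoring rule
#'
#' When maximal observed inhibition stays strictly below 50% even at the top
#' tested concentration, no accurate IC50 exists and the result is reported
#' as greater than the censor limit. Otherwise the fitted value is reported
#' exactly (the partial flag travels alongside as the table asterisk).
#'
#' @param fitted_ic50 fitted midpoint, micromolar (may be `NA` on fit failure).
#' @param max_observed_pct maximum mean %I over the series.
#' @param limit censor limit, micromolar (defaults to the top tested
#'   concentration in the calling code).
#' @return [censored_value()].
#' @export
censor_ic50 <- function(fitted_ic50, max_observed_pct, limit = 100) {
  if (max_observed_pct < 50 || is.na(fitted_ic50)) {
    censored_value(">", censor_limit = limit)
  } else {
    censored_value("=", fitted_ic50, limit)
  }
}

#' Fit a censored four-parameter logistic dose-response curve
#'
#' Replicate %I values at each concentration are averaged, then the 4PL is
#' fitted to mean %I against log10 concentration by bounded
#' Levenberg-Marquardt least squares. Bounds: bottom in [-20, 30], top in
#' [30, 120], IC50 within [lowest dose / 4, 4 x top dose], hill in (0, 10].
#' Initialization: bottom = min %I, top = max %I (clamped into bounds), IC50 =
#' concentration nearest half-maximal response, hill = 1. The partial-curve
#' and censoring rules are then applied; if the optimizer fails (or the
#' response is constant) the result carries no parameters and a censored
#' IC50 with `no_fit = TRUE`.
#'
#' @param conc concentrations, micromolar (>= 5 distinct values spanning at
#'   least 2 log2 units).
#' @param pct_i %I observations, same length as `conc` (replicates allowed:
#'   repeat concentrations).
#' @param censor_limit censor limit; default the top tested concentration.
#' @param plateau_tol plateau tolerance for the asymptote test.
#' @return list of class `fit_4pl`: `params` (list bottom/top/ic50/hill or
#'   `NULL`), `max_observed_pct`, `top_dose_pct`, `partial`, `ic50`
#'   (censored_value), `no_fit`, `rmse`, `n_points`.
#' @export
fit_4pl <- function(conc, pct_i, censor_limit = NULL, plateau_tol = 5) {
  stopifnot(length(conc) == length(pct_i))
  keep <- is.finite(conc) & is.finite(pct_i) & conc > 0
  conc <- conc[keep]; pct_i <- pct_i[keep]
  mu <- tapply(pct_i, conc, mean)
  cc <- as.numeric(names(mu))
  o <- order(cc)
  cc <- cc[o]; mu <- as.numeric(mu)[o]
  if (length(cc) < 5L) stop("need at least 5 distinct concentrations",
                            call. = FALSE)
  if (log2(max(cc) / min(cc)) < 2) {
    stop("concentrations must span at least 2 doubling steps", call. = FALSE)
  }
  if (is.null(censor_limit)) censor_limit <- max(cc)
  max_obs <- max(mu)
  top_dose_pct <- mu[length(mu)]

  params <- NULL
  rmse <- NA_real_
  no_fit <- FALSE
  if (stats::var(mu) == 0) {
    no_fit <- TRUE
  } else {
    lc <- log10(cc)
    lower <- c(bottom = -20, top = 30, lic50 = log10(min(cc) / 4),
               hill = 1e-3)
    upper <- c(bottom = 30, top = 120, lic50 = log10(4 * max(cc)), hill = 10)
    lic0 <- lc[which.min(abs(mu - (min(mu) + max(mu)) / 2))]
    lic0 <- min(max(lic0, lower["lic50"]), upper["lic50"])
    # Levenberg-Marquardt from a single start is brittle (boundary-pinned
    # local optima, occasional singular initial Jacobian); a small start
    # grid over hill and the asymptotes keeps the best fit by SSE.
    starts <- expand.grid(
      bottom = unique(c(min(max(min(mu), -20), 30), 0)),
      top = unique(c(max(min(max(mu), 120), 30), 100)),
      hill = c(0.5, 1, 2, 4))
    best_sse <- Inf
    fit <- NULL
    for (s in seq_len(nrow(starts))) {
      cand <- tryCatch(
        minpack.lm::nlsLM(
          mu ~ bottom + (top - bottom) / (1 + 10^(hill * (lic50 - lc))),
          start = list(bottom = starts$bottom[s], top = starts$top[s],
                       lic50 = unname(lic0), hill = starts$hill[s]),
          lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(cand)) {
        sse <- sum(stats::resid(cand)^2)
        if (sse < best_sse) {
          best_sse <- sse
          fit <- cand
        }
      }
    }
    if (is.null(fit)) {
      no_fit <- TRUE
    } else {
      cf <- stats::coef(fit)
      params <- list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                     ic50 = unname(10^cf["lic50"]), hill = unname(cf["hill"]))
      rmse <- sqrt(best_sse / length(mu))
    }
  }
  partial <- flag_partial(max_obs, top_dose_pct,
                          if (is.null(params)) NA else params$top, plateau_tol)
  ic50 <- censor_ic50(if (is.null(params)) NA else params$ic50, max_obs,
                      censor_limit)
  structure(list(params = params, max_observed_pct = max_obs,
                 top_dose_pct = top_dose_pct, partial = partial, ic50 = ic50,
                 no_fit = no_fit, rmse = rmse, n_points = length(cc)),
            class = "fit_4pl")
}

#' Fold shift between censored potency values
#'
#' Compares the potency without effector (`ref`) and with effector (`treat`):
#' \itemize{
#'   \item both exact: `magnitude = max(r, 1/r)` with `r = ref/treat`;
#'     direction `gain` if the effector lowered the IC50, `loss` if it raised
#'     it, `none` if equal; qualifier `"="`.
#'   \item `treat` censored, `ref` exact: a potency loss of at least
#'     `limit / ref` fold (qualifier `">"`), a true lower bound.
#'   \item `ref` censored, `treat` exact: a gain of at least `limit / treat`
#'     fold.
#'   \item both censored: `indeterminate` -- censored values never enter
#'     ratios as if exact.
#' }
#' When the exact operand already exceeds the censor limit the bound is
#' vacuous (< 1) and the shift is `indeterminate` with magnitude 1.
#'
#' @param ref [censored_value()] at 0 uM effector.
#' @param treat [censored_value()] with effector co-treatment.
#' @return list of class `fold_shift`: `direction` (gain/loss/none/
#'   indeterminate), `qualifier` (`"="`/`">"`), `magnitude` (>= 1).
#' @export
fold_shift <- function(ref, treat) {
  stopifnot(inherits(ref, "censored_value"), inherits(treat, "censored_value"))
  if (ref$value <= 0 || treat$value <= 0) {
    stop("potency values must be positive", call. = FALSE)
  }
  mk <- function(direction, qualifier, magnitude) {
    structure(list(direction = direction, qualifier = qualifier,
                   magnitude = magnitude), class = "fold_shift")
  }
  rc <- ref$qualifier == ">"
  tc <- treat$qualifier == ">"
  if (rc && tc) return(mk("indeterminate", ">", 1))
  if (!rc && !tc) {
    r <- ref$value / treat$value
    if (r == 1) return(mk("none", "=", 1))
    return(mk(if (r > 1) "gain" else "loss", "=", max(r, 1 / r)))
  }
  if (tc) {                             # treat censored: potency lost
    bound <- treat$censor_limit / ref$value
    if (bound <= 1) return(mk("indeterminate", ">", 1))
    return(mk("loss", ">", bound))
  }
  bound <- ref$censor_limit / treat$value  # ref censored: potency gained
  if (bound <= 1) return(mk("indeterminate", ">", 1))
  mk("gain", ">", bound)
}

#' @export
format.fold_shift <- function(x, ...) {
  if (x$direction %in% c("none", "indeterminate")) return(x$direction)
  paste0(x$direction, " ", if (x$qualifier == ">") ">" else "",
         round(x$magnitude), "-fold")
}

#' Agonist/antagonist confirmation from fold shifts
#'
#' A compound is `agonist_confirmed` when any cell line shows a potency gain
#' of at least `fold_threshold` at the confirmation effector concentration
#' (default 80 uM); `antagonist_confirmed` likewise for losses. Censored
#' bounds count when the bound itself meets the threshold (they are true
#' lower bounds). If different lines confirm opposite directions the call
#' follows the larger magnitude and the conflict is flagged.
#'
#' @param shifts data.frame with columns `cell_line`, `effector_uM`,
#'   `direction`, `qualifier`, `magnitude` (one row per evaluated shift; see
#'   [fold_shift()]).
#' @param fold_threshold confirmation threshold (default 2).
#' @param effector_conc effector concentration at which confirmation is
#'   assessed (default 80).
#' @return list of class `modulation_call`: `call` (agonist_confirmed /
#'   antagonist_confirmed / neutral), `conflict`, `best_gain`, `best_loss`,
#'   `evidence` (the input rows at `effector_conc`).
#' @export
classify_modulation <- function(shifts, fold_threshold = 2,
                                effector_conc = 80) {
  shifts <- as.data.frame(shifts)
  if (nrow(shifts) == 0L) stop("empty fold-shift evidence", call. = FALSE)
  ev <- shifts[shifts$effector_uM == effector_conc, , drop = FALSE]
  gains <- ev$magnitude[ev$direction == "gain"]
  losses <- ev$magnitude[ev$direction == "loss"]
  best_gain <- if (length(gains)) max(gains) else NA_real_
  best_loss <- if (length(losses)) max(losses) else NA_real_
  ag <- !is.na(best_gain) && best_gain >= fold_threshold
  an <- !is.na(best_loss) && best_loss >= fold_threshold
  conflict <- ag && an
  call <- if (conflict) {
    if (best_gain >= best_loss) "agonist_confirmed" else "antagonist_confirmed"
  } else if (ag) "agonist_confirmed" else if (an) "antagonist_confirmed"
  else "neutral"
  structure(list(call = call, conflict = conflict, best_gain = best_gain,
                 best_loss = best_loss, evidence = ev),
            class = "modulation_call")
}

#' Cell-line panel profiling of confirmed compounds
#'
#' Counts, per compound, the cell lines in which the effector shifted potency
#' by at least `fold_threshold` (in the compound's confirmed direction) at
#' either panel effector concentration (30 or 80 uM). A compound is
#' `panel_confirmed` when at least `min_lines` qualifying lines are
#' non-retinoblastoma, i.e. the combination effect generalizes beyond the
#' screening disease model. Also emits a heatmap-ready matrix of printed
#' IC50 entries per (compound, line, effector concentration).
#'
#' @param shifts data.frame with columns `compound_id`, `cell_line`,
#'   `effector_uM`, `direction`, `qualifier`, `magnitude`.
#' @param line_info data.frame with columns `cell_line` and `retinoblastoma`
#'   (logical) covering every line in `shifts`.
#' @param direction per-compound direction to count (`"gain"` for agonists,
#'   `"loss"` for antagonists); a named character vector keyed by
#'   compound_id, or a single value for all.
#' @param fold_threshold qualifying threshold (default 2).
#' @param effector_concs panel concentrations considered (default 30 and 80).
#' @param min_lines required number of qualifying non-retinoblastoma lines.
#' @param ic50_table optional data.frame `compound_id`, `cell_line`,
#'   `effector_uM`, `ic50_label` used to build the heatmap matrix.
#' @return list: `summary` (compound_id, direction, n_qualifying_lines,
#'   n_qualifying_nonrb, panel_confirmed), `heatmap` (matrix of labels or
#'   `NULL`).
#' @export
panel_profile <- function(shifts, line_info, direction, fold_threshold = 2,
                          effector_concs = c(30, 80), min_lines = 3,
                          ic50_table = NULL) {
  shifts <- as.data.frame(shifts)
  unknown <- setdiff(unique(shifts$cell_line), line_info$cell_line)
  if (length(unknown)) {
    stop("cell line(s) without retinoblastoma label: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  compounds <- unique(shifts$compound_id)
  dir_of <- function(id) {
    if (length(direction) == 1L && is.null(names(direction))) direction
    else unname(direction[[id]])
  }
  rows <- lapply(compounds, function(id) {
    want <- dir_of(id)
    s <- shifts[shifts$compound_id == id &
                  shifts$effector_uM %in% effector_concs &
                  shifts$direction == want &
                  shifts$magnitude >= fold_threshold, , drop = FALSE]
    qual <- unique(s$cell_line)
    nonrb <- qual[!line_info$retinoblastoma[match(qual, line_info$cell_line)]]
    data.frame(compound_id = id, direction = want,
               n_qualifying_lines = length(qual),
               n_qualifying_nonrb = length(nonrb),
               panel_confirmed = length(nonrb) >= min_lines)
  })
  summary <- do.call(rbind, rows)
  heat <- NULL
  if (!is.null(ic50_table)) {
    key <- paste(ic50_table$cell_line, ic50_table$effector_uM, sep = "@")
    heat <- stats::xtabs(~ compound_id + key,
                         data = data.frame(compound_id = ic50_table$compound_id,
                                           key = key))
    heat <- matrix(NA_character_, nrow = length(unique(ic50_table$compound_id)),
                   ncol = length(unique(key)),
                   dimnames = list(unique(ic50_table$compound_id),
                                   sort(unique(key))))
    for (i in seq_len(nrow(ic50_table))) {
      heat[ic50_table$compound_id[i], key[i]] <- ic50_table$ic50_label[i]
    }
  }
  list(summary = summary, heatmap = heat)
}

#' Format a dose-response results row
#'
#' Censored entries print as `">100"` and partial entries carry a trailing
#' `"*"`, the notation of published potency tables.
#'
#' @param ic50 [censored_value()].
#' @param partial logical partial-curve flag.
#' @return character scalar, e.g. `"8.6"`, `">100*"`.
#' @export
format_ic50 <- function(ic50, partial = FALSE) {
  paste0(format(ic50), if (partial) "*" else "")
}
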