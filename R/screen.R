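#' Percent inhibition
#'
#' Plate normalization of a raw read against the control means of the same
#' condition: \eqn{\%I = (\mu_{high} - read) / (\mu_{high} - \mu_{low}) \times 100}.
#' 0% at the vehicle (high) control mean, 100% at the full-kill (low) control
#' mean. Values are never clipped: negative %I (growth stimulation) and
#' values above 100 are legal and preserved. Controls must come from the
#' plate set treated with the same effector concentration as the read;
#' cross-condition normalization is only ever a diagnostic.
#'
#' @param read raw signal(s).
#' @param mu_high,mu_low control means.
#' @return percent inhibition, same length as `read`.
#' @export
percent_inhibition <- function(read, mu_high, mu_low) {
  if (mu_high == mu_low) {
    stop("%I undefined: control means are equal", call. = FALSE)
  }
  (mu_high - read) / (mu_high - mu_low) * 100
}

#' Duplicate-screen concordance
#'
#' Squared Pearson correlation of replicate-1 against replicate-2 percent
#' inhibition across the screen; the standard reproducibility summary for a
#' duplicate screen.
#'
#' @param rep1,rep2 paired %I vectors (>= 3 pairs).
#' @return R-squared.
#' @export
replicate_concordance <- function(rep1, rep2) {
  keep <- !is.na(rep1) & !is.na(rep2)
  rep1 <- rep1[keep]; rep2 <- rep2[keep]
  if (length(rep1) < 3L) stop("need at least 3 replicate pairs", call. = FALSE)
  if (stats::var(rep1) == 0 || stats::var(rep2) == 0) {
    stop("R^2 undefined: a replicate has zero variance", call. = FALSE)
  }
  stats::cor(rep1, rep2)^2
}

.dual_classes <- c("agonist_candidate", "antagonist_candidate", "active_both",
                   "inactive", "ambiguous")

#' Dual-condition hit classification
#'
#' Classifies a compound from its mean %I with (`pct_plus`) and without
#' (`pct_minus`) the companion effector, against a single threshold (default
#' 50%):
#' \itemize{
#'   \item `agonist_candidate`: at least threshold with effector, at most
#'     threshold without, and strictly more inhibition with effector;
#'   \item `antagonist_candidate`: the mirror image;
#'   \item `active_both`: above threshold in both conditions (potent
#'     regardless of effector);
#'   \item `inactive`: below threshold in both;
#'   \item `ambiguous`: exactly at threshold in both (the one tie the
#'     selection rule cannot orient).
#' }
#' The strict ordering between conditions makes the classes mutually
#' exclusive: a compound is never simultaneously agonist and antagonist.
#'
#' @param pct_plus,pct_minus mean %I with / without effector (vectorized).
#' @param hit_pct selection threshold in percent, strictly between 0 and 100.
#' @return character vector of classes.
#' @export
classify_dual_condition <- function(pct_plus, pct_minus, hit_pct = 50) {
  stopifnot(hit_pct > 0, hit_pct < 100)
  stopifnot(length(pct_plus) == length(pct_minus))
  out <- character(length(pct_plus))
  out[pct_plus > hit_pct & pct_minus > hit_pct] <- "active_both"
  out[pct_plus < hit_pct & pct_minus < hit_pct] <- "inactive"
  ag <- pct_plus >= hit_pct & pct_minus <= hit_pct & pct_plus > pct_minus
  an <- pct_minus >= hit_pct & pct_plus <= hit_pct & pct_minus > pct_plus
  out[ag] <- "agonist_candidate"
  out[an] <- "antagonist_candidate"
  out[pct_plus == hit_pct & pct_minus == hit_pct] <- "ambiguous"
  out[is.na(pct_plus) | is.na(pct_minus)] <- NA_character_
  out
}

#' Per-compound screen profiles from plate data
#'
#' Normalizes every sample well against its own condition's control means
#' (computed from the control wells on the same condition's plates), averages
#' duplicates, and classifies each compound per cell line.
#'
#' @param plates `plate_data` for a whole screen: both effector conditions,
#'   one or more cell lines, duplicate sample wells.
#' @param effector_pair numeric length-2: the "without"/"with" effector
#'   concentrations to contrast (default `c(0, 80)`).
#' @param hit_pct selection threshold.
#' @param strict_replicates if `TRUE`, each replicate must satisfy the class
#'   rule individually, not just the mean (optional strict mode).
#' @return data.frame: `compound_id`, `cell_line`, `pct_minus`, `pct_plus`,
#'   replicate values (`;`-joined in `reps_minus`/`reps_plus`) and `class`.
#' @export
screen_profiles <- function(plates, effector_pair = c(0, 80), hit_pct = 50,
                            strict_replicates = FALSE) {
  plates <- as.data.frame(plates)
  plates <- plates[plates$effector_uM %in% effector_pair, ]
  if (nrow(plates) == 0L) stop("no wells at the requested effector pair",
                               call. = FALSE)
  cond_key <- interaction(plates$cell_line, plates$effector_uM, drop = TRUE)
  pieces <- lapply(split(plates, cond_key), function(p) {
    st <- control_stats(p)
    s <- p[p$role == "sample" & !is.na(p$compound_id), ]
    s$pct_i <- percent_inhibition(s$signal, st$mu_high, st$mu_low)
    s
  })
  sm <- do.call(rbind, pieces)
  agg <- stats::aggregate(pct_i ~ compound_id + cell_line + effector_uM,
                          data = sm, FUN = mean)
  reps <- stats::aggregate(pct_i ~ compound_id + cell_line + effector_uM,
                           data = sm,
                           FUN = function(x) paste(signif(x, 8), collapse = ";"))
  names(reps)[names(reps) == "pct_i"] <- "reps"
  agg <- merge(agg, reps, by = c("compound_id", "cell_line", "effector_uM"))
  lo <- agg[agg$effector_uM == effector_pair[1], ]
  hi <- agg[agg$effector_uM == effector_pair[2], ]
  prof <- merge(
    stats::setNames(lo[, c("compound_id", "cell_line", "pct_i", "reps")],
                    c("compound_id", "cell_line", "pct_minus", "reps_minus")),
    stats::setNames(hi[, c("compound_id", "cell_line", "pct_i", "reps")],
                    c("compound_id", "cell_line", "pct_plus", "reps_plus")),
    by = c("compound_id", "cell_line"))
  prof$class <- classify_dual_condition(prof$pct_plus, prof$pct_minus, hit_pct)
  if (strict_replicates) {
    rp <- function(s) as.numeric(strsplit(s, ";")[[1]])
    for (i in seq_len(nrow(prof))) {
      cls <- prof$class[i]
      if (cls %in% c("agonist_candidate", "antagonist_candidate")) {
        per_rep <- classify_dual_condition(
          rp(prof$reps_plus[i]),
          rep(rp(prof$reps_minus[i]), length.out = length(rp(prof$reps_plus[i]))),
          hit_pct)
        if (!all(per_rep == cls)) prof$class[i] <- "ambiguous"
      }
    }
  }
  prof[order(prof$compound_id, prof$cell_line), , drop = FALSE]
}

#' Cross-cell-line refinement of candidates
#'
#' A candidate from the primary cell line survives only if it carries the
#' same dual-condition class in the secondary line; candidates missing the
#' secondary line are excluded with a warning. Output keeps the per-line %I
#' evidence.
#'
#' @param profiles output of [screen_profiles()] covering both cell lines.
#' @param primary,secondary cell-line identifiers.
#' @return list with data.frames `agonists` and `antagonists` (wide per-line
#'   evidence) and `dropped` (compound, reason).
#' @export
refine_across_cell_lines <- function(profiles, primary, secondary) {
  p1 <- profiles[profiles$cell_line == primary, ]
  p2 <- profiles[profiles$cell_line == secondary, ]
  if (nrow(p1) == 0L) stop("primary cell line absent from profiles",
                           call. = FALSE)
  pick <- function(klass) {
    cand <- p1[!is.na(p1$class) & p1$class == klass, ]
    if (nrow(cand) == 0L) {
      return(list(kept = cand[0, ], dropped = data.frame(compound_id = character(),
                                                         reason = character())))
    }
    m <- match(cand$compound_id, p2$compound_id)
    missing <- is.na(m)
    if (any(missing)) {
      warning(sum(missing), " ", klass, " candidate(s) missing the secondary",
              " cell line; excluded", call. = FALSE)
    }
    same <- !missing & p2$class[m] == klass
    kept <- cand[same, c("compound_id", "pct_minus", "pct_plus")]
    names(kept) <- c("compound_id", "primary_pct_minus", "primary_pct_plus")
    kept$secondary_pct_minus <- p2$pct_minus[m][same]
    kept$secondary_pct_plus <- p2$pct_plus[m][same]
    dropped <- data.frame(
      compound_id = cand$compound_id[!same],
      reason = ifelse(missing[!same], "missing secondary cell line",
                      paste0("secondary class: ", p2$class[m][!same])))
    list(kept = kept, dropped = dropped)
  }
  ag <- pick("agonist_candidate")
  an <- pick("antagonist_candidate")
  list(agonists = ag$kept, antagonists = an$kept,
       dropped = rbind(ag$dropped, an$dropped))
}

#' Collapse candidate wells to unique compounds
#'
#' Multi-sourced libraries carry the same compound in several wells; hits
#' collapse by canonical identifier and the copy count is kept as a
#' concordance signal (the same compound selected independently from two
#' libraries is flagged `independently_replicated`).
#'
#' @param candidate_ids character vector of candidate compound names/ids (one
#'   per selected library well).
#' @param registry output of [build_registry()] covering all candidates.
#' @return data.frame `compound_id`, `n_selected_wells`, `copies`,
#'   `independently_replicated`.
#' @export
deduplicate_hits <- function(candidate_ids, registry) {
  ids <- canonical_compound_id(candidate_ids)
  m <- match(ids, registry$compound_id)
  if (anyNA(m)) {
    stop("candidate absent from registry: ", ids[which(is.na(m))[1]],
         call. = FALSE)
  }
  tab <- table(ids)
  out <- data.frame(compound_id = names(tab),
                    n_selected_wells = as.integer(tab))
  out$copies <- registry$copies[match(out$compound_id, registry$compound_id)]
  out$independently_replicated <- out$n_selected_wells > 1L
  out[order(out$compound_id), , drop = FALSE]
}
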