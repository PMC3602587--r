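#' Resolved pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: selection
#' threshold (50 %I), confirmation fold threshold (2), Z' robustness gate
#' (0.5), growth-linearity R-squared (0.95), plateau tolerance (5 points),
#' censor limit (100 uM), effector concentrations (0/30/80 uM), screen size
#' and planted classes, noise model, and the cell-line panel with
#' retinoblastoma tags. A run's resolved config is archived as JSON next to
#' its outputs.
#'
#' @param seed global seed fanned out to stage sub-seeds.
#' @param n_compounds,planted screen size and planted class counts.
#' @param noise_cv,plate_shift_sd well/plate noise (see [noise_model()]).
#' @param hit_pct,fold_threshold,zprime_gate,linearity_r2,plateau_tol,censor_limit
#'   pipeline thresholds.
#' @param effector_concs tested effector concentrations, micromolar.
#' @param screen_lines the two screening cell lines (primary first).
#' @param panel_lines extra dose-response panel lines.
#' @param panel_rb logical: retinoblastoma tag per panel line.
#' @param dr_noise_sd dose-response %I noise SD.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, n_compounds = 6912,
                       planted = c(agonist = 88, antagonist = 67),
                       noise_cv = 0, plate_shift_sd = 0,
                       hit_pct = 50, fold_threshold = 2, zprime_gate = 0.5,
                       linearity_r2 = 0.95, plateau_tol = 5,
                       censor_limit = 100,
                       effector_concs = c(0, 30, 80),
                       screen_lines = c("Y79", "RB355"),
                       panel_lines = c("OCM290", "A2780", "MDA-MB-231"),
                       panel_rb = c(FALSE, FALSE, FALSE),
                       dr_noise_sd = 0) {
  structure(list(
    seed = as.integer(seed), n_compounds = n_compounds, planted = planted,
    noise_cv = noise_cv, plate_shift_sd = plate_shift_sd, hit_pct = hit_pct,
    fold_threshold = fold_threshold, zprime_gate = zprime_gate,
    linearity_r2 = linearity_r2, plateau_tol = plateau_tol,
    censor_limit = censor_limit, effector_concs = effector_concs,
    screen_lines = screen_lines, panel_lines = panel_lines,
    panel_rb = panel_rb, dr_noise_sd = dr_noise_sd
  ), class = "run_config")
}

#' Planted dose-response truth for confirmed-hit follow-up
#'
#' Builds the 4PL truth table the dose-response generator consumes: for each
#' followed-up compound and cell line, a base IC50 (log-uniform in 2-40 uM)
#' shifted under effector co-treatment by the compound's planted class --
#' agonists gain 4-fold at 80 uM (2-fold at 30), antagonists lose 8-fold at
#' 80 (2.5-fold at 30), inactive/neutral compounds shift < 1.3-fold.
#'
#' @param compound_ids compounds to follow up.
#' @param classes planted class per compound (`agonist` / `antagonist` /
#'   other).
#' @param cell_lines lines to profile.
#' @param effector_concs effector concentrations (must include 0).
#' @param noise_sd per-point %I noise SD.
#' @param seed integer seed.
#' @return truth data.frame for [generate_dose_response()].
#' @export
make_dose_truth <- function(compound_ids, classes, cell_lines,
                            effector_concs = c(0, 30, 80), noise_sd = 0,
                            seed = 1) {
  stopifnot(0 %in% effector_concs)
  set.seed(sub_seed(seed, "dose"))
  grid <- expand.grid(compound_id = compound_ids, cell_line = cell_lines,
                      stringsAsFactors = FALSE)
  base <- 10^stats::runif(nrow(grid), log10(2), log10(40))
  out <- list()
  for (eff in effector_concs) {
    g <- grid
    g$effector_uM <- eff
    cls <- classes[match(g$compound_id, compound_ids)]
    fold <- rep(1, nrow(g))
    if (eff >= 80) {
      fold[cls == "agonist"] <- 1 / 4
      fold[cls == "antagonist"] <- 8
    } else if (eff > 0) {
      fold[cls == "agonist"] <- 1 / 2
      fold[cls == "antagonist"] <- 2.5
    }
    g$bottom <- 0
    g$top <- 100
    g$ic50 <- base * fold
    g$hill <- 1.2
    g$noise_sd <- noise_sd
    out[[length(out) + 1L]] <- g
  }
  do.call(rbind, out)
}

#' Simulate a complete synthetic dataset on disk
#'
#' Writes everything the analysis stage consumes: screening plates, a
#' control run, dose-response tables for the planted hits across the panel,
#' a turbidity series, growth curves, nuclei images, the ground-truth
#' manifest and the resolved config. Same seed, same bytes.
#'
#' @param config [run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the list of written paths.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output dir: ", out_dir,
                                 call. = FALSE)
  nm <- noise_model(config$noise_cv, config$plate_shift_sd, config$seed)
  paths <- character()

  cm <- default_control_means()
  ctrl <- rbind(
    generate_control_run(cm$mu_high[1], cm$mu_low[1], nm, 3,
                         config$screen_lines[1], 0),
    generate_control_run(cm$mu_high[2], cm$mu_low[2],
                         noise_model(nm$cv, nm$plate_shift_sd, nm$seed + 7),
                         3, config$screen_lines[1], max(config$effector_concs)))
  paths["control_run"] <- file.path(out_dir, "control_run.csv")
  write_plate_table(ctrl, paths["control_run"])

  scr <- generate_screen(
    n_compounds = config$n_compounds, planted = config$planted, noise = nm,
    cell_lines = config$screen_lines,
    effector_pair = c(0, max(config$effector_concs)),
    hit_pct = config$hit_pct)
  paths["screen_plates"] <- file.path(out_dir, "screen_plates.csv")
  write_plate_table(scr$plates, paths["screen_plates"])
  paths["truth_screen"] <- file.path(out_dir, "truth_screen.csv")
  utils::write.csv(scr$truth, paths["truth_screen"], row.names = FALSE)

  hit_ids <- scr$truth$compound_id[scr$truth$class %in%
                                     c("agonist", "antagonist")]
  hit_cls <- scr$truth$class[match(hit_ids, scr$truth$compound_id)]
  dr_truth <- make_dose_truth(
    hit_ids, hit_cls, c(config$screen_lines, config$panel_lines),
    config$effector_concs, config$dr_noise_sd, config$seed)
  design <- make_doubling_dilutions(config$censor_limit, 12)
  dr <- generate_dose_response(dr_truth, design, n_reps = 2,
                               seed = config$seed)
  paths["dose_response"] <- file.path(out_dir, "dose_response.csv")
  utils::write.csv(dr, paths["dose_response"], row.names = FALSE)
  paths["truth_dose"] <- file.path(out_dir, "truth_dose.csv")
  utils::write.csv(dr_truth, paths["truth_dose"], row.names = FALSE)

  tb <- generate_turbidity(seed = config$seed)
  paths["turbidity"] <- file.path(out_dir, "turbidity.csv")
  utils::write.csv(
    data.frame(conc_uM = tb$concentrations, turbidity_ntu = tb$turbidity),
    paths["turbidity"], row.names = FALSE)
  paths["turbidity_baseline"] <- file.path(out_dir, "turbidity_baseline.csv")
  utils::write.csv(data.frame(turbidity_ntu = tb$baseline_values),
                   paths["turbidity_baseline"], row.names = FALSE)

  gr <- generate_growth(seed = config$seed)
  paths["growth"] <- file.path(out_dir, "growth.csv")
  utils::write.csv(gr, paths["growth"], row.names = FALSE)

  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  img_truth <- data.frame(file = character(), n_true = integer())
  for (i in 1:3) {
    im <- generate_nuclei_image(n_nuclei = 30 + 10 * i, radius = 6,
                                overlap_fraction = 0, size = 256,
                                seed = config$seed + i)
    f <- sprintf("nuclei_%02d.png", i)
    write_image_gray(im$pixels, file.path(img_dir, f))
    img_truth <- rbind(img_truth, data.frame(file = f, n_true = im$n_true))
  }
  paths["image_manifest"] <- file.path(out_dir, "image_manifest.csv")
  utils::write.csv(img_truth, paths["image_manifest"], row.names = FALSE)

  paths["config"] <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), paths["config"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(
    planted = as.list(config$planted), n_compounds = config$n_compounds,
    seed = config$seed, files = as.list(paths))
  paths["manifest"] <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Analyze a simulated (or equivalently formatted) dataset
#'
#' Runs the full pipeline: control-run QC (warning, not a halt, when a
#' condition fails the Z' gate -- screening proceeded historically despite a
#' weak co-treated condition), growth-linearity selection, solubility limit,
#' screen normalization and dual-condition selection, cross-line refinement,
#' hit deduplication, censored 4PL dose-response fitting, fold-shift
#' confirmation and panel profiling, and nuclei counting on any provided
#' images. Writes delimited results tables plus a JSON analysis manifest.
#'
#' @param config [run_config()] (thresholds are read from it).
#' @param in_dir directory written by [run_simulate()].
#' @param out_dir results directory (created if missing).
#' @return invisibly, a list with the main result objects: `qc`,
#'   `screen_profiles`, `refined`, `dose_results`, `calls`, `panel`,
#'   `warnings`.
#' @export
run_analyze <- function(config, in_dir, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(in_dir) ||
      !file.exists(file.path(in_dir, "screen_plates.csv"))) {
    stop("input directory missing simulated dataset: ", in_dir, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings <- data.frame(stage = character(), message = character())
  note <- function(stage, msg) {
    warnings <<- rbind(warnings, data.frame(stage = stage, message = msg))
  }

  # ---- QC on the screen's own control wells, per condition ----
  plates <- read_plate_table(file.path(in_dir, "screen_plates.csv"))
  conds <- unique(plates[, c("cell_line", "effector_uM")])
  qc <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i) {
    p <- plates[plates$cell_line == conds$cell_line[i] &
                  plates$effector_uM == conds$effector_uM[i], ]
    rep <- qc_report(p, config$zprime_gate)
    data.frame(cell_line = conds$cell_line[i],
               effector_uM = conds$effector_uM[i],
               n_high = rep$stats$n_high, n_low = rep$stats$n_low,
               mu_high = rep$stats$mu_high, mu_low = rep$stats$mu_low,
               sd_high = rep$stats$sd_high, sd_low = rep$stats$sd_low,
               cv_high = rep$stats$cv_high, cv_low = rep$stats$cv_low,
               s_n = rep$s_n$ratio, s_n_label = rep$s_n$label,
               zprime = rep$zprime, band = rep$band, robust = rep$robust)
  }))
  for (i in which(!qc$robust)) {
    note("qc", sprintf("low-robustness condition (%s, %g uM): Z' = %.2f",
                       qc$cell_line[i], qc$effector_uM[i], qc$zprime[i]))
  }
  utils::write.csv(qc, file.path(out_dir, "qc_report.csv"), row.names = FALSE)

  # ---- growth and solubility, when provided ----
  growth_sel <- NULL
  gf <- file.path(in_dir, "growth.csv")
  if (file.exists(gf)) {
    growth_sel <- assess_growth(utils::read.csv(gf), config$linearity_r2)
    utils::write.csv(growth_sel$per_density,
                     file.path(out_dir, "growth_linearity.csv"),
                     row.names = FALSE)
  }
  solub <- NULL
  tf <- file.path(in_dir, "turbidity.csv")
  if (file.exists(tf)) {
    tb <- utils::read.csv(tf)
    bl <- utils::read.csv(file.path(in_dir, "turbidity_baseline.csv"))
    solub <- solubility_limit(tb$conc_uM, tb$turbidity_ntu, bl$turbidity_ntu)
  }

  # ---- screen selection ----
  eff_max <- max(config$effector_concs)
  prof <- screen_profiles(plates, effector_pair = c(0, eff_max),
                          hit_pct = config$hit_pct)
  utils::write.csv(prof, file.path(out_dir, "screen_scatter.csv"),
                   row.names = FALSE)
  refined <- refine_across_cell_lines(prof, config$screen_lines[1],
                                      config$screen_lines[2])
  registry <- build_registry(data.frame(
    name = unique(prof$compound_id), library_source = "synthetic"))
  hits_ag <- if (nrow(refined$agonists)) {
    deduplicate_hits(refined$agonists$compound_id, registry)
  } else refined$agonists[0, 0]
  hits_an <- if (nrow(refined$antagonists)) {
    deduplicate_hits(refined$antagonists$compound_id, registry)
  } else refined$antagonists[0, 0]
  utils::write.csv(refined$agonists, file.path(out_dir, "hits_agonists.csv"),
                   row.names = FALSE)
  utils::write.csv(refined$antagonists,
                   file.path(out_dir, "hits_antagonists.csv"),
                   row.names = FALSE)

  # ---- dose-response fits and fold-shift classification ----
  dose_results <- NULL
  calls <- NULL
  panel <- NULL
  df <- file.path(in_dir, "dose_response.csv")
  if (file.exists(df)) {
    dr <- utils::read.csv(df)
    grp <- interaction(dr$compound_id, dr$cell_line, dr$effector_uM,
                       drop = TRUE)
    fits <- lapply(split(dr, grp), function(d) {
      ft <- fit_4pl(d$conc_uM, d$pct_inhibition,
                    censor_limit = config$censor_limit,
                    plateau_tol = config$plateau_tol)
      data.frame(compound_id = d$compound_id[1], cell_line = d$cell_line[1],
                 effector_uM = d$effector_uM[1],
                 ic50_qualifier = ft$ic50$qualifier, ic50_uM = ft$ic50$value,
                 partial_flag = ft$partial, max_pct = ft$max_observed_pct,
                 hill = if (is.null(ft$params)) NA else ft$params$hill,
                 top = if (is.null(ft$params)) NA else ft$params$top,
                 bottom = if (is.null(ft$params)) NA else ft$params$bottom,
                 ic50_label = format_ic50(ft$ic50, ft$partial))
    })
    dose_results <- do.call(rbind, fits)
    rownames(dose_results) <- NULL
    utils::write.csv(dose_results,
                     file.path(out_dir, "dose_response_results.csv"),
                     row.names = FALSE)

    shifts <- compute_fold_shifts(dose_results, config$censor_limit)
    utils::write.csv(shifts, file.path(out_dir, "fold_shifts.csv"),
                     row.names = FALSE)
    calls <- do.call(rbind, lapply(split(shifts, shifts$compound_id),
                                   function(s) {
      mc <- classify_modulation(s, config$fold_threshold, eff_max)
      data.frame(compound_id = s$compound_id[1], call = mc$call,
                 conflict = mc$conflict, best_gain = mc$best_gain,
                 best_loss = mc$best_loss)
    }))
    rownames(calls) <- NULL
    utils::write.csv(calls, file.path(out_dir, "modulation_calls.csv"),
                     row.names = FALSE)

    line_info <- data.frame(
      cell_line = c(config$screen_lines, config$panel_lines),
      retinoblastoma = c(TRUE, TRUE, config$panel_rb))
    confirmed <- calls[calls$call != "neutral", ]
    if (nrow(confirmed)) {
      dirs <- stats::setNames(
        ifelse(confirmed$call == "agonist_confirmed", "gain", "loss"),
        confirmed$compound_id)
      panel <- panel_profile(
        shifts[shifts$compound_id %in% confirmed$compound_id, ], line_info,
        direction = dirs, fold_threshold = config$fold_threshold,
        ic50_table = dose_results[, c("compound_id", "cell_line",
                                      "effector_uM", "ic50_label")])
      utils::write.csv(panel$summary, file.path(out_dir, "panel_summary.csv"),
                       row.names = FALSE)
      utils::write.csv(panel$heatmap, file.path(out_dir, "ic50_heatmap.csv"))
    }
  } else {
    note("dose_response", "no dose-response table found; stage skipped")
  }

  # ---- nuclei counting on provided images ----
  img_counts <- NULL
  imf <- file.path(in_dir, "image_manifest.csv")
  if (file.exists(imf)) {
    man <- utils::read.csv(imf)
    img_counts <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
      px <- read_image_gray(file.path(in_dir, "images", man$file[i]))
      seg <- segment_nuclei(px)
      data.frame(file = man$file[i], n_true = man$n_true[i],
                 n_counted = seg$count)
    }))
    utils::write.csv(img_counts, file.path(out_dir, "nuclei_counts.csv"),
                     row.names = FALSE)
  }

  utils::write.csv(warnings, file.path(out_dir, "warnings.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(qc_all_robust = all(qc$robust),
         n_agonist_hits = nrow(refined$agonists),
         n_antagonist_hits = nrow(refined$antagonists),
         growth_selected_density = if (is.null(growth_sel)) NULL else
           growth_sel$selected_density,
         solubility_limit_uM = if (is.null(solub)) NULL else solub$limit,
         n_warnings = nrow(warnings)),
    file.path(out_dir, "analysis_manifest.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(qc = qc, screen_profiles = prof, refined = refined,
                 hits_agonists = hits_ag, hits_antagonists = hits_an,
                 dose_results = dose_results, calls = calls, panel = panel,
                 growth = growth_sel, solubility = solub,
                 img_counts = img_counts, warnings = warnings))
}

#' Fold shifts from a dose-response results table
#'
#' Pairs every curve with its 0 uM effector reference in the same compound
#' and cell line and computes the censored fold shift.
#'
#' @param dose_results data.frame as written by [run_analyze()] (columns
#'   `compound_id`, `cell_line`, `effector_uM`, `ic50_qualifier`, `ic50_uM`).
#' @param censor_limit censor limit used for the fits.
#' @return data.frame `compound_id`, `cell_line`, `effector_uM`, `direction`,
#'   `qualifier`, `magnitude`.
#' @export
compute_fold_shifts <- function(dose_results, censor_limit = 100) {
  dr <- as.data.frame(dose_results)
  ref <- dr[dr$effector_uM == 0, ]
  trt <- dr[dr$effector_uM != 0, ]
  out <- lapply(seq_len(nrow(trt)), function(i) {
    r <- ref[ref$compound_id == trt$compound_id[i] &
               ref$cell_line == trt$cell_line[i], ]
    if (nrow(r) != 1L) return(NULL)
    fs <- fold_shift(
      censored_value(r$ic50_qualifier, r$ic50_uM, censor_limit),
      censored_value(trt$ic50_qualifier[i], trt$ic50_uM[i], censor_limit))
    data.frame(compound_id = trt$compound_id[i],
               cell_line = trt$cell_line[i],
               effector_uM = trt$effector_uM[i],
               direction = fs$direction, qualifier = fs$qualifier,
               magnitude = fs$magnitude)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
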