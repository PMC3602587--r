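#' Well-level noise model
#'
#' Fluorescence HTS noise scales with signal, so wells draw multiplicative
#' log-normal noise with the given coefficient of variation (mean preserved),
#' plus an optional additive per-plate offset. All generators are
#' bit-reproducible for a fixed seed; a single global seed fans out to
#' per-stage sub-seeds as `seed + stage ordinal` so stages are independently
#' reproducible.
#'
#' @param cv well-level multiplicative CV, percent (0 = noise-free).
#' @param plate_shift_sd SD of the additive per-plate offset, signal units.
#' @param seed integer seed.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(cv = 5, plate_shift_sd = 0, seed = 1) {
  stopifnot(cv >= 0, plate_shift_sd >= 0)
  structure(list(cv = cv, plate_shift_sd = plate_shift_sd,
                 seed = as.integer(seed)), class = "noise_model")
}

# stage ordinals for the seed-splitting rule
.stage_ord <- c(control = 1L, screen = 2L, dose = 3L, turbidity = 4L,
                growth = 5L, image = 6L)

#' @rdname noise_model
#' @param stage stage name (one of control, screen, dose, turbidity, growth,
#'   image).
#' @export
sub_seed <- function(seed, stage) {
  (as.integer(seed) + .stage_ord[[stage]]) %% .Machine$integer.max
}

# multiplicative log-normal noise with mean mu and CV cv%
.noisy <- function(mu, cv) {
  if (cv == 0) return(mu)
  sdlog <- sqrt(log1p((cv / 100)^2))
  mu * stats::rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a dedicated control run
#'
#' `n_plates` all-high-control plates plus `n_plates` all-low-control plates
#' (384 wells each) for one condition, mimicking the pre-screen robustness
#' run.
#'
#' @param mu_high,mu_low target control means (high > low > 0).
#' @param noise [noise_model()].
#' @param n_plates plates per role.
#' @param cell_line,effector_uM condition annotation.
#' @return `plate_data` data.frame.
#' @export
generate_control_run <- function(mu_high, mu_low, noise = noise_model(),
                                 n_plates = 3, cell_line = "Y79",
                                 effector_uM = 0) {
  if (!(mu_high > mu_low && mu_low > 0)) {
    stop("need mu_high > mu_low > 0", call. = FALSE)
  }
  if (n_plates == 0) {
    return(.as_plate_data(data.frame(plate_id = character(),
                                     well = character())))
  }
  set.seed(sub_seed(noise$seed, "control"))
  rows <- list()
  for (role in c("high_control", "low_control")) {
    mu <- if (role == "high_control") mu_high else mu_low
    for (p in seq_len(n_plates)) {
      shift <- if (noise$plate_shift_sd > 0) {
        stats::rnorm(1, 0, noise$plate_shift_sd)
      } else 0
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = sprintf("CTRL_%s_E%g_%s_%02d", cell_line, effector_uM,
                           if (role == "high_control") "HI" else "LO", p),
        well = well_name(0:383), role = role,
        signal = pmax(.noisy(rep(mu, 384), noise$cv) + shift, 0),
        cell_line = cell_line, effector_uM = effector_uM)
    }
  }
  .as_plate_data(do.call(rbind, rows))
}

#' Default condition control means
#'
#' Control means per (cell line, effector concentration) used by the screen
#' generator, patterned on a real control run: the effector itself reduces
#' the vehicle-well signal (it kills about half the cells at its working
#' concentration), narrowing the signal window in the co-treated condition.
#' @return data.frame `cell_line`, `effector_uM`, `mu_high`, `mu_low`.
#' @export
default_control_means <- function() {
  data.frame(
    cell_line = c("Y79", "Y79", "RB355", "RB355"),
    effector_uM = c(0, 80, 0, 80),
    mu_high = c(14426, 8065, 14154, 5803),
    mu_low = c(1483, 2557, 1516, 2758))
}

#' Simulate a duplicate dual-condition screen with planted hit classes
#'
#' Generates a full primary screen: every compound in duplicate at one test
#' concentration, two cell lines, effector present or absent, 384-well
#' plates with samples in columns 1-22 and 16 high / 16 low controls in
#' columns 23/24. Compound classes are planted with a margin (default 15
#' percentage points) from the selection threshold so zero-noise output is
#' exactly classifiable: agonists land in [thr+margin, 90] with effector and
#' [10, thr-margin] without; antagonists mirrored; `potent_both` in
#' [thr+margin, 95] under both conditions; the rest inactive in
#' [-10, thr-margin]. True effects are drawn per cell line but the class is
#' shared, so cross-line refinement retains every planted hit.
#'
#' @param n_compounds library size.
#' @param planted named counts, e.g. `c(agonist = 88, antagonist = 67,
#'   potent_both = 40)`; remainder inactive.
#' @param noise [noise_model()].
#' @param cell_lines two screening cell lines.
#' @param effector_pair without/with effector concentrations.
#' @param control_means per-condition control means (see
#'   [default_control_means()]).
#' @param hit_pct selection threshold the planting is anchored to.
#' @param margin planted distance from the threshold, percentage points.
#' @param test_conc_uM screening concentration annotation.
#' @return list: `plates` (`plate_data`), `truth` (data.frame `compound_id`,
#'   `class`, and per-line true %I columns `pct_<line>_minus`/`_plus`).
#' @export
generate_screen <- function(n_compounds = 6912,
                            planted = c(agonist = 88, antagonist = 67),
                            noise = noise_model(),
                            cell_lines = c("Y79", "RB355"),
                            effector_pair = c(0, 80),
                            control_means = default_control_means(),
                            hit_pct = 50, margin = 15, test_conc_uM = 10) {
  stopifnot(length(cell_lines) == 2L, length(effector_pair) == 2L)
  if (sum(planted) > n_compounds) {
    stop("planted class counts exceed n_compounds", call. = FALSE)
  }
  set.seed(sub_seed(noise$seed, "screen"))
  classes <- rep("inactive", n_compounds)
  at <- 0L
  for (cl in names(planted)) {
    if (planted[[cl]] > 0) {
      classes[at + seq_len(planted[[cl]])] <- cl
      at <- at + planted[[cl]]
    }
  }
  compound_id <- sprintf("CPD%05d", seq_len(n_compounds))
  truth <- data.frame(compound_id = compound_id, class = classes)
  lo <- hit_pct - margin
  hi <- hit_pct + margin
  draw <- function(cls, side) {
    # side: "minus" (no effector) or "plus" (with effector)
    n <- length(cls)
    x <- numeric(n)
    weak <- stats::runif(n, -10, lo)
    strong <- stats::runif(n, hi, 90)
    x <- ifelse(cls == "inactive", weak, x)
    x <- ifelse(cls == "potent_both", stats::runif(n, hi, 95), x)
    if (side == "plus") {
      x <- ifelse(cls == "agonist", pmax(strong, 10 + stats::runif(n, hi - 10, 80)), x)
      x <- ifelse(cls == "antagonist", stats::runif(n, 10, lo), x)
    } else {
      x <- ifelse(cls == "agonist", stats::runif(n, 10, lo), x)
      x <- ifelse(cls == "antagonist", strong, x)
    }
    x
  }
  layout <- layout_by_column()
  sample_wells <- layout$well[layout$role == "sample"]
  hi_wells <- layout$well[layout$role == "high_control"]
  lo_wells <- layout$well[layout$role == "low_control"]
  n_per_plate <- length(sample_wells)        # 352
  n_plates <- ceiling(n_compounds / n_per_plate)
  rows <- list()
  for (line in cell_lines) {
    for (side in c("minus", "plus")) {
      eff <- effector_pair[if (side == "minus") 1L else 2L]
      cm <- control_means[control_means$cell_line == line &
                            control_means$effector_uM == eff, ]
      if (nrow(cm) != 1L) {
        stop("control_means must cover (", line, ", ", eff, " uM)",
             call. = FALSE)
      }
      truth[[paste0("pct_", line, "_", side)]] <- draw(classes, side)
      true_pct <- truth[[paste0("pct_", line, "_", side)]]
      span <- cm$mu_high - cm$mu_low
      for (rep_i in 1:2) {
        for (p in seq_len(n_plates)) {
          idx <- ((p - 1L) * n_per_plate + 1L):min(p * n_per_plate, n_compounds)
          k <- length(idx)
          shift <- if (noise$plate_shift_sd > 0) {
            stats::rnorm(1, 0, noise$plate_shift_sd)
          } else 0
          mu_sample <- cm$mu_high - true_pct[idx] / 100 * span
          plate_id <- sprintf("SCR_%s_E%g_R%d_P%02d", line, eff, rep_i, p)
          rows[[length(rows) + 1L]] <- data.frame(
            plate_id = plate_id,
            well = c(sample_wells[seq_len(k)], hi_wells, lo_wells),
            role = c(rep("sample", k), rep("high_control", 16),
                     rep("low_control", 16)),
            signal = pmax(c(
              .noisy(mu_sample, noise$cv),
              .noisy(rep(cm$mu_high, 16), noise$cv),
              .noisy(rep(cm$mu_low, 16), noise$cv)) + shift, 0),
            compound_id = c(compound_id[idx], rep(NA_character_, 32)),
            conc_uM = c(rep(test_conc_uM, k), rep(NA_real_, 32)),
            cell_line = line, effector_uM = eff,
            replicate = rep_i)
          if (k < n_per_plate) {
            spare <- sample_wells[(k + 1L):n_per_plate]
            rows[[length(rows) + 1L]] <- data.frame(
              plate_id = plate_id, well = spare, role = "empty",
              signal = NA_real_, compound_id = NA_character_,
              conc_uM = NA_real_, cell_line = line, effector_uM = eff,
              replicate = rep_i)
          }
        }
      }
    }
  }
  list(plates = .as_plate_data(do.call(rbind, rows)), truth = truth)
}

#' Simulate dose-response curves from planted 4PL truths
#'
#' Samples %I at each design concentration from the true four-parameter
#' logistic plus Gaussian noise, for every (compound, cell line, effector
#' concentration) row of the truth table.
#'
#' @param truth data.frame with columns `compound_id`, `cell_line`,
#'   `effector_uM`, `bottom`, `top`, `ic50`, `hill`, `noise_sd` (%I units).
#' @param design concentration vector from [make_doubling_dilutions()].
#' @param n_reps replicates per concentration.
#' @param seed integer seed.
#' @return data.frame `compound_id`, `cell_line`, `effector_uM`, `conc_uM`,
#'   `replicate`, `pct_inhibition`.
#' @export
generate_dose_response <- function(truth, design, n_reps = 2, seed = 1) {
  stopifnot(all(diff(design) < 0), all(design > 0))
  set.seed(sub_seed(seed, "dose"))
  truth <- as.data.frame(truth)
  out <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    mu <- four_pl(design, tr$bottom, tr$top, tr$ic50, tr$hill)
    data.frame(compound_id = tr$compound_id, cell_line = tr$cell_line,
               effector_uM = tr$effector_uM,
               conc_uM = rep(design, n_reps),
               replicate = rep(seq_len(n_reps), each = length(design)),
               pct_inhibition = rep(mu, n_reps) +
                 if (tr$noise_sd > 0) {
                   stats::rnorm(length(design) * n_reps, 0, tr$noise_sd)
                 } else 0)
  })
  do.call(rbind, out)
}

#' Simulate a nephelometry turbidity series
#'
#' Turbidity sits at the control-buffer baseline below the planted solubility
#' limit and rises clearly above the baseline + 3 SD threshold at and above
#' it. The baseline replicate readings are constructed as
#' `mean + c(-1, 0, 1) * sd`, so their sample mean and SD reproduce the
#' requested pair exactly. The planted limit snaps to the lowest tested
#' concentration at or above it (a dilution series can only localize the
#' limit to a tested dose); the default design's top concentration is chosen
#' so the canonical 400 uM limit is itself a tested dilution. A limit above
#' the tested range yields an all-baseline series (nothing precipitates); a
#' limit below the lowest tested concentration cannot be represented and
#' errors.
#'
#' @param limit planted solubility limit, micromolar.
#' @param baseline_mean,baseline_sd control-buffer turbidity, NTU.
#' @param design tested concentrations (doubling dilutions).
#' @param seed integer seed.
#' @param noise_frac fractional jitter on below-threshold readings.
#' @return list: `concentrations`, `turbidity`, `baseline_values`,
#'   `limit_planted` (the snapped, detectable limit).
#' @export
generate_turbidity <- function(limit = 400, baseline_mean = 4,
                               baseline_sd = 16 / 3,
                               design = make_doubling_dilutions(6400, 24),
                               seed = 1, noise_frac = 0.05) {
  if (limit < min(design)) {
    stop("planted limit below the tested range", call. = FALSE)
  }
  set.seed(sub_seed(seed, "turbidity"))
  thr <- baseline_mean + 3 * baseline_sd
  conc <- sort(design)
  limit <- if (any(conc >= limit)) min(conc[conc >= limit]) else Inf
  turb <- numeric(length(conc))
  below <- conc < limit
  turb[below] <- pmax(baseline_mean *
                        (1 + stats::rnorm(sum(below), 0, noise_frac)), 0)
  turb[below] <- pmin(turb[below], 0.8 * thr)
  if (any(!below)) {
    # rises with concentration, always clear of the threshold
    turb[!below] <- thr * (1.5 + 2 * log2(conc[!below] / limit + 1)) *
      (1 + stats::rnorm(sum(!below), 0, noise_frac))
    turb[!below] <- pmax(turb[!below], 1.2 * thr)
  }
  list(concentrations = conc, turbidity = turb,
       baseline_values = baseline_mean + c(-1, 0, 1) * baseline_sd,
       limit_planted = limit)
}

#' Simulate growth-kinetics curves
#'
#' Signal grows linearly with time (slope proportional to seeding density)
#' until each density's saturation time, then plateaus -- dense wells exhaust
#' the readout earlier, sparse wells stay linear through the horizon.
#'
#' @param densities cells/well.
#' @param linear_until hours of linear growth per density (named vector or
#'   single value).
#' @param rate signal per hour per 1000 cells.
#' @param timepoints measurement times, hours.
#' @param seed integer seed.
#' @param cv measurement CV, percent (0 = exact).
#' @return data.frame `density`, `time_h`, `signal`.
#' @export
generate_growth <- function(densities = c(1000, 2000, 4000, 8000, 16000, 32000),
                            linear_until = c(`1000` = 120, `2000` = 120,
                                             `4000` = 120, `8000` = 72,
                                             `16000` = 48, `32000` = 48),
                            rate = 1, timepoints = c(24, 48, 72, 96, 120),
                            seed = 1, cv = 0) {
  stopifnot(all(densities > 0))
  set.seed(sub_seed(seed, "growth"))
  if (length(linear_until) == 1L) {
    linear_until <- stats::setNames(rep(linear_until, length(densities)),
                                    densities)
  }
  rows <- lapply(densities, function(d) {
    lu <- linear_until[[as.character(d)]]
    mu <- rate * d / 1000 * pmin(timepoints, lu)
    data.frame(density = d, time_h = timepoints,
               signal = .noisy(mu, cv))
  })
  do.call(rbind, rows)
}

#' Simulate a nuclei image with known count
#'
#' Gaussian-profile bright disks on a dark background. A fraction of nuclei
#' is planted overlapping (center distance 1.2 radii from an existing
#' nucleus, the clump-breaking test case); the rest keep at least 2.4 radii
#' of separation. Placement is rejection-sampled; an infeasible packing
#' errors out.
#'
#' @param n_nuclei planted count.
#' @param radius nucleus radius, pixels.
#' @param overlap_fraction fraction of nuclei planted as clumped pairs.
#' @param size image size, pixels (square).
#' @param seed integer seed.
#' @return list: `pixels` (matrix), `n_true`, `centers` (n x 2).
#' @export
generate_nuclei_image <- function(n_nuclei, radius = 6, overlap_fraction = 0,
                                  size = 256, seed = 1) {
  stopifnot(n_nuclei >= 0, radius > 0, overlap_fraction >= 0,
            overlap_fraction <= 1)
  set.seed(sub_seed(seed, "image"))
  img <- matrix(0, size, size)
  if (n_nuclei == 0) {
    return(list(pixels = img, n_true = 0L, centers = matrix(0, 0, 2)))
  }
  n_overlap <- round(overlap_fraction * n_nuclei)
  centers <- matrix(NA_real_, n_nuclei, 2)
  margin <- 2 * radius
  sep <- 2.4 * radius
  placed <- 0L
  tries <- 0L
  while (placed < n_nuclei) {
    tries <- tries + 1L
    if (tries > 20000L) stop("infeasible packing for requested nucleus count",
                             call. = FALSE)
    make_pair <- placed > 0L && (n_nuclei - placed) <= n_overlap
    if (make_pair) {
      anchor <- centers[sample.int(placed, 1), ]
      ang <- stats::runif(1, 0, 2 * pi)
      cand <- anchor + 1.2 * radius * c(cos(ang), sin(ang))
      if (any(cand < margin | cand > size - margin)) next
      others <- centers[seq_len(placed), , drop = FALSE]
      d <- sqrt(rowSums((others - matrix(cand, placed, 2, byrow = TRUE))^2))
      d <- d[d > 1e-9]
      if (length(d) && min(d) < 1.15 * radius) next
    } else {
      cand <- stats::runif(2, margin, size - margin)
      if (placed > 0L) {
        others <- centers[seq_len(placed), , drop = FALSE]
        d <- sqrt(rowSums((others - matrix(cand, placed, 2, byrow = TRUE))^2))
        if (min(d) < sep) next
      }
    }
    placed <- placed + 1L
    centers[placed, ] <- cand
  }
  sigma <- radius / 2
  ext <- ceiling(3 * sigma)
  for (i in seq_len(n_nuclei)) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    xr <- max(1, floor(cx - ext)):min(size, ceiling(cx + ext))
    yr <- max(1, floor(cy - ext)):min(size, ceiling(cy + ext))
    gx <- exp(-((xr - cx)^2) / (2 * sigma^2))
    gy <- exp(-((yr - cy)^2) / (2 * sigma^2))
    img[xr, yr] <- pmax(img[xr, yr], outer(gx, gy))
  }
  list(pixels = img, n_true = as.integer(n_nuclei), centers = centers)
}
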