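#' Parse 384-well addresses
#'
#' Well addresses follow plate-reader export convention: row letter `A`--`P`
#' plus 1-based column `1`--`24` (e.g. `"A1"`, `"P24"`). The internal index is
#' 0-based row-major, so the pair maps bijectively onto `0:383`.
#'
#' @param well character vector of well addresses.
#' @return data.frame with columns `well`, `row` (letter), `col` (integer) and
#'   `index` (0-based row-major position).
#' @examples
#' parse_wells(c("A1", "B12", "P24"))
#' @export
parse_wells <- function(well) {
  well <- toupper(trimws(as.character(well)))
  m <- regmatches(well, regexec("^([A-Z])([0-9]{1,2})$", well))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop("malformed well address at entry ", which(bad)[1], ": '",
         well[which(bad)[1]], "'", call. = FALSE)
  }
  row <- vapply(m, `[`, character(1), 2)
  col <- as.integer(vapply(m, `[`, character(1), 3))
  row_i <- match(row, LETTERS[1:16])
  if (anyNA(row_i)) {
    stop("well row letter out of range A-P at entry ", which(is.na(row_i))[1],
         ": '", well[which(is.na(row_i))[1]], "'", call. = FALSE)
  }
  if (any(col < 1 | col > 24)) {
    stop("well column out of range 1-24 at entry ",
         which(col < 1 | col > 24)[1], call. = FALSE)
  }
  data.frame(well = well, row = row, col = col,
             index = (row_i - 1L) * 24L + (col - 1L))
}

#' Format well addresses from 0-based indices
#' @param index integer vector in 0..383.
#' @return character vector of addresses like "A1".
#' @export
well_name <- function(index) {
  index <- as.integer(index)
  stopifnot(all(index >= 0L & index <= 383L))
  paste0(LETTERS[index %/% 24L + 1L], index %% 24L + 1L)
}

.well_roles <- c("sample", "high_control", "low_control", "empty")

#' Column-banded plate layout
#'
#' Builds a role map for a 384-well plate by assigning whole columns to roles,
#' the common physical arrangement in which edge columns carry controls. The
#' published screen does not state its control layout; this default (samples in
#' columns 1--22, vehicle high controls in 23, full-kill low controls in 24)
#' is a configurable assumption giving 352 sample and 16 + 16 control wells.
#'
#' @param sample_cols,high_cols,low_cols,empty_cols integer column sets; every
#'   column 1--24 must be assigned exactly once.
#' @return data.frame with columns `well` and `role` covering all 384 wells.
#' @export
layout_by_column <- function(sample_cols = 1:22, high_cols = 23,
                             low_cols = 24, empty_cols = integer()) {
  assigned <- c(sample_cols, high_cols, low_cols, empty_cols)
  if (anyDuplicated(assigned) || !setequal(assigned, 1:24)) {
    stop("layout must assign every column 1-24 exactly once", call. = FALSE)
  }
  col_role <- character(24)
  col_role[sample_cols] <- "sample"
  col_role[high_cols] <- "high_control"
  col_role[low_cols] <- "low_control"
  col_role[empty_cols] <- "empty"
  idx <- 0:383
  data.frame(well = well_name(idx), role = col_role[idx %% 24L + 1L])
}

.plate_columns <- c("plate_id", "well", "role", "signal", "compound_id",
                    "conc_uM", "cell_line", "effector_uM", "replicate")

.as_plate_data <- function(df) {
  for (col in .plate_columns) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col %in% c("signal", "conc_uM", "effector_uM")) {
        rep(NA_real_, nrow(df))
      } else if (col == "replicate") {
        rep(NA_integer_, nrow(df))
      } else rep(NA_character_, nrow(df))
    }
  }
  df <- df[, .plate_columns]
  df$signal <- as.numeric(df$signal)
  df$conc_uM <- as.numeric(df$conc_uM)
  df$effector_uM <- as.numeric(df$effector_uM)
  df$replicate <- as.integer(df$replicate)
  class(df) <- c("plate_data", "data.frame")
  df
}

#' Read a per-well plate table
#'
#' Reads a delimited text table (comma default, tab accepted; UTF-8, header
#' required) with one row per well and columns `plate_id`, `well`, `role`,
#' `signal` plus optional `compound_id`, `conc_uM`, `cell_line`,
#' `effector_uM`, `replicate`. A blank signal parses to missing (`NA`), never
#' to 0 -- 0 is a legal signal. When `layout_spec` is supplied its role
#' assignment overrides conflicting per-row roles, with a warning naming the
#' affected wells.
#'
#' @param path file path.
#' @param layout_spec optional data.frame from [layout_by_column()] (or any
#'   `well`/`role` map) applied to every plate.
#' @param sep field separator; `""` (default) auto-detects comma vs tab from
#'   the header line.
#' @return a `plate_data` data.frame (all plates, long format, one row per
#'   well) ordered by plate then well index.
#' @export
read_plate_table <- function(path, layout_spec = NULL, sep = "") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) {
    warning("empty plate table: ", path, call. = FALSE)
    return(.as_plate_data(data.frame(plate_id = character(),
                                     well = character())))
  }
  if (identical(sep, "")) sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = "",
                          strip.white = TRUE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) {
    warning("plate table has a header but no rows: ", path, call. = FALSE)
    return(.as_plate_data(df))
  }
  need <- c("plate_id", "well", "signal")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plate table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  pw <- parse_wells(df$well)
  df$well <- pw$well
  key <- paste(df$plate_id, df$well)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (plate_id, well): ", d, call. = FALSE)
  }
  if (!"role" %in% names(df)) df$role <- NA_character_
  sig <- suppressWarnings(as.numeric(df$signal))
  if (any(!is.na(df$signal) & is.na(sig))) {
    stop("non-numeric signal value in row ",
         which(!is.na(df$signal) & is.na(sig))[1], call. = FALSE)
  }
  if (any(!is.na(sig) & sig < 0)) {
    stop("negative signal in row ", which(!is.na(sig) & sig < 0)[1],
         call. = FALSE)
  }
  df$signal <- sig
  if (!is.null(layout_spec)) {
    spec_role <- layout_spec$role[match(df$well, layout_spec$well)]
    conflict <- !is.na(df$role) & !is.na(spec_role) & df$role != spec_role
    if (any(conflict)) {
      warning("layout spec overrides file roles for ", sum(conflict),
              " well(s), e.g. ", key[conflict][1], call. = FALSE)
    }
    df$role <- ifelse(is.na(spec_role), df$role, spec_role)
  }
  bad_role <- !is.na(df$role) & !df$role %in% .well_roles
  if (any(bad_role)) {
    stop("unknown well role '", df$role[bad_role][1], "'", call. = FALSE)
  }
  out <- .as_plate_data(df)
  out[order(out$plate_id, parse_wells(out$well)$index), , drop = FALSE]
}

#' Write a plate table
#'
#' Inverse of [read_plate_table()]: `read(write(p))` reproduces `p`
#' field-for-field. Missing signals (empty wells) serialize as blank fields.
#'
#' @param plates `plate_data` data.frame.
#' @param path output path; comma-separated, header always written.
#' @export
write_plate_table <- function(plates, path) {
  plates <- .as_plate_data(as.data.frame(plates))
  utils::write.table(plates, path, sep = ",", na = "", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate plate invariants
#'
#' Checks, per plate: every sample well is annotated with a compound, signals
#' are finite and non-negative, and (unless `all_control = TRUE`) at least 8
#' high-control and 8 low-control wells are present.
#'
#' @param plates `plate_data` data.frame (one or more plates).
#' @param all_control flag for dedicated control plates, which are exempt from
#'   the minimum-control rule.
#' @return data.frame of violations (`plate_id`, `well`, `issue`); zero rows
#'   iff the plates are valid.
#' @export
validate_plate <- function(plates, all_control = FALSE) {
  plates <- .as_plate_data(as.data.frame(plates))
  out <- list()
  add <- function(plate_id, well, issue) {
    out[[length(out) + 1L]] <<- data.frame(plate_id = plate_id, well = well,
                                           issue = issue)
  }
  for (pid in unique(plates$plate_id)) {
    p <- plates[plates$plate_id == pid, ]
    if (!all_control) {
      if (sum(p$role == "high_control", na.rm = TRUE) < 8) {
        add(pid, NA_character_, "insufficient high controls (< 8)")
      }
      if (sum(p$role == "low_control", na.rm = TRUE) < 8) {
        add(pid, NA_character_, "insufficient low controls (< 8)")
      }
    }
    un <- p$role == "sample" & is.na(p$compound_id)
    for (w in p$well[which(un)]) add(pid, w, "sample well lacks compound annotation")
    bad <- !is.na(p$signal) & (!is.finite(p$signal) | p$signal < 0)
    for (w in p$well[which(bad)]) add(pid, w, "signal not finite and non-negative")
  }
  if (length(out) == 0L) {
    return(data.frame(plate_id = character(), well = character(),
                      issue = character()))
  }
  do.call(rbind, out)
}

#' Build a compound registry with cross-library deduplication
#'
#' Screening libraries assembled from several vendors contain multiple copies
#' of the same compound. Canonical identity is the case-folded,
#' whitespace-normalized primary name (no structural canonicalization);
#' listings sharing it merge into one record whose `copies` counts library
#' wells, so the total well count is conserved.
#'
#' @param records data.frame with columns `name` and `library_source`.
#' @return data.frame with one row per canonical compound: `compound_id`,
#'   `names` (distinct source spellings, `;`-joined), `library_source`
#'   (distinct sources, `;`-joined), `copies`.
#' @export
build_registry <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("name", "library_source") %in% names(records))) {
    stop("records need columns 'name' and 'library_source'", call. = FALSE)
  }
  if (any(is.na(records$name) | trimws(records$name) == "")) {
    stop("listing without a name", call. = FALSE)
  }
  id <- canonical_compound_id(records$name)
  sp <- split(seq_len(nrow(records)), id)
  out <- data.frame(
    compound_id = names(sp),
    names = vapply(sp, function(i) paste(unique(records$name[i]), collapse = ";"),
                   character(1)),
    library_source = vapply(sp, function(i)
      paste(unique(records$library_source[i]), collapse = ";"), character(1)),
    copies = vapply(sp, length, integer(1)),
    row.names = NULL
  )
  out[order(out$compound_id), , drop = FALSE]
}

#' Canonical compound identifier
#'
#' Case-folds and collapses internal whitespace; the registry and hit
#' deduplication both key on this.
#' @param name character vector of compound names.
#' @return character vector of canonical identifiers.
#' @export
canonical_compound_id <- function(name) {
  tolower(gsub("\\s+", " ", trimws(as.character(name))))
}
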