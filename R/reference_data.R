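#' Published confirmation-study IC50 tables
#'
#' Ships the printed potency tables of the originating screen as plain-text
#' reference data: the viability (Alamar Blue) IC50s of the 21 resupplied
#' hits toward the two screening retinoblastoma lines, the nuclei-count
#' proliferation IC50s toward the adherent uveal melanoma line, and the
#' figure-legend IC50s of three microtubule inhibitors across panel lines.
#' Entries keep the table notation (`">100"` censored, trailing `"*"`
#' partial) and are parsed into censored values on load.
#'
#' @param readout `"viability"`, `"nuclei"` or `"panel"`.
#' @return data.frame with the original columns plus `ic50_qualifier`,
#'   `ic50_uM` and `partial`.
#' @export
load_reference_ic50 <- function(readout = c("viability", "nuclei", "panel")) {
  readout <- match.arg(readout)
  f <- system.file("extdata", paste0(readout, "_ic50.csv"),
                   package = "effectorscreen", mustWork = TRUE)
  df <- utils::read.csv(f, check.names = FALSE)
  parsed <- parse_ic50_entry(df$ic50, censor_limit = 100)
  df$ic50_qualifier <- vapply(parsed, function(p) p$ic50$qualifier,
                              character(1))
  df$ic50_uM <- vapply(parsed, function(p) p$ic50$value, numeric(1))
  df$partial <- vapply(parsed, function(p) p$partial, logical(1))
  df
}

#' Fold shifts recomputed from a reference IC50 table
#'
#' Applies the censored fold-shift algebra to every (compound, cell line,
#' effector concentration) of a reference table against its 0 uM entry.
#'
#' @inheritParams load_reference_ic50
#' @return data.frame `compound_id`, `cell_line`, `effector_uM`, `direction`,
#'   `qualifier`, `magnitude` (plus `role` where present).
#' @export
reference_fold_shifts <- function(readout = c("viability", "nuclei",
                                              "panel")) {
  readout <- match.arg(readout)
  df <- load_reference_ic50(readout)
  names(df)[names(df) == "compound"] <- "compound_id"
  sh <- compute_fold_shifts(df, censor_limit = 100)
  if ("role" %in% names(df)) {
    sh$role <- df$role[match(sh$compound_id, df$compound_id)]
  }
  if ("retinoblastoma" %in% names(df)) {
    sh$retinoblastoma <- df$retinoblastoma[match(sh$cell_line, df$cell_line)]
  }
  sh
}
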