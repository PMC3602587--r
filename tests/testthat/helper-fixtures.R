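# Small in-code fixtures shared across test files.

# A minimal valid one-plate table: 352 annotated samples, 16 high + 16 low
# controls, constant signals unless overridden.
make_test_plate <- function(plate_id = "P1", mu_high = 14426, mu_low = 1483,
                            sample_signal = 8000, cell_line = "Y79",
                            effector_uM = 0) {
  layout <- layout_by_column()
  n_s <- sum(layout$role == "sample")
  sig <- numeric(384)
  sig[layout$role == "sample"] <- sample_signal
  sig[layout$role == "high_control"] <- mu_high
  sig[layout$role == "low_control"] <- mu_low
  df <- data.frame(
    plate_id = plate_id, well = layout$well, role = layout$role,
    signal = sig,
    compound_id = ifelse(layout$role == "sample",
                         sprintf("CPD%03d", cumsum(layout$role == "sample")),
                         NA_character_),
    conc_uM = ifelse(layout$role == "sample", 10, NA_real_),
    cell_line = cell_line, effector_uM = effector_uM, replicate = 1L)
  df
}

write_plate_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write_plate_table(df, path)
  path
}

expect_setequal_chr <- function(a, b) {
  testthat::expect_true(setequal(a, b),
                        info = paste("sets differ:",
                                     paste(symdiff_chr(a, b), collapse = ", ")))
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))
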