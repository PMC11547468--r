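# Case-table and spectrum file I/O. CSV throughout; `#` comment headers
# tolerated; unknown extra columns pass through untouched.

.case_required <- c("metal", "radius_nm", "dna_length_A", "angle_deg",
                    "theoretical_length_A", "observed_fluorescence",
                    "nset_quench_theory", "fret_quench_theory",
                    "quenching")

# documented schema ranges; violations warn (real data may exceed the
# synthetic-design ranges), never error
.case_ranges <- list(
  radius_nm = c(1, 50), angle_deg = c(0, 90),
  nset_quench_theory = c(0, 1), fret_quench_theory = c(0, 1),
  quenching = c(-1, 1)
)

#' Read a case table from CSV
#'
#' Validates the required schema columns and warns (does not error) on
#' values outside the documented ranges. Extra columns are preserved.
#'
#' @param path CSV path.
#' @return A data frame of cases.
#' @export
read_case_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  miss <- setdiff(.case_required, names(df))
  if (length(miss))
    stop("case table lacks required column(s): ", paste(miss, collapse = ", "))
  for (col in names(.case_ranges)) {
    rng <- .case_ranges[[col]]
    v <- df[[col]]
    if (any(v < rng[1] | v > rng[2], na.rm = TRUE))
      warning(sprintf("column %s has values outside [%g, %g]",
                      col, rng[1], rng[2]))
  }
  df
}

#' Write a case table to CSV
#'
#' @param cases Case table data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_case_table <- function(cases, path) {
  utils::write.csv(cases, path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column spectrum from CSV
#'
#' Expects `wavelength_nm,value` (any second column name accepted);
#' wavelengths must be strictly increasing and values finite.
#'
#' @param path CSV path.
#' @return A data frame with the file's two columns.
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2) stop("spectrum file needs two columns")
  if (!"wavelength_nm" %in% names(df))
    stop("spectrum file lacks a wavelength_nm column")
  if (any(diff(df$wavelength_nm) <= 0))
    stop("wavelengths must be strictly increasing (duplicates not allowed)")
  if (any(!is.finite(as.matrix(df[1:2]))))
    stop("spectrum contains non-finite values")
  df
}

#' Write a two-column spectrum to CSV
#'
#' @param spectrum Data frame whose first column is `wavelength_nm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path) {
  utils::write.csv(spectrum, path, row.names = FALSE)
  invisible(path)
}
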