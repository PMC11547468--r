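# Bundled reference worked-example table: TET donor (539 nm) paired with
# metal nanospheres of commercial sizes.

#' Reference TET / metal-nanosphere parameter table
#'
#' The bundled worked-example table for the TET donor (emission maximum
#' 539 nm): per metal and diameter, the Mie molar extinction, the
#' size-corrected complex dielectric at 539 nm, the spectral overlap
#' integral, and the NSET and FRET 50%-quenching distances. It is the
#' calibration oracle for the absorptivity geometry factor and the donor
#' quantum yield (see [calibrate_dye_parameters()]), and the input for
#' the package's worked examples. The silver 10 nm overlap integral is
#' mutually inconsistent with its printed Forster distance under the
#' consensus calibration (flagged by `outlier_J`); the platinum overlap
#' integrals are likewise flagged and excluded from calibration.
#'
#' @return A data frame with columns `metal`, `diameter_nm`,
#'   `molar_extinction`, `eps_real`, `eps_imag`, `eps_mod2`,
#'   `overlap_integral`, `nset_d0_A`, `fret_d0_A`, `outlier_J`.
#' @export
tet_reference <- function() {
  path <- system.file("extdata", "tet_np_reference.csv",
                      package = "nsetr", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  df$outlier_J <- as.logical(df$outlier_J)
  df
}
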