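# High-level forward model: metal + size + dye -> corrected dielectric,
# Mie extinction, skin depth, absorptivity, NSET d0 and FRET R0.

#' Full donor-acceptor transfer system
#'
#' Runs the forward chain for one dye / metal-nanosphere pair: bulk
#' dielectric table, size-multiplier correction at the donor emission
#' maximum, Mie molar extinction, skin depth, particle absorptivity,
#' the NSET 50%-quenching distance d0 and (via the spectral overlap with
#' the Mie extinction spectrum) the Forster radius R0.
#'
#' @param metal `"gold"` or `"silver"` for the bundled tables, or any
#'   metal when `table` is supplied.
#' @param diameter_nm Particle diameter in nm.
#' @param dye A [donor_dye()].
#' @param medium A [transfer_medium()].
#' @param scattering_constant Optional override of the registry C value.
#' @param mode Dielectric correction mode, see [corrected_epsilon()].
#' @param table Optional [dielectric_table()]; default bundled table.
#' @param mie_medium_index Medium index for the Mie extinction entering
#'   the absorptivity (default 1.40, the same biomolecular index used in
#'   the Forster radius; see the methods vignette).
#' @param alpha Orientation prefactor for d0.
#' @inheritParams np_absorptivity
#' @return An object of class `transfer_system`: a list with the
#'   computed quantities (`epsilon`, `n`, `kappa`, `skin_depth_nm`,
#'   `molar_ext`, `absorptivity`, `J`, `nset_d0_A`, `fret_R0_A`, inputs).
#' @examples
#' \donttest{
#' ts <- transfer_system("gold", 10)
#' ts$nset_d0_A
#' }
#' @export
transfer_system <- function(metal, diameter_nm, dye = donor_dye(),
                            medium = transfer_medium(),
                            scattering_constant = NULL,
                            mode = "multiplier", table = NULL,
                            mie_medium_index = 1.40,
                            alpha = nset_alpha_default(),
                            bracket = "calibrated",
                            prefactor = 11.856128) {
  params <- drude_params(metal)
  if (!is.null(scattering_constant))
    params$scattering_constant <- scattering_constant
  if (is.null(table)) table <- metal_dielectric_table(metal)
  radius <- diameter_nm / 2
  lam0 <- dye$emission_peak_nm

  eps0 <- corrected_epsilon(table, lam0, params, radius, mode = mode)
  ri <- refractive_index(eps0)
  delta <- skin_depth(lam0, eps0)

  grid <- dye$spectrum$wavelength_nm
  rng <- range(table$wavelength_nm)
  grid <- grid[grid >= rng[1] & grid <= rng[2]]
  eps_grid <- corrected_epsilon(table, grid, params, radius, mode = mode)
  mie <- mie_cross_sections(radius, grid, eps_grid,
                            medium_index = mie_medium_index)
  ext_spec <- data.frame(wavelength_nm = grid,
                         molar_extinction = mie$molar_extinction)
  molar0 <- ext_spec$molar_extinction[match(round(lam0), grid)]
  if (is.na(molar0))
    molar0 <- mie_cross_sections(radius, lam0, eps0,
                                 medium_index = mie_medium_index)$molar_extinction

  acc <- acceptor_np(metal, radius, eps0, molar0,
                     extinction_spectrum = ext_spec)
  j <- overlap_integral(dye$spectrum, ext_spec)
  structure(list(
    metal = metal, diameter_nm = diameter_nm, dye = dye, medium = medium,
    params = params, mode = mode,
    epsilon = eps0, n = ri$n, kappa = ri$kappa, skin_depth_nm = delta,
    molar_ext = molar0, extinction_spectrum = ext_spec,
    absorptivity = np_absorptivity(molar0, radius, delta,
                                   bracket = bracket, prefactor = prefactor),
    J = j,
    nset_d0_A = nset_d0(acc, dye, medium, alpha = alpha,
                        bracket = bracket, prefactor = prefactor),
    fret_R0_A = forster_radius(j, dye$quantum_yield, medium)
  ), class = "transfer_system")
}

#' @export
print.transfer_system <- function(x, ...) {
  cat(sprintf("Transfer system: %s sphere, d = %g nm; donor %s (%g nm, QY %.2f)\n",
              x$metal, x$diameter_nm, x$dye$name,
              x$dye$emission_peak_nm, x$dye$quantum_yield))
  cat(sprintf("  dielectric at %g nm: %.3f %+.3fi  (|eps|^2 = %.2f)\n",
              x$dye$emission_peak_nm, Re(x$epsilon), Im(x$epsilon),
              Mod(x$epsilon)^2))
  cat(sprintf("  n + i kappa = %.3f + %.3fi,  skin depth = %.1f nm\n",
              x$n, x$kappa, x$skin_depth_nm))
  cat(sprintf("  molar extinction = %.3g M^-1 cm^-1,  J = %.3g M^-1 cm^-1 nm^4\n",
              x$molar_ext, x$J))
  cat(sprintf("  NSET d0 = %.2f A,   FRET R0 = %.2f A\n",
              x$nset_d0_A, x$fret_R0_A))
  invisible(x)
}

#' Quenching-efficiency curve for a fitted or computed system
#'
#' @param d0_A Characteristic distance in Angstrom.
#' @param from_A,to_A Separation range in Angstrom.
#' @param by_A Step in Angstrom.
#' @param exponent 4 (NSET) or 6 (FRET).
#' @return Data frame `distance_A`, `efficiency`.
#' @export
quench_curve <- function(d0_A, from_A = 50, to_A = 400, by_A = 1,
                         exponent = 4) {
  r <- seq(from_A, to_A, by = by_A)
  data.frame(distance_A = r,
             efficiency = quench_efficiency(r, d0_A, exponent))
}
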