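# FRET and NSET characteristic distances for a dye donor and a metal
# nanosphere acceptor, and the supporting spectral arithmetic.

#' Donor dye description
#'
#' @param name Dye label. The default `"tet"` is tetrachlorofluorescein,
#'   emission maximum 539 nm, quantum yield 0.43 (the value recovered by
#'   [calibrate_dye_parameters()] from the bundled reference table).
#' @param emission_peak_nm Emission maximum in nm.
#' @param quantum_yield Donor quantum yield in (0, 1].
#' @param spectrum Optional emission spectrum: data frame
#'   `wavelength_nm`, `intensity` on a 1 nm grid. When `NULL` a Gaussian
#'   of width `fwhm_nm` centered on the peak is synthesized and
#'   normalized to unit area.
#' @param fwhm_nm Full width at half maximum of the synthesized Gaussian
#'   (default 25 nm).
#' @return An object of class `donor_dye`.
#' @export
donor_dye <- function(name = "tet", emission_peak_nm = 539,
                      quantum_yield = 0.43, spectrum = NULL,
                      fwhm_nm = 25) {
  if (quantum_yield <= 0 || quantum_yield > 1)
    stop("quantum yield must be in (0, 1]")
  if (emission_peak_nm <= 0) stop("emission peak must be positive")
  if (is.null(spectrum)) {
    sdev <- fwhm_nm / (2 * sqrt(2 * log(2)))
    grid <- seq(round(emission_peak_nm - 4 * sdev),
                round(emission_peak_nm + 4 * sdev))
    intensity <- stats::dnorm(grid, emission_peak_nm, sdev)
    spectrum <- data.frame(wavelength_nm = grid,
                           intensity = intensity / sum(intensity))
  } else {
    stopifnot(all(c("wavelength_nm", "intensity") %in% names(spectrum)))
    spectrum$intensity <- spectrum$intensity / sum(spectrum$intensity)
  }
  structure(list(name = name, emission_peak_nm = emission_peak_nm,
                 quantum_yield = quantum_yield, spectrum = spectrum),
            class = "donor_dye")
}

#' Optical environment of the donor-acceptor pair
#'
#' Holds the two refractive descriptions the model uses: the biomolecular
#' medium index entering the Forster radius, and the double-stranded-DNA
#' solvent constants entering the NSET distance.
#'
#' @param fret_index Medium refractive index in the Forster radius
#'   (default 1.4, standard biomolecular value).
#' @param np_index Solvent (ds-DNA) refractive index in the NSET formula
#'   (default 2.5046).
#' @param solvent_dielectric Solvent (ds-DNA) dielectric constant
#'   (default 1.5881).
#' @param kappa2 Dipole orientation factor (default 2/3, isotropic
#'   dynamic averaging).
#' @return An object of class `transfer_medium`.
#' @export
transfer_medium <- function(fret_index = 1.4, np_index = 2.5046,
                            solvent_dielectric = 1.5881, kappa2 = 2 / 3) {
  vals <- c(fret_index, np_index, solvent_dielectric, kappa2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("medium parameters must be positive")
  structure(list(fret_index = fret_index, np_index = np_index,
                 solvent_dielectric = solvent_dielectric, kappa2 = kappa2),
            class = "transfer_medium")
}

#' Metal nanosphere acceptor at the donor emission wavelength
#'
#' @param metal Metal label (informational).
#' @param radius_nm Particle radius in nm (positive).
#' @param epsilon Complex dielectric of the metal at the donor emission
#'   maximum (size-corrected).
#' @param molar_ext Molar extinction coefficient at the donor emission
#'   maximum, M^-1 cm^-1 (>= 0).
#' @param extinction_spectrum Optional acceptor extinction spectrum
#'   (data frame `wavelength_nm`, `molar_extinction`) for overlap
#'   integrals.
#' @return An object of class `acceptor_np`.
#' @export
acceptor_np <- function(metal, radius_nm, epsilon, molar_ext,
                        extinction_spectrum = NULL) {
  if (radius_nm <= 0) stop("radius must be positive")
  if (molar_ext < 0) stop("molar extinction must be >= 0")
  structure(list(metal = metal, radius_nm = radius_nm,
                 epsilon = as.complex(epsilon), molar_ext = molar_ext,
                 extinction_spectrum = extinction_spectrum),
            class = "acceptor_np")
}

#' Spectral overlap integral J
#'
#' `J = sum FD(lambda) * epsA(lambda) * lambda^4 * dlambda` on a shared
#' 1 nm grid, with the donor spectrum normalized to unit area. Units
#' M^-1 cm^-1 nm^4.
#'
#' @param donor_spectrum Data frame `wavelength_nm`, `intensity` (1 nm
#'   grid; normalized internally).
#' @param acceptor_spectrum Data frame `wavelength_nm`,
#'   `molar_extinction` (M^-1 cm^-1, 1 nm grid).
#' @return The overlap integral J. Disjoint wavelength supports give 0
#'   with a warning.
#' @export
overlap_integral <- function(donor_spectrum, acceptor_spectrum) {
  stopifnot(all(c("wavelength_nm", "intensity") %in% names(donor_spectrum)),
            all(c("wavelength_nm", "molar_extinction") %in%
                  names(acceptor_spectrum)))
  lam <- intersect(donor_spectrum$wavelength_nm,
                   acceptor_spectrum$wavelength_nm)
  if (length(lam) == 0) {
    warning("donor and acceptor spectra have disjoint wavelength supports")
    return(0)
  }
  fd <- donor_spectrum$intensity / sum(donor_spectrum$intensity)
  names(fd) <- donor_spectrum$wavelength_nm
  ea <- acceptor_spectrum$molar_extinction
  names(ea) <- acceptor_spectrum$wavelength_nm
  key <- as.character(lam)
  sum(fd[key] * ea[key] * lam^4)
}

#' Forster radius from the overlap integral
#'
#' `R0 = 0.211 * (kappa2 * n^-4 * QD * J)^(1/6)` in Angstrom, with J in
#' M^-1 cm^-1 nm^4.
#'
#' @param J Overlap integral (>= 0).
#' @param quantum_yield Donor quantum yield.
#' @param medium A [transfer_medium()] (uses `fret_index` and `kappa2`).
#' @return Forster radius in Angstrom.
#' @examples
#' forster_radius(6.51e19, 0.43, transfer_medium())  # ~274.9 A
#' @export
forster_radius <- function(J, quantum_yield, medium = transfer_medium()) {
  if (any(J < 0)) stop("overlap integral must be >= 0")
  0.211 * (medium$kappa2 * medium$fret_index^-4 * quantum_yield * J)^(1 / 6)
}

# bracket readings for the absorptivity geometry factor, in cm
.absorptivity_bracket <- function(bracket, radius_cm, skin_cm, prefactor) {
  switch(bracket,
    calibrated   = prefactor * (2 * radius_cm)^2 / skin_cm,
    surface_skin = (2 * radius_cm)^2 / skin_cm,
    skin_product = 2 * radius_cm * skin_cm / 1e-7,  # scaled to cm by 1 nm
    chord        = 2 * radius_cm * (2 * radius_cm - skin_cm) / 1e-7,
    capped       = 2 * radius_cm * pmin(2 * radius_cm, skin_cm) / 1e-7,
    stop("unknown bracket reading: ", bracket)
  )
}

#' Absorptivity of a single metal nanoparticle
#'
#' `A = 1000 * ln(10) * eps_lambda * B / (N_A * V)` with V the particle
#' volume in cm^3 and B a geometry factor built from the particle
#' diameter and the skin depth. The printed form of the geometry factor
#' in the source model is typographically corrupted; the default
#' `"calibrated"` reading `B = c0 * (2r)^2 / delta_skin` (c0 = 11.856128)
#' is the reading that reproduces the bundled reference 50%-quenching
#' distances (see the methods vignette for the calibration). The literal
#' candidate readings remain available via `bracket`.
#'
#' @param molar_ext Molar extinction at the donor emission wavelength,
#'   M^-1 cm^-1.
#' @param radius_nm Particle radius in nm.
#' @param skin_depth_nm Skin depth at the donor emission wavelength, nm.
#' @param bracket Geometry-factor reading: `"calibrated"` (default),
#'   `"surface_skin"` ((2r)^2/delta), `"skin_product"` (2r*delta),
#'   `"chord"` (2r*(2r-delta)), `"capped"` (2r*min(2r, delta)).
#' @param prefactor Dimensionless prefactor of the calibrated reading.
#' @return Absorptivity A (dimensionless in the model's working units);
#'   linear in `molar_ext`.
#' @export
np_absorptivity <- function(molar_ext, radius_nm, skin_depth_nm,
                            bracket = c("calibrated", "surface_skin",
                                        "skin_product", "chord", "capped"),
                            prefactor = 11.856128) {
  bracket <- match.arg(bracket)
  if (any(radius_nm <= 0)) stop("radius must be positive")
  if (any(skin_depth_nm <= 0)) stop("skin depth must be positive")
  if (any(molar_ext < 0)) stop("molar extinction must be >= 0")
  r_cm <- radius_nm * 1e-7
  d_cm <- skin_depth_nm * 1e-7
  v_cm3 <- 4 / 3 * pi * r_cm^3
  b <- .absorptivity_bracket(bracket, r_cm, d_cm, prefactor)
  1e3 * log(10) * molar_ext * b / (.const$avogadro * v_cm3)
}

#' NSET 50%-quenching distance d0
#'
#' The donor-acceptor separation at which nanometal surface energy
#' transfer halves the donor emission:
#' `d0 = alpha * (lambda_emis / n_p) * (A * Phi)^(1/4) *
#'       ((n_m / (2 n_p)) * (1 + eps1^2 / |eps2|^2))^(1/4)`
#' with `A` the particle absorptivity ([np_absorptivity()]), `Phi` the
#' donor quantum yield, `n_m` the real refractive index of the metal at
#' the emission wavelength and `eps1`, `eps2` the solvent and metal
#' dielectrics. Linear in `alpha`; scales as `(A * Phi)^(1/4)`.
#'
#' @param acceptor An [acceptor_np()].
#' @param donor A [donor_dye()].
#' @param medium A [transfer_medium()].
#' @param alpha Orientation prefactor (default
#'   [nset_alpha_default()], about 0.1159).
#' @inheritParams np_absorptivity
#' @return d0 in Angstrom.
#' @export
nset_d0 <- function(acceptor, donor = donor_dye(),
                    medium = transfer_medium(),
                    alpha = nset_alpha_default(),
                    bracket = "calibrated", prefactor = 11.856128) {
  if (alpha <= 0) stop("alpha must be positive")
  eps <- acceptor$epsilon
  mod2 <- Mod(eps)^2
  if (any(mod2 == 0)) stop("metal dielectric has zero modulus")
  n_m <- refractive_index(eps)$n
  delta <- skin_depth(donor$emission_peak_nm, eps)
  a_np <- np_absorptivity(acceptor$molar_ext, acceptor$radius_nm, delta,
                          bracket = bracket, prefactor = prefactor)
  np <- medium$np_index
  geom <- (n_m / (2 * np)) *
    (1 + medium$solvent_dielectric^2 / mod2)
  d0_nm <- alpha * (donor$emission_peak_nm / np) *
    (a_np * donor$quantum_yield)^(1 / 4) * geom^(1 / 4)
  10 * d0_nm
}

#' Energy-transfer quenching efficiency
#'
#' `E = 1 / (1 + (r/d)^p)` with `p = 4` for NSET (surface energy
#' transfer) and `p = 6` for FRET (dipole-dipole transfer). Equals 1/2
#' exactly at `r = d` and decreases strictly with separation.
#'
#' @param separation_A Donor-acceptor separation in Angstrom (positive).
#' @param d0_A Characteristic 50% distance in Angstrom (positive).
#' @param exponent Distance-dependence power: 4 (NSET, default) or 6
#'   (FRET).
#' @return Efficiency in (0, 1).
#' @examples
#' quench_efficiency(156.41, 156.41)          # 0.5
#' quench_efficiency(200, 156.41, exponent = 6)
#' @export
quench_efficiency <- function(separation_A, d0_A, exponent = 4) {
  if (any(separation_A <= 0) || any(d0_A <= 0))
    stop("separation and d0 must be positive")
  1 / (1 + (separation_A / d0_A)^exponent)
}

#' Recover the donor quantum yield from reference (J, R0) pairs
#'
#' Inverts the Forster-radius formula per row and takes the geometric
#' mean, i.e. the minimizer of squared log-residuals; rows whose
#' predicted R0 under the consensus yield deviates more than `flag_tol`
#' are flagged as outliers.
#'
#' @param rows Data frame with columns `J` (overlap integral) and `R0_A`
#'   (Forster radius, Angstrom); at least two rows.
#' @param medium A [transfer_medium()].
#' @param flag_tol Relative R0 residual above which a row is flagged
#'   (default 0.10).
#' @return A list with `quantum_yield`, `per_row` (implied yield per
#'   row), `residual` (relative R0 residuals under the consensus yield)
#'   and `outlier` (logical flags).
#' @export
calibrate_dye_parameters <- function(rows, medium = transfer_medium(),
                                     flag_tol = 0.10) {
  stopifnot(all(c("J", "R0_A") %in% names(rows)))
  if (nrow(rows) < 2) stop("need at least two (J, R0) rows to calibrate")
  pref <- medium$kappa2 * medium$fret_index^-4
  qd_row <- (rows$R0_A / 0.211)^6 / (pref * rows$J)
  qd <- exp(mean(log(qd_row)))
  r0_pred <- forster_radius(rows$J, qd, medium)
  resid <- r0_pred / rows$R0_A - 1
  list(quantum_yield = qd, per_row = qd_row, residual = resid,
       outlier = abs(resid) > flag_tol)
}

#' Scattering-background correction of an emission spectrum
#'
#' Scales a reference (dye-free nanoparticle) emission spectrum by the
#' ratio of sample to reference absorbance at the plasmon peak and
#' subtracts it from the sample emission, isolating the dye emission.
#' Negative values are clipped to zero and counted.
#'
#' @param sample_abs Sample absorbance at the plasmon peak (> 0 reference
#'   required).
#' @param reference_abs Reference absorbance at the plasmon peak (> 0).
#' @param reference_emission Numeric vector: reference emission spectrum.
#' @param sample_emission Numeric vector of the same length: sample
#'   emission spectrum.
#' @return A list with `spectrum` (corrected emission), `factor` (the
#'   relative concentration factor) and `n_clipped`.
#' @export
background_correct <- function(sample_abs, reference_abs,
                               reference_emission, sample_emission) {
  if (reference_abs <= 0) stop("reference absorbance must be positive")
  if (length(reference_emission) != length(sample_emission))
    stop("emission spectra must share a grid")
  factor <- sample_abs / reference_abs
  corr <- sample_emission - factor * reference_emission
  n_clip <- sum(corr < 0)
  corr[corr < 0] <- 0
  list(spectrum = corr, factor = factor, n_clipped = n_clip)
}
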