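# Physical constants (CODATA) and unit conversions, centralized.
# Units policy: wavelengths nm, photon energies eV, distances reported in
# Angstrom (computed in nm internally), molar extinction M^-1 cm^-1.

.const <- list(
  hbar_eVs   = 6.582119569e-16,  # reduced Planck constant, eV s
  hc_eVnm    = 1239.84198,       # h*c, eV nm
  avogadro   = 6.02214076e23,    # mol^-1
  nm_per_cm  = 1e7
)

#' Convert wavelength to photon energy
#'
#' @param wavelength_nm Wavelength in nm (positive).
#' @return Photon energy in eV.
#' @examples
#' photon_energy(539)       # ~2.30 eV, TET emission maximum
#' @export
photon_energy <- function(wavelength_nm) {
  stopifnot(is.numeric(wavelength_nm))
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  .const$hc_eVnm / wavelength_nm
}

#' Convert photon energy to wavelength
#'
#' @param energy_ev Photon energy in eV (positive).
#' @return Wavelength in nm.
#' @export
energy_wavelength <- function(energy_ev) {
  stopifnot(is.numeric(energy_ev))
  if (any(energy_ev <= 0)) stop("photon energy must be positive")
  .const$hc_eVnm / energy_ev
}

#' Default orientation prefactor of the NSET distance formula
#'
#' The orientation-averaged donor-to-plasmon vector prefactor
#' `alpha = (9/2)^(1/4) / (4*pi)`, the value used when the donor dipole
#' orientation is averaged over the nanoparticle surface.
#'
#' @return A length-one numeric, approximately 0.1159.
#' @export
nset_alpha_default <- function() (9 / 2)^(1 / 4) / (4 * pi)

# run code under a fixed seed, restoring RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
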