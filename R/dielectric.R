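# Size-corrected complex dielectric functions of metals.
#
# The free-electron (Drude) term with a surface-scattering damping
# correction, two interband corrections (a logistic increment to the
# imaginary part, and a critical-point oscillator sum), a size-dependent
# multiplier for tabulated bulk data, and the derived optical quantities
# (complex refractive index, skin depth).

#' Size-dependent plasmon damping constant
#'
#' `Gamma_r = Gamma_inf + C * hbar * v_f / r`: the bulk damping plus a
#' surface-scattering term that grows as the particle shrinks below the
#' electron mean free path. Strictly decreasing in radius, affine in the
#' scattering constant C, and tending to the bulk value as `r -> Inf`.
#'
#' @param params A [drude_params()] object.
#' @param radius_nm Particle radius in nm (positive; may be vectorized).
#' @return Damping constant in eV.
#' @examples
#' size_damping(drude_params("gold"), 5)   # ~0.129 eV
#' @export
size_damping <- function(params, radius_nm) {
  params <- drude_params(params)
  if (any(!is.finite(radius_nm)) || any(radius_nm <= 0))
    stop("radius must be positive")
  params$gamma_inf +
    params$scattering_constant * .const$hbar_eVs * params$fermi_velocity /
      (radius_nm * 1e-9)
}

#' Drude dielectric function, optionally size-corrected
#'
#' Free-electron dielectric
#' `eps = eps_inf - wp^2/(w^2 + G^2) + i * G * wp^2 / (w * (w^2 + G^2))`,
#' with `G` the bulk damping when `radius_nm` is `NULL` and the
#' size-dependent damping of [size_damping()] otherwise.
#'
#' @param omega_ev Photon energy in eV (positive; vectorized).
#' @inheritParams size_damping
#' @param radius_nm Particle radius in nm, or `NULL` for the bulk metal.
#' @return Complex dielectric value(s).
#' @examples
#' drude_epsilon(2.3, drude_params("gold"))   # about -5.62 + 0.454i
#' @export
drude_epsilon <- function(omega_ev, params, radius_nm = NULL) {
  params <- drude_params(params)
  if (any(!is.finite(omega_ev)) || any(omega_ev <= 0))
    stop("photon energy must be positive")
  g <- if (is.null(radius_nm)) params$gamma_inf else size_damping(params, radius_nm)
  wp2 <- params$omega_p^2
  complex(
    real = params$eps_inf - wp2 / (omega_ev^2 + g^2),
    imaginary = g * wp2 / (omega_ev * (omega_ev^2 + g^2))
  )
}

#' Logistic interband increment to the imaginary dielectric
#'
#' A sigmoidal bound-electron (d-band to conduction-band) absorption term
#' `A / (1 + exp((wc - w) / width))` appended to the Drude imaginary part.
#' Accurate for gold in the 1-3 eV window; monotone increasing in `w`,
#' bounded in (0, A).
#'
#' @param omega_ev Photon energy in eV (positive; vectorized).
#' @param amplitude Saturation amplitude A (default 5.6).
#' @param width Transition width in eV (default 0.17).
#' @param center Transition center `wc` in eV (default 2.43).
#' @return Imaginary-dielectric increment (dimensionless).
#' @export
logistic_interband <- function(omega_ev, amplitude = 5.6, width = 0.17,
                               center = 2.43) {
  if (any(!is.finite(omega_ev)) || any(omega_ev <= 0))
    stop("photon energy must be positive")
  if (width <= 0) stop("width must be positive")
  amplitude / (1 + exp((center - omega_ev) / width))
}

#' Critical-point oscillator interband dielectric
#'
#' Evaluates the two-term oscillator sum
#' `sum_i A_i * w_i * (exp(i*phi_i)/(w_i - w - i*g_i) +
#'                     exp(-i*phi_i)/(w_i + w + i*g_i))`
#' over the supplied oscillators. Oscillator parameters are not bundled;
#' they must come from a fit to measured data for the metal at hand.
#'
#' @param omega_ev Photon energy in eV (positive; vectorized).
#' @param oscillators A data frame with columns `amplitude`, `omega`
#'   (eV), `phi` (radians) and `gamma` (eV), one row per oscillator.
#' @return Complex dielectric contribution(s).
#' @export
breshike_interband <- function(omega_ev, oscillators) {
  if (any(!is.finite(omega_ev)) || any(omega_ev <= 0))
    stop("photon energy must be positive")
  if (missing(oscillators) || is.null(oscillators) || nrow(oscillators) == 0)
    stop("no interband oscillator parameters supplied")
  need <- c("amplitude", "omega", "phi", "gamma")
  miss <- setdiff(need, names(oscillators))
  if (length(miss)) stop("oscillator table lacks columns: ",
                         paste(miss, collapse = ", "))
  out <- complex(real = numeric(length(omega_ev)))
  for (i in seq_len(nrow(oscillators))) {
    a <- oscillators$amplitude[i]; w0 <- oscillators$omega[i]
    ph <- oscillators$phi[i]; g <- oscillators$gamma[i]
    out <- out + a * w0 * (
      exp(1i * ph) / (w0 - omega_ev - 1i * g) +
      exp(-1i * ph) / (w0 + omega_ev + 1i * g)
    )
  }
  out
}

#' Size-dependent dielectric multiplication factors
#'
#' Ratios of the size-corrected to the bulk Drude terms, applied
#' separately to the real and imaginary parts of a tabulated bulk
#' dielectric to graft nanoscale damping onto measured data (which
#' already contains the interband physics the bare Drude model misses):
#' real factor `(eps_inf - wp^2/(w^2+Gr^2)) / (eps_inf - wp^2/(w^2+Ginf^2))`,
#' imaginary factor `(Gr/(w^2+Gr^2)) / (Ginf/(w^2+Ginf^2))`. Both tend to
#' 1 as the radius grows or the scattering constant vanishes.
#'
#' @inheritParams drude_epsilon
#' @param radius_nm Particle radius in nm (positive).
#' @param tol Absolute singularity guard on the real-factor denominator;
#'   the bulk Drude real part crosses zero at one wavelength, where the
#'   factor is undefined.
#' @return A list with numeric vectors `real` and `imag`.
#' @export
size_multiplier <- function(omega_ev, params, radius_nm, tol = 1e-9) {
  params <- drude_params(params)
  if (any(!is.finite(omega_ev)) || any(omega_ev <= 0))
    stop("photon energy must be positive")
  gr <- size_damping(params, radius_nm)
  gi <- params$gamma_inf
  wp2 <- params$omega_p^2
  den_r <- params$eps_inf - wp2 / (omega_ev^2 + gi^2)
  if (any(abs(den_r) < tol)) {
    bad <- energy_wavelength(omega_ev[which(abs(den_r) < tol)[1]])
    stop(sprintf(
      "bulk Drude real part crosses zero near %.2f nm; size multiplier undefined there",
      bad
    ))
  }
  num_r <- params$eps_inf - wp2 / (omega_ev^2 + gr^2)
  list(
    real = num_r / den_r,
    imag = (gr / (omega_ev^2 + gr^2)) / (gi / (omega_ev^2 + gi^2))
  )
}

#' Complex refractive index from a dielectric value
#'
#' Principal square root `n + i*kappa = sqrt(eps)` written in the
#' numerically stable half-angle form `n = sqrt((|eps|+eps')/2)`,
#' `kappa = sqrt((|eps|-eps')/2)`.
#'
#' @param eps Complex dielectric value(s) (or a numeric real part with
#'   `imag` supplied separately).
#' @param imag Optional imaginary part when `eps` is numeric.
#' @return A list with numeric vectors `n` and `kappa`, both `>= 0`.
#' @examples
#' refractive_index(complex(real = -4.75, imaginary = 3.80))
#' @export
refractive_index <- function(eps, imag = NULL) {
  if (!is.complex(eps)) eps <- complex(real = eps, imaginary = if (is.null(imag)) 0 else imag)
  m <- Mod(eps)
  list(n = sqrt(pmax(m + Re(eps), 0) / 2), kappa = sqrt(pmax(m - Re(eps), 0) / 2))
}

#' Electromagnetic skin depth of a metal
#'
#' Penetration depth `delta = lambda / (2 * pi * kappa)` with `kappa` the
#' imaginary part of the complex refractive index, assuming unit relative
#' magnetic permeability.
#'
#' @param wavelength_nm Wavelength in nm.
#' @param eps Complex dielectric of the metal at that wavelength.
#' @return Skin depth in nm.
#' @examples
#' skin_depth(539, complex(real = -4.75, imaginary = 3.80))  # ~36.9 nm
#' @export
skin_depth <- function(wavelength_nm, eps) {
  kap <- refractive_index(eps)$kappa
  if (any(kap <= 0))
    stop("material is transparent at this wavelength (kappa = 0); no skin depth")
  wavelength_nm / (2 * pi * kap)
}
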