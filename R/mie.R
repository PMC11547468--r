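# Mie theory for metal nanospheres: extinction, scattering and
# absorption efficiencies via the Bohren-Huffman recurrences, converted
# to cross-sections and molar extinction coefficients.

# efficiencies for one (relative index m, size parameter x);
# logarithmic-derivative downward recurrence, Wiscombe truncation
mie_efficiencies_one <- function(m, x) {
  if (!is.finite(Re(m)) || !is.finite(Im(m)))
    stop("non-finite refractive index in Mie evaluation")
  if (x <= 0) stop("size parameter must be positive")
  if (Mod(m - 1) < 1e-12) return(c(ext = 0, sca = 0, abs = 0))
  nmax <- ceiling(x + 4 * x^(1 / 3) + 2)
  mx <- m * x
  nmx <- max(nmax, ceiling(Mod(mx))) + 16
  D <- complex(real = numeric(nmx))
  for (n in nmx:2) D[n - 1] <- n / mx - 1 / (D[n] + n / mx)
  psi0 <- cos(x); psi1 <- sin(x)
  chi0 <- -sin(x); chi1 <- cos(x)
  xi1 <- complex(real = psi1, imaginary = -chi1)
  qext <- 0; qsca <- 0
  for (n in seq_len(nmax)) {
    psi <- (2 * n - 1) / x * psi1 - psi0
    chi <- (2 * n - 1) / x * chi1 - chi0
    xi <- complex(real = psi, imaginary = -chi)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    an <- (da * psi - psi1) / (da * xi - xi1)
    bn <- (db * psi - psi1) / (db * xi - xi1)
    qext <- qext + (2 * n + 1) * Re(an + bn)
    qsca <- qsca + (2 * n + 1) * (Mod(an)^2 + Mod(bn)^2)
    psi0 <- psi1; psi1 <- psi
    chi0 <- chi1; chi1 <- chi
    xi1 <- xi
  }
  qext <- 2 / x^2 * qext
  qsca <- 2 / x^2 * qsca
  c(ext = qext, sca = qsca, abs = qext - qsca)
}

#' Convert an extinction cross-section to a molar extinction coefficient
#'
#' `eps_lambda = sigma * N_A / (1000 * ln 10)`, mapping a per-particle
#' cross-section in cm^2 to the decadic molar coefficient in M^-1 cm^-1.
#'
#' @param sigma_cm2 Cross-section(s) in cm^2.
#' @return Molar extinction in M^-1 cm^-1.
#' @export
molar_extinction <- function(sigma_cm2) {
  sigma_cm2 * .const$avogadro / (1e3 * log(10))
}

#' Mie cross-sections and molar extinction of a metal nanosphere
#'
#' Evaluates the Mie series for a homogeneous sphere at each wavelength
#' and returns efficiencies, cross-sections (cm^2) and the decadic molar
#' extinction coefficient. Energy bookkeeping `Qext = Qsca + Qabs` holds
#' by construction of the series.
#'
#' @param radius_nm Sphere radius in nm (positive).
#' @param wavelength_nm Wavelength grid in nm.
#' @param epsilon Complex dielectric of the particle at each wavelength
#'   (length 1 or `length(wavelength_nm)`).
#' @param medium_index Real refractive index of the surrounding medium
#'   (default 1.33, aqueous colloid).
#' @return A data frame with columns `wavelength_nm`, `q_ext`, `q_sca`,
#'   `q_abs`, `sigma_ext_cm2`, `sigma_sca_cm2`, `sigma_abs_cm2`,
#'   `molar_extinction`.
#' @examples
#' eps <- complex(real = -4.75, imaginary = 3.80)
#' mie_cross_sections(5, 539, eps, medium_index = 1.40)
#' @export
mie_cross_sections <- function(radius_nm, wavelength_nm, epsilon,
                               medium_index = 1.33) {
  if (radius_nm <= 0) stop("radius must be positive")
  if (medium_index < 1) stop("medium index must be >= 1")
  if (any(wavelength_nm <= 0)) stop("wavelengths must be positive")
  epsilon <- as.complex(epsilon)
  if (length(epsilon) == 1) epsilon <- rep(epsilon, length(wavelength_nm))
  if (length(epsilon) != length(wavelength_nm))
    stop("epsilon must match the wavelength grid")
  bad <- which(!is.finite(Re(epsilon)) | !is.finite(Im(epsilon)))
  if (length(bad))
    stop(sprintf("non-finite dielectric at %g nm", wavelength_nm[bad[1]]))
  geom_cm2 <- pi * (radius_nm * 1e-7)^2
  q <- t(vapply(seq_along(wavelength_nm), function(i) {
    m <- sqrt(epsilon[i]) / medium_index
    x <- 2 * pi * medium_index * radius_nm / wavelength_nm[i]
    mie_efficiencies_one(m, x)
  }, numeric(3)))
  data.frame(
    wavelength_nm = wavelength_nm,
    q_ext = q[, "ext"], q_sca = q[, "sca"], q_abs = q[, "abs"],
    sigma_ext_cm2 = q[, "ext"] * geom_cm2,
    sigma_sca_cm2 = q[, "sca"] * geom_cm2,
    sigma_abs_cm2 = q[, "abs"] * geom_cm2,
    molar_extinction = molar_extinction(q[, "ext"] * geom_cm2)
  )
}

#' Beer-Lambert absorbance spectrum of a nanoparticle colloid
#'
#' `A(lambda) = eps_lambda(lambda) * c * l` from the Mie molar
#' extinction.
#'
#' @inheritParams mie_cross_sections
#' @param concentration_M Particle molar concentration (>= 0).
#' @param path_cm Optical path length in cm.
#' @return A data frame `wavelength_nm`, `absorbance`.
#' @export
absorbance_spectrum <- function(radius_nm, wavelength_nm, epsilon,
                                concentration_M, path_cm = 1,
                                medium_index = 1.33) {
  if (concentration_M < 0) stop("concentration must be >= 0")
  mx <- mie_cross_sections(radius_nm, wavelength_nm, epsilon, medium_index)
  data.frame(
    wavelength_nm = wavelength_nm,
    absorbance = mx$molar_extinction * concentration_M * path_cm
  )
}
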