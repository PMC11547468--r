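# Synthetic case tables with the statistical structure of the DNA-ruler
# quenching study: two metals, two sphere sizes, four duplex lengths,
# tilt-projected separations, and noisy observed quenching generated
# from the package's own forward model.

#' Configuration of the synthetic case-table generator
#'
#' Defaults emulate the study design the case-table schema comes from:
#' 56 cases (52 gold, 4 silver), radii 5 and 10 nm, duplexes of
#' 20/40/60/80 bp, tilt uniform on 0-39 degrees, Gaussian observation
#' noise of 0.08 on the quenching efficiency, and a small (0.005)
#' repeatability noise tying observed fluorescence to `1 - quenching`.
#'
#' @param n Number of cases.
#' @param n_silver Number of silver cases (the rest are gold).
#' @param radius_choices Radii to sample from, nm.
#' @param bp_choices Duplex lengths to sample from, base pairs.
#' @param tilt_range Uniform tilt range, degrees.
#' @param tilt_error_choices Orientation one-sigma choices, degrees.
#' @param quench_sigma Gaussian noise s.d. on observed quenching.
#' @param fluor_sigma Gaussian noise s.d. on observed fluorescence about
#'   `1 - quenching`.
#' @param linker_offset_A Linker offset of the case-table length
#'   convention, Angstrom (duplex length = 3.4*bp + offset; the tilt
#'   projection applies to the full length in this convention).
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n = 56, n_silver = 4,
                             radius_choices = c(5, 10),
                             bp_choices = c(20, 40, 60, 80),
                             tilt_range = c(0, 39),
                             tilt_error_choices = c(3, 4),
                             quench_sigma = 0.08, fluor_sigma = 0.005,
                             linker_offset_A = 58.52, seed = 42) {
  if (n < 1 || n_silver < 0 || n_silver > n) stop("invalid case counts")
  if (quench_sigma < 0 || fluor_sigma < 0) stop("noise must be >= 0")
  structure(list(n = n, n_silver = n_silver,
                 radius_choices = radius_choices, bp_choices = bp_choices,
                 tilt_range = tilt_range,
                 tilt_error_choices = tilt_error_choices,
                 quench_sigma = quench_sigma, fluor_sigma = fluor_sigma,
                 linker_offset_A = linker_offset_A, seed = seed),
            class = "generator_config")
}

#' Generate a synthetic case table
#'
#' Samples the design columns (metal, radius, duplex length, tilt),
#' derives the geometric separations with the rigid-rod ruler, runs the
#' forward model (size-corrected dielectric, Mie extinction, d0, R0)
#' at the generating parameters `(true_c, true_alpha)`, and sets
#' observed quenching to the theoretical NSET efficiency plus Gaussian
#' noise (truncated to `[-1, 1]`). Observed fluorescence is
#' `1 - quenching` plus repeatability noise, mirroring the
#' complementarity of the source schema. Deterministic given
#' `config$seed`.
#'
#' @param config A [generator_config()].
#' @param true_c Generating scattering constant (default 0.33).
#' @param true_alpha Generating orientation prefactor (default
#'   [nset_alpha_default()]).
#' @param dye,medium Donor and medium descriptions.
#' @return A data frame, one row per case, with columns `metal`,
#'   `radius_nm`, `radius_error_nm`, `dna_length_A`, `angle_deg`,
#'   `angle_error_deg`, `theoretical_length_A`, `length_error_A`,
#'   `observed_fluorescence`, `nset_quench_theory`, `fret_quench_theory`,
#'   `alpha`, `scattering_c`, `eps_real`, `eps_imag`, `eps_mod2`,
#'   `overlap_integral`, `nset_d0_A`, `fret_d0_A`, `molar_extinction`
#'   and the target `quenching`.
#' @examples
#' \donttest{
#' cases <- generate_cases(generator_config(seed = 7))
#' }
#' @export
generate_cases <- function(config = generator_config(),
                           true_c = 0.33,
                           true_alpha = nset_alpha_default(),
                           dye = donor_dye(), medium = transfer_medium()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n
    metal <- rep("gold", n)
    if (config$n_silver > 0)
      metal[sample.int(n, config$n_silver)] <- "silver"
    radius <- sample(config$radius_choices, n, replace = TRUE)
    bp <- sample(config$bp_choices, n, replace = TRUE)
    tilt <- stats::runif(n, config$tilt_range[1], config$tilt_range[2])
    tilt_err <- sample(config$tilt_error_choices, n, replace = TRUE)

    dna_len <- 3.4 * bp + config$linker_offset_A
    cons <- dna_construct(bp, offset_A = config$linker_offset_A,
                          tilt_deg = tilt, tilt_error_deg = tilt_err,
                          project = "full")
    sep <- clegg_distance(cons)
    len_err <- distance_error(cons)

    # forward model once per unique (metal, radius)
    combo <- paste(metal, radius)
    sys <- list()
    for (cb in unique(combo)) {
      i <- which(combo == cb)[1]
      sys[[cb]] <- transfer_system(metal[i], 2 * radius[i], dye, medium,
                                   scattering_constant = true_c,
                                   alpha = true_alpha)
    }
    pick <- function(f) vapply(combo, function(cb) f(sys[[cb]]), numeric(1),
                               USE.NAMES = FALSE)
    d0 <- pick(function(s) s$nset_d0_A)
    r0 <- pick(function(s) s$fret_R0_A)

    q_theory <- quench_efficiency(sep, d0, exponent = 4)
    q_fret <- quench_efficiency(sep, r0, exponent = 6)
    q_obs <- q_theory + stats::rnorm(n, 0, config$quench_sigma)
    q_obs <- pmin(pmax(q_obs, -1), 1)
    fluor <- 1 - q_obs + stats::rnorm(n, 0, config$fluor_sigma)

    data.frame(
      metal = metal,
      radius_nm = radius,
      radius_error_nm = radius / 5,
      dna_length_A = dna_len,
      angle_deg = tilt,
      angle_error_deg = tilt_err,
      theoretical_length_A = sep,
      length_error_A = len_err,
      observed_fluorescence = fluor,
      nset_quench_theory = q_theory,
      fret_quench_theory = q_fret,
      alpha = 2 / 3,
      scattering_c = true_c,
      eps_real = pick(function(s) Re(s$epsilon)),
      eps_imag = pick(function(s) Im(s$epsilon)),
      eps_mod2 = pick(function(s) Mod(s$epsilon)^2),
      overlap_integral = pick(function(s) s$J),
      nset_d0_A = d0,
      fret_d0_A = r0,
      molar_extinction = pick(function(s) s$molar_ext),
      quenching = q_obs
    )
  })
}

#' Paired absorbance / donor-emission spectra fixture
#'
#' A Mie absorbance spectrum for a metal sphere (aqueous colloid)
#' together with the normalized Gaussian donor emission on the same
#' 1 nm grid, for overlap-integral and background-correction work.
#'
#' @param metal `"gold"` or `"silver"`.
#' @param diameter_nm Sphere diameter, nm.
#' @param wavelength_range Range in nm, within the bundled table.
#' @param concentration_M Particle concentration for the Beer-Lambert
#'   absorbance (default 1 nM).
#' @param dye A [donor_dye()].
#' @param medium_index Medium index for the colloid spectrum (default
#'   1.33).
#' @return A list with data frames `absorbance` (`wavelength_nm`,
#'   `absorbance`) and `emission` (`wavelength_nm`, `intensity`, unit
#'   area over the grid).
#' @export
generate_spectra_fixture <- function(metal, diameter_nm,
                                     wavelength_range = c(300, 800),
                                     concentration_M = 1e-9,
                                     dye = donor_dye(),
                                     medium_index = 1.33) {
  table <- metal_dielectric_table(metal)
  grid <- seq(wavelength_range[1], wavelength_range[2])
  params <- drude_params(metal)
  eps <- corrected_epsilon(table, grid, params, diameter_nm / 2,
                           mode = "multiplier")
  absorb <- absorbance_spectrum(diameter_nm / 2, grid, eps,
                                concentration_M,
                                medium_index = medium_index)
  em <- stats::approx(dye$spectrum$wavelength_nm, dye$spectrum$intensity,
                      xout = grid, yleft = 0, yright = 0)$y
  list(absorbance = absorb,
       emission = data.frame(wavelength_nm = grid,
                             intensity = em / sum(em)))
}
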