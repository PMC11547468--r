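gold <- drude_params("gold")

test_that("size-dependent damping has the right value, limits and shape", {
  # hand unit conversion: hbar*v_f/r = 0.18298 eV at r = 5 nm, x0.33 + 0.06909
  expect_equal(size_damping(gold, 5), 0.129474, tolerance = 1e-4)
  expect_equal(size_damping(gold, 1e9), gold$gamma_inf, tolerance = 1e-6)
  expect_equal(size_damping(drude_params("gold", scattering_constant = 0), 3),
               gold$gamma_inf)
  r <- c(2, 5, 10, 20, 50)
  expect_true(all(diff(size_damping(gold, r)) < 0))
  # affine in C
  g1 <- size_damping(drude_params("gold", scattering_constant = 1), 5)
  g2 <- size_damping(drude_params("gold", scattering_constant = 2), 5)
  g0 <- size_damping(drude_params("gold", scattering_constant = 0), 5)
  expect_equal(g2 - g1, g1 - g0, tolerance = 1e-12)
  expect_error(size_damping(gold, -1), "positive")
})

test_that("Drude dielectric matches hand evaluation and its limits", {
  eps <- drude_epsilon(2.3, gold)
  expect_equal(Re(eps), -5.625, tolerance = 2e-4)
  expect_equal(Im(eps), 0.454, tolerance = 1e-3)
  # no free electrons
  expect_equal(drude_epsilon(2.3, drude_params("gold", omega_p = 0)),
               complex(real = 9.5, imaginary = 0))
  # high-frequency limit
  hi <- drude_epsilon(1e4, gold)
  expect_equal(Re(hi), gold$eps_inf, tolerance = 1e-6)
  expect_equal(Im(hi), 0, tolerance = 1e-9)
  expect_error(drude_epsilon(-2, gold), "positive")
})

test_that("logistic interband term has midpoint, saturation and bounds", {
  expect_equal(logistic_interband(2.43, center = 2.43), 5.6 / 2)
  expect_equal(logistic_interband(2.43 - 0.17, center = 2.43),
               5.6 / (1 + exp(1)))
  expect_equal(logistic_interband(0.1, center = 2.43), 0, tolerance = 1e-5)
  expect_equal(logistic_interband(50, center = 2.43), 5.6, tolerance = 1e-8)
  w <- seq(0.5, 5, by = 0.05)
  v <- logistic_interband(w)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 5.6))
})

test_that("critical-point oscillator sum matches a direct transcription", {
  osc <- data.frame(amplitude = c(2.3, 0.7), omega = c(2.7, 3.1),
                    phi = c(-0.8, 0.4), gamma = c(0.4, 1.1))
  w <- c(1.2, 2.3, 3.3)
  expect_equal(breshike_interband(w, osc), oracle_cp_sum(w, osc),
               tolerance = 1e-12)
  # zero amplitude contributes nothing
  osc0 <- data.frame(amplitude = 0, omega = 2.7, phi = 0.3, gamma = 0.4)
  expect_equal(breshike_interband(2.3, osc0), 0 + 0i)
  # the two bracketed terms are conjugate-symmetric under w -> -w
  one <- osc[1, ]
  t1 <- function(w) exp(1i * one$phi) / (one$omega - w - 1i * one$gamma)
  t2 <- function(w) exp(-1i * one$phi) / (one$omega + w + 1i * one$gamma)
  expect_equal(t1(2.3), Conj(t2(-2.3)), tolerance = 1e-12)
  expect_error(breshike_interband(2.3, NULL), "oscillator")
})

test_that("size multiplier tends to identity and matches hand evaluation", {
  m_inf <- size_multiplier(2.3, gold, 1e12)
  expect_equal(m_inf$real, 1, tolerance = 1e-10)
  expect_equal(m_inf$imag, 1, tolerance = 1e-10)
  m_c0 <- size_multiplier(2.3, drude_params("gold", scattering_constant = 0), 5)
  expect_equal(m_c0$real, 1, tolerance = 1e-12)
  expect_equal(m_c0$imag, 1, tolerance = 1e-12)
  # hand evaluation of the imaginary factor from the damping constants
  gr <- size_damping(gold, 5)
  gi <- gold$gamma_inf
  w2 <- 2.3^2
  expect_equal(size_multiplier(2.3, gold, 5)$imag,
               (gr * (w2 + gi^2)) / (gi * (w2 + gr^2)), tolerance = 1e-12)
  # singularity guard names a wavelength
  w_sing <- sqrt(gold$omega_p^2 / gold$eps_inf - gold$gamma_inf^2)
  expect_error(size_multiplier(w_sing, gold, 5), "nm")
})

test_that("refractive index square-roots the dielectric and round-trips", {
  expect_equal(refractive_index(4 + 0i), list(n = 2, kappa = 0))
  expect_equal(refractive_index(-1 + 0i), list(n = 0, kappa = 1))
  ri <- refractive_index(complex(real = -4.75, imaginary = 3.80))
  expect_equal(ri$n, 0.815, tolerance = 2e-3)
  expect_equal(ri$kappa, 2.327, tolerance = 1e-3)
  # property: (n + i kappa)^2 == eps over a wide modulus range
  set.seed(11)
  mods <- 10^stats::runif(200, -3, 3)
  args <- stats::runif(200, 0, pi)   # upper half-plane (absorbing)
  eps <- complex(modulus = mods, argument = args)
  ri <- refractive_index(eps)
  back <- (complex(real = ri$n, imaginary = ri$kappa))^2
  expect_equal(back, eps, tolerance = 1e-12)
})

test_that("skin depth follows lambda/(2 pi kappa)", {
  expect_equal(skin_depth(2 * pi, complex(real = 0, imaginary = 2)), 1)
  expect_equal(skin_depth(539, complex(real = -4.75, imaginary = 3.80)),
               36.9, tolerance = 2e-3)
  d1 <- skin_depth(400, complex(real = -3, imaginary = 2))
  d2 <- skin_depth(800, complex(real = -3, imaginary = 2))
  expect_equal(d2, 2 * d1)
  expect_error(skin_depth(539, 2.25 + 0i), "transparent")
})

test_that("bulk table interpolation is node-exact, continuous, bounded", {
  tab <- metal_dielectric_table("gold")
  i <- c(10, 57, 300)
  at_nodes <- corrected_epsilon(tab, tab$wavelength_nm[i], mode = "none")
  expect_equal(Re(at_nodes), tab$eps_real[i], tolerance = 1e-12)
  expect_equal(Im(at_nodes), tab$eps_imag[i], tolerance = 1e-12)
  # continuity across a node
  eps_l <- corrected_epsilon(tab, 500 - 1e-7, mode = "none")
  eps_r <- corrected_epsilon(tab, 500 + 1e-7, mode = "none")
  expect_equal(eps_l, eps_r, tolerance = 1e-6)
  expect_error(corrected_epsilon(tab, 299, mode = "none"), "range")
  expect_error(corrected_epsilon(tab, 801, mode = "none"), "range")
})

test_that("corrected dielectric reproduces the reference gold value", {
  tab <- metal_dielectric_table("gold")
  # large radius leaves the bulk table untouched
  big <- corrected_epsilon(tab, 539, gold, 1e12, mode = "multiplier")
  bulk <- corrected_epsilon(tab, 539, mode = "none")
  expect_equal(big, bulk, tolerance = 1e-9)
  # 10 nm sphere: squared modulus near the reference 36.95
  eps <- corrected_epsilon(tab, 539, gold, 5, mode = "multiplier")
  expect_equal(Mod(eps)^2, 36.95, tolerance = 5e-3)
  # logistic mode equals the analytic model
  lo <- corrected_epsilon(tab, 539, gold, 5, mode = "logistic")
  expect_equal(lo, drude_epsilon(photon_energy(539), gold, 5) +
                 1i * logistic_interband(photon_energy(539)),
               tolerance = 1e-12)
})
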