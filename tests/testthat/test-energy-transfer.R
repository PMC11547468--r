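ref <- tet_reference()
consensus <- ref[!ref$outlier_J & ref$metal != "platinum", ]

test_that("overlap integral handles degenerate spectra and matches quadrature", {
  donor <- donor_dye()
  zero_acc <- data.frame(wavelength_nm = donor$spectrum$wavelength_nm,
                         molar_extinction = 0)
  expect_equal(overlap_integral(donor$spectrum, zero_acc), 0)
  # delta-like single-bin donor
  one <- data.frame(wavelength_nm = 539, intensity = 1)
  acc <- data.frame(wavelength_nm = 539, molar_extinction = 1.01e8)
  expect_equal(overlap_integral(one, acc), 1.01e8 * 539^4)
  # smooth spectra: trapezoid oracle within 0.5%
  fix <- generate_spectra_fixture("gold", 10, c(450, 650))
  acc2 <- data.frame(wavelength_nm = fix$absorbance$wavelength_nm,
                     molar_extinction = fix$absorbance$absorbance / 1e-9)
  j_pkg <- overlap_integral(fix$emission, acc2)
  lam <- fix$emission$wavelength_nm
  j_orc <- oracle_overlap_trapz(lam, fix$emission$intensity,
                                acc2$molar_extinction)
  expect_equal(j_pkg, j_orc, tolerance = 5e-3)
  # disjoint supports warn and return zero
  far <- data.frame(wavelength_nm = 900:950, molar_extinction = 1e6)
  expect_warning(j0 <- overlap_integral(donor$spectrum, far), "disjoint")
  expect_equal(j0, 0)
})

test_that("Forster radius matches the worked example and its scaling", {
  med <- transfer_medium()
  expect_equal(forster_radius(6.51e19, 0.43, med), 274.89, tolerance = 0.01)
  expect_equal(forster_radius(0, 0.43, med), 0)
  j <- 3.2e18
  expect_equal(forster_radius(64 * j, 0.43, med),
               2 * forster_radius(j, 0.43, med), tolerance = 1e-12)
  expect_error(forster_radius(-1, 0.43, med), ">= 0")
})

test_that("one calibrated yield reproduces every consensus Forster distance", {
  cal <- calibrate_dye_parameters(
    data.frame(J = consensus$overlap_integral, R0_A = consensus$fret_d0_A))
  expect_equal(cal$quantum_yield, 0.43, tolerance = 0.01)
  r0 <- forster_radius(consensus$overlap_integral, 0.43, transfer_medium())
  expect_equal(r0, consensus$fret_d0_A, tolerance = 0.01)
})

test_that("yield calibration inverts exactly and flags the outlier rows", {
  # synthetic self-consistent rows from a known yield
  j <- c(2e18, 7e19, 4e20)
  rows <- data.frame(J = j, R0_A = forster_radius(j, 0.317))
  cal <- calibrate_dye_parameters(rows)
  expect_equal(cal$quantum_yield, 0.317, tolerance = 1e-6)
  expect_false(any(cal$outlier))
  # the silver 10 nm row is inconsistent with the consensus calibration
  with10 <- rbind(consensus[c("overlap_integral", "fret_d0_A")],
                  ref[ref$metal == "silver" & ref$diameter_nm == 10,
                      c("overlap_integral", "fret_d0_A")])
  names(with10) <- c("J", "R0_A")
  cal2 <- calibrate_dye_parameters(with10)
  expect_true(cal2$outlier[nrow(with10)])
  expect_false(any(cal2$outlier[seq_len(nrow(with10) - 1)]))
  expect_error(calibrate_dye_parameters(rows[1, ]), "two")
})

test_that("absorptivity is linear in extinction and zero at zero", {
  expect_equal(np_absorptivity(0, 5, 36.9), 0)
  a1 <- np_absorptivity(1e8, 5, 36.9)
  expect_equal(np_absorptivity(2e8, 5, 36.9), 2 * a1, tolerance = 1e-12)
  expect_error(np_absorptivity(1e8, -5, 36.9), "radius")
  expect_error(np_absorptivity(1e8, 5, 0), "skin")
})

test_that("NSET d0 reproduces reference rows and its homogeneity", {
  row <- ref[ref$metal == "gold" & ref$diameter_nm == 10, ]
  acc <- acceptor_np("gold", 5,
                     complex(real = row$eps_real, imaginary = row$eps_imag),
                     row$molar_extinction)
  d0 <- nset_d0(acc)
  expect_equal(d0, row$nset_d0_A, tolerance = 0.05)
  # linear in alpha, fourth-root in the quantum yield
  expect_equal(nset_d0(acc, alpha = 2 * nset_alpha_default()), 2 * d0,
               tolerance = 1e-12)
  dye16 <- donor_dye(quantum_yield = 0.43 / 16)
  expect_equal(nset_d0(acc, dye16), d0 / 2, tolerance = 1e-12)
  expect_error(nset_d0(acc, alpha = 0), "alpha")
})

test_that("quenching efficiency has the exact half point and limits", {
  expect_equal(quench_efficiency(156.41, 156.41), 0.5)
  expect_equal(quench_efficiency(78, 156, exponent = 4), 16 / 17,
               tolerance = 1e-3)
  expect_equal(quench_efficiency(1e9, 150), 0, tolerance = 1e-12)
  r <- seq(40, 400, by = 5)
  e4 <- quench_efficiency(r, 150, 4)
  e6 <- quench_efficiency(r, 150, 6)
  expect_true(all(diff(e4) < 0))
  expect_true(all(e4 > 0 & e4 < 1))
  # the shallower NSET curve lies above FRET beyond the common d0
  expect_true(all(e4[r > 150] > e6[r > 150]))
  expect_error(quench_efficiency(-1, 150), "positive")
})

test_that("background correction recovers a constructed dye component", {
  expect_equal(background_correct(1, 1, c(1, 2, 3), c(1, 2, 3))$spectrum,
               c(0, 0, 0))
  s <- c(0.2, 1, 0.4)
  expect_equal(background_correct(0.5, 2, rep(0, 3), s)$spectrum, s)
  # sample = dye + 0.7 * reference scattering, absorbance ratio 0.7
  lam <- 525:700
  dye_em <- exp(-(lam - 539)^2 / 200)
  scatter <- 5 * exp(-(lam - 530)^2 / 5000)
  out <- background_correct(0.7, 1, scatter, dye_em + 0.7 * scatter)
  expect_equal(out$spectrum, dye_em, tolerance = 1e-10)
  expect_equal(out$n_clipped, 0)
  expect_error(background_correct(1, 0, 1, 1), "positive")
})
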