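# Independent oracles, deliberately implemented apart from the package
# code paths they check.

# quasi-static (Rayleigh) absorption cross-section of a small sphere, cm^2
oracle_quasistatic_abs <- function(eps, radius_nm, wavelength_nm, n_med) {
  em <- n_med^2
  v_cm3 <- 4 / 3 * pi * (radius_nm * 1e-7)^3
  lam_cm <- wavelength_nm * 1e-7
  18 * pi * v_cm3 * em^1.5 / lam_cm *
    Im(eps) / ((Re(eps) + 2 * em)^2 + Im(eps)^2)
}

# trapezoid-rule overlap integral on a common grid
oracle_overlap_trapz <- function(lam, fd, ea) {
  fd <- fd / sum(fd)            # unit-area donor on the 1 nm grid
  f <- fd * ea * lam^4
  sum((f[-1] + f[-length(f)]) / 2 * diff(lam))
}

# element-by-element re-summations
oracle_mre <- function(p, o) {
  s <- 0
  for (i in seq_along(p)) s <- s + abs(100 * (p[i] - o[i]) / o[i])
  s / length(p)
}
oracle_rmse <- function(p, o) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - o[i])^2
  sqrt(s / length(p))
}
oracle_r2 <- function(o, p) {
  m <- sum(o) / length(o)
  1 - sum((o - p)^2) / sum((o - m)^2)
}

# direct term-by-term transcription of the critical-point oscillator sum
oracle_cp_sum <- function(w, osc) {
  total <- 0 + 0i
  for (i in seq_len(nrow(osc))) {
    t1 <- exp(1i * osc$phi[i]) / (osc$omega[i] - w - 1i * osc$gamma[i])
    t2 <- exp(-1i * osc$phi[i]) / (osc$omega[i] + w + 1i * osc$gamma[i])
    total <- total + osc$amplitude[i] * osc$omega[i] * (t1 + t2)
  }
  total
}

# small noise-free case table whose generating parameters are known
make_noisefree_cases <- function(seed = 3, n = 24, true_c = 0.7,
                                 true_alpha = 0.12) {
  generate_cases(
    generator_config(n = n, n_silver = max(2, round(n / 12)),
                     quench_sigma = 0, fluor_sigma = 0, seed = seed),
    true_c = true_c, true_alpha = true_alpha
  )
}
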