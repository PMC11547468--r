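# Exhaustive grid search over the surface-scattering constant C and the
# orientation prefactor alpha, minimizing MRE/RMSE between predicted and
# observed fluorescence quenching over a case table. `nset_fit()` is the
# user-facing fitting function; the pieces (predict_quench, mre, rmse,
# exhaustive_search, refine_search) are exported for direct use.

#' Mean relative error (percent)
#'
#' `MRE = (1/N) * sum |100 * (Qc - Qa) / Qa|` between computed and
#' observed quenching.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @param epsilon Optional threshold: observations with `|Qa| < epsilon`
#'   are excluded (their count is attached as attribute `n_excluded`).
#'   Without it, any zero observation is an error.
#' @return The MRE in percent.
#' @export
mre <- function(predicted, observed, epsilon = NULL) {
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ")
  if (is.null(epsilon)) {
    bad <- which(observed == 0)
    if (length(bad))
      stop("observed quenching is zero at indices ",
           paste(bad, collapse = ", "),
           "; MRE undefined (set epsilon to exclude)")
    keep <- rep(TRUE, length(observed))
  } else {
    keep <- abs(observed) >= epsilon
  }
  out <- mean(abs(100 * (predicted[keep] - observed[keep]) / observed[keep]))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Root-mean-square error
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return `sqrt(mean((Qc - Qa)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed lengths differ")
  sqrt(mean((predicted - observed)^2))
}

# canonical metal key from a case-table label
.metal_key <- function(x) {
  vapply(tolower(as.character(x)), function(m)
    switch(m, au = , gold = "gold", ag = , silver = "silver",
           cu = , copper = "copper", pt = , platinum = "platinum",
           stop("unknown metal in case table: ", m)),
    character(1), USE.NAMES = FALSE)
}

# unit-alpha NSET d0 (Angstrom) for one metal/radius over a vector of
# scattering constants; the full forward chain of the calculator modules.
# molar_ext: NULL to recompute by Mie per C, or a fixed value to reuse.
.unit_d0_vs_c <- function(metal, radius_nm, c_values, dye, medium,
                          mie_medium_index, bracket, prefactor,
                          table = NULL, molar_ext = NULL) {
  params <- drude_params(metal)
  if (is.null(table)) table <- metal_dielectric_table(metal)
  lam0 <- dye$emission_peak_nm
  bulk <- interp_dielectric(table, lam0)
  w <- photon_energy(lam0)
  vapply(c_values, function(cc) {
    p <- params; p$scattering_constant <- cc
    m <- size_multiplier(w, p, radius_nm)
    eps <- complex(real = Re(bulk) * m$real, imaginary = Im(bulk) * m$imag)
    n_m <- refractive_index(eps)$n
    delta <- skin_depth(lam0, eps)
    ext <- if (is.null(molar_ext)) {
      mie_cross_sections(radius_nm, lam0, eps,
                         medium_index = mie_medium_index)$molar_extinction
    } else molar_ext
    a_np <- np_absorptivity(ext, radius_nm, delta,
                            bracket = bracket, prefactor = prefactor)
    geom <- (n_m / (2 * medium$np_index)) *
      (1 + medium$solvent_dielectric^2 / Mod(eps)^2)
    10 * (lam0 / medium$np_index) *
      (a_np * dye$quantum_yield)^(1 / 4) * geom^(1 / 4)
  }, numeric(1))
}

# validate the case-table columns the search needs
.check_cases <- function(cases, need_target = TRUE) {
  need <- c("metal", "radius_nm", "theoretical_length_A")
  if (need_target) need <- c(need, "quenching")
  miss <- setdiff(need, names(cases))
  if (length(miss))
    stop("case table lacks required columns: ", paste(miss, collapse = ", "))
  if (nrow(cases) < 1) stop("case table is empty")
  invisible(cases)
}

#' Predicted NSET quenching for a case table at given (C, alpha)
#'
#' Re-runs the forward chain per case: size-corrected dielectric at the
#' donor emission maximum with scattering constant `c`, skin depth,
#' absorptivity, `d0` with prefactor `alpha`, and the 1/r^4 quenching
#' efficiency at the case separation (`theoretical_length_A`).
#'
#' @param cases Case table (see [generate_cases()] for the schema).
#' @param c Scattering constant.
#' @param alpha Orientation prefactor.
#' @param dye,medium Donor and medium descriptions.
#' @param recompute_extinction When `TRUE` (default) the Mie molar
#'   extinction is recomputed from the corrected dielectric at each `c`;
#'   when `FALSE` the case table's stored `molar_extinction` column is
#'   reused.
#' @param mie_medium_index Medium index for Mie recomputation.
#' @inheritParams np_absorptivity
#' @return Numeric vector of predicted quenching efficiencies.
#' @export
predict_quench <- function(cases, c, alpha, dye = donor_dye(),
                           medium = transfer_medium(),
                           recompute_extinction = TRUE,
                           mie_medium_index = 1.40,
                           bracket = "calibrated", prefactor = 11.856128) {
  .check_cases(cases, need_target = FALSE)
  if (alpha < 0) stop("alpha must be >= 0")
  if (alpha == 0) return(rep(0, nrow(cases)))
  key <- .metal_key(cases$metal)
  combo <- paste(key, cases$radius_nm)
  d0 <- numeric(nrow(cases))
  for (cb in unique(combo)) {
    i <- which(combo == cb)
    ext <- if (recompute_extinction) NULL else {
      if (is.null(cases$molar_extinction))
        stop("recompute_extinction = FALSE needs a molar_extinction column")
      cases$molar_extinction[i[1]]
    }
    d0[i] <- alpha * .unit_d0_vs_c(key[i[1]], cases$radius_nm[i[1]], c,
                                   dye, medium, mie_medium_index,
                                   bracket, prefactor, molar_ext = ext)
  }
  quench_efficiency(cases$theoretical_length_A, d0, exponent = 4)
}

#' Define a (alpha, C) search grid
#'
#' @param alpha Range `c(lo, hi)` for the orientation prefactor.
#' @param c Range `c(lo, hi)` for the scattering constant.
#' @param points Points per axis (>= 2).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(alpha = base::c(0, 4), c = base::c(0.1, 2),
                      points = 100) {
  if (points < 2) stop("points per axis must be >= 2")
  if (alpha[1] >= alpha[2] || c[1] >= c[2]) stop("ranges must have lo < hi")
  structure(list(alpha_values = seq(alpha[1], alpha[2], length.out = points),
                 c_values = seq(c[1], c[2], length.out = points)),
            class = "grid_spec")
}

# argmin with deterministic alpha-major tie-break (scan C within alpha)
.argmin_alpha_major <- function(m) {
  k <- which.min(t(m))               # t(m): [n_c x n_alpha], column-major
  n_c <- ncol(m)
  a <- ceiling(k / n_c)
  c_i <- k - (a - 1) * n_c
  c(alpha = a, c = c_i)
}

#' Exhaustive grid search over (C, alpha)
#'
#' Evaluates the forward model at every grid node for every case and
#' returns both error surfaces and their argmins. Fully deterministic;
#' ties broken by the first node in alpha-major scan order.
#'
#' @param cases Case table with a `quenching` target column.
#' @param grid A [grid_spec()].
#' @param mre_epsilon Passed to [mre()] to exclude near-zero
#'   observations (default `NULL`: zero observations are an error).
#' @inheritParams predict_quench
#' @return An object of class `nset_grid`: alpha/C grids, `mre` and
#'   `rmse` surfaces (`[alpha x C]` matrices), per-objective argmins and
#'   the evaluation count.
#' @export
exhaustive_search <- function(cases, grid = grid_spec(),
                              dye = donor_dye(), medium = transfer_medium(),
                              recompute_extinction = TRUE,
                              mie_medium_index = 1.40,
                              bracket = "calibrated", prefactor = 11.856128,
                              mre_epsilon = NULL) {
  .check_cases(cases)
  av <- grid$alpha_values
  cv <- grid$c_values
  obs <- cases$quenching
  if (is.null(mre_epsilon)) {
    if (any(obs == 0))
      stop("observed quenching contains zeros; set mre_epsilon")
    keep <- rep(TRUE, length(obs))
  } else keep <- abs(obs) >= mre_epsilon

  key <- .metal_key(cases$metal)
  combo <- paste(key, cases$radius_nm)
  ucombo <- unique(combo)
  # unit-alpha d0 per unique (metal, radius) over the C grid
  k_unit <- matrix(0, length(ucombo), length(cv),
                   dimnames = list(ucombo, NULL))
  for (cb in ucombo) {
    i <- which(combo == cb)[1]
    ext <- if (recompute_extinction) NULL else {
      if (is.null(cases$molar_extinction))
        stop("recompute_extinction = FALSE needs a molar_extinction column")
      cases$molar_extinction[i]
    }
    k_unit[cb, ] <- .unit_d0_vs_c(key[i], cases$radius_nm[i], cv,
                                  dye, medium, mie_medium_index,
                                  bracket, prefactor, molar_ext = ext)
  }
  n_a <- length(av); n_c <- length(cv)
  sum_abs <- matrix(0, n_a, n_c)
  sum_sq <- matrix(0, n_a, n_c)
  for (i in seq_len(nrow(cases))) {
    # d0[alpha, C] = alpha (x) unit-d0(C); efficiency at this separation
    d0 <- outer(av, k_unit[combo[i], ])
    eff <- ifelse(d0 > 0,
                  1 / (1 + (cases$theoretical_length_A[i] / d0)^4), 0)
    if (keep[i]) sum_abs <- sum_abs + abs(100 * (eff - obs[i]) / obs[i])
    sum_sq <- sum_sq + (eff - obs[i])^2
  }
  mre_surface <- sum_abs / sum(keep)
  rmse_surface <- sqrt(sum_sq / length(obs))
  am <- .argmin_alpha_major(mre_surface)
  ar <- .argmin_alpha_major(rmse_surface)
  structure(list(
    alpha_values = av, c_values = cv,
    mre = mre_surface, rmse = rmse_surface,
    argmin_mre = c(c = unname(cv[am["c"]]), alpha = unname(av[am["alpha"]])),
    argmin_rmse = c(c = unname(cv[ar["c"]]), alpha = unname(av[ar["alpha"]])),
    min_mre = mre_surface[am["alpha"], am["c"]],
    min_rmse = rmse_surface[ar["alpha"], ar["c"]],
    n_excluded = sum(!keep),
    evaluations = n_a * n_c * nrow(cases)
  ), class = "nset_grid")
}

#' @export
print.nset_grid <- function(x, ...) {
  cat(sprintf("Exhaustive (alpha, C) grid: %d x %d nodes, %d evaluations\n",
              length(x$alpha_values), length(x$c_values), x$evaluations))
  cat(sprintf("  min MRE  = %.4f %% at C = %.4g, alpha = %.4g\n",
              x$min_mre, x$argmin_mre["c"], x$argmin_mre["alpha"]))
  cat(sprintf("  min RMSE = %.6f   at C = %.4g, alpha = %.4g\n",
              x$min_rmse, x$argmin_rmse["c"], x$argmin_rmse["alpha"]))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d near-zero observations excluded from MRE)\n",
                x$n_excluded))
  invisible(x)
}

#' Default coarse-to-fine refinement stages
#'
#' Three fixed stages narrowing the alpha band while keeping the full C
#' band: alpha in (0, 4), (0.04, 2), (0.04, 0.1); C in (0.1, 2)
#' throughout.
#'
#' @param points Points per axis per stage.
#' @return A list of [grid_spec()] objects.
#' @export
default_stages <- function(points = 100) {
  list(grid_spec(alpha = c(0, 4), c = c(0.1, 2), points = points),
       grid_spec(alpha = c(0.04, 2), c = c(0.1, 2), points = points),
       grid_spec(alpha = c(0.04, 0.1), c = c(0.1, 2), points = points))
}

#' Coarse-to-fine sequence of exhaustive searches
#'
#' Runs the fixed refinement stages in order (the bands are part of the
#' protocol, not auto-centered) and reports the cumulative evaluation
#' count.
#'
#' @param cases Case table.
#' @param stages List of [grid_spec()] objects (default
#'   [default_stages()]).
#' @param ... Passed to [exhaustive_search()].
#' @return An object of class `nset_refine`: list of `nset_grid` stage
#'   results plus `cumulative_evaluations`.
#' @export
refine_search <- function(cases, stages = default_stages(), ...) {
  if (length(stages) == 0) stop("refinement policy is empty")
  res <- lapply(stages, function(g) exhaustive_search(cases, g, ...))
  structure(list(stages = res,
                 cumulative_evaluations =
                   sum(vapply(res, `[[`, numeric(1), "evaluations"))),
            class = "nset_refine")
}

#' @export
print.nset_refine <- function(x, ...) {
  cat(sprintf("Refined grid search: %d stages, %s evaluations total\n",
              length(x$stages),
              format(x$cumulative_evaluations, big.mark = ",")))
  for (i in seq_along(x$stages)) {
    s <- x$stages[[i]]
    cat(sprintf(
      "  stage %d: alpha [%.3g, %.3g], C [%.3g, %.3g] -> MRE %.4f at (C=%.4g, alpha=%.4g)\n",
      i, min(s$alpha_values), max(s$alpha_values),
      min(s$c_values), max(s$c_values),
      s$min_mre, s$argmin_mre["c"], s$argmin_mre["alpha"]))
  }
  invisible(x)
}
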