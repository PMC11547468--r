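# The fitting front end: nset_fit() runs the coarse-to-fine exhaustive
# grid search and returns a classed model object with the usual methods.

#' Fit the NSET quenching model to a case table
#'
#' Estimates the surface-scattering constant C and the orientation
#' prefactor alpha by exhaustive grid search: the forward model
#' (size-corrected dielectric, skin depth, absorptivity, d0, 1/r^4
#' efficiency) is evaluated at every node of a coarse-to-fine sequence
#' of (alpha, C) grids and the node minimizing the chosen objective is
#' selected. No gradients, no stochastic search: the estimate is the
#' exact grid argmin and is fully reproducible.
#'
#' @param cases Case table (see [generate_cases()] for the schema);
#'   must contain `metal`, `radius_nm`, `theoretical_length_A` and the
#'   observed `quenching` target.
#' @param stages List of [grid_spec()] stages (default
#'   [default_stages()]: alpha bands (0, 4), (0.04, 2), (0.04, 0.1) with
#'   C in (0.1, 2), 100 x 100 nodes each).
#' @param objective `"mre"` (default; mean relative error, percent) or
#'   `"rmse"`; both surfaces are always computed.
#' @param ... Passed to [exhaustive_search()] (e.g. `mre_epsilon`,
#'   `recompute_extinction`, `bracket`).
#' @return An object of class `nset_fit` with methods `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals` and `plot`.
#' @examples
#' \donttest{
#' cases <- generate_cases(generator_config(seed = 1))
#' fit <- nset_fit(cases, stages = default_stages(points = 25))
#' coef(fit)
#' }
#' @export
nset_fit <- function(cases, stages = default_stages(),
                     objective = c("mre", "rmse"), ...) {
  objective <- match.arg(objective)
  search <- refine_search(cases, stages, ...)
  final <- search$stages[[length(search$stages)]]
  est <- if (objective == "mre") final$argmin_mre else final$argmin_rmse
  dots <- list(...)
  pdots <- dots[intersect(names(dots), names(formals(predict_quench)))]
  fitted_q <- do.call(predict_quench,
                      c(list(cases = cases, c = est["c"],
                             alpha = est["alpha"]), pdots))
  structure(list(
    coefficients = est,
    objective = objective,
    value = if (objective == "mre") final$min_mre else final$min_rmse,
    min_mre = final$min_mre, min_rmse = final$min_rmse,
    search = search,
    cases = cases,
    fitted.values = fitted_q,
    residuals = cases$quenching - fitted_q,
    nobs = nrow(cases),
    dots = pdots,
    call = match.call()
  ), class = "nset_fit")
}

#' @export
coef.nset_fit <- function(object, ...) object$coefficients

#' @export
fitted.nset_fit <- function(object, ...) object$fitted.values

#' @export
residuals.nset_fit <- function(object, ...) object$residuals

#' Predict quenching for new cases from a fitted model
#'
#' @param object An [nset_fit()] object.
#' @param newdata Optional case table; default the fitting table.
#' @param ... Ignored.
#' @return Predicted quenching efficiencies.
#' @export
predict.nset_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  est <- object$coefficients
  do.call(predict_quench,
          c(list(cases = newdata, c = est["c"], alpha = est["alpha"]),
            object$dots))
}

#' @export
print.nset_fit <- function(x, ...) {
  cat("NSET quenching model, exhaustive grid-search fit\n")
  cat(sprintf("  %d cases; %d stages, %s evaluations\n", x$nobs,
              length(x$search$stages),
              format(x$search$cumulative_evaluations, big.mark = ",")))
  cat(sprintf("  C = %.4g, alpha = %.4g  (objective %s = %.4f)\n",
              x$coefficients["c"], x$coefficients["alpha"],
              toupper(x$objective), x$value))
  invisible(x)
}

#' @export
summary.nset_fit <- function(object, ...) {
  s <- list(
    coefficients = object$coefficients,
    objective = object$objective,
    min_mre = object$min_mre,
    min_rmse = object$min_rmse,
    nobs = object$nobs,
    stages = lapply(object$search$stages, function(st)
      c(alpha_lo = min(st$alpha_values), alpha_hi = max(st$alpha_values),
        c_lo = min(st$c_values), c_hi = max(st$c_values),
        min_mre = st$min_mre, min_rmse = st$min_rmse)),
    cumulative_evaluations = object$search$cumulative_evaluations,
    residual_summary = summary(object$residuals)
  )
  class(s) <- "summary.nset_fit"
  s
}

#' @export
print.summary.nset_fit <- function(x, ...) {
  cat("NSET quenching model, exhaustive grid-search fit\n")
  cat(sprintf("Cases: %d   Evaluations: %s\n", x$nobs,
              format(x$cumulative_evaluations, big.mark = ",")))
  cat("Stages:\n")
  for (i in seq_along(x$stages)) {
    st <- x$stages[[i]]
    cat(sprintf(
      "  %d: alpha [%g, %g] x C [%g, %g]  min MRE %.4f, min RMSE %.6f\n",
      i, st["alpha_lo"], st["alpha_hi"], st["c_lo"], st["c_hi"],
      st["min_mre"], st["min_rmse"]))
  }
  cat(sprintf("Estimates (%s): C = %.4g, alpha = %.4g\n",
              toupper(x$objective), x$coefficients["c"],
              x$coefficients["alpha"]))
  cat("Residuals:\n"); print(x$residual_summary)
  invisible(x)
}

#' Error-surface image of a fitted model
#'
#' Draws the final-stage objective surface over (C, alpha) with the
#' estimate marked.
#'
#' @param x An [nset_fit()] object.
#' @param objective Surface to draw (default the fitted objective).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.nset_fit <- function(x, objective = x$objective, ...) {
  st <- x$search$stages[[length(x$search$stages)]]
  z <- if (objective == "mre") st$mre else st$rmse
  graphics::image(st$c_values, st$alpha_values, t(z),
                  xlab = "scattering constant C",
                  ylab = "orientation prefactor alpha",
                  main = sprintf("%s surface (final stage)",
                                 toupper(objective)), ...)
  graphics::points(x$coefficients["c"], x$coefficients["alpha"],
                   pch = 4, cex = 1.5, lwd = 2)
  invisible(x)
}
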