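test_that("error metrics match brute-force re-summation", {
  expect_equal(mre(c(0.5), c(0.4)), 25, ignore_attr = TRUE)
  expect_equal(rmse(c(0.5), c(0.4)), 0.1)
  expect_equal(mre(c(0.3, 0.2), c(0.3, 0.2)), 0, ignore_attr = TRUE)
  expect_equal(rmse(c(0.3, 0.2), c(0.3, 0.2)), 0)
  set.seed(4)
  p <- stats::runif(30); o <- stats::runif(30, 0.1, 1)
  expect_equal(as.numeric(mre(p, o)), oracle_mre(p, o), tolerance = 1e-12)
  expect_equal(rmse(p, o), oracle_rmse(p, o), tolerance = 1e-12)
  # constant offset has closed-form RMSE
  expect_equal(rmse(o + 0.07, o), 0.07, tolerance = 1e-12)
  expect_error(mre(c(1, 2), c(1, 0)), "indices 2")
  expect_equal(attr(mre(c(1, 2), c(1, 0), epsilon = 0.5), "n_excluded"), 1)
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("predicted quenching behaves as the forward model dictates", {
  cases <- make_noisefree_cases(n = 12)
  expect_equal(predict_quench(cases, 0.5, 0), rep(0, 12))
  # monotone increasing in alpha
  p1 <- predict_quench(cases, 0.5, 0.08)
  p2 <- predict_quench(cases, 0.5, 0.16)
  expect_true(all(p2 > p1))
  # at the generating parameters it reproduces the stored theory exactly
  p <- predict_quench(cases, 0.7, 0.12)
  expect_equal(p, cases$nset_quench_theory, tolerance = 1e-12)
  # a case sitting exactly at its own d0 quenches 50%
  one <- cases[1, ]
  one$theoretical_length_A <- one$nset_d0_A
  expect_equal(predict_quench(one, 0.7, 0.12), 0.5, tolerance = 1e-12)
  # reusing the stored extinction equals recomputation at the generating C
  expect_equal(predict_quench(cases, 0.7, 0.12, recompute_extinction = FALSE),
               p, tolerance = 1e-12)
})

test_that("a 2x2 grid equals four independent evaluations", {
  cases <- make_noisefree_cases(n = 10)
  g <- exhaustive_search(cases, grid_spec(alpha = c(0.05, 0.2),
                                          c = c(0.3, 1.5), points = 2),
                         mre_epsilon = 1e-9)
  for (i in 1:2) for (j in 1:2) {
    p <- predict_quench(cases, g$c_values[j], g$alpha_values[i])
    expect_equal(g$mre[i, j],
                 as.numeric(mre(p, cases$quenching, epsilon = 1e-9)),
                 tolerance = 1e-12)
    expect_equal(g$rmse[i, j], rmse(p, cases$quenching), tolerance = 1e-12)
  }
  expect_equal(g$evaluations, 2 * 2 * 10)
})

test_that("surfaces are deterministic, order-invariant, with exact argmin", {
  cases <- make_noisefree_cases(n = 14)
  gs <- grid_spec(alpha = c(0.04, 0.2), c = c(0.1, 2), points = 9)
  g1 <- exhaustive_search(cases, gs, mre_epsilon = 1e-9)
  g2 <- exhaustive_search(cases, gs, mre_epsilon = 1e-9)
  expect_identical(g1$mre, g2$mre)
  expect_identical(g1$rmse, g2$rmse)
  shuf <- cases[rev(seq_len(nrow(cases))), ]
  g3 <- exhaustive_search(shuf, gs, mre_epsilon = 1e-9)
  expect_equal(g3$mre, g1$mre, tolerance = 1e-12)
  # argmin against independent full re-enumeration
  best <- c(Inf, NA, NA)
  for (a in g1$alpha_values) for (cc in g1$c_values) {
    v <- rmse(predict_quench(cases, cc, a), cases$quenching)
    if (v < best[1]) best <- c(v, cc, a)
  }
  expect_equal(unname(g1$argmin_rmse), best[2:3], tolerance = 1e-12)
  expect_equal(g1$min_rmse, best[1], tolerance = 1e-12)
})

test_that("noise-free tables are recovered exactly on a grid containing truth", {
  cases <- make_noisefree_cases(n = 20, true_c = 0.7, true_alpha = 0.12)
  # 0.7 and 0.12 are nodes of these grids
  gs <- grid_spec(alpha = c(0.04, 0.2), c = c(0.5, 0.9), points = 5)
  expect_true(any(abs(gs$alpha_values - 0.12) < 1e-12))
  expect_true(any(abs(gs$c_values - 0.7) < 1e-9))
  g <- exhaustive_search(cases, gs, mre_epsilon = 1e-9)
  expect_equal(unname(g$argmin_mre), c(0.7, 0.12), tolerance = 1e-9)
  expect_equal(unname(g$argmin_rmse), c(0.7, 0.12), tolerance = 1e-9)
  expect_equal(g$min_rmse, 0, tolerance = 1e-10)
})

test_that("refinement runs the staged protocol and cannot get worse", {
  cases <- make_noisefree_cases(n = 12)
  one <- refine_search(cases, list(grid_spec(points = 7)), mre_epsilon = 1e-9)
  solo <- exhaustive_search(cases, grid_spec(points = 7), mre_epsilon = 1e-9)
  expect_equal(one$stages[[1]]$mre, solo$mre)
  expect_equal(one$cumulative_evaluations, solo$evaluations)
  # evaluation accounting of the full protocol: 3 stages x points^2 x cases
  stages <- default_stages(points = 10)
  rs <- refine_search(cases, stages, mre_epsilon = 1e-9)
  expect_equal(rs$cumulative_evaluations, 3 * 100 * 12)
  # objectives are nonincreasing across the nested zero-noise stages
  vals <- vapply(rs$stages, `[[`, numeric(1), "min_rmse")
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(refine_search(cases, list()), "empty")
})

test_that("alpha is identified under noise while C is model-degenerate", {
  a_star <- 0.04 + 55 * 0.06 / 99     # a stage-3 grid node
  cases <- generate_cases(generator_config(seed = 42), true_c = 0.8,
                          true_alpha = a_star)
  fin <- refine_search(cases, default_stages(points = 50),
                       mre_epsilon = 1e-6)$stages[[3]]
  astep <- diff(fin$alpha_values[1:2])
  expect_lt(abs(fin$argmin_rmse["alpha"] - a_star), 4 * astep)
  # the C direction is a ridge: with 52 gold cases the forward model is
  # nearly C-invariant, so the RMSE profile over C is flat to ~noise/sqrt(n)
  prof <- apply(fin$rmse, 2, min)
  expect_lt(diff(range(prof)), 0.02)
})

test_that("nset_fit returns a coherent model object", {
  cases <- make_noisefree_cases(n = 16, true_c = 0.7, true_alpha = 0.12)
  fit <- nset_fit(cases,
                  stages = list(grid_spec(alpha = c(0.04, 0.2),
                                          c = c(0.5, 0.9), points = 5)),
                  mre_epsilon = 1e-9)
  expect_s3_class(fit, "nset_fit")
  expect_equal(unname(coef(fit)), c(0.7, 0.12), tolerance = 1e-9)
  expect_equal(fitted(fit), cases$nset_quench_theory, tolerance = 1e-10)
  expect_equal(residuals(fit), cases$quenching - fitted(fit))
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, cases[3:5, ]), fitted(fit)[3:5], tolerance = 1e-12)
  expect_output(print(fit), "C = 0.7")
  expect_output(print(summary(fit)), "Stages")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
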