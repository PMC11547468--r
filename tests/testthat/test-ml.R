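cases56 <- generate_cases(generator_config(seed = 42))

test_that("min-max standardization scales, encodes and inverts", {
  fm <- standardize_cases(cases56)
  expect_true(all(fm$x >= 0 & fm$x <= 1))
  expect_true(all(fm$x[, "metal"] %in% c(0, 1)))
  expect_equal(sum(fm$x[, "metal"]), sum(cases56$metal == "silver"))
  # constant columns map to zero and are recorded
  expect_true(all(c("alpha", "scattering_c") %in% fm$constant))
  expect_true(all(fm$x[, "alpha"] == 0))
  # a column already spanning [0, 1] with min 0, max 1 is unchanged
  df <- cases56; df$unit <- seq(0, 1, length.out = nrow(df))
  expect_equal(standardize_cases(df)$x[, "unit"], df$unit,
               ignore_attr = TRUE)
  # round-trip inverse
  back <- unstandardize(fm)
  num <- setdiff(colnames(back), "metal")
  expect_equal(back[, num], as.matrix(cases56[, num]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(standardize_cases(cases56, target = "nope"), "target")
})

test_that("R^2 matches a hand-summed oracle and its anchors", {
  y <- c(1, 2, 3, 5)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  set.seed(8)
  o <- stats::rnorm(40); p <- o + stats::rnorm(40, 0, 0.3)
  expect_equal(r_squared(o, p), oracle_r2(o, p), tolerance = 1e-12)
  expect_error(r_squared(rep(1, 5), 1:5), "equal")
})

test_that("the L1 learner has its OLS and full-shrinkage limits", {
  set.seed(2)
  x <- cbind(a = stats::runif(40), b = stats::runif(40))
  y <- 2 * x[, "a"] - 3 * x[, "b"] + 1
  ols <- fit_l1_linear(x, y, penalty = 0)
  expect_equal(unname(coef(ols)), c(1, 2, -3), tolerance = 1e-8)
  big <- fit_l1_linear(x, y, penalty = 1e6)
  expect_equal(unname(coef(big)[-1]), c(0, 0))
  expect_warning(flat <- fit_l1_linear(x, rep(0.4, 40)), "intercept-only")
  expect_equal(predict(flat, x), rep(0.4, 40))
  # L1 path: active set is nonincreasing in the penalty
  fm <- standardize_cases(cases56)
  pens <- c(1e-4, 1e-3, 1e-2, 1e-1)
  nz <- vapply(pens, function(p)
    sum(coef(fit_l1_linear(fm$x, fm$y, penalty = p))[-1] != 0), numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("the perceptron is seed-reproducible and fits simple targets", {
  set.seed(5)
  x <- matrix(stats::runif(120), 30)
  y <- 0.8 * x[, 1] - 0.3 * x[, 2] + 0.1
  f1 <- fit_mlp(x, y, seed = 7)
  f2 <- fit_mlp(x, y, seed = 7)
  expect_identical(predict(f1, x), predict(f2, x))
  fc <- fit_mlp(x, rep(0.7, 30), seed = 7)
  expect_lt(max(abs(predict(fc, x) - 0.7)), 5e-3)
  expect_error(fit_mlp(x[1:5, ], y[1:5]), "10 rows")
})

test_that("held-out performance on the synthetic table mirrors the study", {
  rep56 <- run_validation_suite(cases56, seed = 42)
  expect_true(all(as.matrix(rep56) <= 1))
  expect_true(all(as.matrix(rep56) > 0.97))
  # same seed gives the identical report (fold memberships included)
  rep2 <- run_validation_suite(cases56, seed = 42)
  expect_identical(as.data.frame(rep56), as.data.frame(rep2))
})

test_that("a deterministic linear target is fit perfectly by the linear learner", {
  df <- cases56
  df$quenching <- 0.9 - 0.5 * df$observed_fluorescence
  fm <- standardize_cases(df)
  tr <- seq_len(37)
  fit <- fit_l1_linear(fm$x[tr, ], fm$y[tr], penalty = 0)
  expect_equal(r_squared(fm$y[-tr], predict(fit, fm$x[-tr, ])), 1,
               tolerance = 1e-6)
})

test_that("shuffled targets destroy the fit (leakage control)", {
  fm <- standardize_cases(cases56)
  set.seed(9)
  yp <- sample(fm$y)
  tr <- seq_len(37)
  lasso <- fit_l1_linear(fm$x[tr, ], yp[tr])
  expect_lt(r_squared(yp[-tr], predict(lasso, fm$x[-tr, ])), 0.2)
  suppressWarnings(mlp <- fit_mlp(fm$x[tr, ], yp[tr]))
  expect_lt(r_squared(yp[-tr], predict(mlp, fm$x[-tr, ])), 0.2)
})
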