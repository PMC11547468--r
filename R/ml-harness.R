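# Regression validation harness: min-max standardization, L1-regularized
# linear regression (glmnet) and a single-hidden-layer perceptron (nnet),
# evaluated under three validation designs with R^2 reporting.

#' Min-max standardize a case table into a feature matrix
#'
#' Encodes the metal as gold = 0 / silver = 1, takes every numeric
#' column except the target, and scales each to `[0, 1]` by
#' `(x - min) / (max - min)`. Constant columns map to 0 (and are
#' recorded); the transform is invertible for non-constant columns via
#' the returned scaling parameters.
#'
#' @param cases Case table ([generate_cases()] schema or compatible).
#' @param target Name of the target column (default `"quenching"`).
#' @param drop_theoretical Drop the theoretical quench columns
#'   (`nset_quench_theory`, `fret_quench_theory`) for ablation.
#' @return A list of class `feature_matrix`: `x` (matrix in `[0, 1]`),
#'   `y` (target vector), `min`/`max` per column, `constant` (names of
#'   constant columns).
#' @export
standardize_cases <- function(cases, target = "quenching",
                              drop_theoretical = FALSE) {
  if (!target %in% names(cases)) stop("no target column '", target, "'")
  df <- cases
  if ("metal" %in% names(df))
    df$metal <- ifelse(.metal_key(df$metal) == "silver", 1, 0)
  drop <- target
  if (drop_theoretical)
    drop <- c(drop, "nset_quench_theory", "fret_quench_theory")
  feats <- setdiff(names(df), drop)
  non_num <- feats[!vapply(df[feats], is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric feature column(s): ", paste(non_num, collapse = ", "))
  x <- as.matrix(df[feats])
  if (any(!is.finite(x))) stop("non-finite feature values")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  rng <- maxs - mins
  const <- names(rng)[rng == 0]
  scl <- sweep(x, 2, mins)
  scl <- sweep(scl, 2, ifelse(rng == 0, 1, rng), "/")
  scl[, const] <- 0
  structure(list(x = scl, y = df[[target]], min = mins, max = maxs,
                 constant = const, target = target),
            class = "feature_matrix")
}

#' Invert the min-max standardization
#'
#' @param fm A `feature_matrix` from [standardize_cases()].
#' @param x Scaled matrix (default the stored one).
#' @return Matrix on the original scale (constant columns restored to
#'   their constant value).
#' @export
unstandardize <- function(fm, x = fm$x) {
  rng <- fm$max - fm$min
  out <- sweep(x, 2, ifelse(rng == 0, 0, rng), "*")
  sweep(out, 2, fm$min, "+")
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @return The R^2 (<= 1; negative when the fit is worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("need equal-length vectors of at least 2 values")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("observed values are all equal; R^2 undefined")
  1 - sum((observed - predicted)^2) / tss
}

#' L1-regularized (Lasso) linear regression
#'
#' Coordinate-descent Lasso via glmnet with the penalty chosen by
#' k-fold cross-validation (or fixed via `penalty`). With `penalty = 0`
#' on full-rank data this is ordinary least squares.
#'
#' @param x Feature matrix.
#' @param y Target vector.
#' @param penalty Optional fixed penalty (lambda); `NULL` (default)
#'   selects it by cross-validation.
#' @param nfolds Folds for the penalty selection.
#' @param seed Seed for the fold assignment.
#' @return An object of class `l1_fit` with `coef`/`predict` methods.
#' @export
fit_l1_linear <- function(x, y, penalty = NULL, nfolds = 5, seed = 42) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two rows")
  if (stats::var(y) == 0) {
    warning("all targets equal; returning intercept-only model")
    return(structure(list(intercept_only = mean(y),
                          lambda = Inf, coefficients = NULL),
                     class = "l1_fit"))
  }
  if (is.null(penalty)) {
    cv <- with_seed(seed,
      glmnet::cv.glmnet(x, y, alpha = 1, nfolds = min(nfolds, nrow(x))))
    penalty <- cv$lambda.min
  }
  fit <- glmnet::glmnet(x, y, alpha = 1, lambda = penalty,
                        thresh = 1e-12)
  structure(list(fit = fit, lambda = penalty,
                 coefficients = stats::coef(fit)[, 1]),
            class = "l1_fit")
}

#' @export
coef.l1_fit <- function(object, ...) object$coefficients

#' @export
predict.l1_fit <- function(object, newx, ...) {
  if (!is.null(object$intercept_only))
    return(rep(object$intercept_only, nrow(as.matrix(newx))))
  as.numeric(glmnet::predict.glmnet(object$fit, as.matrix(newx),
                                    s = object$lambda))
}

#' Single-hidden-layer perceptron regressor
#'
#' A feed-forward network with one hidden layer (logistic units, linear
#' output) trained by quasi-Newton optimization with weight decay;
#' reproducible given the seed. Works on `[0, 1]`-scaled features.
#'
#' @param x Feature matrix (scaled).
#' @param y Target vector.
#' @param size Hidden units (default 8).
#' @param decay Weight decay (default 1e-4).
#' @param maxit Maximum training iterations.
#' @param seed Seed for the weight initialization.
#' @return An object of class `mlp_fit` with a `predict` method.
#' @export
fit_mlp <- function(x, y, size = 8, decay = 1e-4, maxit = 2000,
                    seed = 42) {
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("need at least 10 rows to train the perceptron")
  net <- with_seed(seed,
    nnet::nnet(x, y, size = size, decay = decay, maxit = maxit,
               linout = TRUE, trace = FALSE))
  if (net$convergence != 0)
    warning(sprintf("perceptron stopped at maxit; final loss %.3g",
                    net$value))
  structure(list(net = net), class = "mlp_fit")
}

#' @export
predict.mlp_fit <- function(object, newx, ...) {
  as.numeric(stats::predict(object$net, as.matrix(newx)))
}

.fit_learner <- function(learner, x, y, seed)
  switch(learner,
         lasso = fit_l1_linear(x, y, seed = seed),
         mlp = fit_mlp(x, y, seed = seed),
         stop("unknown learner: ", learner))

#' Run the three-design validation suite
#'
#' For each learner (Lasso and perceptron) runs: (1) a 2/3 training to
#' 1/3 testing split; (2) 5-fold cross-validation (mean train/test R^2
#' over folds); (3) a blind design where 10% of the rows are withheld
#' up front, the remainder re-split 2/3-1/3, and the withheld rows
#' scored as a validation set. All randomization flows from `seed`.
#'
#' @param cases Case table (>= 15 rows).
#' @param seed Integer seed.
#' @param learners Character vector among `"lasso"`, `"mlp"`.
#' @param drop_theoretical Passed to [standardize_cases()].
#' @return An object of class `quench_ml_report`: a data frame with one
#'   row per learner and columns `run_train`, `run_test`, `cv_train`,
#'   `cv_test`, `blind_train`, `blind_test`, `blind_valid`.
#' @export
run_validation_suite <- function(cases, seed = 42,
                                 learners = c("lasso", "mlp"),
                                 drop_theoretical = FALSE) {
  if (nrow(cases) < 15) stop("need at least 15 cases")
  fm <- standardize_cases(cases, drop_theoretical = drop_theoretical)
  x <- fm$x; y <- fm$y
  n <- nrow(x)
  out <- data.frame(row.names = learners)
  splits <- with_seed(seed, list(
    run_train = sample.int(n, round(2 * n / 3)),
    folds = sample(rep_len(1:5, n)),
    blind = sample.int(n, max(1, round(0.1 * n)))
  ))
  for (lr in learners) {
    tr <- splits$run_train
    fit <- .fit_learner(lr, x[tr, , drop = FALSE], y[tr], seed)
    out[lr, "run_train"] <- r_squared(y[tr], predict(fit, x[tr, , drop = FALSE]))
    out[lr, "run_test"] <- r_squared(y[-tr], predict(fit, x[-tr, , drop = FALSE]))

    cv_tr <- cv_te <- numeric(5)
    for (k in 1:5) {
      te <- which(splits$folds == k)
      fit <- .fit_learner(lr, x[-te, , drop = FALSE], y[-te], seed + k)
      cv_tr[k] <- r_squared(y[-te], predict(fit, x[-te, , drop = FALSE]))
      cv_te[k] <- r_squared(y[te], predict(fit, x[te, , drop = FALSE]))
    }
    out[lr, "cv_train"] <- mean(cv_tr)
    out[lr, "cv_test"] <- mean(cv_te)

    hold <- splits$blind
    rest <- setdiff(seq_len(n), hold)
    tr2 <- with_seed(seed + 99, sample(rest, round(2 * length(rest) / 3)))
    te2 <- setdiff(rest, tr2)
    fit <- .fit_learner(lr, x[tr2, , drop = FALSE], y[tr2], seed)
    out[lr, "blind_train"] <- r_squared(y[tr2], predict(fit, x[tr2, , drop = FALSE]))
    out[lr, "blind_test"] <- r_squared(y[te2], predict(fit, x[te2, , drop = FALSE]))
    out[lr, "blind_valid"] <- r_squared(y[hold], predict(fit, x[hold, , drop = FALSE]))
  }
  structure(out, class = c("quench_ml_report", "data.frame"))
}

#' @export
print.quench_ml_report <- function(x, digits = 5, ...) {
  cat("Validation R^2 (rows: learners; designs: split / 5-fold CV / 10% blind)\n")
  print.data.frame(round(as.data.frame(x), digits))
  invisible(x)
}
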