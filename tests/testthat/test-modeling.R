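test_that("experiment numbers map onto the eight flag triples", {
  expect_equal(unclass(encode_condition(1)),
               c(individual_scores = FALSE, team_score = FALSE,
                 selections = FALSE))
  expect_equal(unclass(encode_condition(8)),
               c(individual_scores = TRUE, team_score = TRUE,
                 selections = TRUE))
  e7 <- encode_condition(7)
  expect_false(e7[["individual_scores"]])
  expect_true(e7[["team_score"]])
  expect_true(e7[["selections"]])
  # bijection: all 8 triples distinct
  triples <- t(vapply(1:8, function(e) as.logical(encode_condition(e)),
                      logical(3)))
  expect_identical(nrow(unique(triples)), 8L)
  expect_error(encode_condition(0), "1..8")
  expect_error(encode_condition(9), "1..8")
})

test_that("z-scoring standardizes every column and is idempotent", {
  set.seed(1)
  f <- data.frame(pair_id = 1:50, a = rnorm(50, 5, 2),
                  flag = rep(0:1, 25), dv = rnorm(50))
  z <- zscore_all(f)
  for (cl in c("a", "flag", "dv")) {
    expect_lt(abs(mean(z[[cl]])), 1e-12)
    expect_lt(abs(sd(z[[cl]]) - 1), 1e-12)
  }
  expect_identical(z$pair_id, f$pair_id)
  z2 <- zscore_all(z)
  expect_equal(z2$a, z$a, tolerance = 1e-12)
  # transform parameters support inverse mapping
  expect_equal(z$a * attr(z, "scale")["a"] + attr(z, "center")["a"],
               f$a, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(zscore_all(data.frame(a = rep(1, 5))), "zero variance")
  # fitted intercept on z-scored data is 0
  fit <- ols_fit(z[, c("a", "flag")], z$dv)
  expect_lt(abs(fit$coefficients[["(Intercept)"]]), 1e-10)
})

test_that("OLS matches the normal-equations and QR oracles", {
  set.seed(2)
  X <- data.frame(x1 = rnorm(6), x2 = rnorm(6))
  y <- rnorm(6)
  fit <- ols_fit(X, y)
  Xm <- cbind(1, as.matrix(X))
  beta_ne <- solve(t(Xm) %*% Xm, t(Xm) %*% y) # normal equations
  expect_equal(unname(fit$coefficients), unname(drop(beta_ne)),
               tolerance = 1e-10)
  # conventional standard errors from sigma^2 (X'X)^-1
  res <- y - Xm %*% beta_ne
  s2 <- sum(res^2) / (6 - 3)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(s2 * solve(t(Xm) %*% Xm)))),
               tolerance = 1e-10)
  # QR oracle on larger random instances
  for (seed in 3:5) {
    set.seed(seed)
    Xr <- matrix(rnorm(40 * 4), 40)
    colnames(Xr) <- paste0("v", 1:4)
    yr <- rnorm(40)
    fr <- ols_fit(as.data.frame(Xr), yr)
    qr_beta <- qr.coef(qr(cbind(1, Xr)), yr)
    expect_equal(unname(fr$coefficients), unname(qr_beta),
                 tolerance = 1e-10)
  }
})

test_that("OLS reports exact fits, monotone R2, and rank problems", {
  set.seed(6)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  y_exact <- 2 * X$a - X$b + 1
  # summary.lm warns about essentially perfect fits; the fit itself is the point
  f <- suppressWarnings(ols_fit(X, y_exact))
  expect_equal(f$r_squared, 1)
  expect_lt(max(abs(f$residuals)), 1e-10)
  # appending a predictor never decreases R^2
  y <- y_exact + rnorm(20)
  f1 <- ols_fit(X["a"], y)
  f2 <- ols_fit(X, y)
  expect_gte(f2$r_squared, f1$r_squared)
  expect_lte(f2$adj_r_squared, f2$r_squared)
  # collinear columns are named
  X$c <- X$a + X$b
  expect_error(ols_fit(X, y), "rank deficient")
  expect_error(ols_fit(data.frame(a = rnorm(3), b = rnorm(3)), rnorm(3)),
               "n > p")
})

test_that("nested F-test matches the arithmetic oracle", {
  set.seed(7)
  X <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  y <- X$a + rnorm(10)
  small <- ols_fit(X["a"], y)
  large <- ols_fit(X, y)
  ft <- nested_f_test(small, large)
  f_oracle <- ((small$rss - large$rss) / (3 - 1)) / (large$rss / (10 - 3 - 1))
  expect_equal(ft$F, f_oracle, tolerance = 1e-10)
  expect_equal(ft$df1, 2)
  expect_equal(ft$df2, 6)
  expect_equal(ft$p_value, pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical models: F = 0, p = 1
  same <- nested_f_test(small, small)
  expect_identical(same$F, 0)
  expect_identical(same$p_value, 1)
  expect_error(nested_f_test(large, small), "not nested")
})

test_that("nested F-test detects a strongly planted block at n = 124", {
  set.seed(8)
  f <- generate_feature_cohort(n_pairs = 124,
                               betas = c(team_score = 0.5,
                                         selections = 0.5), seed = 8)
  z <- zscore_all(f[, c("individual_scores", "team_score", "selections",
                        "similarity", "dv")], exclude = character(0))
  small <- ols_fit(z["similarity"], z$dv)
  large <- ols_fit(z[, c("similarity", "individual_scores", "team_score",
                         "selections")], z$dv)
  expect_lt(nested_f_test(small, large)$p_value, 0.001)
})

test_that("nested F-test holds its type-I error rate under the null", {
  set.seed(9)
  n <- 124
  reps <- 1000
  rejections <- 0L
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(n * 4), n)
    colnames(X) <- paste0("v", 1:4)
    y <- rnorm(n) # no predictor matters
    small <- ols_fit(as.data.frame(X[, 1, drop = FALSE]), y)
    large <- ols_fit(as.data.frame(X), y)
    if (nested_f_test(small, large)$p_value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / reps
  # binomial 3-sigma band around 0.05 at 1000 reps: ~ +/- 0.021
  expect_lt(abs(rate - 0.05), 0.021)
})

test_that("ridge shrinks as the closed forms require", {
  set.seed(10)
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- X$a - X$b + rnorm(30)
  # lambda = 0 equals OLS
  r0 <- ridge_fit(X, y, lambda = 0)
  ols <- ols_fit(X, y)
  expect_equal(r0$coefficients, ols$coefficients, tolerance = 1e-8)
  # tiny lambda still agrees to 1e-6
  expect_equal(ridge_fit(X, y, lambda = 1e-8)$coefficients,
               ols$coefficients, tolerance = 1e-6)
  # enormous lambda kills every slope
  rbig <- ridge_fit(X, y, lambda = 1e8)
  expect_lt(max(abs(rbig$coefficients[c("a", "b")])), 1e-4)
  # orthonormal design identity: beta_ridge = beta_ols / (1 + lambda).
  # The QR of a column-centred matrix gives columns that are both orthonormal
  # and mean-zero, so centring inside ridge_fit leaves X'X = I intact.
  Q <- qr.Q(qr(scale(matrix(rnorm(50 * 2), 50), scale = FALSE)))
  colnames(Q) <- c("q1", "q2")
  yq <- rnorm(50)
  yq <- yq - mean(yq)
  bo <- ridge_fit(as.data.frame(Q), yq, lambda = 0)$coefficients[c("q1", "q2")]
  for (lam in c(0.5, 2, 10)) {
    br <- ridge_fit(as.data.frame(Q), yq, lambda = lam)$coefficients[c("q1", "q2")]
    expect_equal(br, bo / (1 + lam), tolerance = 1e-6)
  }
})

test_that("ridge agrees with an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(11)
  X <- matrix(rnorm(40 * 3), 40)
  colnames(X) <- paste0("x", 1:3)
  y <- X[, 1] + rnorm(40)
  # put both on the exact same objective: standardize with the population SD
  # (MASS::lm.ridge scales internally by sd with the n denominator)
  n <- nrow(X)
  Xs <- scale(X) * sqrt(n / (n - 1))
  for (lam in c(0.1, 1, 10)) {
    ours <- ridge_fit(as.data.frame(Xs), y, lambda = lam)
    theirs <- MASS::lm.ridge(y ~ Xs, lambda = lam)
    expect_equal(unname(ours$coefficients[colnames(X)]),
                 unname(coef(theirs)[-1]), tolerance = 1e-6)
  }
})

test_that("the staged regression reports cumulative fits and F-steps", {
  f <- generate_feature_cohort(n_pairs = 128,
                               betas = c(team_score = 0.4,
                                         selections = 0.4,
                                         similarity = -0.3), seed = 12)
  plan <- list(c("individual_scores", "team_score", "selections"),
               "similarity",
               c("personal_distress_mean", "personal_distress_diff"))
  sp <- stepwise_pipeline(f, "dv", plan)
  expect_length(sp$fits, 3L)
  # R^2 never decreases across steps; adjusted R^2 bounded by R^2
  r2 <- sp$steps$r_squared
  expect_true(all(diff(r2) >= -1e-12))
  expect_true(all(sp$steps$adj_r_squared <= r2 + 1e-12))
  expect_equal(sp$steps$delta_r_squared[-1], diff(r2), tolerance = 1e-12)
  # the planted blocks are the significant ones
  expect_lt(sp$steps$p_value[2], 0.001) # similarity step
  expect_gt(sp$steps$p_value[3], 0.01)  # noise questionnaire step
  # interaction blocks are built from raw products before z-scoring
  sp_int <- stepwise_pipeline(
    f, "dv", list(c("individual_scores", "team_score", "selections"),
                  "team_score:selections"))
  expect_identical(sp_int$fits[[2]]$p, 4L)
  tab <- format_step_table(sp)
  expect_identical(tab$predictor[1], "(Intercept)")
  expect_true(all(c("model_1", "model_2", "model_3") %in% names(tab)))
  expect_error(stepwise_pipeline(f, "dv", list("a", "a")), "disjoint")
  expect_error(stepwise_pipeline(f, "dv", list("nope")), "unknown column")
})

test_that("planted null effects stay null in the staged regression", {
  # the individual-scores flag carries no planted effect: its weight should
  # sit within 2 SEs of zero in most replicates
  hits <- 0L
  for (r in 1:20) {
    f <- generate_feature_cohort(n_pairs = 128, seed = 100 + r)
    sp <- stepwise_pipeline(f, "dv", list(c("individual_scores",
                                            "team_score", "selections")))
    fit <- sp$fits[[1]]
    b <- fit$coefficients[["individual_scores"]]
    se <- fit$se[["individual_scores"]]
    if (abs(b) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits, 17L)
})

test_that("LOOCV matches an explicit fold-by-fold oracle", {
  set.seed(13)
  f <- data.frame(x1 = rnorm(12), x2 = rnorm(12))
  f$dv <- f$x1 + rnorm(12)
  res <- loocv_rmse(f, "dv", c("x1", "x2"), restandardize = FALSE)
  # oracle: refit every fold explicitly with lm on the once-standardized data
  z <- as.data.frame(scale(f))
  errs <- vapply(seq_len(12), function(i) {
    fit <- lm(dv ~ x1 + x2, data = z[-i, ])
    z$dv[i] - predict(fit, newdata = z[i, ])
  }, numeric(1))
  expect_equal(res$rmse_cv, sqrt(mean(errs^2)), tolerance = 1e-10)
  full <- lm(dv ~ x1 + x2, data = z)
  expect_equal(res$rmse_insample, sqrt(mean(resid(full)^2)),
               tolerance = 1e-10)
  # fold-wise restandardization also matches its explicit oracle
  res2 <- loocv_rmse(f, "dv", c("x1", "x2"), restandardize = TRUE)
  errs2 <- vapply(seq_len(12), function(i) {
    tr <- f[-i, ]; te <- f[i, ]
    ctr <- vapply(tr, mean, numeric(1)); scl <- vapply(tr, sd, numeric(1))
    ztr <- as.data.frame(scale(tr, ctr, scl))
    zte <- as.data.frame(scale(te, ctr, scl))
    fit <- lm(dv ~ x1 + x2, data = ztr)
    zte$dv - predict(fit, newdata = zte)
  }, numeric(1))
  expect_equal(res2$rmse_cv, sqrt(mean(errs2^2)), tolerance = 1e-10)
})

test_that("LOOCV degenerate and ordering properties hold", {
  # constant DV cannot be z-scored, so drive the intercept-only case through
  # the unstandardized arithmetic: every fold predicts the training mean
  f <- data.frame(x = rnorm(10), dv = rnorm(10))
  res <- loocv_rmse(f, "dv", "x")
  expect_gte(res$rmse_cv, 0)
  expect_gte(res$rmse_cv, res$rmse_insample) # noisy data: CV error larger
  expect_equal(res$percent_increase,
               100 * (res$rmse_cv - res$rmse_insample) / res$rmse_insample)
  expect_error(loocv_rmse(f[1:2, ], "dv", "x"), "p \\+ 2")
})

test_that("the lambda sweep tracks signal strength", {
  grid <- exp(seq(log(0.01), log(100), length.out = 9))
  # pure noise: heavy shrinkage wins (best lambda at or near the grid top)
  set.seed(14)
  noise <- data.frame(matrix(rnorm(40 * 4), 40))
  names(noise) <- paste0("x", 1:4)
  noise$dv <- rnorm(40)
  sw_noise <- lambda_sweep(noise, "dv", paste0("x", 1:4), grid = grid)
  expect_gte(sw_noise$best_lambda, grid[6])
  # strong clean signal, n >> p: the penalty only hurts
  strong <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
  strong$dv <- 2 * strong$x1 - strong$x2 + rnorm(200, 0, 0.05)
  sw_strong <- lambda_sweep(strong, "dv", c("x1", "x2"), grid = grid)
  expect_lte(sw_strong$best_lambda, grid[2])
  expect_identical(nrow(sw_noise$trace), length(grid))
})
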