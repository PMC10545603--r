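condition_flag_table <- function() {
  m <- rbind(
    c(0, 0, 0), # 1: no information
    c(1, 0, 0), # 2: individual scores
    c(0, 1, 0), # 3: team score
    c(0, 0, 1), # 4: selections
    c(1, 1, 0), # 5: team score + individual scores
    c(1, 0, 1), # 6: selections + individual scores
    c(0, 1, 1), # 7: selections + team score
    c(1, 1, 1)  # 8: all information
  )
  colnames(m) <- c("individual_scores", "team_score", "selections")
  m
}

#' Encode an experiment number as condition flags
#'
#' Bijection between the eight experiments and the three binary information
#' predictors: experiment 1 shows nothing, 2 the individual scores, 3 the team
#' score, 4 the partner's selections, 5 team + individual scores, 6 selections
#' + individual scores, 7 selections + team score, 8 everything.
#'
#' @param experiment_number integer in 1..8.
#' @return a [condition_flags()] object.
#' @examples
#' encode_condition(7) # team score and selections, no individual scores
#' @export
encode_condition <- function(experiment_number) {
  if (length(experiment_number) != 1L || is.na(experiment_number) ||
      experiment_number %% 1 != 0 ||
      experiment_number < 1 || experiment_number > 8)
    stop("experiment_number must be an integer in 1..8", call. = FALSE)
  f <- condition_flag_table()[experiment_number, ]
  condition_flags(f["individual_scores"], f["team_score"], f["selections"])
}

#' Z-score every column of a feature table
#'
#' Standardizes all numeric columns (dependent variables and binary flags
#' included) to mean 0, SD 1, keeping the centring/scaling parameters as
#' attributes for inverse mapping. Identifier columns can be excluded.
#'
#' @param features data.frame of numeric columns.
#' @param exclude column names to pass through untouched (default:
#'   `"pair_id"`, `"experiment"` if present).
#' @return data.frame with attributes `"center"` and `"scale"`.
#' @examples
#' z <- zscore_all(data.frame(a = 1:5, b = c(2, 4, 6, 8, 10)))
#' colMeans(z)
#' @export
zscore_all <- function(features, exclude = c("pair_id", "experiment")) {
  cols <- setdiff(names(features), exclude)
  ctr <- scl <- stats::setNames(numeric(length(cols)), cols)
  out <- features
  for (cl in cols) {
    x <- features[[cl]]
    if (!is.numeric(x) && !is.logical(x))
      stop("column '", cl, "' is not numeric", call. = FALSE)
    x <- as.numeric(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("column '", cl, "' has zero variance and cannot be z-scored",
           call. = FALSE)
    ctr[cl] <- mean(x)
    scl[cl] <- s
    out[[cl]] <- (x - ctr[cl]) / s
  }
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

model_fit <- function(coefficients, se, rss, tss, n, p, residuals, fitted,
                      lambda = NULL) {
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  structure(list(coefficients = coefficients, se = se, rss = rss, tss = tss,
                 r_squared = r2, adj_r_squared = adj, n = n, p = p,
                 df_residual = n - p - 1, residuals = residuals,
                 fitted = fitted, lambda = lambda,
                 predictors = setdiff(names(coefficients), "(Intercept)")),
            class = "jointmot_fit")
}

#' @export
print.jointmot_fit <- function(x, ...) {
  kind <- if (is.null(x$lambda)) "OLS" else
    sprintf("ridge (lambda = %g)", x$lambda)
  cat(kind, "fit:", x$n, "rows,", x$p, "predictors\n")
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(round(tab, 4))
  cat(sprintf("R^2 = %.4f, adjusted R^2 = %.4f\n",
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Ordinary least squares on standardized data
#'
#' Fits `y ~ X` by least squares (via [stats::lm()]) and packages the
#' standardized coefficients, conventional (homoskedastic) standard errors,
#' residual sum of squares and (adjusted) R-squared. With z-scored inputs the
#' intercept is 0 and the slopes are standardized regression weights.
#'
#' @param X data.frame or matrix of predictors (no intercept column).
#' @param y numeric response.
#' @return a `"jointmot_fit"`.
#' @examples
#' X <- data.frame(a = rnorm(20), b = rnorm(20))
#' f <- ols_fit(X, X$a + rnorm(20, 0, 0.1))
#' f$r_squared
#' @export
ols_fit <- function(X, y) {
  X <- as.data.frame(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p + 1)
    stop("need n > p + 1 observations to fit and estimate error variance",
         call. = FALSE)
  dat <- cbind(X, .y = y)
  fit <- stats::lm(.y ~ ., data = dat)
  if (fit$rank < p + 1) {
    dropped <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  model_fit(coefficients = stats::coef(fit),
            se = sm$coefficients[, "Std. Error"],
            rss = sum(stats::resid(fit)^2),
            tss = sum((y - mean(y))^2),
            n = n, p = p,
            residuals = stats::resid(fit), fitted = stats::fitted(fit))
}

#' Ridge regression with an unpenalized intercept
#'
#' Minimizes `RSS + lambda * ||beta||^2` over the slope coefficients (the
#' intercept is not penalized; on z-scored data it is 0). Solved in closed
#' form on centred data: `beta = (X'X + lambda I)^{-1} X'y`.
#'
#' @param X data.frame or matrix of predictors.
#' @param y numeric response.
#' @param lambda non-negative L2 penalty.
#' @return a `"jointmot_fit"` (standard errors are `NA`: penalized estimates
#'   have no conventional OLS standard error).
#' @examples
#' X <- data.frame(a = rnorm(20), b = rnorm(20))
#' ridge_fit(X, rnorm(20), lambda = 1)$coefficients
#' @export
ridge_fit <- function(X, y, lambda = 0) {
  stopifnot(lambda >= 0)
  X <- as.matrix(as.data.frame(X))
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  beta <- solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, yc))
  beta <- drop(beta)
  intercept <- ym - sum(xm * beta)
  fitted <- drop(X %*% beta) + intercept
  res <- y - fitted
  coefs <- c("(Intercept)" = intercept, stats::setNames(beta, colnames(X)))
  model_fit(coefficients = coefs,
            se = stats::setNames(rep(NA_real_, p + 1), names(coefs)),
            rss = sum(res^2), tss = sum((y - ym)^2), n = n, p = p,
            residuals = res, fitted = fitted, lambda = lambda)
}

#' Nested-model F-test
#'
#' Tests whether the larger model explains significantly more variance than a
#' model built from a subset of its predictors, on the same rows:
#' `F = ((RSS_s - RSS_l) / (p_l - p_s)) / (RSS_l / (n - p_l - 1))`.
#'
#' @param fit_small,fit_large `"jointmot_fit"` objects; the small model's
#'   predictors must be a subset of the large model's and both must be fit to
#'   the same `n` rows.
#' @return list with `F`, `df1`, `df2`, `p_value`. Identical models give
#'   `F = 0`, `p = 1`.
#' @examples
#' X <- data.frame(a = rnorm(30), b = rnorm(30))
#' y <- X$a + rnorm(30)
#' nested_f_test(ols_fit(X["a"], y), ols_fit(X, y))
#' @export
nested_f_test <- function(fit_small, fit_large) {
  if (fit_small$n != fit_large$n)
    stop("models were fit to different numbers of rows", call. = FALSE)
  if (!all(fit_small$predictors %in% fit_large$predictors))
    stop("models are not nested: the smaller model's predictors are not a ",
         "subset of the larger model's", call. = FALSE)
  df1 <- fit_large$p - fit_small$p
  df2 <- fit_large$n - fit_large$p - 1
  if (df1 == 0L)
    return(list(F = 0, df1 = 0L, df2 = df2, p_value = 1))
  f <- max(0, (fit_small$rss - fit_large$rss) / df1) /
    (fit_large$rss / df2)
  list(F = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Staged (step-wise block) regression
#'
#' Fits a sequence of cumulative standardized OLS models, adding one predictor
#' block at a time in a fixed order (experimental factors first, then the
#' behavioral and questionnaire predictors, overlap last), and reports each
#' step's gain in explained variance together with the nested F-test against
#' the previous step.
#'
#' Interaction terms may be requested as `"a:b"` block entries; products are
#' formed from the *raw* columns before the table is z-scored, since products
#' of z-scores are a different design.
#'
#' @param features data.frame with one row per retained pair (raw scale; the
#'   function z-scores everything it uses, DV included).
#' @param dv_name name of the dependent-variable column.
#' @param plan ordered list of character vectors, one predictor block per
#'   step.
#' @return an object of class `"jointmot_steps"`: list with `fits` (one
#'   `"jointmot_fit"` per step), `steps` (data.frame: step, predictors added,
#'   R2, delta R2, F, df1, df2, p) and `dv_name`.
#' @examples
#' f <- generate_feature_cohort(seed = 1)
#' sp <- stepwise_pipeline(f, "dv",
#'   plan = list(c("individual_scores", "team_score", "selections"),
#'               "similarity"))
#' sp$steps
#' @export
stepwise_pipeline <- function(features, dv_name, plan) {
  stopifnot(is.list(plan), length(plan) >= 1, dv_name %in% names(features))
  vars <- unlist(plan)
  if (anyDuplicated(vars))
    stop("plan blocks must be disjoint", call. = FALSE)
  # materialize interaction columns from raw 0/1 flags before standardization
  work <- features
  for (v in vars) {
    if (grepl(":", v, fixed = TRUE)) {
      parts <- strsplit(v, ":", fixed = TRUE)[[1]]
      if (!all(parts %in% names(work)))
        stop("interaction '", v, "' references unknown columns",
             call. = FALSE)
      work[[v]] <- Reduce(`*`, lapply(parts, function(p)
        as.numeric(work[[p]])))
    } else if (!v %in% names(work)) {
      stop("plan references unknown column '", v, "'", call. = FALSE)
    }
  }
  z <- zscore_all(work[, c(vars, dv_name)], exclude = character(0))
  y <- z[[dv_name]]
  fits <- vector("list", length(plan))
  rows <- vector("list", length(plan))
  current <- character(0)
  prev <- NULL
  for (s in seq_along(plan)) {
    current <- c(current, plan[[s]])
    fits[[s]] <- ols_fit(z[, current, drop = FALSE], y)
    if (is.null(prev)) {
      ft <- list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                 p_value = NA_real_)
      dr2 <- fits[[s]]$r_squared
    } else {
      ft <- nested_f_test(prev, fits[[s]])
      dr2 <- fits[[s]]$r_squared - prev$r_squared
    }
    rows[[s]] <- data.frame(step = s,
                            added = paste(plan[[s]], collapse = " + "),
                            r_squared = fits[[s]]$r_squared,
                            adj_r_squared = fits[[s]]$adj_r_squared,
                            delta_r_squared = dr2,
                            F = ft$F, df1 = ft$df1, df2 = ft$df2,
                            p_value = ft$p_value)
    prev <- fits[[s]]
  }
  structure(list(fits = fits, steps = do.call(rbind, rows),
                 dv_name = dv_name),
            class = "jointmot_steps")
}

#' @export
print.jointmot_steps <- function(x, ...) {
  cat("staged regression of", x$dv_name, "\n")
  print(x$steps, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tabulate a staged regression like a results table
#'
#' One row per predictor (plus intercept, R2, adjusted R2 and n), one column
#' per step, each cell the standardized weight with its standard error in
#' brackets and significance stars (.05/.01/.001).
#'
#' @param steps a `"jointmot_steps"`.
#' @return data.frame of formatted strings.
#' @export
format_step_table <- function(steps) {
  fits <- steps$fits
  all_pred <- unique(unlist(lapply(fits, function(f) f$predictors)))
  rows <- c("(Intercept)", all_pred)
  out <- data.frame(predictor = rows, stringsAsFactors = FALSE)
  for (s in seq_along(fits)) {
    f <- fits[[s]]
    col <- character(length(rows))
    for (i in seq_along(rows)) {
      nm <- rows[i]
      if (!nm %in% names(f$coefficients)) { col[i] <- ""; next }
      b <- f$coefficients[[nm]]
      se <- f$se[[nm]]
      tval <- b / se
      pv <- 2 * stats::pt(abs(tval), f$df_residual, lower.tail = FALSE)
      stars <- if (nm == "(Intercept)") "" else
        if (pv < 0.001) "***" else if (pv < 0.01) "**" else
          if (pv < 0.05) "*" else ""
      col[i] <- sprintf("%.2f%s (%.2f)", b, stars, se)
    }
    out[[paste0("model_", s)]] <- col
  }
  extra <- data.frame(
    predictor = c("R^2", "Adj. R^2", "Pairs"),
    stringsAsFactors = FALSE)
  for (s in seq_along(fits)) {
    extra[[paste0("model_", s)]] <- c(sprintf("%.2f", fits[[s]]$r_squared),
                                      sprintf("%.2f", fits[[s]]$adj_r_squared),
                                      as.character(fits[[s]]$n))
  }
  rbind(out, extra)
}

#' Leave-one-out cross-validated RMSE
#'
#' Refits the model with each pair left out and predicts the held-out pair's
#' dependent variable. By default the z-scoring parameters are re-estimated
#' inside every fold from the training rows only (no information leakage); a
#' simpler variant that standardizes once on the full data is selectable.
#' Because the data are z-scored, standard deviations are the unit of the
#' reported errors.
#'
#' @param features raw-scale feature data.frame (one row per pair).
#' @param dv_name dependent-variable column name.
#' @param predictors character vector of predictor columns (interactions as
#'   `"a:b"` are formed from raw columns, as in [stepwise_pipeline()]).
#' @param method `"ols"` or `"ridge"`.
#' @param lambda ridge penalty (ignored for `"ols"`).
#' @param restandardize if `TRUE` (default), fold-wise re-standardization.
#' @return list with `rmse_cv`, `rmse_insample`, `percent_increase`, and the
#'   per-fold held-out `errors`.
#' @examples
#' f <- generate_feature_cohort(n_pairs = 40, seed = 1)
#' loocv_rmse(f, "dv", c("team_score", "selections"))$rmse_cv
#' @export
loocv_rmse <- function(features, dv_name, predictors,
                       method = c("ols", "ridge"), lambda = 0,
                       restandardize = TRUE) {
  method <- match.arg(method)
  work <- features
  for (v in predictors) {
    if (grepl(":", v, fixed = TRUE) && !v %in% names(work)) {
      parts <- strsplit(v, ":", fixed = TRUE)[[1]]
      work[[v]] <- Reduce(`*`, lapply(parts, function(p)
        as.numeric(work[[p]])))
    }
  }
  cols <- c(predictors, dv_name)
  work <- work[, cols, drop = FALSE]
  n <- nrow(work)
  if (n < length(predictors) + 2)
    stop("need at least p + 2 rows for leave-one-out refits", call. = FALSE)
  fit_fun <- function(X, y) {
    if (method == "ols") ols_fit(X, y) else ridge_fit(X, y, lambda)
  }
  standardize <- function(df, ref) {
    ctr <- attr(ref, "center"); scl <- attr(ref, "scale")
    for (cl in names(ctr)) df[[cl]] <- (df[[cl]] - ctr[cl]) / scl[cl]
    df
  }
  errors <- numeric(n)
  if (!restandardize) {
    z_all <- zscore_all(work, exclude = character(0))
  }
  for (i in seq_len(n)) {
    if (restandardize) {
      z_tr <- zscore_all(work[-i, , drop = FALSE], exclude = character(0))
      z_te <- standardize(work[i, , drop = FALSE], z_tr)
    } else {
      z_tr <- z_all[-i, , drop = FALSE]
      z_te <- z_all[i, , drop = FALSE]
    }
    f <- fit_fun(z_tr[, predictors, drop = FALSE], z_tr[[dv_name]])
    pred <- f$coefficients[["(Intercept)"]] +
      sum(f$coefficients[predictors] *
            as.numeric(z_te[1, predictors]))
    errors[i] <- z_te[[dv_name]] - pred
  }
  z_full <- zscore_all(work, exclude = character(0))
  f_full <- fit_fun(z_full[, predictors, drop = FALSE], z_full[[dv_name]])
  rmse_in <- sqrt(mean(f_full$residuals^2))
  rmse_cv <- sqrt(mean(errors^2))
  list(rmse_cv = rmse_cv, rmse_insample = rmse_in,
       percent_increase = 100 * (rmse_cv - rmse_in) / rmse_in,
       errors = errors)
}

#' Ridge lambda sweep
#'
#' Evaluates a selection criterion over a grid of L2 penalties (default
#' log-spaced over `[0.01, 100]`) and returns the best lambda with the full
#' trace. The default criterion is leave-one-out RMSE; in-sample RMSE is
#' selectable.
#'
#' @param features,dv_name,predictors as in [loocv_rmse()].
#' @param grid numeric vector of candidate lambdas.
#' @param criterion `"loocv"` (default) or `"insample"`.
#' @param restandardize passed to [loocv_rmse()].
#' @return list with `best_lambda` and `trace` (data.frame of lambda,
#'   criterion value).
#' @examples
#' f <- generate_feature_cohort(n_pairs = 40, seed = 1)
#' sw <- lambda_sweep(f, "dv", c("team_score", "selections"),
#'                    grid = c(0.01, 1, 100))
#' sw$best_lambda
#' @export
lambda_sweep <- function(features, dv_name, predictors,
                         grid = exp(seq(log(0.01), log(100),
                                        length.out = 41)),
                         criterion = c("loocv", "insample"),
                         restandardize = TRUE) {
  criterion <- match.arg(criterion)
  stopifnot(length(grid) >= 1, all(grid >= 0))
  vals <- vapply(grid, function(lam) {
    cv <- loocv_rmse(features, dv_name, predictors, method = "ridge",
                     lambda = lam, restandardize = restandardize)
    if (criterion == "loocv") cv$rmse_cv else cv$rmse_insample
  }, numeric(1))
  list(best_lambda = grid[which.min(vals)],
       trace = data.frame(lambda = grid, criterion = vals))
}
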