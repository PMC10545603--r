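#' Interpersonal Reactivity Index scoring key
#'
#' The IRI has 28 items in four 7-item factors: fantasy, perspective taking,
#' empathic concern and personal distress. The default key is the standard
#' published assignment with reverse-scored items 3, 4, 7, 12, 13, 14, 15, 18
#' and 19; studies using a different form can supply their own key.
#'
#' @param factor_map named list mapping each factor to its 7 item indices.
#' @param reverse integer vector of reverse-scored item indices.
#' @return an object of class `"iri_key"`.
#' @examples
#' iri_key()$reverse
#' @export
iri_key <- function(factor_map = list(
                      fantasy = c(1, 5, 7, 12, 16, 23, 26),
                      perspective_taking = c(3, 8, 11, 15, 21, 25, 28),
                      empathic_concern = c(2, 4, 9, 14, 18, 20, 22),
                      personal_distress = c(6, 10, 13, 17, 19, 24, 27)),
                    reverse = c(3, 4, 7, 12, 13, 14, 15, 18, 19)) {
  items <- sort(unlist(factor_map, use.names = FALSE))
  if (!identical(as.integer(items), 1:28))
    stop("factor_map must partition items 1..28", call. = FALSE)
  if (any(lengths(factor_map) != 7L))
    stop("each factor must have exactly 7 items", call. = FALSE)
  if (!all(reverse %in% 1:28))
    stop("reverse key must be a subset of item ids 1..28", call. = FALSE)
  structure(list(factor_map = lapply(factor_map, as.integer),
                 reverse = as.integer(reverse)),
            class = "iri_key")
}

#' Score an IRI response
#'
#' Reverse-keyed item ratings are inverted (`6 - rating` on the 1-5 scale,
#' `4 - rating` on the classical 0-4 scale) and each factor's 7 item values
#' are summed. On the 1-5 scale every factor score lies in 7..35.
#'
#' @param items numeric vector of 28 ratings.
#' @param key an [iri_key()].
#' @param scale `"1-5"` (default, matching a five-point Likert form) or
#'   `"0-4"` (the classical form).
#' @return named numeric vector of the four factor scores.
#' @examples
#' score_iri(rep(3, 28)) # all factors 21
#' @export
score_iri <- function(items, key = iri_key(), scale = c("1-5", "0-4")) {
  scale <- match.arg(scale)
  if (length(items) != 28L)
    stop("expected 28 item ratings, got ", length(items), call. = FALSE)
  if (anyNA(items)) {
    cond <- simpleError("incomplete questionnaire response: missing items")
    class(cond) <- c("jointmot_incomplete", class(cond))
    stop(cond)
  }
  rng <- if (scale == "1-5") c(1, 5) else c(0, 4)
  if (any(items < rng[1] | items > rng[2]))
    stop("item ratings outside the ", scale, " scale", call. = FALSE)
  flip <- if (scale == "1-5") 6 else 4
  items <- as.numeric(items)
  items[key$reverse] <- flip - items[key$reverse]
  vapply(key$factor_map, function(idx) sum(items[idx]), numeric(1))
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`.
#' Sample variances use the `n - 1` denominator by default; the `n`
#' denominator is available because alpha shifts slightly between the two
#' conventions.
#'
#' @param item_matrix numeric matrix, respondents in rows, items in columns.
#' @param var_denominator `"n-1"` (default) or `"n"`.
#' @return numeric alpha (can be negative; 1 for perfectly consistent items).
#' @examples
#' m <- matrix(rnorm(50), 10, 5)
#' cronbach_alpha(m + rnorm(10)) # shared row effect raises alpha
#' @export
cronbach_alpha <- function(item_matrix, var_denominator = c("n-1", "n")) {
  var_denominator <- match.arg(var_denominator)
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix)
  n <- nrow(item_matrix)
  if (k < 2L || n < 2L)
    stop("cronbach_alpha needs at least 2 items and 2 respondents",
         call. = FALSE)
  if (anyNA(item_matrix))
    stop("item matrix contains missing values", call. = FALSE)
  v <- function(x) {
    s2 <- stats::var(x)
    if (var_denominator == "n") s2 * (n - 1) / n else s2
  }
  total_var <- v(rowSums(item_matrix))
  if (total_var <= 0)
    stop("alpha undefined: total score variance is zero", call. = FALSE)
  item_vars <- apply(item_matrix, 2, v)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}

#' Pair-level questionnaire predictors
#'
#' Because the regression predicts benefits for pairs while questionnaires
#' are individual, each factor contributes two predictors: the pair mean and
#' the absolute difference of the two members' scores. Both are
#' order-invariant.
#'
#' @param score_a,score_b the two members' factor scores.
#' @return named numeric vector `c(mean = , abs_difference = )`; `NA` with an
#'   `"incomplete"` attribute if either score is missing.
#' @examples
#' pair_predictors(25, 15) # mean 20, difference 10
#' @export
pair_predictors <- function(score_a, score_b) {
  if (is.na(score_a) || is.na(score_b)) {
    out <- c(mean = NA_real_, abs_difference = NA_real_)
    attr(out, "incomplete") <- TRUE
    return(out)
  }
  c(mean = (score_a + score_b) / 2, abs_difference = abs(score_a - score_b))
}

#' Drop pairs with incomplete questionnaires
#'
#' Pairs whose questionnaire data are incomplete are removed from *all* model
#' fits up front, so every nested model comparison runs on the same sample.
#'
#' @param features a feature data.frame (rows = pairs) in which questionnaire
#'   predictor columns may contain `NA`.
#' @param columns which columns to scan for missingness; defaults to every
#'   column whose name contains an IRI factor name or "familiarity".
#' @return list with `retained` (the filtered data.frame) and `n_excluded`.
#' @examples
#' f <- data.frame(pair_id = 1:3, personal_distress_mean = c(1, NA, 2))
#' exclude_incomplete_pairs(f)$n_excluded
#' @export
exclude_incomplete_pairs <- function(features, columns = NULL) {
  if (is.null(columns)) {
    pat <- "fantasy|perspective_taking|empathic_concern|personal_distress|familiarity"
    columns <- grep(pat, names(features), value = TRUE)
  }
  if (length(columns) == 0L)
    return(list(retained = features, n_excluded = 0L))
  bad <- apply(is.na(features[, columns, drop = FALSE]), 1, any)
  list(retained = features[!bad, , drop = FALSE], n_excluded = sum(bad))
}
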