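#' Cross-validated LASSO screen of candidate photon parameters
#'
#' Screens the candidate features for discrimination between two groups
#' (typically control vs stressed) with an L1-penalised regression over a
#' log-spaced penalty grid and k-fold cross-validation (binomial deviance
#' for the default logistic model). Features are standardised to unit
#' variance internally; coefficients are reported on both the original and
#' the standardised scale. Selections are returned at the
#' deviance-minimising penalty `lambda_min` and at the parsimonious
#' `lambda_1se` (largest penalty within one standard error of the
#' minimum).
#'
#' @param features data.frame or matrix of numeric candidate features
#'   (rows = samples). Non-numeric columns named `sample_id`/`group` are
#'   dropped automatically so the output of [assemble_features()] can be
#'   passed directly.
#' @param response binary group indicator (two-level factor, logical, or
#'   0/1), length `nrow(features)`; for `family = "gaussian"` any numeric
#'   response.
#' @param k_folds number of CV folds (default 10), assigned stratified by
#'   class under `seed`.
#' @param seed integer seed controlling fold assignment.
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @return Object of class `screening_result`: list with `lambda_path`,
#'   `cv_deviance` (`cvm`, `cvsd`), `lambda_min`, `lambda_1se`,
#'   `coefficients` (at both penalties, raw and standardised scale), and
#'   `selected_features` (at both penalties).
#' @export
lasso_screen <- function(features, response, k_folds = 10, seed = 1L,
                         family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  x <- as.data.frame(features)
  x <- x[, setdiff(names(x), c("sample_id", "group")), drop = FALSE]
  if (!all(vapply(x, is.numeric, logical(1))))
    stop("all feature columns must be numeric", call. = FALSE)
  x <- as.matrix(x)
  if (anyNA(x)) stop("features contain missing values", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(x) < 1) stop("no non-constant features left", call. = FALSE)
  # glmnet needs >= 2 columns; a zero pad column never enters the model
  if (ncol(x) == 1L) x <- cbind(x, .pad = 0)
  if (family == "binomial") {
    y <- if (is.factor(response)) response else factor(response)
    if (nlevels(y) != 2)
      stop("response must have exactly two classes", call. = FALSE)
    if (min(table(y)) < 2)
      stop("need >= 2 samples per class", call. = FALSE)
    if (min(table(y)) < 3)
      warning("fewer than 3 samples in a class: cross-validation folds may ",
              "leave a single-class training set")
  } else y <- as.numeric(response)
  # stratified, seed-controlled fold assignment
  foldid <- integer(length(response))
  with_seed(seed, {
    if (family == "binomial") {
      for (lev in levels(y)) {
        idx <- which(y == lev)
        foldid[idx] <- sample(rep_len(seq_len(k_folds), length(idx)))
      }
    } else foldid[] <- sample(rep_len(seq_len(k_folds), length(y)))
  })
  cv <- glmnet::cv.glmnet(x, y, family = family, foldid = foldid,
                          type.measure = "deviance", standardize = TRUE,
                          nlambda = 100)
  coef_at <- function(s) {
    b <- as.matrix(stats::coef(cv, s = s))
    keep <- setdiff(rownames(b), c("(Intercept)", ".pad"))
    data.frame(feature = keep, coefficient = unname(b[keep, 1]),
               coefficient_std = unname(b[keep, 1]) * unname(sds[keep]),
               stringsAsFactors = FALSE)
  }
  c_min <- coef_at(cv$lambda.min)
  c_1se <- coef_at(cv$lambda.1se)
  structure(list(
    lambda_path = cv$lambda,
    cv_deviance = data.frame(lambda = cv$lambda, cvm = cv$cvm,
                             cvsd = cv$cvsd),
    lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
    coefficients = list(lambda_min = c_min, lambda_1se = c_1se),
    selected_features = list(
      lambda_min = c_min$feature[c_min$coefficient != 0],
      lambda_1se = c_1se$feature[c_1se$coefficient != 0]),
    family = family, k_folds = k_folds, glmnet_cv = cv),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("LASSO screen (%s, %d-fold CV)\n", x$family, x$k_folds))
  cat(sprintf("  lambda_min = %.6g -> {%s}\n", x$lambda_min,
              paste(x$selected_features$lambda_min, collapse = ", ")))
  cat(sprintf("  lambda_1se = %.6g -> {%s}\n", x$lambda_1se,
              paste(x$selected_features$lambda_1se, collapse = ", ")))
  invisible(x)
}

#' PCA stratification of samples on selected features
#'
#' Centred, unit-variance principal component analysis of the selected
#' feature subset, used to visualise how well the photon parameters
#' stratify treatment groups.
#'
#' @param features data.frame with feature columns and optionally
#'   `sample_id`/`group` columns (carried through to the scores).
#' @param select character vector of feature columns to use (default: all
#'   numeric columns).
#' @return list with `scores` (data.frame of component scores plus any
#'   `sample_id`/`group`), `explained_variance` (fractions, non-increasing)
#'   and the `prcomp` object.
#' @export
pca_stratify <- function(features, select = NULL) {
  df <- as.data.frame(features)
  meta <- df[intersect(names(df), c("sample_id", "group"))]
  x <- df[, setdiff(names(df), c("sample_id", "group")), drop = FALSE]
  if (!is.null(select)) x <- x[, select, drop = FALSE]
  if (ncol(x) < 2) stop("need >= 2 features", call. = FALSE)
  if (nrow(x) < 3) stop("need >= 3 samples", call. = FALSE)
  if (any(vapply(x, stats::sd, numeric(1)) == 0))
    stop("zero-variance feature in the selected set", call. = FALSE)
  pc <- stats::prcomp(as.matrix(x), center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- cbind(meta, as.data.frame(pc$x))
  list(scores = scores, explained_variance = ev, prcomp = pc)
}

#' Two-group comparison of a parameter
#'
#' Two-tailed unpaired Student's t-test with pooled variance (the
#' conventional equal-variance form); Welch's correction is available with
#' `var_equal = FALSE`. When both groups are constant with equal means the
#' convention `t = 0, P = 1` is returned (and `|t| = Inf, P = 0` for
#' unequal constant means).
#'
#' @param x,y numeric vectors, >= 2 values each.
#' @param var_equal pooled variance if `TRUE` (default).
#' @return list with `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
group_ttest <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 values per group", call. = FALSE)
  res <- tryCatch(
    stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided"),
    error = function(e) {
      if (!grepl("constant", conditionMessage(e))) stop(e)
      NULL
    })
  if (is.null(res)) {   # zero pooled variance
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0,
                mean_x = mean(x), mean_y = mean(y)))
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean_x = mean(x), mean_y = mean(y))
}
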