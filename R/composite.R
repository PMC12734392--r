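# Composite metabolism/mitochondria score (MM_score): an elastic-net
# penalized logistic model on pathway activities, a coefficient-weighted
# activity sum, and ROC/Youden optimal-cutpoint stratification.

#' Fit a penalized logistic model on pathway activities
#'
#' Minimizes the elastic-net penalized negative log-likelihood
#' \deqn{-\frac1n \sum_i [y_i \eta_i - \log(1 + e^{\eta_i})] +
#'   \lambda\left(\alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2\right)}
#' on standardized features (population 1/n variance) with an unpenalized
#' intercept, via glmnet's cyclic coordinate descent; coefficients are
#' returned on the original activity scale.  Constant features are dropped
#' with a warning before fitting.
#'
#' @param x samples x features numeric matrix (an activity matrix
#'   transposed), with column names.
#' @param y binary outcome (0/1, logical, or two-level factor), >= 2
#'   samples per class.
#' @param alpha elastic-net mixing parameter in \[0, 1\] (1 = lasso).
#' @param lambda penalty strength (>= 0).
#' @param standardize standardize features before penalization (default
#'   TRUE).
#' @return object of class `composite_model`: `features`, `beta`,
#'   `intercept`, `alpha`, `lambda`, `center`, `scale`, `orientation`
#'   (per-selection sign aligning higher scores with outcome 1 on the
#'   training data) and `tuning` (NULL unless produced by
#'   [tune_penalized_logistic()]).
#' @export
fit_penalized_logistic <- function(x, y, alpha, lambda, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as_binary_outcome(y)
  if (length(y) != nrow(x)) stop("`y` must have one value per row of `x`")
  if (min(table(y)) < 2L) stop("need >= 2 samples per outcome class")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]")
  if (!is.numeric(lambda) || lambda < 0) stop("`lambda` must be >= 0")
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2L, ctr)^2))  # population variance
  const <- scl == 0
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    ctr <- ctr[!const]; scl <- scl[!const]
  }
  if (ncol(x) == 0L) stop("no non-constant features left")
  # glmnet requires >= 2 columns; pad single-feature designs with a zero
  # column whose coefficient is structurally 0
  xfit <- if (ncol(x) == 1L) cbind(x, `..pad` = 0) else x
  fit <- glmnet::glmnet(xfit, y, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = standardize,
                        thresh = 1e-12, maxit = 1e6)
  beta <- as.numeric(fit$beta[, 1L])
  names(beta) <- rownames(fit$beta)
  beta <- beta[colnames(x)]
  model <- structure(list(features = colnames(x), beta = beta,
                          intercept = as.numeric(fit$a0[1L]),
                          alpha = alpha, lambda = lambda,
                          center = ctr, scale = scl,
                          standardize = standardize,
                          orientation = c(all = 1, negative = 1, positive = 1),
                          tuning = NULL),
                     class = "composite_model")
  model$orientation <- orient_model(model, x, y)
  model
}

as_binary_outcome <- function(y) {
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("outcome must be binary")
    y <- as.integer(y) - 1L
  }
  if (is.logical(y)) y <- as.integer(y)
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  if (length(unique(y)) < 2L) stop("outcome is constant")
  y
}

orient_model <- function(model, x, y) {
  vapply(c(all = "all", negative = "negative", positive = "positive"),
         function(sel) {
           s <- raw_mm_score(x, model, sel)
           if (stats::sd(s) == 0) return(1)
           d <- mean(s[y == 1]) - mean(s[y == 0])
           if (d < 0) -1 else 1
         }, numeric(1))
}

#' @export
print.composite_model <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("composite_model: %d features (%d nonzero), alpha=%g, lambda=%.4g\n",
              length(x$features), nz, x$alpha, x$lambda))
  cat(sprintf("  intercept %.4g; negative coefficients: %d\n",
              x$intercept, sum(x$beta < 0)))
  invisible(x)
}

#' Tune elastic-net hyperparameters on a stratified split
#'
#' The tuning workflow mirrors standard clinical machine-learning practice:
#' samples are split into training and validation sets (default 0.7/0.3,
#' stratified by outcome class); (alpha, lambda) pairs are evaluated by
#' stratified k-fold cross-validation *within the training set*; the
#' selected pair maximizes the cross-validated metric with two parsimony
#' safeguards, and the final model is refit on the full data at the
#' selected pair.  The held-out validation AUC of the training-only model
#' is recorded for reporting.
#'
#' Selection rule: candidates whose CV metric is statistically
#' indistinguishable from the best (within one standard error across
#' folds) are treated as ties, broken toward larger lambda (the sparser
#' model) and then the earlier alpha in the grid.  For the AUC metric
#' there is additionally a chance gate: unless the best CV AUC exceeds the
#' chance level 0.5 by three standard errors (a multiplicity-minded margin
#' for a several-hundred-point grid), the intercept-only null model is
#' selected -- pure-noise panels should not yield a spuriously "predictive"
#' signature.  Fully deterministic given `seed`.
#'
#' @param x samples x features matrix.
#' @param y binary outcome.
#' @param alpha_grid alphas to scan (default `seq(0.1, 1, by = 0.1)`).
#' @param lambda_path explicit lambda values; default NULL lets glmnet
#'   compute its own decreasing path per alpha on the training set.
#' @param split training fraction (default 0.7).
#' @param folds cross-validation folds within the training set (default 5).
#' @param seed integer seed controlling split and fold assignment.
#' @param metric `"auc"` (default, maximized) or `"deviance"` (mean
#'   per-observation binomial deviance, minimized).
#' @return a `composite_model` whose `tuning` field records the CV grid,
#'   the selected pair, the held-out validation AUC, the split indices and
#'   the seed.
#' @export
tune_penalized_logistic <- function(x, y, alpha_grid = seq(0.1, 1, by = 0.1),
                                    lambda_path = NULL, split = 0.7,
                                    folds = 5L, seed = 1L,
                                    metric = c("auc", "deviance")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  y <- as_binary_outcome(y)
  if (any(alpha_grid < 0 | alpha_grid > 1)) stop("alpha_grid must lie in [0, 1]")
  idx <- stratified_split(y, split, seed)
  if (length(unique(y[idx$train])) < 2L || length(unique(y[idx$test])) < 2L)
    stop("stratified split produced a single-class partition; ",
         "need >= 2 samples per class in each part")
  xt <- x[idx$train, , drop = FALSE]; yt <- y[idx$train]
  xv <- x[idx$test, , drop = FALSE];  yv <- y[idx$test]
  fold <- assign_folds(yt, folds, seed)
  eval_col <- function(e, yy) {
    if (metric == "auc") {
      if (stats::sd(e) == 0) 0.5 else auc_rank(e, yy)
    } else {
      mean(-2 * (yy * e - log1p(exp(e))))
    }
  }
  grid <- list()
  for (a in alpha_grid) {
    master <- if (is.null(lambda_path))
      glmnet::glmnet(xt, yt, family = "binomial", alpha = a)
    else
      glmnet::glmnet(xt, yt, family = "binomial", alpha = a,
                     lambda = sort(lambda_path, decreasing = TRUE))
    lam <- master$lambda
    per_fold <- sapply(seq_len(folds), function(f) {
      fit <- glmnet::glmnet(xt[fold != f, , drop = FALSE], yt[fold != f],
                            family = "binomial", alpha = a, lambda = lam)
      eta <- stats::predict(fit, newx = xt[fold == f, , drop = FALSE])
      apply(eta, 2L, eval_col, yy = yt[fold == f])
    })
    per_fold <- matrix(per_fold, nrow = length(lam))
    grid[[length(grid) + 1L]] <-
      data.frame(alpha = a, lambda = lam,
                 cv_metric = rowMeans(per_fold),
                 cv_se = apply(per_fold, 1L, stats::sd) / sqrt(folds),
                 nonzero = master$df)
  }
  grid <- do.call(rbind, grid)
  sgn <- if (metric == "auc") 1 else -1
  score <- sgn * grid$cv_metric
  best <- which(score == max(score))
  best <- best[order(-grid$lambda[best])][1L]
  null_gated <- metric == "auc" &&
    grid$cv_metric[best] - 3 * grid$cv_se[best] <= 0.5
  if (null_gated) {
    sel <- which(grid$nonzero == 0L)
    sel <- if (length(sel)) sel[1L] else which.max(grid$lambda)
  } else {
    sel <- NA_integer_
  }
  if (!null_gated) {
    ok <- score >= score[best] - grid$cv_se[best]
    sel <- which(ok)[order(-grid$lambda[ok])][1L]
  }
  # held-out validation AUC of the training-only model at the selected pair
  val_fit <- glmnet::glmnet(xt, yt, family = "binomial",
                            alpha = grid$alpha[sel],
                            lambda = grid$lambda[sel], thresh = 1e-12)
  eta_v <- drop(stats::predict(val_fit, newx = xv))
  val_auc <- if (stats::sd(eta_v) == 0) 0.5 else auc_rank(eta_v, yv)
  # refit on the full data; when gated, inflate lambda so the final model
  # is exactly the intercept-only null model on the full data too
  refit_lambda <- if (null_gated) 1e3 * max(grid$lambda) else grid$lambda[sel]
  model <- fit_penalized_logistic(x, y, alpha = grid$alpha[sel],
                                  lambda = refit_lambda)
  model$lambda <- grid$lambda[sel]
  model$tuning <- list(grid = grid, metric = metric, folds = folds,
                       best_alpha = grid$alpha[sel],
                       best_lambda = grid$lambda[sel],
                       best_cv_metric = grid$cv_metric[sel],
                       validation_auc = val_auc,
                       null_gated = null_gated,
                       split = split, seed = seed,
                       train_index = idx$train, test_index = idx$test)
  model
}

assign_folds <- function(y, folds, seed) {
  set.seed(as.integer(seed) + 1L)
  fold <- integer(length(y))
  for (cls in sort(unique(y))) {
    i <- which(y == cls)
    fold[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  fold
}

stratified_split <- function(y, split, seed) {
  set.seed(as.integer(seed))
  train <- integer(0)
  for (cls in sort(unique(y))) {
    i <- which(y == cls)
    k <- max(1L, round(length(i) * split))
    if (k >= length(i)) k <- length(i) - 1L  # keep both parts non-empty
    train <- c(train, sample(i, k))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

raw_mm_score <- function(x, model, selection) {
  b <- model$beta
  keep <- switch(selection,
                 all = rep(TRUE, length(b)),
                 negative = b < 0,
                 positive = b > 0)
  drop(x[, model$features, drop = FALSE][, keep, drop = FALSE] %*% b[keep])
}

#' Composite MM_score from a fitted model
#'
#' Per sample, the coefficient-weighted sum of selected pathway activities:
#' `MM = sum over selected features of beta_f * activity_f` (intercept
#' excluded).  `selection = "negative"` keeps only features with negative
#' coefficients -- the convention used when summarizing metabolism/
#' mitochondria repression signatures -- while the default `"all"` uses
#' every coefficient.  The model's training-data orientation for the chosen
#' selection is applied so that higher scores associate with outcome 1; the
#' applied sign is recorded in the `orientation` attribute.
#'
#' @param activity sets x samples activity matrix (features in rows), or a
#'   samples x features matrix (auto-detected from the model's feature
#'   names).
#' @param model a `composite_model`.
#' @param selection `"all"`, `"negative"` or `"positive"`.
#' @return named numeric score vector (one per sample) with attributes
#'   `orientation` (+1/-1 as applied) and `selection`.
#' @export
mm_score <- function(activity, model,
                     selection = c("all", "negative", "positive")) {
  selection <- match.arg(selection)
  stopifnot(inherits(model, "composite_model"))
  activity <- as.matrix(activity)
  if (all(model$features %in% rownames(activity))) {
    x <- t(activity[model$features, , drop = FALSE])
  } else if (all(model$features %in% colnames(activity))) {
    x <- activity[, model$features, drop = FALSE]
  } else {
    miss <- setdiff(model$features,
                    union(rownames(activity), colnames(activity)))
    stop("activity matrix is missing model feature(s): ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  s <- raw_mm_score(x, model, selection)
  orient <- unname(model$orientation[selection])
  if (is.na(orient)) orient <- 1
  structure(s * orient, orientation = orient, selection = selection,
            names = rownames(x))
}

#' Rank-sum (Mann-Whitney) AUC with tie correction
#'
#' Ties contribute 1/2 via midranks.  Returns 0.5 for constant scores.
#'
#' @param score numeric scores.
#' @param y binary outcome.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(score, y) {
  y <- as_binary_outcome(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(score)  # midranks: ties count 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC AUC and Youden-optimal cutpoint
#'
#' AUC by the rank-sum formula with tie correction; candidate thresholds
#' are the observed score values.  The direction calling positives is
#' `">="` when AUC >= 0.5 and `"<="` otherwise.  The threshold maximizing
#' Youden's J = sensitivity + specificity - 1 is returned; ties on J are
#' broken toward higher specificity, then toward the smaller threshold.
#' Constant scores give AUC 0.5 and a degenerate flag (no threshold).
#'
#' @param score numeric score vector.
#' @param outcome binary outcome (1 = case).
#' @return object of class `cutpoint_result`: list with `threshold`, `auc`,
#'   `sensitivity`, `specificity`, `youden`, `direction`, `degenerate`, and
#'   `stratum` (per-sample `"low"`/`"high"` labels; `"high"` = called
#'   positive).
#' @export
roc_cutpoint <- function(score, outcome) {
  y <- as_binary_outcome(outcome)
  if (length(score) != length(y)) stop("score/outcome length mismatch")
  auc <- auc_rank(score, y)
  if (length(unique(score)) == 1L) {
    return(structure(list(threshold = NA_real_, auc = 0.5,
                          sensitivity = NA_real_, specificity = NA_real_,
                          youden = NA_real_, direction = ">=",
                          degenerate = TRUE,
                          stratum = rep(NA_character_, length(y))),
                     class = "cutpoint_result"))
  }
  direction <- if (auc >= 0.5) ">=" else "<="
  thr <- sort(unique(score))
  ge <- direction == ">="
  sens <- vapply(thr, function(t)
    mean(if (ge) score[y == 1] >= t else score[y == 1] <= t), numeric(1))
  spec <- vapply(thr, function(t)
    mean(if (ge) score[y == 0] < t else score[y == 0] > t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[order(-spec[best], thr[best])][1L]
  called <- if (ge) score >= thr[best] else score <= thr[best]
  structure(list(threshold = thr[best], auc = auc,
                 sensitivity = sens[best], specificity = spec[best],
                 youden = j[best], direction = direction, degenerate = FALSE,
                 stratum = ifelse(called, "high", "low")),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  if (x$degenerate) {
    cat("cutpoint_result: degenerate (constant scores), AUC 0.5\n")
  } else {
    cat(sprintf(
      "cutpoint_result: AUC %.3f, threshold %.4g (%s), sens %.3f, spec %.3f, J %.3f\n",
      x$auc, x$threshold, x$direction, x$sensitivity, x$specificity, x$youden))
  }
  invisible(x)
}

#' Serialize / restore a composite model as JSON
#'
#' @param model a `composite_model`.
#' @param path output JSON path.
#' @return `path` invisibly for write; a `composite_model` for read.
#' @export
write_composite_model <- function(model, path) {
  stopifnot(inherits(model, "composite_model"))
  obj <- model[c("features", "beta", "intercept", "alpha", "lambda",
                 "center", "scale", "standardize")]
  obj$orientation <- as.list(model$orientation)
  if (!is.null(model$tuning))
    obj$tuning <- model$tuning[c("metric", "best_alpha", "best_lambda",
                                 "best_metric", "split", "seed")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_composite_model
#' @export
read_composite_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = obj$features,
                 beta = stats::setNames(as.numeric(obj$beta), obj$features),
                 intercept = obj$intercept, alpha = obj$alpha,
                 lambda = obj$lambda,
                 center = stats::setNames(as.numeric(obj$center), obj$features),
                 scale = stats::setNames(as.numeric(obj$scale), obj$features),
                 standardize = isTRUE(obj$standardize),
                 orientation = unlist(obj$orientation),
                 tuning = obj$tuning),
            class = "composite_model")
}
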