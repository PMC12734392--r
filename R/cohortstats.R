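# Cohort-level statistics used to characterize score strata: contingency
# chi-square (Yates-corrected for 2x2), two-sample t (raw values or printed
# summary statistics), one-way ANOVA, Kaplan-Meier/log-rank, and
# multivariable logistic regression with separation flagging.

new_test_result <- function(statistic, df, p, method, degenerate = FALSE) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p.value = unname(p), method = method,
                 degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.5g, df %s, p = %.7g%s\n", x$method,
              x$statistic, paste(x$df, collapse = ","), x$p.value,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson \eqn{X^2 = \sum (O-E)^2/E} with expected counts from the
#' row/column margins, df = (r-1)(c-1).  `correction = "auto"` applies the
#' Yates continuity correction (|O-E| reduced by 0.5, floored at 0) exactly
#' when the table is 2x2, and no correction otherwise -- the convention that
#' reproduces published clinical-table p-values for both 2x2 and wider
#' tables.
#'
#' @param table r x c matrix of non-negative integer counts (r, c >= 2).
#' @param correction `"auto"`, `"yates"` (2x2 only) or `"none"`.
#' @return a `test_result`.
#' @export
chi_square_test <- function(table, correction = c("auto", "yates", "none")) {
  correction <- match.arg(correction)
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != floor(tab)))
    stop("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2x2")
  if (sum(tab) == 0) stop("empty table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin: a row or column sums to zero")
  is2x2 <- nrow(tab) == 2L && ncol(tab) == 2L
  if (correction == "yates" && !is2x2)
    stop("Yates correction is defined for 2x2 tables only")
  correct <- switch(correction, auto = is2x2, yates = TRUE, none = FALSE)
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_test_result(res$statistic, res$parameter, res$p.value,
                  if (correct) "chi-square (Yates)" else "chi-square")
}

#' Two-sample t-test from values or summary statistics
#'
#' Accepts raw vectors or `list(mean=, sd=, n=)` summaries (so p-values
#' printed alongside mean (sd) table rows can be checked).  `"student"`
#' pools the variances (df = n1+n2-2); `"welch"` uses the Satterthwaite
#' approximation.  Two-sided.
#'
#' @param a,b numeric vectors, or lists with `mean`, `sd`, `n`.
#' @param variant `"student"` or `"welch"`.
#' @return a `test_result`.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  summ <- function(x) {
    if (is.list(x)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(x)))
      list(m = x$mean, s = x$sd, n = x$n)
    } else {
      list(m = mean(x), s = stats::sd(x), n = length(x))
    }
  }
  sa <- summ(a); sb <- summ(b)
  if (sa$n < 2L || sb$n < 2L) stop("each group needs n >= 2")
  if (sa$s < 0 || sb$s < 0) stop("negative standard deviation")
  if (sa$s == 0 && sb$s == 0 && sa$m == sb$m)
    return(new_test_result(NA_real_, NA_real_, NA_real_,
                           paste0(variant, " t-test"), degenerate = TRUE))
  if (variant == "student") {
    df <- sa$n + sb$n - 2
    sp2 <- ((sa$n - 1) * sa$s^2 + (sb$n - 1) * sb$s^2) / df
    tstat <- (sa$m - sb$m) / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  } else {
    va <- sa$s^2 / sa$n; vb <- sb$s^2 / sb$n
    tstat <- (sa$m - sb$m) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  }
  new_test_result(tstat, df, 2 * stats::pt(-abs(tstat), df),
                  paste0(variant, " t-test"))
}

#' One-way (Fisher) ANOVA
#'
#' F = MS_between / MS_within with the classical equal-variance
#' decomposition.  Zero within-group mean square is flagged degenerate.
#'
#' @param values numeric response vector.
#' @param groups factor/vector of group labels (>= 2 levels).
#' @return a `test_result` with `df = c(df_between, df_within)`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (length(values) != length(groups)) stop("length mismatch")
  k <- nlevels(groups); n <- length(values)
  if (n - k < 1L) stop("no residual degrees of freedom")
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tabulate(groups)
  ss_b <- sum(ns * (means - gm)^2)
  ss_w <- sum((values - means[as.integer(groups)])^2)
  df_b <- k - 1; df_w <- n - k
  if (ss_w == 0)
    return(new_test_result(NA_real_, c(df_b, df_w), NA_real_,
                           "one-way ANOVA", degenerate = TRUE))
  f <- (ss_b / df_b) / (ss_w / df_w)
  new_test_result(f, c(df_b, df_w), stats::pf(f, df_b, df_w, lower.tail = FALSE),
                  "one-way ANOVA")
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Right-censored Kaplan-Meier estimation and the standard log-rank test
#' (at each distinct event time, observed minus expected events in group 1
#' with hypergeometric variance; \eqn{X^2 = (\sum O - \sum E)^2/\sum V} on
#' 1 df), computed with the survival package.
#'
#' @param time positive follow-up times (e.g. months).
#' @param event event indicator: 1 = event (death), 0 = right-censored.
#' @param group two-level group labels (e.g. score strata).
#' @return list with `curves` (data.frame: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`) and `test` (a `test_result`).
#' @export
km_logrank <- function(time, event, group) {
  if (any(time <= 0)) stop("survival times must be positive")
  event <- as.integer(event)
  if (!all(event %in% 0:1)) stop("event must be 0 (censored) or 1 (event)")
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (any(tabulate(group) == 0L)) stop("a group has no samples")
  if (sum(event) == 0L) stop("log-rank requires at least one event")
  sf <- survival::survfit(survival::Surv(time, event) ~ group)
  strata_id <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^group=", "", strata_id),
                       time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, surv = sf$surv,
                       stringsAsFactors = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  list(curves = curves, test = new_test_result(sd$chisq, 1L, p, "log-rank"))
}

#' Multivariable logistic regression with separation flagging
#'
#' Binomial-logit GLM fit by iteratively reweighted least squares
#' (convergence on relative deviance change < 1e-10, max 100 iterations).
#' Reports odds ratios `exp(beta)` with Wald 95% CIs
#' `exp(beta +/- 1.96 SE)`.  Terms showing the signature of complete or
#' quasi-complete separation (|beta| > 15 or SE > 1e3 on the standardized
#' predictor scale) are flagged rather than fatal, since a cell with zero
#' events (e.g. a center contributing no mutated tumors) is a common and
#' interpretable pattern in clinical tables.
#'
#' @param design samples x terms numeric matrix (indicators already
#'   expanded), with column names; an intercept is added internally.
#' @param outcome binary outcome.
#' @return object of class `logistic_model`: data.frame `terms` with
#'   columns `term`, `estimate`, `se`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p`, `separation`, plus fields `converged`, `deviance`,
#'   `null_deviance`.
#' @export
logistic_model <- function(design, outcome) {
  y <- as_binary_outcome(outcome)
  X <- as.matrix(design)
  if (nrow(X) == 0L && length(y) > 0L && is.null(dim(design)))
    stop("`design` must be a samples x terms matrix")
  if (nrow(X) != length(y)) stop("design/outcome dimension mismatch")
  if (is.null(colnames(X)) && ncol(X) > 0L)
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("design matrix must be finite")
  if (length(y) <= ncol(X) + 1L) stop("need more samples than model terms")
  Xi <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xi)
  if (qrX$rank < ncol(Xi)) {
    aliased <- colnames(Xi)[qrX$pivot[(qrX$rank + 1L):ncol(Xi)]]
    stop("collinear design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  w <- NULL
  fit <- withCallingHandlers(
    stats::glm.fit(Xi, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100L)),
    warning = function(cnd) {
      w <<- conditionMessage(cnd)
      invokeRestart("muffleWarning")
    })
  sep_warned <- !is.null(w) && grepl("fitted probabilities", w)
  beta <- fit$coefficients
  # Wald SEs from the final IRLS weights
  Wh <- sqrt(fit$weights)
  XtWX <- crossprod(Xi * Wh)
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) {
    MASSlike <- solve(XtWX + diag(1e-10, ncol(XtWX)))
    MASSlike
  })
  se <- sqrt(diag(cov))
  sds <- c(1, apply(X, 2L, stats::sd))
  sds[sds == 0] <- 1
  sep_flag <- abs(beta * sds) > 15 | se * sds > 1e3
  if (!fit$converged && !sep_warned && !any(sep_flag))
    stop("IRLS failed to converge without evidence of separation")
  if (any(sep_flag) || sep_warned)
    warning("possible separation; flagged term(s): ",
            paste(names(beta)[sep_flag], collapse = ", "))
  z <- beta / se
  terms <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), odds_ratio = exp(unname(beta)),
                      ci_low = exp(unname(beta - 1.96 * se)),
                      ci_high = exp(unname(beta + 1.96 * se)),
                      p = 2 * stats::pnorm(-abs(z)),
                      separation = unname(sep_flag),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(terms = terms, converged = fit$converged || sep_warned,
                 deviance = fit$deviance, null_deviance = fit$null.deviance),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model (binomial logit)\n")
  df <- x$terms
  df$odds_ratio <- signif(df$odds_ratio, 3)
  df$ci_low <- signif(df$ci_low, 3); df$ci_high <- signif(df$ci_high, 3)
  df$p <- signif(df$p, 3)
  print(df[, c("term", "odds_ratio", "ci_low", "ci_high", "p", "separation")],
        row.names = FALSE)
  invisible(x)
}

#' Published cohort contingency tables
#'
#' Loads the clinical contingency tables of the GSE44076 (tissue cohort)
#' and GSE103479 (score-stratified colorectal cohort) studies shipped with
#' the package as plain counts, for re-computation of the published
#' chi-square p-values.
#'
#' @return named list of count matrices (rows = variable levels, columns =
#'   cohort groups).
#' @export
cohort_contingency_tables <- function() {
  path <- system.file("extdata", "cohort_contingency.csv",
                      package = "pathactivity", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$variable), function(d) {
    tab <- stats::xtabs(count ~ level + group, data = d)
    tab <- tab[unique(d$level), unique(d$group), drop = FALSE]
    m <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    m
  })
  out[unique(df$variable)]
}
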