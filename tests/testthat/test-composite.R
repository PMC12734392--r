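test_that("huge penalty collapses to the null model with logit intercept", {
  set.seed(41)
  x <- matrix(rnorm(16 * 6), 16, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(1, 0, 0, 0), 4)  # mean 0.25
  m <- suppressWarnings(fit_penalized_logistic(x, y, alpha = 0.5, lambda = 1e6))
  expect_equal(unname(m$beta), rep(0, 6))
  expect_equal(m$intercept, qlogis(0.25), tolerance = 1e-6)
})

test_that("unpenalized fit matches the Newton-Raphson oracle", {
  set.seed(42)
  n <- 200
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "f1"))
  y <- rbinom(n, 1, plogis(0.3 + 1.2 * x[, 1]))
  m <- fit_penalized_logistic(x, y, alpha = 1, lambda = 0)
  ref <- oracle_logistic_nr(x, y)
  expect_equal(m$intercept, unname(ref[1]), tolerance = 1e-4)
  expect_equal(unname(m$beta), unname(ref[2]), tolerance = 1e-4)
})

test_that("ridge solution minimizes the stated objective (BFGS oracle)", {
  set.seed(43)
  n <- 150; lambda <- 0.08
  x <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rbinom(n, 1, plogis(0.8 * x[, 1] - 0.5 * x[, 2]))
  m <- fit_penalized_logistic(x, y, alpha = 0, lambda = lambda)
  # independent minimization of the ridge objective on standardized scale
  ctr <- colMeans(x); scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  obj <- function(par) {
    eta <- par[1] + xs %*% par[2:3]
    -mean(y * eta - log1p(exp(eta))) + lambda / 2 * sum(par[2:3]^2)
  }
  o <- optim(c(0, 0, 0), obj, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 1000))
  beta_std <- m$beta * scl  # back to standardized scale for comparison
  expect_equal(unname(beta_std), o$par[2:3], tolerance = 1e-3)
})

test_that("constant features are dropped with a warning", {
  set.seed(44)
  x <- cbind(f1 = rnorm(20), flat = rep(2, 20))
  y <- rep(0:1, 10)
  expect_warning(m <- fit_penalized_logistic(x, y, 0.5, 0.01), "constant")
  expect_equal(m$features, "f1")
})

test_that("tuning is deterministic and degenerate grids return the null model", {
  co <- simulate_cohort(sim_cohort_config(n_samples = 120, n_features = 10,
                                          seed = 77))
  m1 <- tune_penalized_logistic(co$activity, co$outcome, seed = 3)
  m2 <- tune_penalized_logistic(co$activity, co$outcome, seed = 3)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$tuning$best_lambda, m2$tuning$best_lambda)

  m3 <- suppressWarnings(
    tune_penalized_logistic(co$activity, co$outcome, alpha_grid = 0.5,
                            lambda_path = 1e6, seed = 3))
  expect_equal(unname(m3$beta), rep(0, 10))
  expect_equal(m3$tuning$validation_auc, 0.5)
})

test_that("mm_score is the coefficient-weighted activity sum with selection", {
  feats <- c("A", "B", "C")
  model <- structure(list(features = feats,
                          beta = setNames(c(2, -1, 0), feats),
                          intercept = 5, alpha = 0.5, lambda = 0.1,
                          center = setNames(rep(0, 3), feats),
                          scale = setNames(rep(1, 3), feats),
                          standardize = TRUE,
                          orientation = c(all = 1, negative = 1, positive = 1),
                          tuning = NULL),
                     class = "composite_model")
  act <- matrix(c(0.1, -0.3,   # A
                  0.2, 0.2,    # B
                  9, 9), 3, 2, byrow = TRUE,
                dimnames = list(feats, c("s1", "s2")))
  # single positive feature: plain dot product, intercept excluded
  m1 <- model; m1$beta <- setNames(c(2, 0, 0), feats)
  expect_equal(as.vector(mm_score(act, m1, "all")), c(0.2, -0.6))
  # all-zero coefficients
  m0 <- model; m0$beta <- setNames(rep(0, 3), feats)
  expect_equal(as.vector(mm_score(act, m0, "all")), c(0, 0))
  # selection picks the coefficient sign subsets
  expect_equal(as.vector(mm_score(act, model, "negative")), c(-0.2, -0.2))
  expect_equal(as.vector(mm_score(act, model, "positive")), c(0.2, -0.6))
  expect_equal(as.vector(mm_score(act, model, "all")), c(0, -0.8))
  # missing feature is an error naming it
  expect_error(mm_score(act[1:2, ], model), "missing model feature")
})

test_that("mm_score equals a matrix-product oracle and is linear", {
  set.seed(45)
  feats <- paste0("F", 1:8)
  beta <- setNames(rnorm(8), feats)
  model <- structure(list(features = feats, beta = beta, intercept = 1,
                          alpha = 0.3, lambda = 0.05,
                          center = setNames(rep(0, 8), feats),
                          scale = setNames(rep(1, 8), feats),
                          standardize = TRUE,
                          orientation = c(all = 1, negative = 1, positive = 1),
                          tuning = NULL),
                     class = "composite_model")
  A <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(feats, paste0("s", 1:5)))
  B <- matrix(rnorm(8 * 5), 8, 5, dimnames = dimnames(A))
  expect_equal(as.vector(mm_score(A, model, "all")),
               unname(drop(t(A) %*% beta)))
  expect_equal(mm_score(2 * A + 3 * B, model, "all"),
               2 * mm_score(A, model, "all") + 3 * mm_score(B, model, "all"))
})

test_that("nonzero coefficient count is non-increasing along a lambda path", {
  co <- simulate_cohort(sim_cohort_config(seed = 46))
  lam <- 10^seq(-3, 0, length.out = 12)
  nz <- vapply(lam, function(l) {
    m <- fit_penalized_logistic(co$activity, co$outcome, alpha = 1, lambda = l)
    sum(m$beta != 0)
  }, numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("roc_cutpoint handles separation, degeneracy, and matches brute force", {
  # perfect separation
  cp <- roc_cutpoint(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(cp$auc, 1)
  expect_equal(cp$sensitivity, 1)
  expect_equal(cp$specificity, 1)
  expect_equal(cp$threshold, 0.8)

  # constant scores
  cpd <- roc_cutpoint(rep(2, 6), c(0, 1, 0, 1, 0, 1))
  expect_true(cpd$degenerate)
  expect_equal(cpd$auc, 0.5)

  # random instances: AUC by pair counting, J by exhaustive enumeration
  set.seed(47)
  for (i in 1:25) {
    n <- sample(6:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    cp <- roc_cutpoint(s, y)
    expect_equal(cp$auc, oracle_auc_pairs(s, y), tolerance = 1e-12)
    if (!cp$degenerate)
      expect_equal(cp$youden, oracle_best_youden(s, y, cp$direction),
                   tolerance = 1e-12)
  }
})

test_that("AUC is antisymmetric under score negation for tie-free scores", {
  set.seed(48)
  y <- rbinom(30, 1, 0.5); y[1:2] <- 0:1
  s <- rnorm(30)
  expect_equal(auc_rank(s, y) + auc_rank(-s, y), 1)
})

test_that("composite model JSON round-trips", {
  co <- simulate_cohort(sim_cohort_config(n_samples = 80, n_features = 6,
                                          k = 2, seed = 49))
  m <- fit_penalized_logistic(co$activity, co$outcome, 0.5, 0.02)
  f <- tempfile(fileext = ".json")
  write_composite_model(m, f)
  back <- read_composite_model(f)
  expect_equal(back$beta, m$beta)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$orientation, m$orientation)
  s1 <- mm_score(t(co$activity), m, "all")
  s2 <- mm_score(t(co$activity), back, "all")
  expect_equal(s1, s2)
})
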