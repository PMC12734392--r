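test_that("chi-square reproduces published cohort p-values with auto correction", {
  tabs <- cohort_contingency_tables()
  # Yates-corrected 2x2: metastasis-stage by score stratum
  expect_equal(chi_square_test(tabs$metastasis)$p.value, 0.0058267,
               tolerance = 1e-5)
  # uncorrected df = 2: gender and tumor location across tissue groups
  expect_equal(chi_square_test(tabs$gender)$p.value, 0.04273, tolerance = 1e-4)
  expect_equal(chi_square_test(tabs$location)$p.value, 0.15003, tolerance = 1e-4)
})

test_that("chi-square basics: proportional rows, margins, correction rules", {
  prop <- matrix(c(10, 20, 30, 60), 2, 2, byrow = TRUE)
  r <- chi_square_test(prop, correction = "none")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  # uncorrected statistic dominates the Yates-corrected one on 2x2
  set.seed(51)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    expect_gte(chi_square_test(tab, "none")$statistic,
               chi_square_test(tab, "yates")$statistic)
  }

  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "degenerate margin")
  expect_error(chi_square_test(matrix(1:6, 3, 2), correction = "yates"),
               "2x2")
  expect_error(chi_square_test(matrix(c(1.5, 2, 3, 4), 2, 2)),
               "non-negative integers")
})

test_that("two-sample t works from raw values and printed summaries", {
  r <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  # summary-statistic route equals the closed-form pooled computation
  a <- list(mean = 5, sd = 1, n = 10); b <- list(mean = 6, sd = 1, n = 10)
  r2 <- two_sample_t(a, b, "student")
  sp2 <- (9 * 1 + 9 * 1) / 18
  t_ref <- (5 - 6) / sqrt(sp2 * (1 / 10 + 1 / 10))
  expect_equal(r2$statistic, t_ref)
  expect_equal(r2$df, 18)
  expect_equal(r2$p.value, 2 * pt(-abs(t_ref), 18))

  # raw-value route agrees with stats::t.test
  set.seed(52)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  expect_equal(two_sample_t(x, y, "student")$p.value,
               t.test(x, y, var.equal = TRUE)$p.value)
  expect_equal(two_sample_t(x, y, "welch")$p.value, t.test(x, y)$p.value)

  # degenerate: zero spread, equal means
  expect_true(two_sample_t(c(2, 2, 2), c(2, 2))$degenerate)
})

test_that("welch p is never smaller than student p for equal group sizes", {
  set.seed(53)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    x <- rnorm(n, sd = 0.5); y <- rnorm(n, 1, sd = 2)
    expect_gte(two_sample_t(x, y, "welch")$p.value,
               two_sample_t(x, y, "student")$p.value - 1e-12)
  }
})

test_that("one-way ANOVA matches the sums-of-squares oracle and t^2 identity", {
  # equal group means with spread: F = 0
  v <- c(-1, 1, -2, 2, -3, 3)
  g <- rep(c("a", "b", "c"), each = 2)
  r <- one_way_anova(v, g)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  # two groups: F equals the squared student t
  set.seed(54)
  x <- rnorm(8); y <- rnorm(9, 0.7)
  fa <- one_way_anova(c(x, y), rep(c("x", "y"), c(8, 9)))
  tt <- two_sample_t(x, y, "student")
  expect_equal(fa$statistic, tt$statistic^2, tolerance = 1e-12)
  expect_equal(fa$p.value, tt$p.value, tolerance = 1e-12)

  # random 3-group data against explicit sums of squares
  vals <- rnorm(30); grp <- sample(c("p", "q", "r"), 30, replace = TRUE,
                                   prob = c(.4, .3, .3))
  fa3 <- one_way_anova(vals, grp)
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(z) length(z) * (mean(z) - gm)^2))
  ssw <- sum(unlist(tapply(vals, grp, function(z) (z - mean(z))^2)))
  f_ref <- (ssb / 2) / (ssw / 27)
  expect_equal(fa3$statistic, f_ref, tolerance = 1e-12)

  expect_true(one_way_anova(c(1, 1, 2, 2), c("a", "a", "b", "b"))$degenerate)
})

test_that("log-rank matches the hand-computed hypergeometric oracle", {
  # identical survival in both groups: X^2 = 0
  r0 <- km_logrank(c(1, 2, 3, 1, 2, 3), c(1, 1, 0, 1, 1, 0),
                   rep(c("a", "b"), each = 3))
  expect_equal(r0$test$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$test$p.value, 1, tolerance = 1e-12)

  # toy: A = {1 event, 2 event}, B = {2 event, 3 censored}
  # t=1: n=4, d=1, E_A=1/2, V=1/4;  t=2: n=3, d=2, E_A=2/3, V=2/9
  # O_A=2, E_A=7/6, V=17/36 -> X^2 = (5/6)^2 / (17/36) = 25/17
  r <- km_logrank(c(1, 2, 2, 3), c(1, 1, 1, 0), c("A", "A", "B", "B"))
  expect_equal(r$test$statistic, 25 / 17, tolerance = 1e-10)
  expect_equal(r$test$p.value, pchisq(25 / 17, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # KM curves are non-increasing and bounded by 1 (survival 1 at t = 0)
  expect_true(all(r$curves$surv <= 1))
  for (g in unique(r$curves$group))
    expect_true(all(diff(r$curves$surv[r$curves$group == g]) <= 0))

  expect_error(km_logrank(c(1, 2), c(0, 0), c("a", "b")), "at least one event")
  expect_error(km_logrank(c(1, 2), c(1, 1), c("a", "a")), "two groups")
  expect_error(km_logrank(c(0, 2), c(1, 1), c("a", "b")), "positive")
})

test_that("logistic model reproduces the 2x2 odds-ratio identity", {
  # counts a=10, b=20 (x=1), c=30, d=40 (x=0); OR = (10*40)/(20*30)
  x <- c(rep(1, 30), rep(0, 70))
  y <- c(rep(1, 10), rep(0, 20), rep(1, 30), rep(0, 40))
  m <- logistic_model(matrix(x, dimnames = list(NULL, "exposed")), y)
  or <- m$terms$odds_ratio[m$terms$term == "exposed"]
  expect_equal(or, (10 * 40) / (20 * 30), tolerance = 1e-6)

  # intercept-only model with balanced outcome
  m0 <- logistic_model(matrix(numeric(0), nrow = 10, ncol = 0),
                       rep(0:1, 5))
  expect_equal(m0$terms$estimate[1], 0, tolerance = 1e-8)
})

test_that("logistic model matches the Newton-Raphson oracle on random designs", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(60:200, 1)
    X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("x1", "x2")))
    y <- rbinom(n, 1, plogis(0.2 + 0.8 * X[, 1] - 0.4 * X[, 2]))
    if (length(unique(y)) < 2) next
    m <- logistic_model(X, y)
    ref <- oracle_logistic_nr(X, y)
    expect_equal(m$terms$estimate, unname(ref), tolerance = 1e-6)
  }
})

test_that("separation is flagged, not fatal; collinearity names the alias", {
  # perfectly separating predictor (the zero-events-in-a-center pattern)
  x <- c(rep(0, 20), rep(1, 20))
  y <- c(rep(0, 20), rep(1, 20))
  expect_warning(m <- logistic_model(matrix(x, dimnames = list(NULL, "sep")),
                                     y),
                 "separation")
  expect_true(m$terms$separation[m$terms$term == "sep"])

  X <- cbind(a = rnorm(30), b = 0)
  X[, "b"] <- 2 * X[, "a"]
  expect_error(logistic_model(X, rbinom(30, 1, 0.5)), "collinear")
})

test_that("Wald intervals bracket the odds ratio as exp(beta +/- 1.96 se)", {
  set.seed(56)
  X <- matrix(rnorm(100), 100, 1, dimnames = list(NULL, "x"))
  y <- rbinom(100, 1, plogis(X[, 1]))
  m <- logistic_model(X, y)
  row <- m$terms[m$terms$term == "x", ]
  expect_equal(row$ci_low, exp(row$estimate - 1.96 * row$se))
  expect_equal(row$ci_high, exp(row$estimate + 1.96 * row$se))
  expect_lt(row$ci_low, row$odds_ratio)
  expect_gt(row$ci_high, row$odds_ratio)
})
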