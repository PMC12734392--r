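# Independent oracle implementations used to validate the package's
# computational routes.  Deliberately written as plain double loops /
# closed forms, sharing no code with the package internals.

# per-gene kernel-CDF statistic by explicit double loop
oracle_kcdf <- function(X, kernel) {
  p <- nrow(X); n <- ncol(X)
  out <- matrix(NA_real_, p, n, dimnames = dimnames(X))
  for (i in seq_len(p)) {
    x <- X[i, ]
    for (j in seq_len(n)) {
      out[i, j] <- switch(kernel,
        gaussian = {
          h <- sd(x) / 4
          if (h == 0) 0.5 else mean(sapply(x, function(xk) pnorm((x[j] - xk) / h)))
        },
        poisson = mean(sapply(x, function(xk) ppois(x[j], xk + 0.5))),
        ecdf = mean(sapply(x, function(xk) xk <= x[j])))
    }
  }
  out
}

# exhaustive random-walk score: recompute every prefix sum from scratch
oracle_walk_es <- function(ordering, r, members, tau, mode) {
  p <- length(r)
  mem_o <- members[ordering]
  r_o <- r[ordering]^tau
  denom_in <- sum(r_o[mem_o])
  m <- sum(members)
  nu <- numeric(p)
  for (l in seq_len(p)) {
    num <- if (denom_in > 0) sum(r_o[seq_len(l)][mem_o[seq_len(l)]]) / denom_in
           else sum(mem_o[seq_len(l)]) / m
    nu[l] <- num - sum(!mem_o[seq_len(l)]) / (p - m)
  }
  if (mode == "maxdiff") max(nu, 0) + min(nu, 0) else nu[which.max(abs(nu))]
}

# straight-line composition: kernel CDF -> ranks -> walk, no shared code
oracle_score_activity <- function(X, sets, kernel, tau = 1, mode = "maxdiff") {
  stat <- oracle_kcdf(X, kernel)
  p <- nrow(X); n <- ncol(X)
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(X)))
  for (j in seq_len(n)) {
    o <- order(stat[, j], decreasing = TRUE)
    rk <- integer(p); rk[o] <- seq_len(p)
    r <- abs(p / 2 - rk)
    for (s in seq_along(sets)) {
      members <- rownames(X) %in% sets[[s]]
      out[s, j] <- oracle_walk_es(o, r, members, tau, mode)
    }
  }
  out
}

# unpenalized logistic regression by explicit Newton-Raphson
oracle_logistic_nr <- function(X, y, tol = 1e-12, maxit = 200L) {
  Xi <- cbind(1, X)
  beta <- rep(0, ncol(Xi))
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    grad <- crossprod(Xi, y - mu)
    H <- crossprod(Xi * W, Xi)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

# AUC by exhaustive pair counting (ties contribute 1/2)
oracle_auc_pairs <- function(score, y) {
  cases <- score[y == 1]; ctrls <- score[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}

# best Youden J over all observed thresholds for a given direction
oracle_best_youden <- function(score, y, direction) {
  best <- -Inf
  for (t in unique(score)) {
    if (direction == ">=") {
      sens <- mean(score[y == 1] >= t); spec <- mean(score[y == 0] < t)
    } else {
      sens <- mean(score[y == 1] <= t); spec <- mean(score[y == 0] > t)
    }
    best <- max(best, sens + spec - 1)
  }
  best
}

# hierarchical variance simulation for moderated-t recovery:
# sigma^2_g ~ scaled-inv-chisq(d0, s02); s^2_g | sigma^2_g ~ sigma^2 chisq_d / d
simulate_group_variances <- function(G, d0, s02, d, seed) {
  set.seed(seed)
  sigma2 <- d0 * s02 / rchisq(G, d0)
  s2 <- sigma2 * rchisq(G, d) / d
  structure(list(sets = paste0("S", seq_len(G)), delta = rep(0, G),
                 s2 = s2, df = d, v = 0.2,
                 n = c(a = d / 2 + 1, b = d / 2 + 1), levels = c("a", "b")),
            class = "group_fit")
}
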