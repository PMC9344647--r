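# Independent oracles used to cross-check the package's statistics.  Each is
# written against the defining formula, on a different code path from the
# implementation it checks.

# Closed-form OLS via explicit normal equations (X'X)^{-1} X'y, with the
# exact t-distribution for the coefficient in column `col`.
oracle_ols <- function(y, X, col = 2) {
  XtX <- t(X) %*% X
  XtXinv <- solve(XtX)
  beta <- XtXinv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * XtXinv[col, col])
  tval <- beta[col] / se
  list(beta = beta[col], se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), df = df)
}

# Full-enumeration exact HWE null distribution written from explicit
# binomial coefficients: P(n_het | n_minor, n) = C(n, n_hom_min)
# C(n - n_hom_min, n_het) 2^n_het / C(2n, n_minor).  Independent of the
# package's lgamma route.
oracle_hwe_distribution <- function(n_minor, n_total) {
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n_total - n_minor), by = 2)
  hom_min <- (n_minor - hets) / 2
  logp <- lchoose(n_total, hom_min) + lchoose(n_total - hom_min, hets) +
    hets * log(2) - lchoose(2 * n_total, n_minor)
  prob <- exp(logp - max(logp))
  list(hets = hets, prob = prob / sum(prob))
}

oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  d <- oracle_hwe_distribution(n_minor, n)
  obs <- d$prob[match(n_Aa, d$hets)]
  min(1, sum(d$prob[d$prob <= obs * (1 + 1e-12)]))
}

# Hand-written Newton-Raphson IRLS for the logistic log-likelihood, with
# Wald SEs from the inverse observed information.  Non-intercept columns
# are standardised for conditioning and the requested coefficients mapped
# back (a pure reparameterisation of the same likelihood).
oracle_irls <- function(y, X, tol = 1e-10, maxit = 50) {
  centers <- c(0, colMeans(X[, -1, drop = FALSE]))
  scales <- c(1, apply(X[, -1, drop = FALSE], 2, stats::sd))
  X <- sweep(sweep(X, 2, centers), 2, scales, "/")
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  info <- t(X) %*% (X * (mu * (1 - mu)))
  se <- sqrt(diag(solve(info)))
  # Undo the column scaling (intercept not reported).
  list(beta = beta / scales, se = se / scales,
       p = 2 * stats::pnorm(-abs(beta / se)))
}

# Single-covariate recursive partial correlation r_xy.z.
oracle_partial_r <- function(x, y, z) {
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}
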