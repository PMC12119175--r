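# Independent oracles and small data builders shared across test files.
# These deliberately avoid the package's internal code paths: the IRLS
# oracle solves the normal equations directly, and the marginal-likelihood
# oracle integrates each group effect on a dense trapezoid grid.

# Poisson GLM by hand-rolled IRLS over the normal equations
oracle_irls_poisson <- function(X, y, offset, maxit = 100, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) / mean(exp(offset)))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    mu <- exp(eta)
    W <- diag(mu)
    z <- eta - offset + (y - mu) / mu
    beta_new <- solve(t(X) %*% W %*% X, t(X) %*% W %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- drop(beta_new)
      break
    }
    beta <- drop(beta_new)
  }
  list(beta = beta,
       loglik = sum(dpois(y, exp(drop(X %*% beta) + offset), log = TRUE)))
}

# dense-trapezoid marginal log-likelihood for a single Gaussian intercept
oracle_marginal_loglik <- function(beta, sigma, theta = NULL, X, y, offset,
                                   group, span = 8, grid = 4001) {
  eta0 <- drop(X %*% beta) + offset
  sum(vapply(split(seq_along(y), group), function(ii) {
    u <- seq(-span * sigma, span * sigma, length.out = grid)
    vals <- vapply(u, function(uu) {
      ll <- if (is.null(theta))
        sum(dpois(y[ii], exp(eta0[ii] + uu), log = TRUE))
      else sum(dnbinom(y[ii], mu = exp(eta0[ii] + uu), size = theta,
                       log = TRUE))
      exp(ll + dnorm(uu, 0, sigma, log = TRUE))
    }, numeric(1))
    log(sum(vals) * (u[2] - u[1]))
  }, numeric(1)))
}

# quick count dataset with standard-normal covariates (no habitat structure)
make_count_data <- function(n, beta = c(x1 = 0.5), intercept = -3.5,
                            sigma_year = 0, n_years = 5, theta = NULL,
                            effort = NULL, species = "af", seed = NULL,
                            competitor_beta = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effort)) effort <- sample(90:160, n, replace = TRUE)
  dat <- data.frame(effort = effort,
                    year = sample(seq(2000, 1999 + n_years), n, replace = TRUE))
  for (v in names(beta)) dat[[v]] <- rnorm(n)
  u <- rnorm(n_years, 0, sigma_year)
  eta <- intercept + u[dat$year - 1999] +
    drop(as.matrix(dat[names(beta)]) %*% beta)
  mu <- dat$effort * exp(eta)
  dat[[paste0("count_", species)]] <-
    if (is.null(theta)) rpois(n, mu) else rnbinom(n, mu = mu, size = theta)
  dat
}

expect_between <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}
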