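# Count regressions with log link and trap-effort offset: Poisson / NB2,
# optionally with a single (year) random intercept whose marginal likelihood
# is integrated by adaptive Gauss-Hermite quadrature (1 node = Laplace).

#' Specify a count model
#'
#' @param species `"af"` or `"cg"` (or any suffix such that the response
#'   column is `count_<species>`).
#' @param predictors character vector of predictor columns (unique; already
#'   standardised by the caller if comparable coefficients are wanted).
#' @param family `"poisson"` or `"negbin"` (NB2).
#' @param random_intercept `"year"` or `"none"`.
#' @param interactions character vector of `"a:b"` terms; both sides must be
#'   listed main effects.
#' @return a `habseg_spec` list.
#' @export
count_model_spec <- function(species, predictors = character(),
                             family = c("poisson", "negbin"),
                             random_intercept = c("year", "none"),
                             interactions = character()) {
  family <- match.arg(family)
  random_intercept <- match.arg(random_intercept)
  predictors <- as.character(predictors)
  if (anyDuplicated(predictors))
    stop_domain("`predictors` must be unique")
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% predictors))
      stop_domain("interaction `", ia,
                  "` must be `a:b` with both main effects listed")
  }
  structure(list(species = species, predictors = predictors, family = family,
                 random_intercept = random_intercept,
                 interactions = as.character(interactions)),
            class = "habseg_spec")
}

spec_terms <- function(spec) c(spec$predictors, spec$interactions)

spec_drop_term <- function(spec, term) {
  if (term %in% spec$interactions) {
    spec$interactions <- setdiff(spec$interactions, term)
  } else if (term %in% spec$predictors) {
    spec$predictors <- setdiff(spec$predictors, term)
    keep <- vapply(spec$interactions, function(ia) {
      !term %in% strsplit(ia, ":", fixed = TRUE)[[1]]
    }, logical(1))
    spec$interactions <- spec$interactions[keep]
  } else {
    stop_domain("term `", term, "` not in model")
  }
  spec
}

# fast hand-built design matrix: intercept, numeric main effects, products
design_matrix <- function(spec, data) {
  n <- nrow(data)
  p <- length(spec$predictors)
  X <- matrix(1, n, 1L + p + length(spec$interactions))
  cn <- c("(Intercept)", spec$predictors, spec$interactions)
  for (j in seq_len(p)) X[, j + 1L] <- data[[spec$predictors[j]]]
  for (j in seq_along(spec$interactions)) {
    ab <- strsplit(spec$interactions[j], ":", fixed = TRUE)[[1]]
    X[, 1L + p + j] <- data[[ab[1]]] * data[[ab[2]]]
  }
  colnames(X) <- cn
  X
}

ETA_CAP <- 30  # exp() guard on the linear predictor

pois_ll <- function(y, eta) sum(y * eta - exp(pmin(eta, ETA_CAP)) - lgamma(y + 1))
nb_ll <- function(y, eta, theta) {
  mu <- exp(pmin(eta, ETA_CAP))
  sum(lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
        theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu) + (y == 0)))
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Integrates a single Gaussian random intercept out of a Poisson or NB2
#' log-link count model. Each group's integrand is re-centred at its
#' conditional mode with the Laplace curvature (adaptive rule); `q = 1`
#' reduces to the Laplace approximation.
#'
#' @param beta fixed-effect coefficients, first element intercept.
#' @param sigma random-intercept SD (>= 0; values below 1e-10 are floored).
#' @param theta NB2 dispersion, or `NULL` for Poisson.
#' @param X design matrix (first column 1s).
#' @param y counts.
#' @param offset per-row offset (log trap-nights).
#' @param group grouping factor (one random intercept level per group).
#' @param q quadrature nodes.
#' @return maximised-free marginal log-likelihood value (a number).
#' @export
aghq_marginal_loglik <- function(beta, sigma, theta = NULL, X, y, offset,
                                 group, q = 15) {
  gh <- gauss_hermite(q)
  idx <- split(seq_along(y), group)
  eta0 <- drop(X %*% beta) + offset
  sigma <- max(sigma, 1e-10)
  family <- if (is.null(theta)) "poisson" else "negbin"
  sum(vapply(idx, function(ii) {
    aghq_group(y[ii], eta0[ii], sigma, theta, family, gh)$ll
  }, numeric(1)))
}

group_mode <- function(y, eta0, sigma, theta, family) {
  u <- 0
  for (it in 1:50) {
    mu <- exp(pmin(eta0 + u, ETA_CAP))
    if (family == "poisson") {
      g <- sum(y - mu); f <- sum(mu)
    } else {
      g <- sum(theta * (y - mu) / (theta + mu))
      f <- sum(theta * mu * (theta + y) / (theta + mu)^2)
    }
    g <- g - u / sigma^2
    H <- -f - 1 / sigma^2
    step <- g / H
    if (!is.finite(step)) step <- 0
    step <- sign(step) * min(abs(step), 3)
    u <- u - step
    if (abs(g) < 1e-10 || abs(step) < 1e-12) break
  }
  list(u = u, H = H)
}

aghq_group <- function(y, eta0, sigma, theta, family, gh) {
  m <- group_mode(y, eta0, sigma, theta, family)
  tau <- 1 / sqrt(-m$H)
  h <- function(u) {
    ll <- if (family == "poisson") pois_ll(y, eta0 + u)
          else nb_ll(y, eta0 + u, theta)
    ll + stats::dnorm(u, 0, sigma, log = TRUE)
  }
  uk <- m$u + sqrt(2) * tau * gh$nodes
  a <- log(gh$weights) + gh$nodes^2 + vapply(uk, h, numeric(1))
  amax <- max(a)
  list(ll = amax + log(sum(exp(a - amax))) + log(sqrt(2) * tau), mode = m$u)
}

# Poisson IRLS on a prebuilt design; the workhorse of the enumeration and
# jackknife loops, so kept lean (.lm.fit, no formula interface).
irls_poisson <- function(X, y, offset, tol = 1e-10, maxit = 60) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- log((sum(y) + 0.1) / sum(exp(offset)))
  eta <- drop(X %*% beta) + offset
  ll_old <- -Inf
  conv <- FALSE
  for (it in seq_len(maxit)) {
    mu <- exp(pmin(eta, ETA_CAP))
    w <- sqrt(mu)
    z <- eta - offset + (y - mu) / mu
    fit <- .lm.fit(X * w, z * w)
    if (fit$rank < p) {
      bad <- colnames(X)[fit$pivot[-seq_len(fit$rank)]]
      stop_domain("rank-deficient design; aliased terms: ",
                  paste(bad, collapse = ", "))
    }
    beta_new <- numeric(p)
    beta_new[fit$pivot] <- fit$coefficients
    eta <- drop(X %*% beta_new) + offset
    ll <- pois_ll(y, eta)
    beta <- beta_new
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      conv <- TRUE
      break
    }
    ll_old <- ll
  }
  mu <- exp(pmin(eta, ETA_CAP))
  XtWX <- crossprod(X * sqrt(mu))
  vcov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  list(beta = setNames(beta, colnames(X)), loglik = pois_ll(y, eta),
       vcov = vcov, fitted = mu, converged = conv)
}

#' Fit a count model
#'
#' Maximum likelihood for the four cases poisson/negbin x with/without year
#' random intercept. The GLM cases use iteratively reweighted least squares
#' (Poisson) or quasi-Newton ML over (beta, log theta) (NB2); the mixed
#' cases maximise the adaptive-quadrature marginal likelihood over
#' (beta, log sigma[, log theta]) with deterministic starting values (GLM
#' coefficients, sigma = 0.5, theta = 1).
#'
#' @param spec a [count_model_spec()].
#' @param data data.frame with `count_<species>`, `effort`, predictor columns
#'   and (if needed) `year`.
#' @param nodes quadrature nodes for the random intercept (1 = Laplace).
#' @return `habseg_fit` list: `coefficients`, `se`, `vcov`, `loglik`, `aic`,
#'   `aicc`, `n`, `k`, `sigma_year`, `theta`, `ranef`, `fitted`,
#'   `converged`, plus the spec and training data for downstream refits.
#' @export
fit_count_model <- function(spec, data, nodes = 15) {
  resp <- paste0("count_", spec$species)
  y <- data[[resp]]
  if (is.null(y)) stop_domain("response column `", resp, "` not found")
  if (any(y < 0)) stop_domain("counts must be nonnegative")
  if (is.null(data$effort) || any(data$effort < 1))
    stop_domain("`effort` must be present and >= 1")
  offset <- log(data$effort)
  X <- design_matrix(spec, data)
  p <- ncol(X)
  n <- length(y)
  use_re <- spec$random_intercept == "year"
  if (use_re && is.null(data$year)) stop_domain("`year` column required")
  group <- if (use_re) factor(data$year) else NULL

  start_fit <- irls_poisson(X, y, offset)
  theta_hat <- NULL
  sigma_hat <- NULL
  ranef <- NULL
  message <- ""

  if (!use_re && spec$family == "poisson") {
    beta <- start_fit$beta
    loglik <- start_fit$loglik
    vcov_b <- start_fit$vcov
    fitted <- start_fit$fitted
    converged <- start_fit$converged
  } else {
    has_theta <- spec$family == "negbin"
    par0 <- c(start_fit$beta,
              if (use_re) log(0.5),
              if (has_theta) log(1))
    lower <- c(rep(-Inf, p), if (use_re) log(1e-6), if (has_theta) log(1e-4))
    upper <- c(rep(Inf, p), if (use_re) log(50), if (has_theta) log(1e6))
    i_sig <- if (use_re) p + 1L else NA_integer_
    i_th <- if (has_theta) p + use_re + 1L else NA_integer_
    negll <- function(par) {
      beta <- par[seq_len(p)]
      th <- if (has_theta) exp(par[i_th]) else NULL
      if (use_re) {
        -aghq_marginal_loglik(beta, exp(par[i_sig]), th, X, y, offset,
                              group, q = nodes)
      } else {
        -nb_ll(y, drop(X %*% beta) + offset, th)
      }
    }
    opt <- nlminb(par0, negll, lower = lower, upper = upper,
                  control = list(rel.tol = 1e-10, x.tol = 1e-8,
                                 iter.max = 500, eval.max = 2000))
    beta <- setNames(opt$par[seq_len(p)], colnames(X))
    loglik <- -opt$objective
    converged <- opt$convergence == 0
    if (!converged) message <- opt$message %||% "optimizer did not converge"
    if (use_re) sigma_hat <- exp(opt$par[i_sig])
    if (has_theta) theta_hat <- exp(opt$par[i_th])
    H <- tryCatch(optimHess(opt$par, negll), error = function(e) NULL)
    vcov_all <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    vcov_b <- if (!is.null(vcov_all) && all(diag(vcov_all)[seq_len(p)] > 0))
      vcov_all[seq_len(p), seq_len(p), drop = FALSE] else NULL
    eta <- drop(X %*% beta) + offset
    if (use_re) {
      idx <- split(seq_len(n), group)
      modes <- vapply(idx, function(ii) {
        group_mode(y[ii], eta[ii], max(sigma_hat, 1e-10), theta_hat,
                   spec$family)$u
      }, numeric(1))
      ranef <- setNames(modes, names(idx))
      eta <- eta + ranef[as.character(group)]
    }
    fitted <- exp(pmin(eta, ETA_CAP))
  }

  k <- p + length(sigma_hat) + length(theta_hat)
  se <- if (!is.null(vcov_b)) sqrt(pmax(diag(vcov_b), 0)) else rep(NA_real_, p)
  names(se) <- colnames(X)
  structure(list(
    spec = spec, coefficients = beta, se = se, vcov = vcov_b,
    loglik = loglik, aic = -2 * loglik + 2 * k,
    aicc = if (n > k + 1) aicc(loglik, k, n) else NA_real_, n = n, k = k,
    sigma_year = sigma_hat, theta = theta_hat, ranef = ranef,
    fitted = as.numeric(fitted), y = y, offset = offset,
    data = data, converged = converged, message = message),
    class = "habseg_fit")
}

#' @export
print.habseg_fit <- function(x, ...) {
  cat(sprintf("count model [%s | %s | RE: %s] n=%d k=%d logLik=%.3f AICc=%.3f\n",
              x$spec$species, x$spec$family, x$spec$random_intercept,
              x$n, x$k, x$loglik, x$aicc))
  print(round(cbind(estimate = x$coefficients, se = x$se), 4))
  if (!is.null(x$sigma_year)) cat("sigma_year:", round(x$sigma_year, 4), "\n")
  if (!is.null(x$theta)) cat("theta:", round(x$theta, 4), "\n")
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' `AIC = -2 logLik + 2k`; `AICc = AIC + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop_domain("AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Likelihood-ratio test between nested fits
#'
#' @param full,reduced `habseg_fit` objects on the same data and family, the
#'   reduced model's terms a subset of the full model's.
#' @return list with `statistic` (clipped at 0), `df`, `p.value`.
#' @export
lr_test <- function(full, reduced) {
  if (!inherits(full, "habseg_fit") || !inherits(reduced, "habseg_fit"))
    stop_domain("both arguments must be habseg_fit objects")
  if (full$spec$family != reduced$spec$family)
    stop_domain("LR test requires the same family")
  if (full$n != reduced$n)
    stop_domain("models were fitted to different data")
  if (!all(spec_terms(reduced$spec) %in% spec_terms(full$spec)) ||
      reduced$k > full$k)
    stop_domain("`reduced` is not nested in `full`")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$k - reduced$k
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}

# LR p-value for each term of a fit (refit without the term)
term_pvalues <- function(fit, nodes = 15) {
  terms <- spec_terms(fit$spec)
  out <- setNames(numeric(length(terms)), terms)
  chi <- out
  for (tm in terms) {
    red <- fit_count_model(spec_drop_term(fit$spec, tm), fit$data,
                           nodes = nodes)
    lt <- lr_test(fit, red)
    out[tm] <- lt$p.value
    chi[tm] <- lt$statistic
  }
  attr(out, "statistic") <- chi
  out
}

#' Predicted response curve for one habitat variable
#'
#' Predicted captures for a reference trapping effort as one standardised
#' variable moves over a z-score grid, all other variables held at their
#' mean (z = 0).
#'
#' @param fit a `habseg_fit`.
#' @param variable one of the fitted predictors.
#' @param z z-score grid.
#' @param effort reference trapping effort (default 100 trap-nights).
#' @param year optional year level whose predicted random intercept is added.
#' @return data.frame with `z` and `predicted`.
#' @export
predict_response <- function(fit, variable, z = seq(-2, 2, length.out = 41),
                             effort = 100, year = NULL) {
  if (!variable %in% names(fit$coefficients))
    stop_domain("variable `", variable, "` not in the fitted model")
  u <- 0
  if (!is.null(year)) {
    if (is.null(fit$ranef) || !as.character(year) %in% names(fit$ranef))
      stop_domain("no predicted random effect for year ", year)
    u <- fit$ranef[[as.character(year)]]
  }
  eta <- fit$coefficients[["(Intercept)"]] + fit$coefficients[[variable]] * z + u
  data.frame(z = z, predicted = effort * exp(eta))
}
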