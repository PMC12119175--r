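# Explained-variance accounting on the latent (log-link) scale: marginal
# r2, per-variable-group partial r2, contrasting-vs-shared partition, and
# parametric-bootstrap confidence intervals.

resid_var_latent <- function(fit, method) {
  X <- design_matrix(fit$spec, fit$data)
  lambda_bar <- exp(mean(drop(X %*% fit$coefficients)) + mean(fit$offset))
  extra <- if (fit$spec$family == "negbin") 1 / fit$theta else 0
  if (method == "lognormal") log(1 + 1 / lambda_bar + extra)
  else 1 / lambda_bar + extra
}

#' Marginal r2 of a count model
#'
#' Variance explained by the fixed effects on the latent scale:
#' `var(X beta) / (var(X beta) + sigma_year^2 + resid)`, where the
#' observation-level residual variance uses the lognormal approximation
#' `ln(1 + 1/lambda + 1/theta)` (or the delta form `1/lambda + 1/theta`)
#' with `lambda = exp(mean linear predictor + mean offset)`.
#'
#' @param fit a `habseg_fit`.
#' @param method `"lognormal"` (default) or `"delta"`.
#' @return r2 in `[0, 1)`.
#' @export
model_r2 <- function(fit, method = c("lognormal", "delta")) {
  method <- match.arg(method)
  X <- design_matrix(fit$spec, fit$data)
  if (ncol(X) == 1L) return(0)
  vf <- var(drop(X[, -1, drop = FALSE] %*% fit$coefficients[-1]))
  s2 <- if (is.null(fit$sigma_year)) 0 else fit$sigma_year^2
  vf / (vf + s2 + resid_var_latent(fit, method))
}

fixed_effect_var <- function(fit) {
  X <- design_matrix(fit$spec, fit$data)
  if (ncol(X) == 1L) return(0)
  var(drop(X[, -1, drop = FALSE] %*% fit$coefficients[-1]))
}

#' Partial r2 of a predictor subset
#'
#' The variation explained by the full model that the reduced model (the
#' full model without `S`, refitted on the same data) cannot explain:
#' `(var(X b_full) - var(X_red b_red)) / (var(X b_full) + sigma_year^2 +
#' resid)`. Both numerator terms are measured against the full model's
#' total-variance denominator, so partial r2 values of orthogonal
#' predictors add up to the model r2 and `S = all predictors` recovers
#' [model_r2()] exactly. Negative finite-sample differences are floored at
#' 0.
#'
#' @param fit full-model `habseg_fit`.
#' @param S character vector of predictors to attribute (subset of the
#'   fitted terms); the empty set gives 0.
#' @param method passed to [model_r2()].
#' @param nodes quadrature nodes for the refit.
#' @return partial r2 >= 0.
#' @export
partial_r2 <- function(fit, S, method = c("lognormal", "delta"), nodes = 15) {
  method <- match.arg(method)
  if (!length(S)) return(0)
  terms <- spec_terms(fit$spec)
  if (!all(S %in% terms))
    stop_domain("subset not in model: ",
                paste(setdiff(S, terms), collapse = ", "))
  spec <- fit$spec
  for (tm in S) if (tm %in% spec_terms(spec)) spec <- spec_drop_term(spec, tm)
  reduced <- fit_count_model(spec, fit$data, nodes = nodes)
  v_full <- fixed_effect_var(fit)
  s2 <- if (is.null(fit$sigma_year)) 0 else fit$sigma_year^2
  denom <- v_full + s2 + resid_var_latent(fit, method)
  max(0, (v_full - fixed_effect_var(reduced)) / denom)
}

#' Percentage of explained variation attributed to a variable group
#'
#' @param partial group partial r2 (any scale).
#' @param total model r2 on the same scale; must be positive.
#' @return `100 * partial / total`.
#' @export
contrast_share <- function(partial, total) {
  check_number(total, "total", lower = 1e-12)
  check_number(partial, "partial", lower = 0)
  100 * partial / total
}

#' Partition explained variance into contrasting and shared habitat effects
#'
#' Classifies each significant variable as *contrasting* (significant in
#' only one species, or in both with opposite coefficient signs) or
#' *shared* (significant in both with the same sign), then reports each
#' species' group partial r2 and the contrasting share of its explained
#' variation. Classification is symmetric in the species order.
#'
#' @param fit_a,fit_c the two species' best-model fits on the same
#'   transects.
#' @param alpha significance level for the LR term tests.
#' @param method passed to [model_r2()].
#' @param nodes quadrature nodes.
#' @return list: `classification` (data.frame variable/class), and per
#'   species `model_r2`, `contrasting_r2`, `shared_r2`, `share`
#'   (contrasting share of explained variation, percent).
#' @export
contrast_partition <- function(fit_a, fit_c, alpha = 0.05,
                               method = "lognormal", nodes = 15) {
  if (fit_a$n != fit_c$n)
    stop_domain("the two fits must use the same transects")
  pa <- term_pvalues(fit_a, nodes = nodes)
  pc <- term_pvalues(fit_c, nodes = nodes)
  sig_a <- names(pa)[pa < alpha]
  sig_c <- names(pc)[pc < alpha]
  vars <- union(sig_a, sig_c)
  cls <- vapply(vars, function(v) {
    in_a <- v %in% sig_a
    in_c <- v %in% sig_c
    if (in_a && in_c) {
      same <- sign(fit_a$coefficients[[v]]) == sign(fit_c$coefficients[[v]])
      if (same) "shared" else "contrasting"
    } else "contrasting"
  }, character(1))
  contrasting <- vars[cls == "contrasting"]
  shared <- vars[cls == "shared"]
  per_species <- function(fit) {
    r2 <- model_r2(fit, method)
    ct <- partial_r2(fit, intersect(contrasting, spec_terms(fit$spec)),
                     method, nodes)
    sh <- partial_r2(fit, intersect(shared, spec_terms(fit$spec)),
                     method, nodes)
    list(model_r2 = r2, contrasting_r2 = ct, shared_r2 = sh,
         share = if (r2 > 0) contrast_share(ct, r2) else 0)
  }
  list(classification = data.frame(variable = vars, class = unname(cls)),
       af = per_species(fit_a), cg = per_species(fit_c))
}

#' Parametric-bootstrap CI for (partial) r2
#'
#' Simulates responses from the fitted model (new year effects from
#' `N(0, sigma_year^2)`, counts from the fitted family), refits the same
#' specification and recomputes the statistic; the CI is the 2.5/97.5
#' percentile of the bootstrap sample. Seed-deterministic. Refit failures
#' are dropped with a count; more than 20% failures is an error.
#'
#' @param fit a `habseg_fit`.
#' @param n_boot bootstrap draws (>= 100).
#' @param seed RNG seed.
#' @param S optional predictor subset: CI of `partial_r2(fit, S)` instead of
#'   the model r2.
#' @param level confidence level (default 0.95).
#' @param method passed to [model_r2()].
#' @param nodes quadrature nodes.
#' @return list: `estimate`, `lower`, `upper`, `n_fail`, `boot`.
#' @export
r2_ci <- function(fit, n_boot = 1000, seed = 1, S = NULL, level = 0.95,
                  method = "lognormal", nodes = 15) {
  if (n_boot < 100) stop_domain("`n_boot` must be >= 100")
  set.seed(seed)
  X <- design_matrix(fit$spec, fit$data)
  eta_fix <- drop(X %*% fit$coefficients) + fit$offset
  years <- if (!is.null(fit$ranef)) factor(fit$data$year) else NULL
  stat <- function(f) if (is.null(S)) model_r2(f, method)
                      else partial_r2(f, S, method, nodes)
  boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    eta <- eta_fix
    if (!is.null(years)) {
      u <- rnorm(nlevels(years), 0, fit$sigma_year)
      eta <- eta + u[as.integer(years)]
    }
    mu <- exp(pmin(eta, ETA_CAP))
    ystar <- if (fit$spec$family == "poisson") rpois(length(mu), mu)
             else rnbinom(length(mu), mu = mu, size = fit$theta)
    dat <- fit$data
    dat[[paste0("count_", fit$spec$species)]] <- ystar
    boot[b] <- tryCatch(
      stat(fit_count_model(fit$spec, dat, nodes = nodes)),
      error = function(e) NA_real_)
  }
  n_fail <- sum(is.na(boot))
  if (n_fail > 0.2 * n_boot)
    stop_domain("bootstrap refit failure rate too high: ", n_fail, "/", n_boot)
  qs <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  list(estimate = stat(fit), lower = unname(qs[1]), upper = unname(qs[2]),
       n_fail = n_fail, boot = boot)
}
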