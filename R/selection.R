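# AICc multimodel inference: exhaustive main-effect subsets, the
# delta-AICc < 2 competing set with Akaike weights, model-averaged
# coefficients, and reduction to the best all-significant model.

model_label <- function(vars) {
  if (!length(vars)) "1" else paste(sort(vars), collapse = "+")
}

#' Fit and rank all main-effect subsets by AICc
#'
#' Fits the `2^p` subsets of the candidate variables (intercept always
#' included) and ranks them by AICc, ties broken by fewer parameters and
#' then by the model label.
#'
#' @param species response species suffix.
#' @param candidates candidate predictor columns (at most 15).
#' @param data data.frame (predictors standardised by the caller).
#' @param family,random_intercept,nodes passed to the fits.
#' @return `habseg_ranking`: `table` (model, k, loglik, aicc, delta) and
#'   `fits` (list in rank order).
#' @export
enumerate_and_rank <- function(species, candidates, data,
                               family = "poisson",
                               random_intercept = "none", nodes = 15) {
  p <- length(candidates)
  if (p > 15)
    stop_domain("too many candidate variables (", p,
                "): restrict the candidate list to at most 15")
  nmod <- bitwShiftL(1L, p)
  fits <- vector("list", nmod)
  labels <- character(nmod)
  for (m in seq_len(nmod) - 1L) {
    vars <- candidates[bitwAnd(bitwShiftR(m, seq_len(p) - 1L), 1L) == 1L]
    spec <- count_model_spec(species, vars, family = family,
                             random_intercept = random_intercept)
    fits[[m + 1L]] <- fit_count_model(spec, data, nodes = nodes)
    labels[m + 1L] <- model_label(vars)
  }
  tab <- data.frame(
    model = labels,
    k = vapply(fits, `[[`, numeric(1), "k"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    stringsAsFactors = FALSE)
  # models with undefined AICc (n <= k + 1) cannot enter the ranking
  ok <- !is.na(tab$aicc)
  if (!any(ok)) stop_domain("no model has a defined AICc (n too small)")
  tab <- tab[ok, , drop = FALSE]
  fits <- fits[ok]
  ord <- order(tab$aicc, tab$k, tab$model)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab$delta <- tab$aicc - tab$aicc[1]
  structure(list(table = tab, fits = fits[ord], species = species,
                 candidates = candidates),
            class = "habseg_ranking")
}

#' Competing model set (delta AICc < threshold)
#'
#' Retains models with AICc within `delta` of the best and renormalises
#' Akaike weights `exp(-delta_i/2)` within the retained set.
#'
#' @param ranking a [enumerate_and_rank()] result.
#' @param delta strict retention threshold (default 2).
#' @return `habseg_competing`: `table` (with `weight`), `fits`.
#' @export
competing_set <- function(ranking, delta = 2) {
  if (!nrow(ranking$table)) stop_domain("empty ranking")
  keep <- ranking$table$delta < delta
  tab <- ranking$table[keep, , drop = FALSE]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  structure(list(table = tab, fits = ranking$fits[keep],
                 species = ranking$species),
            class = "habseg_competing")
}

#' Model-averaged coefficients over a competing set
#'
#' Full averaging substitutes 0 for a variable absent from a model before
#' weighting (the default, shrinking towards 0); conditional averaging
#' renormalises weights over the models that contain the variable.
#' Unconditional standard errors follow the usual multimodel formula
#' `sum_i w_i sqrt(se_i^2 + (b_i - bbar)^2)`.
#'
#' @param cs a [competing_set()].
#' @param mode `"full"` or `"conditional"`.
#' @param variables optional extra variables to report (0 when absent from
#'   every competing model).
#' @return data.frame: `variable`, `estimate`, `se`, `n_models`.
#' @export
average_coefficients <- function(cs, mode = c("full", "conditional"),
                                 variables = NULL) {
  mode <- match.arg(mode)
  if (!length(cs$fits)) stop_domain("empty competing set")
  vars <- unique(c(unlist(lapply(cs$fits, function(f)
    setdiff(names(f$coefficients), "(Intercept)"))), variables))
  w <- cs$table$weight
  rows <- lapply(vars, function(v) {
    b <- vapply(cs$fits, function(f) f$coefficients[v], numeric(1))
    s <- vapply(cs$fits, function(f) f$se[v], numeric(1))
    present <- !is.na(b)
    if (!any(present))
      return(data.frame(variable = v, estimate = 0, se = 0, n_models = 0L))
    if (mode == "full") {
      b[!present] <- 0
      s[!present] <- 0
      wi <- w
    } else {
      b <- b[present]
      s <- s[present]
      wi <- w[present] / sum(w[present])
    }
    bbar <- sum(wi * b)
    sebar <- sum(wi * sqrt(s^2 + (b - bbar)^2))
    data.frame(variable = v, estimate = bbar, se = sebar,
               n_models = sum(present))
  })
  do.call(rbind, rows)
}

#' Best model containing only significant predictors
#'
#' Walks the competing set from the top and returns the first model in
#' which every predictor's LR-test p-value is below `alpha`; if none
#' qualifies, backward-eliminates from the top model (iteratively dropping
#' the largest-p predictor and refitting). The intercept-only model is a
#' valid terminus. The path taken is recorded.
#'
#' @param ranking a [enumerate_and_rank()] result.
#' @param alpha significance level (default 0.05).
#' @param delta competing-set threshold (default 2).
#' @param nodes quadrature nodes.
#' @return list: `fit`, `pvalues`, `path` (character log).
#' @export
best_significant_model <- function(ranking, alpha = 0.05, delta = 2,
                                   nodes = 15) {
  cs <- competing_set(ranking, delta = delta)
  path <- character(0)
  for (i in seq_along(cs$fits)) {
    fit <- cs$fits[[i]]
    pv <- term_pvalues(fit, nodes = nodes)
    if (!length(pv) || all(pv < alpha)) {
      path <- c(path, sprintf("rank-%d model `%s` all-significant: selected",
                              i, cs$table$model[i]))
      return(list(fit = fit, pvalues = pv, path = path))
    }
    path <- c(path, sprintf("rank-%d model `%s` has non-significant terms (%s)",
                            i, cs$table$model[i],
                            paste(names(pv)[pv >= alpha], collapse = ", ")))
  }
  path <- c(path, "no competing model all-significant: backward elimination")
  fit <- cs$fits[[1]]
  repeat {
    pv <- term_pvalues(fit, nodes = nodes)
    if (!length(pv) || all(pv < alpha)) break
    worst <- names(pv)[which.max(pv)]
    path <- c(path, sprintf("dropping `%s` (p = %.3g)", worst, max(pv)))
    fit <- fit_count_model(spec_drop_term(fit$spec, worst), fit$data,
                           nodes = nodes)
  }
  list(fit = fit, pvalues = pv, path = path)
}
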