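# Interspecific competition: augment a species' habitat model with the
# competitor's standardised trapping rate and habitat x competitor
# interactions.

#' Competitor-augmented habitat model
#'
#' Adds the competitor's standardised trapping rate (z-score of captures per
#' 100 trap-nights, standardised within the analysed transects) to the focal
#' species' habitat model, LR-tests it against the habitat-only model,
#' computes its partial-r2 share of the explained variation, and then tests
#' each habitat-by-competitor interaction one at a time against the
#' main-effects-plus-competitor model, Holm-adjusted across interactions.
#'
#' @param best_fit the focal species' best habitat model (`habseg_fit`).
#' @param competitor species suffix of the competitor (its counts must be in
#'   `count_<competitor>`).
#' @param alpha significance level.
#' @param standardize standardise the competitor rate (default TRUE).
#' @param nodes quadrature nodes.
#' @return `habseg_competition`: `b`, `se`, `lr` (statistic/df/p),
#'   `share` (competitor fraction of explained variation, in [0, 1]),
#'   `direction` (`"suppression"`, `"facilitation"` or `"none"`),
#'   `interactions` (data.frame with raw and Holm-adjusted p), `fit`.
#' @export
fit_competition_model <- function(best_fit, competitor, alpha = 0.05,
                                  standardize = TRUE, nodes = 15) {
  data <- best_fit$data
  ccol <- paste0("count_", competitor)
  if (is.null(data[[ccol]]))
    stop_domain("competitor counts `", ccol, "` not found")
  rate <- trapping_rate(data[[ccol]], data$effort)
  if (sd(rate) == 0)
    stop_domain("degenerate predictor: competitor rate is constant")
  data$comp_rate <- if (standardize) zscore(rate)$z else rate
  spec <- best_fit$spec
  spec$predictors <- c(spec$predictors, "comp_rate")
  base_fit <- fit_count_model(best_fit$spec, data, nodes = nodes)
  aug_fit <- fit_count_model(spec, data, nodes = nodes)
  lr <- lr_test(aug_fit, base_fit)
  b <- aug_fit$coefficients[["comp_rate"]]
  r2 <- model_r2(aug_fit)
  share <- if (r2 > 0) partial_r2(aug_fit, "comp_rate", nodes = nodes) / r2
           else 0
  direction <- if (lr$p.value >= alpha) "none"
               else if (b < 0) "suppression" else "facilitation"
  habitat <- best_fit$spec$predictors
  inter <- NULL
  if (length(habitat)) {
    rows <- lapply(habitat, function(h) {
      sp2 <- spec
      sp2$interactions <- paste0(h, ":comp_rate")
      f2 <- fit_count_model(sp2, data, nodes = nodes)
      lt <- lr_test(f2, aug_fit)
      data.frame(interaction = sp2$interactions,
                 estimate = f2$coefficients[[sp2$interactions]],
                 statistic = lt$statistic, p.value = lt$p.value)
    })
    inter <- do.call(rbind, rows)
    inter$p.adjusted <- stats::p.adjust(inter$p.value, method = "holm")
  }
  structure(list(
    focal = best_fit$spec$species, competitor = competitor,
    b = b, se = aug_fit$se[["comp_rate"]],
    lr = lr, share = min(1, share), direction = direction,
    interactions = inter, fit = aug_fit), class = "habseg_competition")
}

#' Cross the two directed competition tests
#'
#' @param result_a_on_c,result_c_on_a [fit_competition_model()] results for
#'   the two directions, fitted on the same transects.
#' @return list: `label` (`"symmetric"`, `"asymmetric"` or `"none"`),
#'   `suppressed` (the species whose abundance is reduced, for the
#'   asymmetric case), and both results.
#' @export
asymmetry_report <- function(result_a_on_c, result_c_on_a) {
  sig1 <- result_a_on_c$direction != "none"
  sig2 <- result_c_on_a$direction != "none"
  label <- if (sig1 && sig2) "symmetric" else if (sig1 || sig2) "asymmetric"
           else "none"
  suppressed <- if (label == "asymmetric") {
    if (sig1) result_a_on_c$focal else result_c_on_a$focal
  } else NA_character_
  list(label = label, suppressed = suppressed,
       forward = result_a_on_c, reverse = result_c_on_a)
}
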