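# Habitat segregation as a partial-r2-weighted Euclidean distance between
# the two species' averaged coefficient vectors, with the paired
# leave-one-out-per-stratum jackknife and its CI / t test, plus the
# rank-sum abundance comparisons.

DISTANCE_CONVENTIONS <- c("mean_w", "coord_w", "coord_sqrtw", "norm_w")

#' Build a species response vector for one stratum
#'
#' Runs selection on the stratum: ranks all candidate subsets by AICc, keeps
#' the competing set, model-averages the coefficients (full averaging by
#' default) and attaches per-variable weights equal to the partial r2 of
#' each variable in the union model (all variables appearing in any
#' competing model), on the proportion scale. Variables absent from every
#' competing model get coefficient and weight 0.
#'
#' @param data stratum data.frame (predictors standardised by the caller).
#' @param species response species suffix.
#' @param candidates candidate predictors.
#' @param stratum label carried along (e.g. `"low"`).
#' @param family,random_intercept,nodes,delta,mode selection settings.
#' @return `habseg_response`: `beta`, `w` (named, aligned to `candidates`),
#'   `species`, `stratum`, `models` (competing variable subsets).
#' @export
response_vector <- function(data, species, candidates, stratum = NA,
                            family = "poisson", random_intercept = "none",
                            nodes = 15, delta = 2, mode = "full") {
  ranking <- enumerate_and_rank(species, candidates, data, family = family,
                                random_intercept = random_intercept,
                                nodes = nodes)
  cs <- competing_set(ranking, delta = delta)
  models <- lapply(cs$table$model, function(lab) {
    if (lab == "1") character(0) else strsplit(lab, "+", fixed = TRUE)[[1]]
  })
  response_from_models(data, species, models, candidates, stratum,
                       family, random_intercept, nodes, mode)
}

# Average coefficients and compute partial-r2 weights over a given list of
# model variable subsets (refitted on `data`); used both for the fresh
# selection path and for jackknife reuse of a stored model set.
response_from_models <- function(data, species, models, candidates,
                                 stratum = NA, family = "poisson",
                                 random_intercept = "none", nodes = 15,
                                 mode = "full") {
  fits <- lapply(models, function(vars) {
    fit_count_model(count_model_spec(species, vars, family = family,
                                     random_intercept = random_intercept),
                    data, nodes = nodes)
  })
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  ok <- !is.na(aiccs)
  if (!any(ok)) stop_domain("no model has a defined AICc (n too small)")
  fits <- fits[ok]
  models <- models[ok]
  aiccs <- aiccs[ok]
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  cs <- structure(list(
    table = data.frame(model = vapply(models, model_label, character(1)),
                       aicc = aiccs, delta = d, weight = w / sum(w)),
    fits = fits, species = species), class = "habseg_competing")
  avg <- average_coefficients(cs, mode = mode, variables = candidates)
  beta <- setNames(rep(0, length(candidates)), candidates)
  beta[avg$variable] <- avg$estimate
  union_vars <- sort(unique(unlist(models)))
  wts <- setNames(rep(0, length(candidates)), candidates)
  if (length(union_vars)) {
    union_fit <- fit_count_model(
      count_model_spec(species, union_vars, family = family,
                       random_intercept = random_intercept),
      data, nodes = nodes)
    for (v in union_vars)
      wts[v] <- partial_r2(union_fit, v, nodes = nodes)
  }
  structure(list(beta = beta, w = wts, species = species, stratum = stratum,
                 models = models),
            class = "habseg_response")
}

#' Weighted Euclidean distance between two species' responses
#'
#' Default convention (`"mean_w"`): squared coefficient differences weighted
#' by the species-mean partial r2 on the proportion scale,
#' `d = sqrt(sum_v (w_av + w_cv)/2 * (b_av - b_cv)^2)`. Alternatives:
#' `"coord_w"` weights each species' coordinates by its own partial r2
#' before an unweighted distance, `"coord_sqrtw"` uses sqrt-weighted
#' coordinates, `"norm_w"` renormalises the mean weights to sum to 1.
#'
#' @param vec_a,vec_c `habseg_response` objects (or lists with named `beta`
#'   and `w`) from the same stratum. Variables are aligned on the union of
#'   names, filling 0.
#' @param convention one of `"mean_w"`, `"coord_w"`, `"coord_sqrtw"`,
#'   `"norm_w"`.
#' @return nonnegative distance.
#' @export
weighted_distance <- function(vec_a, vec_c,
                              convention = DISTANCE_CONVENTIONS) {
  convention <- match.arg(convention)
  if (!is.na(vec_a$stratum %||% NA) && !is.na(vec_c$stratum %||% NA) &&
      !identical(vec_a$stratum, vec_c$stratum))
    stop_domain("response vectors come from different strata")
  vars <- union(names(vec_a$beta), names(vec_c$beta))
  if (!length(vars)) stop_domain("no overlapping variables")
  get <- function(x, nm) {
    out <- setNames(rep(0, length(vars)), vars)
    out[names(x[[nm]])] <- x[[nm]]
    out
  }
  ba <- get(vec_a, "beta"); bc <- get(vec_c, "beta")
  wa <- get(vec_a, "w"); wc <- get(vec_c, "w")
  if (any(wa < 0) || any(wc < 0)) stop_domain("weights must be nonnegative")
  switch(convention,
    mean_w = sqrt(sum((wa + wc) / 2 * (ba - bc)^2)),
    coord_w = sqrt(sum((ba * wa - bc * wc)^2)),
    coord_sqrtw = sqrt(sum((ba * sqrt(wa) - bc * sqrt(wc))^2)),
    norm_w = {
      wbar <- (wa + wc) / 2
      s <- sum(wbar)
      if (s <= 0) stop_domain("all weights are zero")
      sqrt(sum(wbar / s * (ba - bc)^2))
    })
}

# per-stratum pipeline: standardise, build both species' response vectors,
# return the distance (and the vectors); `models` (per species) switches to
# reuse mode.
stratum_distance <- function(sub, candidates, stratum, convention,
                             family, random_intercept, nodes, delta, mode,
                             standardize = TRUE, models = NULL) {
  if (standardize) sub <- standardize_predictors(sub, candidates)
  mk <- function(sp) {
    if (is.null(models)) {
      response_vector(sub, sp, candidates, stratum, family,
                      random_intercept, nodes, delta, mode)
    } else {
      response_from_models(sub, sp, models[[sp]], candidates, stratum,
                           family, random_intercept, nodes, mode)
    }
  }
  va <- mk("af"); vc <- mk("cg")
  list(distance = weighted_distance(va, vc, convention), af = va, cg = vc)
}

#' Jackknife distribution of the LOW/HIGH segregation distances
#'
#' Computes the full-data weighted distance in each elevation stratum, then
#' for every combination (i in LOW, k in HIGH) removes transect i from LOW
#' and k from HIGH and reruns the per-stratum pipeline (standardise ->
#' selection -> averaging -> partial-r2 weights -> distance) on the reduced
#' strata. Because the strata are analysed independently, the LOW distance
#' of pair (i, k) depends only on i and the HIGH distance only on k; the
#' pair grid is the cross product of the per-stratum leave-one-out values,
#' `|LOW| x |HIGH|` pairs in total. Fully deterministic.
#'
#' @param data transect data.frame.
#' @param candidates candidate predictors.
#' @param cut elevation cut in m (default 1300).
#' @param convention distance convention, see [weighted_distance()].
#' @param family,random_intercept,nodes,delta,mode selection settings.
#' @param refit_selection if `TRUE` (default) each deletion reruns subset
#'   selection; if `FALSE` the full-data competing model sets are refitted
#'   on the reduced data instead.
#' @param standardize re-standardise the candidates within each (reduced)
#'   stratum before fitting (default TRUE).
#' @return `habseg_distance_report`: `d_low`, `d_high` (full-data points),
#'   `low_loo`, `high_loo` (leave-one-out vectors), `pairs` (data.frame of
#'   all combinations), `n_pairs`, `n_failed` (pairs excluded because a
#'   deletion refit failed; more than 5% is an error).
#' @export
jackknife_distances <- function(data, candidates, cut = 1300,
                                convention = "mean_w", family = "poisson",
                                random_intercept = "none", nodes = 15,
                                delta = 2, mode = "full",
                                refit_selection = TRUE, standardize = TRUE) {
  halves <- split_by_elevation(data, cut)
  n_low <- nrow(halves$low); n_high <- nrow(halves$high)
  if (n_low < 3 || n_high < 3)
    stop_domain("each stratum needs at least 3 transects")
  full <- lapply(list(low = halves$low, high = halves$high), function(sub) {
    stratum_distance(sub, candidates, NA, convention, family,
                     random_intercept, nodes, delta, mode,
                     standardize = standardize)
  })
  loo <- function(sub, models) {
    vapply(seq_len(nrow(sub)), function(i) {
      tryCatch(
        stratum_distance(sub[-i, , drop = FALSE], candidates, NA, convention,
                         family, random_intercept, nodes, delta, mode,
                         standardize = standardize, models = models)$distance,
        error = function(e) NA_real_)
    }, numeric(1))
  }
  reuse <- function(st) if (refit_selection) NULL else
    list(af = full[[st]]$af$models, cg = full[[st]]$cg$models)
  low_loo <- loo(halves$low, reuse("low"))
  high_loo <- loo(halves$high, reuse("high"))
  pairs <- expand.grid(i = seq_len(n_low), k = seq_len(n_high))
  pairs$d_low <- low_loo[pairs$i]
  pairs$d_high <- high_loo[pairs$k]
  failed <- !complete.cases(pairs)
  n_failed <- sum(failed)
  if (n_failed > 0.05 * nrow(pairs))
    stop_domain("jackknife refit failures exceed 5% of pairs (",
                n_failed, "/", nrow(pairs), ")")
  structure(list(
    d_low = full$low$distance, d_high = full$high$distance,
    low_loo = low_loo, high_loo = high_loo,
    pairs = pairs[!failed, , drop = FALSE],
    n_pairs = nrow(pairs), n_failed = n_failed,
    convention = convention), class = "habseg_distance_report")
}

#' Jackknife CIs and the paired t test on the stratum distances
#'
#' Percentile 2.5/97.5 confidence intervals of the LOW and HIGH jackknife
#' samples and a paired one-sample t test of `d_low - d_high` against 0
#' (one-sided, "larger than 0") with `df = n_pairs - 1`. The jackknife
#' deletions are treated as independent samples for the test, matching the
#' convention of the reported df; replicates are not truly independent, so
#' the t statistic is anti-conservative.
#'
#' @param report a [jackknife_distances()] result.
#' @param level confidence level (default 0.95).
#' @return list: `ci_low`, `ci_high` (length-2), `mean_low`, `mean_high`,
#'   `mean_diff`, `t`, `df`, `p.value`, `constant` (TRUE when the
#'   differences have zero variance, in which case `t` is +/-Inf).
#' @export
jackknife_ci_and_test <- function(report, level = 0.95) {
  if (nrow(report$pairs) < 3) stop_domain("need at least 3 jackknife pairs")
  a <- (1 - level) / 2
  dl <- report$pairs$d_low; dh <- report$pairs$d_high
  diff <- dl - dh
  n <- length(diff)
  s <- sd(diff)
  constant <- s == 0
  t <- if (constant) sign(mean(diff)) * Inf else mean(diff) / (s / sqrt(n))
  p <- if (constant) as.numeric(mean(diff) <= 0)
       else pt(t, df = n - 1, lower.tail = FALSE)
  list(ci_low = unname(quantile(dl, c(a, 1 - a))),
       ci_high = unname(quantile(dh, c(a, 1 - a))),
       mean_low = mean(dl), mean_high = mean(dh), mean_diff = mean(diff),
       t = t, df = n - 1, p.value = p, constant = constant)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Midranks for ties. The statistic is the Mann-Whitney U of the first
#' group (its rank sum minus the minimum `n1(n1+1)/2`). The p-value is
#' exact by enumeration when `n1 + n2 <= 12` and there are no ties,
#' otherwise a normal approximation with tie correction.
#'
#' @param x,y numeric samples (e.g. trapping rates of two transect groups).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list: `statistic` (U), `p.value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop_domain("both groups must be nonempty")
  n1 <- length(x); n2 <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(all_v) > 0
  if (n1 + n2 <= 12 && !ties) {
    sets <- combn(n1 + n2, n1)
    allU <- colSums(matrix(rank(all_v)[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
      greater = mean(allU >= U),
      less = mean(allU <= U),
      two.sided = min(1, 2 * min(mean(allU >= U), mean(allU <= U))))
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    tt <- table(all_v)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - n1 * n2 / 2) / sqrt(sigma2)
      p <- switch(alternative,
        greater = pnorm(z, lower.tail = FALSE),
        less = pnorm(z),
        two.sided = 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  list(statistic = U, p.value = p, method = method)
}

#' Distances from a printed coefficient/weight table
#'
#' Ingests a long-format table with columns `variable`, `stratum`,
#' `species`, `beta`, `w` (partial r2 in percent; the censored entry `"<1"`
#' is mapped to `censored_value` percent) and reports the weighted distance
#' per stratum under one or all conventions. Useful for auditing published
#' coefficient tables whose exact weighting convention is unstated.
#'
#' @param table data.frame or CSV path.
#' @param convention a convention name or `"all"`.
#' @param censored_value percent value substituted for `"<1"` entries
#'   (default 0.5, the censored-interval midpoint).
#' @return data.frame: `stratum`, `convention`, `distance`.
#' @export
distance_from_table <- function(table, convention = "all",
                                censored_value = 0.5) {
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  need <- c("variable", "stratum", "species", "beta", "w")
  if (!all(need %in% names(table)))
    stop_domain("table needs columns: ", paste(need, collapse = ", "))
  wraw <- as.character(table$w)
  wnum <- ifelse(grepl("^\\s*<", wraw), censored_value,
                 suppressWarnings(as.numeric(wraw)))
  if (any(is.na(wnum))) stop_domain("unparseable weight entries")
  table$w_prop <- wnum / 100
  convs <- if (identical(convention, "all")) DISTANCE_CONVENTIONS
           else match.arg(convention, DISTANCE_CONVENTIONS)
  out <- list()
  for (st in unique(table$stratum)) {
    sub <- table[table$stratum == st, ]
    vec <- function(sp) {
      ss <- sub[sub$species == sp, ]
      list(beta = setNames(ss$beta, ss$variable),
           w = setNames(ss$w_prop, ss$variable), stratum = st)
    }
    for (cv in convs) {
      out[[length(out) + 1L]] <- data.frame(
        stratum = st, convention = cv,
        distance = weighted_distance(vec("af"), vec("cg"), cv))
    }
  }
  do.call(rbind, out)
}
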