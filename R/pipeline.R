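# End-to-end orchestration: data prep -> per-subset per-species selection ->
# variance partition -> segregation -> competition, with CSV reports and a
# machine-readable run log of every automated decision.

#' Pipeline run configuration
#'
#' @param input path to a transect CSV, or `NULL` to simulate.
#' @param sim a [sim_config()] used when `input` is `NULL`.
#' @param predictors candidate habitat predictors.
#' @param segregation_predictors candidates for the LOW/HIGH stratum models;
#'   defaults to `predictors` without `elevation` (the stratifying variable).
#' @param elevation_cut LOW/HIGH threshold in m (default 1300).
#' @param alpha significance level (default 0.05).
#' @param delta_aicc competing-set threshold (default 2).
#' @param averaging `"full"` or `"conditional"` coefficient averaging.
#' @param convention distance convention, see [weighted_distance()].
#' @param enumeration_random_intercept `"auto"` (follow the per-subset
#'   cascade), `"year"` or `"none"`, for the subset enumeration.
#' @param jackknife run the LOW x HIGH jackknife (default TRUE).
#' @param jackknife_refit rerun selection within each deletion (default
#'   TRUE).
#' @param jackknife_random_intercept random-intercept structure inside the
#'   jackknife deletions; default `"none"` for tractability (a documented
#'   scale-down; set `"year"` to match the main fits).
#' @param n_boot parametric-bootstrap draws for r2 CIs (0 skips CIs).
#' @param nodes quadrature nodes.
#' @param seed RNG seed for simulation and bootstrap.
#' @param outdir output directory for the report files.
#' @return a `habseg_runconfig` list.
#' @export
run_config <- function(input = NULL, sim = NULL,
                       predictors = habitat_variables(),
                       segregation_predictors = NULL,
                       elevation_cut = 1300, alpha = 0.05, delta_aicc = 2,
                       averaging = "full", convention = "mean_w",
                       enumeration_random_intercept = "auto",
                       jackknife = TRUE, jackknife_refit = TRUE,
                       jackknife_random_intercept = "none",
                       n_boot = 0, nodes = 15, seed = 1, outdir = NULL) {
  if (is.null(input) && is.null(sim))
    stop_domain("provide `input` or `sim`")
  check_number(elevation_cut, "elevation_cut", lower = 0)
  check_number(alpha, "alpha", lower = 1e-12, upper = 1)
  check_number(delta_aicc, "delta_aicc", lower = 1e-12)
  if (is.null(segregation_predictors))
    segregation_predictors <- setdiff(predictors, "elevation")
  structure(list(input = input, sim = sim, predictors = predictors,
                 segregation_predictors = segregation_predictors,
                 elevation_cut = elevation_cut, alpha = alpha,
                 delta_aicc = delta_aicc, averaging = averaging,
                 convention = convention,
                 enumeration_random_intercept = enumeration_random_intercept,
                 jackknife = jackknife, jackknife_refit = jackknife_refit,
                 jackknife_random_intercept = jackknife_random_intercept,
                 n_boot = n_boot, nodes = nodes, seed = as.integer(seed),
                 outdir = outdir), class = "habseg_runconfig")
}

#' Validate an input CSV without running the analysis
#'
#' @param path CSV path.
#' @return list with `ok` and row-level `errors` (see
#'   [validate_transects()]).
#' @export
validate_input <- function(path) {
  if (!file.exists(path)) stop_domain("cannot read ", path)
  validate_transects(read.csv(path, stringsAsFactors = FALSE))
}

drop_constant <- function(data, vars, log) {
  keep <- vars[vapply(vars, function(v) sd(data[[v]]) > 0, logical(1))]
  dropped <- setdiff(vars, keep)
  if (length(dropped))
    log(paste("dropped constant predictors:", paste(dropped, collapse = ", ")))
  keep
}

analyze_subset <- function(sub, subset_name, species, config, log) {
  vars <- drop_constant(sub, config$predictors, log)
  sub <- standardize_predictors(sub, vars)
  spec0 <- count_model_spec(species, vars, family = "poisson",
                            random_intercept = "year")
  cascade <- select_family_and_structure(spec0, sub, alpha = config$alpha,
                                         nodes = config$nodes)
  for (d in cascade$decisions)
    log(sprintf("[%s/%s] %s", subset_name, species, d))
  re <- switch(config$enumeration_random_intercept,
               auto = cascade$spec$random_intercept,
               config$enumeration_random_intercept)
  ranking <- enumerate_and_rank(species, vars, sub,
                                family = cascade$spec$family,
                                random_intercept = re, nodes = config$nodes)
  cs <- competing_set(ranking, delta = config$delta_aicc)
  best <- best_significant_model(ranking, alpha = config$alpha,
                                 delta = config$delta_aicc,
                                 nodes = config$nodes)
  for (d in best$path) log(sprintf("[%s/%s] %s", subset_name, species, d))
  avg <- average_coefficients(cs, mode = config$averaging, variables = vars)
  fit <- best$fit
  terms <- spec_terms(fit$spec)
  chis <- attr(best$pvalues, "statistic")
  best_rows <- if (length(terms)) data.frame(
    subset = subset_name, species = species, term = terms,
    estimate = unname(fit$coefficients[terms]),
    se = unname(fit$se[terms]),
    statistic = unname(chis[terms]),
    p.value = unname(best$pvalues[terms]),
    partial_r2 = vapply(terms, function(tm)
      partial_r2(fit, tm, nodes = config$nodes), numeric(1)),
    stringsAsFactors = FALSE) else NULL
  r2 <- model_r2(fit)
  ci <- if (config$n_boot >= 100) {
    out <- r2_ci(fit, n_boot = config$n_boot, seed = config$seed,
                 nodes = config$nodes)
    c(out$lower, out$upper)
  } else c(NA_real_, NA_real_)
  list(fit = fit, ranking = ranking, competing = cs,
       best_rows = best_rows,
       averaged = data.frame(subset = subset_name, species = species,
                             avg, stringsAsFactors = FALSE),
       model_r2 = r2, r2_ci = ci, data = sub)
}

#' Run the full analysis
#'
#' Executes data prep, the collinearity screen, per-subset (ALL, LOW, HIGH,
#' ODD, EVEN) per-species model selection, variance partitioning, the
#' LOW-vs-HIGH segregation jackknife, the rank-sum abundance comparisons and
#' the two directed competition models. When `config$outdir` is set, writes
#' `best_models.csv`, `averaged_coefficients.csv`, `distances.csv`,
#' `competition.csv` and `run_log.json`. Identical config and seed give
#' identical outputs.
#'
#' @param config a [run_config()].
#' @return `habseg_run` list with all stage results and the decision log.
#' @export
run_habitat_analysis <- function(config) {
  set.seed(config$seed)
  log_lines <- character(0)
  log <- function(msg) log_lines <<- c(log_lines, msg)

  data <- if (!is.null(config$input)) read_transects(config$input)
          else generate_dataset(config$sim)
  v <- validate_transects(data)
  if (!v$ok)
    stop_domain("input validation failed:\n  ",
                paste(head(v$errors, 10), collapse = "\n  "))
  log(sprintf("loaded %d transects", nrow(data)))

  coll <- collinearity_screen(data[, config$predictors])
  log(sprintf("collinearity screen: max |rho| = %.3f (%s), max VIF = %.2f (%s)",
              coll$max_abs_rho, if (coll$pass_rho) "pass" else "FAIL",
              max(coll$vif), if (coll$pass_vif) "pass" else "FAIL"))

  elev <- split_by_elevation(data, config$elevation_cut)
  par <- split_by_year_parity(data)
  subsets <- list(all = data, low = elev$low, high = elev$high,
                  odd = par$odd, even = par$even)
  log(sprintf("splits: low %d / high %d, odd %d / even %d",
              nrow(elev$low), nrow(elev$high), nrow(par$odd), nrow(par$even)))

  fits <- list()
  best_rows <- list()
  avg_rows <- list()
  for (sn in names(subsets)) {
    for (sp in c("af", "cg")) {
      res <- analyze_subset(subsets[[sn]], sn, sp, config, log)
      fits[[paste(sn, sp, sep = ".")]] <- res
      best_rows[[paste(sn, sp)]] <- res$best_rows
      avg_rows[[paste(sn, sp)]] <- res$averaged
    }
  }
  best_tab <- do.call(rbind, best_rows[!vapply(best_rows, is.null, TRUE)])
  avg_tab <- do.call(rbind, avg_rows)

  partition <- contrast_partition(fits[["all.af"]]$fit, fits[["all.cg"]]$fit,
                                  alpha = config$alpha, nodes = config$nodes)
  log(sprintf("contrasting share: af %.1f%%, cg %.1f%%",
              partition$af$share, partition$cg$share))

  wil <- list()
  for (sp in c("af", "cg")) {
    rate <- trapping_rate(data[[paste0("count_", sp)]], data$effort)
    grp_e <- split_by_elevation(cbind(data, rate = rate), config$elevation_cut)
    grp_y <- split_by_year_parity(cbind(data, rate = rate))
    wil[[paste0(sp, "_low_vs_high")]] <-
      wilcoxon_rank_sum(grp_e$low$rate, grp_e$high$rate)
    wil[[paste0(sp, "_odd_vs_even")]] <-
      wilcoxon_rank_sum(grp_y$odd$rate, grp_y$even$rate)
  }

  seg <- NULL
  seg_test <- NULL
  if (config$jackknife) {
    seg <- jackknife_distances(
      data, config$segregation_predictors, cut = config$elevation_cut,
      convention = config$convention,
      random_intercept = config$jackknife_random_intercept,
      nodes = config$nodes, delta = config$delta_aicc,
      mode = config$averaging, refit_selection = config$jackknife_refit)
    seg_test <- jackknife_ci_and_test(seg)
    log(sprintf("segregation: d_low %.3f, d_high %.3f, %d pairs, t %.2f",
                seg$d_low, seg$d_high, seg$n_pairs, seg_test$t))
  }

  comp_af <- fit_competition_model(fits[["all.af"]]$fit, "cg",
                                   alpha = config$alpha, nodes = config$nodes)
  comp_cg <- fit_competition_model(fits[["all.cg"]]$fit, "af",
                                   alpha = config$alpha, nodes = config$nodes)
  asym <- asymmetry_report(comp_af, comp_cg)
  log(sprintf("competition: %s%s", asym$label,
              if (!is.na(asym$suppressed))
                paste0(" (suppressed: ", asym$suppressed, ")") else ""))

  run <- structure(list(
    config = config, data = data, collinearity = coll, fits = fits,
    best_models = best_tab, averaged = avg_tab, partition = partition,
    wilcoxon = wil, segregation = seg, segregation_test = seg_test,
    competition = list(af_response = comp_af, cg_response = comp_cg,
                       asymmetry = asym$label, suppressed = asym$suppressed),
    log = log_lines), class = "habseg_run")
  if (!is.null(config$outdir)) write_run_reports(run, config$outdir)
  run
}

write_run_reports <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$best_models, file.path(outdir, "best_models.csv"),
            row.names = FALSE)
  write.csv(run$averaged, file.path(outdir, "averaged_coefficients.csv"),
            row.names = FALSE)
  seg <- run$segregation
  st <- run$segregation_test
  dist_tab <- if (!is.null(seg)) data.frame(
    stratum = c("low", "high"),
    point_distance = c(seg$d_low, seg$d_high),
    jackknife_mean = c(st$mean_low, st$mean_high),
    ci_lower = c(st$ci_low[1], st$ci_high[1]),
    ci_upper = c(st$ci_low[2], st$ci_high[2]),
    n_pairs = seg$n_pairs, t = st$t, df = st$df, p = st$p.value)
  else data.frame()
  write.csv(dist_tab, file.path(outdir, "distances.csv"), row.names = FALSE)
  cmp <- run$competition
  comp_tab <- do.call(rbind, lapply(list(cmp$af_response, cmp$cg_response),
    function(r) data.frame(
      focal = r$focal, competitor = r$competitor, b = r$b, se = r$se,
      statistic = r$lr$statistic, df = r$lr$df, p = r$lr$p.value,
      share = r$share, direction = r$direction)))
  write.csv(comp_tab, file.path(outdir, "competition.csv"), row.names = FALSE)
  logobj <- list(
    seed = run$config$seed,
    alpha = run$config$alpha, delta_aicc = run$config$delta_aicc,
    elevation_cut = run$config$elevation_cut,
    averaging = run$config$averaging, convention = run$config$convention,
    collinearity = list(max_abs_rho = run$collinearity$max_abs_rho,
                        max_vif = max(run$collinearity$vif)),
    wilcoxon = lapply(run$wilcoxon, function(w)
      list(U = w$statistic, p = w$p.value)),
    competition_asymmetry = cmp$asymmetry,
    decisions = run$log)
  jsonlite::write_json(logobj, file.path(outdir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
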