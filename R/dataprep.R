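# Reading, validating, standardising and splitting transect tables.

#' Trapping rate per 100 trap-nights
#'
#' @param count captured individuals (recaptures excluded), nonnegative.
#' @param effort trap-nights, >= 1.
#' @return `100 * count / effort`, vectorised.
#' @export
trapping_rate <- function(count, effort) {
  if (any(!is.finite(effort)) || any(effort < 1))
    stop_domain("`effort` must be >= 1 trap-night")
  if (any(!is.finite(count)) || any(count < 0))
    stop_domain("`count` must be a nonnegative number")
  100 * count / effort
}

#' z-score a numeric vector
#'
#' Centres and rescales to mean 0 and sample SD 1 (n - 1 denominator).
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return list with `z`, `mean`, `sd`.
#' @export
zscore <- function(x) {
  if (length(x) < 2L) stop_domain("zscore needs at least 2 values")
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop_domain("degenerate predictor: zero variance")
  list(z = (x - m) / s, mean = m, sd = s)
}

#' Standardise predictor columns in place
#'
#' Replaces each named column by its z-score; the centre/scale used are kept
#' in the `"scaling"` attribute so the transform can be inverted or reapplied
#' to new data.
#'
#' @param data data.frame.
#' @param vars columns to standardise.
#' @return `data` with the columns standardised.
#' @export
standardize_predictors <- function(data, vars) {
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop_domain("missing predictor columns: ", paste(miss, collapse = ", "))
  sc <- list()
  for (v in vars) {
    zs <- zscore(data[[v]])
    data[[v]] <- zs$z
    sc[[v]] <- c(mean = zs$mean, sd = zs$sd)
  }
  attr(data, "scaling") <- sc
  data
}

#' Collinearity screen: Spearman matrix and VIF
#'
#' Spearman correlations use midranks for ties. VIF_j = 1 / (1 - R^2_j) from
#' an ordinary least-squares regression of predictor j on the others;
#' perfectly collinear predictors get an infinite VIF and a fail flag rather
#' than an error.
#'
#' @param data data.frame or matrix of predictors (>= 2 columns, more rows
#'   than columns).
#' @param rho_threshold flag pairs with |rho| above this (default 0.6).
#' @param vif_threshold flag predictors with VIF at or above this (default 5).
#' @return `habseg_collinearity` list: `rho`, `max_abs_rho`, `vif`,
#'   `pass_rho`, `pass_vif`.
#' @export
collinearity_screen <- function(data, rho_threshold = 0.6, vif_threshold = 5) {
  X <- as.matrix(data)
  p <- ncol(X)
  if (p < 2L) stop_domain("need at least 2 predictors")
  if (nrow(X) <= p) stop_domain("need more rows than predictors for VIF")
  rho <- cor(X, method = "spearman")
  vif <- vapply(seq_len(p), function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    fit <- .lm.fit(Z, yj)
    r2 <- 1 - sum(fit$residuals^2) / sum((yj - mean(yj))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  off <- abs(rho[upper.tri(rho)])
  structure(list(
    rho = rho, max_abs_rho = if (length(off)) max(off) else 0,
    vif = vif,
    pass_rho = (if (length(off)) max(off) else 0) <= rho_threshold,
    pass_vif = all(vif < vif_threshold)), class = "habseg_collinearity")
}

#' Split transects at an elevation cut
#'
#' LOW is elevation at or below the cut, HIGH strictly above; the partition
#' is exhaustive and disjoint.
#'
#' @param records transect data.frame with an `elevation` column.
#' @param cut elevation threshold in m (default 1300).
#' @return list with `low` and `high` data.frames.
#' @export
split_by_elevation <- function(records, cut = 1300) {
  if (is.null(records$elevation)) stop_domain("`elevation` column required")
  low <- records$elevation <= cut
  list(low = records[low, , drop = FALSE],
       high = records[!low, , drop = FALSE])
}

#' Split transects by survey-year parity
#'
#' @param records transect data.frame with a `year` column.
#' @return list with `odd` and `even` data.frames.
#' @export
split_by_year_parity <- function(records) {
  if (is.null(records$year)) stop_domain("`year` column required")
  odd <- records$year %% 2 == 1
  list(odd = records[odd, , drop = FALSE],
       even = records[!odd, , drop = FALSE])
}

#' Validate a transect table
#'
#' Checks the schema and row-level range invariants: effort >= 1, percent
#' covers in [0, 100], moisture in 1..4, rocks and logs in 0..4, counts
#' nonnegative integers, no missing values.
#'
#' @param data data.frame.
#' @return list with `ok` (logical) and `errors` (character vector naming
#'   row and field for each violation).
#' @export
validate_transects <- function(data) {
  errors <- character(0)
  need <- transect_columns()
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    return(list(ok = FALSE,
                errors = paste0("missing column: ", miss)))
  }
  num <- setdiff(need, c("transect_id", "site_id"))
  for (v in num) {
    bad <- which(!is.finite(as.numeric(data[[v]])))
    if (length(bad))
      errors <- c(errors, paste0("row ", bad, ": ", v, " missing/non-numeric"))
  }
  if (length(errors)) return(list(ok = FALSE, errors = errors))
  rule <- function(flag, field, msg) {
    bad <- which(flag)
    if (length(bad))
      errors <<- c(errors, paste0("row ", bad, ": ", field, " ", msg))
  }
  rule(data$effort < 1, "effort", "must be >= 1")
  for (v in c("hcov", "scov", "tcov", "con"))
    rule(data[[v]] < 0 | data[[v]] > 100, v, "must be in [0, 100]")
  rule(!data$moist %in% 1:4, "moist", "must be in 1..4")
  rule(!data$rocks %in% 0:4, "rocks", "must be in 0..4")
  rule(!data$logs %in% 0:4, "logs", "must be in 0..4")
  for (v in c("count_af", "count_cg"))
    rule(data[[v]] < 0 | data[[v]] != round(data[[v]]), v,
         "must be a nonnegative integer")
  list(ok = length(errors) == 0L, errors = errors)
}

#' Read a transect CSV
#'
#' Comma-separated, UTF-8, header row mandatory, columns as in
#' [transect_columns()]. Rows with missing values are rejected (no
#' imputation).
#'
#' @param path file path.
#' @return validated data.frame.
#' @export
read_transects <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  v <- validate_transects(df)
  if (!v$ok)
    stop_domain("invalid transect table ", path, ":\n  ",
                paste(head(v$errors, 10), collapse = "\n  "))
  df[, transect_columns()]
}

#' Write a transect CSV
#'
#' @param data transect data.frame.
#' @param path file path.
#' @export
write_transects <- function(data, path) {
  write.csv(data[, transect_columns()], path, row.names = FALSE,
            quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Share of total captures taken by a set of species
#'
#' @param counts per-species capture totals.
#' @param total total individuals captured across all species.
#' @return percentage `100 * sum(counts) / total`.
#' @export
capture_share <- function(counts, total) {
  check_number(total, "total", lower = 1)
  100 * sum(counts) / total
}
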