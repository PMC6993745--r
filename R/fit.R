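## The SCA engine: standardized OLS per specification, curve assembly,
## summaries and effect translations.
##
## Fitting contract: rows with any missing required variable are dropped
## (listwise deletion); outcome, technology predictor and continuous
## covariates are z-scored on the analysed rows; factor covariates (NVQ)
## enter as dummies with the lowest level as reference; classical OLS
## standard errors; two-sided coefficient t-test. Dichotomous technology
## predictors are z-scored like continuous ones so every specification's
## coefficient lives on one standardized axis.

# Core standardized OLS. Returns the coefficient on `predictor` with
# classical SE/p, the analysed n and R^2. Signals degenerate / insufficient
# conditions instead of guessing.
fit_standardized <- function(df, outcome, predictor, cov_cols, alpha,
                             spec_id = NA_character_) {
  need <- c(outcome, predictor, cov_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    validation_error(paste("data lacks column(s):",
                           paste(missing_cols, collapse = ", ")))
  sub <- df[, need, drop = FALSE]
  cc <- complete.cases(sub)
  sub <- sub[cc, , drop = FALSE]
  n <- nrow(sub)
  if (n < 3) insufficient_error("fewer than 3 complete rows")

  y_raw <- as.numeric(sub[[outcome]])
  x_raw <- as.numeric(sub[[predictor]])
  if (sd(y_raw) == 0) degenerate_error("outcome has zero variance")
  if (sd(x_raw) == 0) degenerate_error("predictor has zero variance")

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- cbind(X, tech = zscore(x_raw))
  for (cv in cov_cols) {
    v <- sub[[cv]]
    if (is.factor(v)) {
      v <- droplevels(v)
      if (nlevels(v) > 1) {
        mm <- model.matrix(~v)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(v)[-1])
        X <- cbind(X, mm)
      }
    } else {
      v <- as.numeric(v)
      if (sd(v) > 0) X <- cbind(X, zscore(v))
      else next  # constant covariate carries no information
      colnames(X)[ncol(X)] <- cv
    }
  }
  y <- zscore(y_raw)
  if (n <= ncol(X))
    insufficient_error("n does not exceed the number of parameters")

  fit <- stats::lm.fit(X, y)
  r <- fit$rank
  if (is.na(fit$coefficients[["tech"]]))
    degenerate_error("technology predictor is collinear with the controls")
  piv <- fit$qr$pivot[seq_len(r)]
  R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
  xtx_inv <- chol2inv(R)
  dfree <- n - r
  sigma2 <- sum(fit$residuals^2) / dfree
  se_piv <- sqrt(diag(xtx_inv) * sigma2)
  se <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  se[piv] <- se_piv
  beta <- unname(fit$coefficients[["tech"]])
  se_b <- unname(se[["tech"]])
  tval <- beta / se_b
  p <- 2 * pt(-abs(tval), dfree)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)

  structure(list(spec_id = spec_id, beta = beta, se = se_b, p = p,
                 n = n, r2 = r2, significant = p < alpha, alpha = alpha,
                 status = "ok"),
            class = "spec_result")
}

spec_fields <- function(spec) {
  if (is.data.frame(spec)) spec <- as.list(spec[1, ])
  for (f in c("day_type", "sleep_measure", "tech_measure", "control_set"))
    if (is.null(spec[[f]])) validation_error(paste("spec lacks field", f))
  if (!spec$day_type %in% day_types ||
      !spec$sleep_measure %in% sleep_measures ||
      !spec$tech_measure %in% tech_measures ||
      !spec$control_set %in% control_sets)
    validation_error("spec field outside its enumeration")
  if (is.null(spec$spec_id))
    spec$spec_id <- paste(spec$day_type, spec$sleep_measure,
                          spec$tech_measure, ctrl_abbrev[spec$control_set],
                          sep = ".")
  spec
}

#' Fit one specification
#'
#' Standardized OLS of the chosen sleep measure on the chosen technology
#' measure with the chosen control set, on the rows of the chosen day type.
#'
#' @param data Derived-measures table from [derive_measures()].
#' @param spec A row of [build_grid()] (or a list with the four decision
#'   fields).
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `spec_result`: `beta`, `se`, `p`, `n`, `r2`, `significant`,
#'   `status`.
#' @export
fit_spec <- function(data, spec, alpha = 0.05) {
  spec <- spec_fields(spec)
  d <- data[data$day_type == spec$day_type, , drop = FALSE]
  res <- fit_standardized(d, outcome = spec$sleep_measure,
                          predictor = spec$tech_measure,
                          cov_cols = covariate_sets()[[spec$control_set]],
                          alpha = alpha, spec_id = spec$spec_id)
  res
}

#' @export
print.spec_result <- function(x, ...) {
  cat(sprintf("<spec_result %s> beta = %.4f (SE %.4f), p = %.3g, n = %d, R2 = %.3f\n",
              x$spec_id, x$beta, x$se, x$p, x$n, x$r2))
  invisible(x)
}

#' Run the full specification curve analysis
#'
#' Fits every specification in the grid and assembles the curve ranked by the
#' standardized coefficient. Degenerate or data-starved specifications are
#' recorded with an explicit `status` code, never dropped silently.
#'
#' @inheritParams fit_spec
#' @param grid An `sca_grid` from [build_grid()] (possibly subset).
#' @param alpha Significance level used for the `significant` flag.
#' @return Object of class `sca_curve`: list with `results` (one row per
#'   specification, ranked by `beta`) and `alpha`.
#' @export
run_sca <- function(data, grid, alpha = 0.05) {
  if (is.null(grid) || nrow(grid) == 0)
    validation_error("specification grid is empty")
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    r <- tryCatch(
      fit_spec(data, row, alpha),
      sleepsca_degenerate_error = function(e)
        list(spec_id = row$spec_id, beta = NA_real_, se = NA_real_,
             p = NA_real_, n = NA_integer_, r2 = NA_real_,
             significant = NA, status = "degenerate"),
      sleepsca_insufficient_error = function(e)
        list(spec_id = row$spec_id, beta = NA_real_, se = NA_real_,
             p = NA_real_, n = NA_integer_, r2 = NA_real_,
             significant = NA, status = "insufficient_data")
    )
    res[[i]] <- data.frame(
      spec_id = row$spec_id, day_type = row$day_type,
      sleep_measure = row$sleep_measure, tech_measure = row$tech_measure,
      control_set = row$control_set,
      beta = r$beta, se = r$se, p = r$p, n = as.integer(r$n %||% NA),
      r2 = r$r2, significant = r$significant, status = r$status,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  ord <- order(results$beta, na.last = TRUE)
  results <- results[ord, ]
  results$rank <- seq_len(nrow(results))
  rownames(results) <- NULL
  structure(list(results = results, alpha = alpha), class = "sca_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sca_curve <- function(x, ...) {
  ok <- x$results[x$results$status == "ok", ]
  cat(sprintf("<sca_curve> %d specifications (%d fitted), alpha = %g\n",
              nrow(x$results), nrow(ok), x$alpha))
  if (nrow(ok) > 0)
    cat(sprintf("  beta range [%.3f, %.3f], median %.3f, %d significant\n",
                min(ok$beta), max(ok$beta), median(ok$beta),
                sum(ok$significant)))
  invisible(x)
}

#' Median standardized coefficient over a subset of the curve
#'
#' @param curve An `sca_curve`.
#' @param ... Named filters over the decision fields (as in [subset_grid()]).
#' @param predicate Optional predicate function on the results data frame.
#' @return Median of `beta` over the selected, successfully fitted
#'   specifications.
#' @export
median_beta <- function(curve, ..., predicate = NULL) {
  res <- subset_grid(curve$results, ..., predicate = predicate)
  res <- res[res$status == "ok", , drop = FALSE]
  if (nrow(res) == 0) validation_error("selection contains no fitted specs")
  median(res$beta)
}

#' Summarise the curve by an analytical decision
#'
#' @param curve An `sca_curve`.
#' @param by One of `day_type`, `sleep_measure`, `tech_measure`,
#'   `control_set`.
#' @return Data frame of per-group median beta, n of specs and significant
#'   count.
#' @export
summarize_curve <- function(curve,
                            by = c("day_type", "sleep_measure",
                                   "tech_measure", "control_set")) {
  by <- match.arg(by)
  res <- curve$results[curve$results$status == "ok", ]
  groups <- split(res, res[[by]])
  out <- data.frame(
    group = names(groups),
    median_beta = vapply(groups, function(g) median(g$beta), numeric(1)),
    n_specs = vapply(groups, nrow, integer(1)),
    n_significant = vapply(groups, function(g) sum(g$significant),
                           integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  names(out)[1] <- by
  out
}

#' Paired comparison of weekday and weekend coefficients
#'
#' Pairs each weekday specification with the weekend specification sharing
#' its sleep measure, technology measure and control set, and applies a
#' paired two-sided t-test to the coefficient differences (weekday minus
#' weekend). Zero variance of the differences is reported as `t = 0`,
#' `p = 1`.
#'
#' @param curve An `sca_curve` covering both day types with matched
#'   specifications.
#' @return List of class `sca_day_comparison`: `t_statistic`, `df`, `p`,
#'   `mean_difference`, `n_pairs`.
#' @export
compare_day_types <- function(curve) {
  res <- curve$results[curve$results$status == "ok", ]
  key <- function(d) paste(d$sleep_measure, d$tech_measure, d$control_set,
                           sep = "|")
  wd <- res[res$day_type == "weekday", ]
  we <- res[res$day_type == "weekend", ]
  wd_k <- key(wd); we_k <- key(we)
  if (nrow(wd) == 0 || nrow(we) == 0 || !setequal(wd_k, we_k) ||
      anyDuplicated(wd_k) || anyDuplicated(we_k))
    validation_error("weekday and weekend specifications are not matched")
  diffs <- wd$beta[order(wd_k)] - we$beta[order(we_k)]
  k <- length(diffs)
  s <- sd(diffs)
  if (s == 0) {
    t <- 0; p <- 1
  } else {
    t <- mean(diffs) / (s / sqrt(k))
    p <- 2 * pt(-abs(t), k - 1)
  }
  structure(list(t_statistic = t, df = k - 1, p = p,
                 mean_difference = mean(diffs), n_pairs = k),
            class = "sca_day_comparison")
}

#' @export
print.sca_day_comparison <- function(x, ...) {
  cat(sprintf("paired t(%d) = %.3f, p = %.3g, mean diff = %.4f over %d pairs\n",
              x$df, x$t_statistic, x$p, x$mean_difference, x$n_pairs))
  invisible(x)
}

#' Pairwise Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations between the given variables.
#' Zero-variance variables produce `NA` entries and are listed in the
#' `flagged` attribute.
#'
#' @param data Data frame.
#' @param vars Character vector of (at least two) column names.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data, vars) {
  if (length(vars) < 2) validation_error("need at least two variables")
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0)
    validation_error(paste("data lacks column(s):",
                           paste(missing_cols, collapse = ", ")))
  m <- suppressWarnings(
    cor(as.data.frame(lapply(data[, vars, drop = FALSE], as.numeric)),
        use = "pairwise.complete.obs"))
  diag(m) <- 1
  flagged <- vars[vapply(vars, function(v)
    sd(as.numeric(data[[v]]), na.rm = TRUE) == 0, logical(1))]
  attr(m, "flagged") <- flagged
  m
}

#' Sleep-difficulty regressions
#'
#' Standardized OLS of a sleep-difficulty item (time to fall asleep, or
#' night waking) on the retrospective screen composite with the full (`all`)
#' covariate set. The difficulty items are day-agnostic, so each person
#' contributes one row.
#'
#' @param data Derived-measures table.
#' @param outcome `"fall_asleep_time"` or `"night_waking"`.
#' @param alpha Significance level.
#' @return A `spec_result`.
#' @export
difficulties_regression <- function(data,
                                    outcome = c("fall_asleep_time",
                                                "night_waking"),
                                    alpha = 0.05) {
  outcome <- match.arg(outcome)
  d <- data[data$day_type == "weekday", , drop = FALSE]  # one row per person
  fit_standardized(d, outcome = outcome, predictor = "time_spent_retro",
                   cov_cols = covariate_sets()[["all"]], alpha = alpha,
                   spec_id = paste0("difficulties.", outcome))
}

#' Translate a raw hours coefficient into minutes and seconds
#'
#' For regressions with an hours-scaled outcome, converts an unstandardized
#' coefficient into the sleep-time change per unit of the predictor,
#' decomposed into whole minutes and seconds (rounded to the nearest second);
#' the sign is reported separately.
#'
#' @param raw_coef Unstandardized coefficient (hours per unit predictor).
#' @return List of class `sca_minutes`: `minutes`, `seconds`, `sign`,
#'   `total_minutes`.
#' @examples
#' coef_to_minutes(-0.15472)  # 9 min 17 s less sleep
#' @export
coef_to_minutes <- function(raw_coef) {
  total_sec <- round(abs(raw_coef) * 3600)
  structure(list(minutes = total_sec %/% 60, seconds = total_sec %% 60,
                 sign = sign(raw_coef), total_minutes = abs(raw_coef) * 60),
            class = "sca_minutes")
}

#' @export
print.sca_minutes <- function(x, ...) {
  cat(sprintf("%s%d min %d s\n", if (x$sign < 0) "-" else "",
              x$minutes, x$seconds))
  invisible(x)
}
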