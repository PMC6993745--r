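## Percentile bootstrap over the whole specification curve.
##
## Each replicate resamples participants (not rows) with replacement at the
## original cohort size and re-runs every specification on the resampled
## table, so the cross-specification correlation of the curve is preserved.

#' Bootstrap the specification curve
#'
#' For each of `n_reps` replicates, resamples persons with replacement,
#' re-runs the full SCA, and records every coefficient and the median
#' summaries. Percentile intervals at `ci_level` are returned per
#' specification and for the overall / per-day-type median beta.
#' Deterministic for a fixed `seed`.
#'
#' @param data Derived-measures table from [derive_measures()].
#' @param grid Specification grid.
#' @param n_reps Number of bootstrap replicates (>= 1; 500 for a full run).
#' @param seed Optional integer seed.
#' @param ci_level Confidence level (default 0.95).
#' @param alpha Significance level passed through to the fits.
#' @return Object of class `sca_boot`: `ci` (per-spec lower/upper),
#'   `median_ci` (overall and per day type), the replicate beta matrix
#'   `betas` (`n_reps` x specs), and the settings.
#' @export
bootstrap_sca <- function(data, grid, n_reps = 500, seed = NULL,
                          ci_level = 0.95, alpha = 0.05) {
  if (!is.numeric(n_reps) || n_reps < 1)
    config_error("n_reps must be a positive integer")
  if (ci_level <= 0 || ci_level >= 1)
    config_error("ci_level must lie in (0, 1)")
  if (is.null(grid) || nrow(grid) == 0)
    validation_error("specification grid is empty")
  if (!is.null(seed)) set.seed(seed)

  persons <- unique(data$person_id)
  rows_by_person <- split(seq_len(nrow(data)), data$person_id)
  nspec <- nrow(grid)
  betas <- matrix(NA_real_, n_reps, nspec,
                  dimnames = list(NULL, grid$spec_id))
  med_overall <- numeric(n_reps)
  med_day <- matrix(NA_real_, n_reps, 2, dimnames = list(NULL, day_types))

  for (b in seq_len(n_reps)) {
    ids <- sample(persons, length(persons), replace = TRUE)
    idx <- unlist(rows_by_person[ids], use.names = FALSE)
    dat_b <- data[idx, , drop = FALSE]
    curve_b <- run_sca(dat_b, grid, alpha)
    res_b <- curve_b$results
    betas[b, ] <- res_b$beta[match(grid$spec_id, res_b$spec_id)]
    ok <- res_b$status == "ok"
    med_overall[b] <- if (any(ok)) median(res_b$beta[ok]) else NA_real_
    for (d in day_types) {
      sel <- ok & res_b$day_type == d
      if (any(sel)) med_day[b, d] <- median(res_b$beta[sel])
    }
  }

  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  qfun <- function(v) quantile(v, probs, na.rm = TRUE, names = FALSE)
  ci <- t(apply(betas, 2, qfun))
  ci <- data.frame(spec_id = grid$spec_id, ci_lower = ci[, 1],
                   ci_upper = ci[, 2], stringsAsFactors = FALSE)
  rownames(ci) <- NULL
  med_list <- list(overall = qfun(med_overall))
  for (d in day_types) med_list[[d]] <- qfun(med_day[, d])
  median_ci <- data.frame(
    subset = names(med_list),
    ci_lower = vapply(med_list, `[`, numeric(1), 1),
    ci_upper = vapply(med_list, `[`, numeric(1), 2),
    stringsAsFactors = FALSE)
  rownames(median_ci) <- NULL

  structure(list(ci = ci, median_ci = median_ci, betas = betas,
                 n_reps = as.integer(n_reps), ci_level = ci_level,
                 seed = seed, alpha = alpha),
            class = "sca_boot")
}

#' @export
print.sca_boot <- function(x, ...) {
  cat(sprintf("<sca_boot> %d replicates, %d specifications, %g%% percentile CIs\n",
              x$n_reps, ncol(x$betas), 100 * x$ci_level))
  invisible(x)
}

#' Attach bootstrap intervals to a curve
#'
#' @param curve An `sca_curve`.
#' @param boot An `sca_boot` computed on the same grid.
#' @return The curve with `ci_lower` / `ci_upper` columns merged into its
#'   results.
#' @export
add_bootstrap <- function(curve, boot) {
  res <- curve$results
  m <- match(res$spec_id, boot$ci$spec_id)
  if (anyNA(m)) validation_error("bootstrap does not cover the curve's specs")
  res$ci_lower <- boot$ci$ci_lower[m]
  res$ci_upper <- boot$ci$ci_upper[m]
  curve$results <- res
  curve$boot <- boot
  curve
}
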