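# Independent brute-force least-squares oracle (explicit normal equations),
# plus small fixture builders used across the test files.

oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- drop(beta) / se
  list(beta = unname(drop(beta)), se = unname(se),
       p = unname(2 * pt(-abs(tval), df)),
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Rebuild the fitting contract's design matrix independently of the package:
# z-scored outcome/predictor/continuous covariates, dummy-coded factors.
oracle_design <- function(df, outcome, predictor, cov_cols) {
  sub <- df[stats::complete.cases(df[, c(outcome, predictor, cov_cols)]),
            c(outcome, predictor, cov_cols), drop = FALSE]
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  X <- cbind(1, zs(as.numeric(sub[[predictor]])))
  for (cv in cov_cols) {
    v <- sub[[cv]]
    if (is.factor(v)) {
      v <- droplevels(v)
      if (nlevels(v) > 1) X <- cbind(X, stats::model.matrix(~v)[, -1])
    } else if (stats::sd(as.numeric(v)) > 0) {
      X <- cbind(X, zs(as.numeric(v)))
    }
  }
  list(y = zs(as.numeric(sub[[outcome]])), X = X)
}

# A diary day built by hand: morning sleep before `wake`, evening sleep from
# `onset`, the given digital slots, OTHER elsewhere.
make_diary <- function(onset = NULL, wake = NULL, digital = integer(0),
                       code = "DIG_TV") {
  slots <- rep("OTHER", 144)
  if (!is.null(wake) && wake > 1) slots[1:(wake - 1)] <- "SLEEP"
  if (!is.null(onset)) slots[onset:144] <- "SLEEP"
  slots[digital] <- code
  slots
}

# A small derived-measures-like table with known structure for fit tests.
make_fit_fixture <- function(n = 30, seed = 1, with_na = FALSE) {
  set.seed(seed)
  df <- data.frame(
    person_id = sprintf("F%03d", seq_len(n)),
    day_type = "weekday",
    bedtime_retro = sample(1:5, n, replace = TRUE),
    bedtime_diary = runif(n, 5, 60),
    total_sleep_retro = rnorm(n, 8.6, 1),
    participation = rbinom(n, 1, 0.8),
    bedtime_use = rbinom(n, 1, 0.5),
    time_spent_diary = rlnorm(n, 1, 0.6),
    time_spent_retro = runif(n, 1, 8),
    fall_asleep_time = sample(1:5, n, replace = TRUE),
    night_waking = sample(1:6, n, replace = TRUE),
    sex = rbinom(n, 1, 0.5),
    age = sample(13:15, n, replace = TRUE),
    mother_white = rbinom(n, 1, 0.85),
    closeness = runif(n, 1, 4),
    longterm_ill = rbinom(n, 1, 0.15),
    motivation = runif(n, 1, 4),
    word_activity = sample(0:20, n, replace = TRUE),
    nvq = factor(sample(1:5, n, replace = TRUE), levels = 1:5),
    time_with_child = sample(1:5, n, replace = TRUE),
    kessler = sample(0:24, n, replace = TRUE),
    income = rlnorm(n, 6, 0.5),
    father_household = rbinom(n, 1, 0.7),
    n_siblings = rpois(n, 1.4),
    stringsAsFactors = FALSE)
  if (with_na) {
    df$income[sample(n, 3)] <- NA
    df$nvq[sample(n, 2)] <- NA
    df$closeness[sample(n, 2)] <- NA
  }
  df
}

small_sim <- function(n = 600, seed = 11, ...) {
  generate_cohort(generator_config(n_participants = n, seed = seed, ...))
}
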