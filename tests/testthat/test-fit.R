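test_that("standardized OLS reduces to known identities", {
  df <- make_fit_fixture(n = 40, seed = 2)
  # outcome identical to predictor, no covariates: beta exactly 1
  r <- sleepsca:::fit_standardized(df, "time_spent_retro",
                                   "time_spent_retro", character(0), 0.05)
  expect_equal(r$beta, 1, tolerance = 1e-12)
  expect_equal(r$r2, 1, tolerance = 1e-12)
  # simple standardized regression equals the Pearson correlation
  r2 <- sleepsca:::fit_standardized(df, "total_sleep_retro",
                                    "time_spent_retro", character(0), 0.05)
  expect_equal(r2$beta, cor(df$total_sleep_retro, df$time_spent_retro),
               tolerance = 1e-12)
})

test_that("fit_spec matches the brute-force normal-equations oracle", {
  for (seed in 1:4) {
    df <- make_fit_fixture(n = 30 + 5 * seed, seed = seed,
                           with_na = seed %% 2 == 0)
    for (cs in c("demographics", "demographics+mother", "all")) {
      spec <- list(day_type = "weekday", sleep_measure = "total_sleep_retro",
                   tech_measure = "time_spent_diary", control_set = cs)
      got <- fit_spec(df, spec)
      od <- oracle_design(df, "total_sleep_retro", "time_spent_diary",
                          covariate_sets()[[cs]])
      want <- oracle_ols(od$y, od$X)
      expect_equal(got$beta, want$beta[2], tolerance = 1e-10)
      expect_equal(got$se, want$se[2], tolerance = 1e-10)
      expect_equal(got$p, want$p[2], tolerance = 1e-10)
      expect_equal(got$r2, want$r2, tolerance = 1e-10)
      expect_equal(got$n, length(od$y))
    }
  }
})

test_that("beta is invariant to affine rescaling of outcome and predictor", {
  df <- make_fit_fixture(n = 45, seed = 7)
  spec <- list(day_type = "weekday", sleep_measure = "bedtime_diary",
               tech_measure = "time_spent_diary",
               control_set = "demographics")
  base <- fit_spec(df, spec)$beta
  df2 <- df
  df2$bedtime_diary <- 3 + 2.5 * df$bedtime_diary
  df2$time_spent_diary <- -1 + 0.2 * df$time_spent_diary
  expect_equal(fit_spec(df2, spec)$beta, base, tolerance = 1e-10)
  df3 <- df
  df3$time_spent_diary <- -df$time_spent_diary   # negated slope flips sign
  expect_equal(fit_spec(df3, spec)$beta, -base, tolerance = 1e-10)
})

test_that("analysed n is non-increasing as covariate blocks are added", {
  sim <- small_sim(n = 900, seed = 17)
  d <- derive_measures(sim)
  ns <- vapply(c("demographics", "demographics+mother", "all"), function(cs)
    fit_spec(d, list(day_type = "weekday", sleep_measure = "bedtime_retro",
                     tech_measure = "time_spent_retro",
                     control_set = cs))$n, integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("degenerate and data-starved specifications raise typed errors", {
  df <- make_fit_fixture(n = 25, seed = 3)
  df$participation <- 1L
  spec <- list(day_type = "weekday", sleep_measure = "bedtime_diary",
               tech_measure = "participation", control_set = "demographics")
  expect_error(fit_spec(df, spec), class = "sleepsca_degenerate_error")
  tiny <- make_fit_fixture(n = 6, seed = 4)
  expect_error(fit_spec(tiny, list(day_type = "weekday",
                                   sleep_measure = "bedtime_diary",
                                   tech_measure = "time_spent_diary",
                                   control_set = "all")),
               class = "sleepsca_insufficient_error")
  expect_error(fit_spec(df, list(day_type = "weekday",
                                 sleep_measure = "bedtime_diary",
                                 tech_measure = "nonsense",
                                 control_set = "all")),
               class = "sleepsca_validation_error")
})

test_that("run_sca assembles a ranked curve and keeps failed specs visible", {
  df <- make_fit_fixture(n = 60, seed = 5)
  g1 <- subset_grid(build_grid(), day_type = "weekday",
                    sleep_measure = "bedtime_diary",
                    tech_measure = "time_spent_diary",
                    control_set = "demographics")
  c1 <- run_sca(df, g1)
  expect_equal(nrow(c1$results), 1L)
  expect_error(run_sca(df, g1[0, ]), class = "sleepsca_validation_error")

  df$participation <- 1L   # degenerate predictor for participation specs
  g <- subset_grid(build_grid(), day_type = "weekday")
  cv <- run_sca(df, g)
  res <- cv$results
  expect_equal(nrow(res), 60L)
  expect_true(all(res$status[res$tech_measure == "participation"] ==
                    "degenerate"))
  ok <- res[res$status == "ok", ]
  expect_false(is.unsorted(ok$beta))          # ranked ascending
  expect_identical(ok$significant, ok$p < cv$alpha)
})

test_that("median_beta handles subsets, medians and empty selections", {
  mk <- function(betas) {
    res <- data.frame(
      spec_id = paste0("s", seq_along(betas)),
      day_type = "weekday",
      sleep_measure = "bedtime_retro",
      tech_measure = rep(c("participation", "bedtime_use"),
                         length.out = length(betas)),
      control_set = "all", beta = betas, status = "ok",
      stringsAsFactors = FALSE)
    structure(list(results = res, alpha = 0.05), class = "sca_curve")
  }
  expect_equal(median_beta(mk(0.42)), 0.42)
  expect_equal(median_beta(mk(c(-0.1, 0, 0.1))), 0)
  expect_equal(median_beta(mk(c(-0.2, -0.1, 0.1, 0.3))), 0.0)
  cv <- mk(c(-0.3, 0.5))
  expect_equal(median_beta(cv, tech_measure = "participation"), -0.3)
  expect_error(median_beta(cv, day_type = "weekend"),
               class = "sleepsca_validation_error")
})

test_that("day-type comparison is the paired t-test over matched specs", {
  mk_curve <- function(wd, we) {
    g <- build_grid()
    res <- g
    res$beta <- NA_real_
    res$beta[res$day_type == "weekday"] <- wd
    res$beta[res$day_type == "weekend"] <- we
    res$status <- "ok"
    structure(list(results = res, alpha = 0.05), class = "sca_curve")
  }
  set.seed(6)
  b <- rnorm(60, 0, 0.1)
  eq <- compare_day_types(mk_curve(b, b))
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p, 1)
  neg <- compare_day_types(mk_curve(b - 0.05 + rnorm(60, 0, 0.01), b))
  expect_lt(neg$t_statistic, 0)
  # hand-computed paired statistic on a fixture
  wd <- c(-0.10, -0.05, 0.02, b[4:60])
  we <- c(-0.02, 0.01, 0.00, b[4:60] + rnorm(57, 0, 0.03))
  got <- compare_day_types(mk_curve(wd, we))
  dif <- wd - we
  expect_equal(got$t_statistic,
               mean(dif) / (sd(dif) / sqrt(60)), tolerance = 1e-12)
  expect_equal(got$df, 59)
  expect_equal(got$mean_difference, mean(dif), tolerance = 1e-12)
  # unmatched grids refuse to compare
  half <- mk_curve(b, b)
  half$results <- half$results[half$results$day_type == "weekday", ]
  expect_error(compare_day_types(half),
               class = "sleepsca_validation_error")
})

test_that("correlation matrix matches the covariance-ratio oracle", {
  df <- make_fit_fixture(n = 50, seed = 8)
  vars <- c("time_spent_retro", "bedtime_retro", "total_sleep_retro",
            "fall_asleep_time")
  m <- correlation_matrix(df, vars)
  expect_equal(diag(m), setNames(rep(1, 4), vars))
  expect_equal(m, t(m))
  for (i in 1:3) for (j in (i + 1):4) {
    x <- df[[vars[i]]]; y <- df[[vars[j]]]
    r_oracle <- mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
    expect_equal(unname(m[i, j]), r_oracle, tolerance = 1e-12)
  }
  df$neg <- -df$time_spent_retro
  m2 <- correlation_matrix(df, c("time_spent_retro", "neg"))
  expect_equal(unname(m2[1, 2]), -1, tolerance = 1e-12)
  df$flat <- 1
  m3 <- correlation_matrix(df, c("time_spent_retro", "flat"))
  expect_identical(attr(m3, "flagged"), "flat")
  expect_error(correlation_matrix(df, "time_spent_retro"),
               class = "sleepsca_validation_error")
})

test_that("difficulty regressions share the fitting contract", {
  r <- sleepsca:::fit_standardized(make_fit_fixture(n = 40, seed = 9),
                                   "time_spent_retro", "time_spent_retro",
                                   character(0), 0.05)
  expect_equal(r$beta, 1, tolerance = 1e-12)
  d <- derive_measures(small_sim(n = 1200, seed = 23))
  got <- difficulties_regression(d, "fall_asleep_time")
  od <- oracle_design(d[d$day_type == "weekday", ], "fall_asleep_time",
                      "time_spent_retro", covariate_sets()$all)
  want <- oracle_ols(od$y, od$X)
  expect_equal(got$beta, want$beta[2], tolerance = 1e-8)
  nul <- difficulties_regression(d, "night_waking")
  expect_lt(abs(nul$beta), 4 / sqrt(nul$n))   # null world: beta ~ 0
})

test_that("coefficients translate to minutes and seconds", {
  z <- coef_to_minutes(0)
  expect_equal(c(z$minutes, z$seconds), c(0, 0))
  m <- coef_to_minutes(-0.15472)
  expect_equal(c(m$minutes, m$seconds, m$sign), c(9, 17, -1))
  h <- coef_to_minutes(1.0)
  expect_equal(c(h$minutes, h$seconds), c(60, 0))
})
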