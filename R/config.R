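## Generator configuration: the "stated world" the synthetic cohort emulates.
##
## All ordinal items are produced by thresholding standard-normal latents at
## cutpoints solved so that the discretised distribution reproduces a target
## mean/SD (the published cohort descriptives where available). Quantities the
## source instrument does not print (wake-item marginals, item SDs, latent
## loadings) are calibrated once from the printed composite descriptives and
## documented in the methods vignette.

#' Solve category probabilities for an ordinal item
#'
#' Finds a discretised normal on categories `1..k` whose mean and standard
#' deviation match the targets: the latent N(mu, sigma) is cut at the
#' half-integer boundaries, with the open tails folded into the end
#' categories. Returns the category probabilities and the standard-normal
#' cutpoints used to threshold a unit-variance latent.
#'
#' @param k Number of categories.
#' @param mean,sd Target mean and standard deviation on the category scale.
#' @return List with `probs` (length `k`), `cutpoints` (length `k - 1`,
#'   strictly increasing, standard-normal scale), and the achieved `mean` and
#'   `sd`.
#' @export
ordinal_distribution <- function(k, mean, sd) {
  if (k < 2L) config_error("ordinal items need at least 2 categories")
  if (mean <= 1 || mean >= k) config_error("target mean outside (1, k)")
  if (sd <= 0) config_error("target sd must be positive")
  cats <- seq_len(k)
  moments <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    bounds <- c(-Inf, seq(1.5, k - 0.5), Inf)
    p <- diff(pnorm(bounds, mu, sig))
    m <- sum(p * cats)
    v <- sum(p * cats^2) - m^2
    list(p = p, mean = m, sd = sqrt(max(v, 0)))
  }
  obj <- function(par) {
    mo <- moments(par)
    (mo$mean - mean)^2 + (mo$sd - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 4000))
  mo <- moments(fit$par)
  if (abs(mo$mean - mean) > 0.01)
    warning(sprintf("ordinal calibration missed target mean by %.3f",
                    mo$mean - mean))
  cp <- qnorm(cumsum(mo$p)[-k])
  list(probs = mo$p, cutpoints = cp, mean = mo$mean, sd = mo$sd)
}

# Mean of max(round(X), 1) for X ~ N(mu, sd): the diary sleep-onset score is a
# rounded latent censored at the scale minimum (the 4 AM fallback). Solve for
# the latent mean so the observed mean hits the printed target.
onset_latent_mean <- function(target_mean, sd) {
  ks <- 1:400
  observed_mean <- function(mu) {
    p <- pnorm(ks + 0.5, mu, sd) - pnorm(ks - 0.5, mu, sd)
    sum(ks * p) + 1 * pnorm(0.5, mu, sd) + 400 * (1 - pnorm(400.5, mu, sd))
  }
  uniroot(function(mu) observed_mean(mu) - target_mean,
          c(target_mean - 5, target_mean + 5), tol = 1e-10)$root
}

default_item_targets <- function() {
  list(
    # Raw bedtime scores: the printed means (3.06 wd, 2.04 we) are for the
    # reversed item, so the raw targets are 6 - mean.
    bed_weekday  = c(k = 5, mean = 6 - 3.06, sd = 0.96),
    bed_weekend  = c(k = 5, mean = 6 - 2.04, sd = 0.93),
    # Wake items are not printed; backed out of the printed total-sleep means
    # (8.62 = 9 - 2.94 + wake_wd; 10.53 = 11 - 3.96 + wake_we).
    wake_weekday = c(k = 5, mean = 2.56, sd = 0.90),
    wake_weekend = c(k = 6, mean = 3.49, sd = 1.10),
    # Each of the four screen items targets the printed composite mean; item
    # SD 1.80 with inter-item loading 0.6 yields composite SD ~ 1.27.
    screen       = c(k = 8, mean = 4.82, sd = 1.80),
    fall_asleep  = c(k = 5, mean = 3.73, sd = 1.27),
    night_waking = c(k = 6, mean = 4.61, sd = 1.37),
    time_with_child = c(k = 5, mean = 3.00, sd = 1.00),
    closeness_close = c(k = 4, mean = 3.20, sd = 0.80),
    closeness_argue = c(k = 4, mean = 1.80, sd = 0.80),
    motiv_pos    = c(k = 4, mean = 3.10, sd = 0.80),
    motiv_neg    = c(k = 4, mean = 2.20, sd = 0.80)
  )
}

default_loadings <- function() {
  list(
    screen_item   = 0.60,   # inter-item correlation of the screen composite
    participation = 0.40,   # probit loading of participation on tech latent;
                            # daily hours ride the same latent via its
                            # conditional copula, so this also sets the
                            # tech <-> duration correlation
    abut          = 0.00,   # before-bed episode indicator: independent draw
    bed_sleep     = 0.65,   # raw bedtime item on (negated) sleep latent
    wake_sleep    = c(weekday = 0.62, weekend = 0.45),
    onset_sleep   = 0.50,   # diary onset score on sleep latent
    wake_diary    = 0.30,   # diary wake slot on (negated) sleep latent
    difficulties  = 0.40,
    # each covariate loads on exactly one of the two independent latents
    # (tech T or sleep U), so the zero-effect configuration is a true null
    # for every specification
    covariates = list(
      sex = c(T = 0.20), age = c(T = 0.10), mother_white = c(T = 0),
      income = c(T = -0.05), father_household = c(U = 0.10),
      n_siblings = c(U = -0.05), word_activity = c(U = 0.10),
      nvq = c(T = -0.10), time_with_child = c(U = 0.15),
      kessler = c(U = -0.25), closeness = c(T = -0.20),
      longterm_ill = c(U = -0.20), motivation = c(T = -0.25)
    )
  )
}

default_missingness <- function() {
  # MCAR per-item rates by covariate block; plausible survey magnitudes
  c(demographics = 0.01, family = 0.06, mother = 0.08, child = 0.05,
    screen = 0.02, sleep = 0.02)
}

zero_effects <- function() {
  eff <- lapply(day_types, function(d)
    setNames(as.list(rep(0, length(tech_measures))), tech_measures))
  setNames(eff, day_types)
}

#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the full parameter set of the generator. Defaults are
#' calibrated to the published cohort descriptives (participation 0.81/0.85,
#' time spent 3.45/4.59 h, before-bed use 0.46/0.47, screen composite 4.82,
#' total sleep 8.62/10.53 h, diary onset scores 30.22/27.74) with all true
#' effect sizes zero.
#'
#' @param n_participants Cohort size (>= 1).
#' @param diary_fraction Proportion of the cohort completing time-use diaries
#'   (default 1/3, the diary subsample share of the source cohort).
#' @param seed Optional integer seed; fixed seed gives bitwise-identical
#'   output.
#' @param true_effects Nested list `true_effects[[day_type]][[tech_measure]]`
#'   of standardized effect sizes linking each technology pathway to the
#'   latent sleep outcomes (diary onset and retrospective bedtime/total
#'   sleep). Defaults to all zero.
#' @param participation_prob Named probabilities of any digital engagement per
#'   diary day type.
#' @param digital_hours Per day type, `c(mean, sd)` of daily digital hours
#'   among participants; drawn from a log-normal matching these moments (the
#'   raw durations are strongly right-skewed).
#' @param bedtime_use_prob Marginal probability (whole diary subsample) of any
#'   digital code in the 30 minutes before sleep onset.
#' @param sleep_onset Per day type, `c(mean, sd)` of the diary sleep-onset
#'   score (1--144 scale, higher = earlier).
#' @param item_targets List of `c(k, mean, sd)` targets for the ordinal items;
#'   see [ordinal_distribution()].
#' @param loadings Latent-structure loadings; see `default_loadings()`.
#' @param missingness_rates Named per-item MCAR rates by covariate block
#'   (`demographics`, `family`, `mother`, `child`, `screen`, `sleep`).
#' @param wake_diary Per day type, `c(mean_slot, sd)` of the diary wake slot.
#' @param fallback_score Onset score assigned when a diary records no sleep
#'   onset (default 1, the scale minimum = 4 AM assumption).
#' @return Object of class `sca_config`.
#' @examples
#' cfg <- generator_config(n_participants = 500, seed = 1)
#' @export
generator_config <- function(n_participants = 10000,
                             diary_fraction = 1 / 3,
                             seed = NULL,
                             true_effects = zero_effects(),
                             participation_prob = c(weekday = 0.81,
                                                    weekend = 0.85),
                             digital_hours = list(
                               weekday = c(mean = 3.45, sd = 2.49),
                               weekend = c(mean = 4.59, sd = 2.98)),
                             bedtime_use_prob = c(weekday = 0.46,
                                                  weekend = 0.47),
                             sleep_onset = list(
                               weekday = c(mean = 30.22, sd = 14.41),
                               weekend = c(mean = 27.74, sd = 13.81)),
                             item_targets = default_item_targets(),
                             loadings = default_loadings(),
                             missingness_rates = default_missingness(),
                             wake_diary = list(
                               weekday = c(mean_slot = 19, sd = 4),
                               weekend = c(mean_slot = 28, sd = 5)),
                             fallback_score = 1) {
  if (!is.numeric(n_participants) || length(n_participants) != 1 ||
      is.na(n_participants) || n_participants < 1)
    config_error("n_participants must be a positive integer")
  n_participants <- as.integer(n_participants)
  if (!is.numeric(diary_fraction) || diary_fraction <= 0 ||
      diary_fraction > 1)
    config_error("diary_fraction must lie in (0, 1]")
  for (d in day_types) {
    p <- participation_prob[[d]]
    if (is.na(p) || p < 0 || p > 1)
      config_error("participation_prob must lie in [0, 1]")
    b <- bedtime_use_prob[[d]]
    if (is.na(b) || b < 0 || b > 1)
      config_error("bedtime_use_prob must lie in [0, 1]")
    if (p > 0 && b > p)
      config_error("bedtime_use_prob cannot exceed participation_prob")
    if (any(digital_hours[[d]] < 0))
      config_error("digital_hours parameters must be non-negative")
    if (sleep_onset[[d]][["sd"]] <= 0)
      config_error("sleep_onset sd must be positive")
  }
  if (any(missingness_rates < 0 | missingness_rates > 1))
    config_error("missingness_rates must lie in [0, 1]")
  for (d in day_types) {
    for (m in tech_measures) {
      e <- true_effects[[d]][[m]]
      if (is.null(e) || !is.finite(e))
        config_error(sprintf("true_effects[[%s]][[%s]] must be finite", d, m))
      if (abs(e) >= 1)
        config_error("standardized true effects must have |effect| < 1")
    }
  }
  if (!fallback_score %in% c(0, 1))
    config_error("fallback_score must be 0 or 1")

  # Solve the ordinal cutpoints once, at configuration time.
  items <- lapply(item_targets, function(t)
    ordinal_distribution(t[["k"]], t[["mean"]], t[["sd"]]))
  for (it in items) {
    if (is.unsorted(it$cutpoints, strictly = TRUE))
      config_error("item cutpoints must be strictly increasing")
  }

  # Latent mean of the onset score such that the rounded, floor-censored
  # score has the target mean.
  onset_mu <- vapply(day_types, function(d)
    onset_latent_mean(sleep_onset[[d]][["mean"]], sleep_onset[[d]][["sd"]]),
    numeric(1))

  structure(list(
    n_participants = n_participants,
    diary_fraction = diary_fraction,
    seed = seed,
    true_effects = true_effects,
    participation_prob = participation_prob,
    digital_hours = digital_hours,
    bedtime_use_prob = bedtime_use_prob,
    sleep_onset = sleep_onset,
    onset_latent_mu = onset_mu,
    item_targets = item_targets,
    items = items,
    loadings = loadings,
    missingness_rates = missingness_rates,
    wake_diary = wake_diary,
    fallback_score = fallback_score
  ), class = "sca_config")
}

#' @export
print.sca_config <- function(x, ...) {
  cat("<sca_config>\n")
  cat("  n_participants:", x$n_participants,
      " diary_fraction:", signif(x$diary_fraction, 3),
      " seed:", if (is.null(x$seed)) "none" else x$seed, "\n")
  eff <- unlist(x$true_effects)
  nz <- eff[eff != 0]
  if (length(nz) == 0) cat("  true effects: all zero (null world)\n")
  else cat("  nonzero effects:",
           paste(names(nz), signif(nz, 3), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# lognormal parameters matching a target mean/sd (sd 0 -> degenerate at mean)
lognormal_params <- function(mean, sd) {
  if (mean <= 0) config_error("digital hours mean must be positive")
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}
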