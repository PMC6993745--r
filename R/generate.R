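## Synthetic cohort generator.
##
## Two independent standard-normal person latents drive everything: T (tech
## propensity) and U (sleep propensity). Ordinal items are thresholded
## standard-normal latents loading on exactly one of the two; skewed
## continuous covariates use a Gaussian copula so their marginals are exact.
## Configured true effects enter additively on the latent diary onset score
## and the latent raw-bedtime item, scaled so the implied standardized
## regression coefficient of the matching specification equals the configured
## value (up to ordinal-discretisation attenuation, see the vignette).

# threshold a unit-variance latent into 1..k using solved cutpoints
threshold_item <- function(latent, item) {
  findInterval(latent, item$cutpoints) + 1L
}

# unit-variance latent loading on a driver latent
load_latent <- function(driver, loading, n) {
  if (abs(loading) >= 1) config_error("latent loadings must have |l| < 1")
  loading * driver + sqrt(1 - loading^2) * rnorm(n)
}

# covariate latent: loads on T or U per the configured link
covariate_latent <- function(name, T, U, loadings, n) {
  link <- loadings$covariates[[name]]
  if (is.null(link)) return(rnorm(n))
  driver <- if (identical(names(link), "T")) T else U
  load_latent(driver, unname(link), n)
}

binary_from_latent <- function(latent, p) as.integer(pnorm(latent) > 1 - p)

#' Generate a synthetic cohort with time-use diaries
#'
#' Draws a person-level cohort table of raw ordinal items and covariates plus
#' 144-slot time-use diaries (weekday and weekend) for the diary subsample.
#' Deterministic for a fixed `config$seed`. Item-level missingness is applied
#' at the configured MCAR rates; `person_id` and `has_diary` are never
#' missing.
#'
#' @param config An [generator_config()] object.
#' @return Object of class `sca_cohort`: a list with `cohort` (data frame of
#'   raw items) and `diaries` (list of two character matrices, one row per
#'   diary completer, 144 columns of activity codes, rownames = person_id).
#' @examples
#' sim <- generate_cohort(generator_config(n_participants = 200, seed = 42))
#' dim(sim$diaries$weekday)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sca_config"))
    config_error("config must be created by generator_config()")
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_participants
  ld <- config$loadings
  items <- config$items

  T <- rnorm(n)   # technology propensity
  U <- rnorm(n)   # sleep propensity (higher = earlier/better sleep)

  ## -- covariates ---------------------------------------------------------
  u_of <- function(name) pnorm(covariate_latent(name, T, U, ld, n))
  sex <- as.integer(u_of("sex") > 1 - 0.5009)                 # 1 = male
  age_u <- u_of("age")
  age <- 13L + findInterval(age_u, c(0.2410, 0.9865))         # 13/14/15 years
  mother_white <- as.integer(u_of("mother_white") > 1 - 0.85)
  income <- qlnorm(u_of("income"), log(400), 0.6)             # GBP / week
  father_household <- as.integer(u_of("father_household") > 1 - 0.72)
  n_siblings <- qpois(u_of("n_siblings"), 1.4)
  word_activity <- qbinom(u_of("word_activity"), 20, 0.55)
  nvq <- findInterval(u_of("nvq"),
                      cumsum(c(0.10, 0.15, 0.30, 0.30))) + 1L  # NVQ 1-5
  time_with_child <- threshold_item(
    covariate_latent("time_with_child", T, U, ld, n), items$time_with_child)
  kessler <- pmin(24L, qnbinom(u_of("kessler"), size = 1.3, mu = 3.2))
  longterm_ill <- as.integer(u_of("longterm_ill") > 1 - 0.13)

  closeness_lat <- covariate_latent("closeness", T, U, ld, n)
  close_mother <- threshold_item(load_latent(closeness_lat, 0.6, n),
                                 items$closeness_close)
  close_father <- threshold_item(load_latent(closeness_lat, 0.6, n),
                                 items$closeness_close)
  argue_mother <- threshold_item(load_latent(-closeness_lat, 0.6, n),
                                 items$closeness_argue)
  argue_father <- threshold_item(load_latent(-closeness_lat, 0.6, n),
                                 items$closeness_argue)

  motiv_lat <- covariate_latent("motivation", T, U, ld, n)
  motiv <- matrix(NA_integer_, n, 6)
  for (j in 1:2)
    motiv[, j] <- threshold_item(load_latent(motiv_lat, 0.6, n),
                                 items$motiv_pos)
  for (j in 3:6)
    motiv[, j] <- threshold_item(load_latent(-motiv_lat, 0.6, n),
                                 items$motiv_neg)

  ## -- retrospective screen items ----------------------------------------
  screen <- matrix(NA_integer_, n, 4)
  for (j in 1:4)
    screen[, j] <- threshold_item(load_latent(T, ld$screen_item, n),
                                  items$screen)
  composite <- rowMeans(screen)

  ## -- technology behaviour and effect terms per day type ----------------
  per_day <- list()
  for (d in day_types) {
    p_d <- config$participation_prob[[d]]
    lat_p <- load_latent(T, ld$participation, n)
    part <- as.integer(pnorm(lat_p) > 1 - p_d)
    # digital_hours is the distribution AMONG participants: map the
    # participation latent's conditional uniform through the target
    # log-normal (keeps the tech correlation, makes the participant-
    # conditional marginal exact)
    hp <- lognormal_params(config$digital_hours[[d]][["mean"]],
                           config$digital_hours[[d]][["sd"]])
    u_cond <- if (p_d > 0) pmin(pmax((pnorm(lat_p) - (1 - p_d)) / p_d,
                                     1e-12), 1 - 1e-12) else rep(0.5, n)
    hours <- ifelse(part == 1L,
                    qlnorm(u_cond, hp[["meanlog"]], hp[["sdlog"]]), 0)
    q_d <- if (p_d > 0) config$bedtime_use_prob[[d]] / p_d else 0
    abut <- binary_from_latent(load_latent(T, ld$abut, n), q_d)
    bu <- part * abut

    # standardized pathway quantities used for effect injection
    z_part <- if (p_d %in% c(0, 1)) rep(0, n) else
      (part - p_d) / sqrt(p_d * (1 - p_d))
    pq <- p_d * q_d
    z_bu <- if (pq %in% c(0, 1)) rep(0, n) else
      (bu - pq) / sqrt(pq * (1 - pq))
    hsd <- config$digital_hours[[d]][["sd"]]
    z_hours <- if (hsd > 0)
      ifelse(part == 1L,
             (hours - config$digital_hours[[d]][["mean"]]) / hsd, 0)
      else rep(0, n)
    z_comp <- if (sd(composite) > 0) zscore(composite) else rep(0, n)

    eff <- config$true_effects[[d]]
    E <- eff$participation * z_part + eff$bedtime_use * z_bu +
      eff$time_spent_diary * z_hours + eff$time_spent_retro * z_comp
    vE <- if (all(E == 0)) 0 else var(E)

    # diary onset score latent: mean-adjusted for rounding/censoring
    lo <- ld$onset_sleep
    w_on <- sqrt(max(0.02, 1 - lo^2 - vE))
    onset_lat <- config$onset_latent_mu[[d]] +
      config$sleep_onset[[d]][["sd"]] * (lo * U + E + w_on * rnorm(n))
    onset_score <- pmin(round(onset_lat), 138)   # slot >= 7 (5 AM)
    onset_slot <- ifelse(onset_score >= 1L, 145L - onset_score, 145L)

    # raw bedtime item: higher = later; effects enter with flipped sign so
    # the reversed (analysed) score carries the configured effect
    lb <- ld$bed_sleep
    w_bed <- sqrt(max(0.02, 1 - lb^2 - vE))
    bed <- threshold_item(-lb * U - E + w_bed * rnorm(n),
                          items[[paste0("bed_", d)]])
    lw <- ld$wake_sleep[[d]]
    wake <- threshold_item(load_latent(-U, lw, n),
                           items[[paste0("wake_", d)]])

    per_day[[d]] <- list(part = part, hours = hours, abut = abut,
                         onset_slot = onset_slot, bed = bed, wake = wake)
  }

  ## -- sleep difficulties (day-agnostic) ----------------------------------
  fall_asleep <- threshold_item(load_latent(-U, ld$difficulties, n),
                                items$fall_asleep)
  night_waking <- threshold_item(load_latent(U, ld$difficulties, n),
                                 items$night_waking)

  has_diary <- runif(n) < config$diary_fraction

  cohort <- data.frame(
    person_id = sprintf("P%06d", seq_len(n)),
    sex = sex, age = age, mother_white = mother_white,
    income = income, father_household = father_household,
    n_siblings = n_siblings, word_activity = word_activity, nvq = nvq,
    time_with_child = time_with_child, kessler = kessler,
    close_mother = close_mother, close_father = close_father,
    argue_mother = argue_mother, argue_father = argue_father,
    longterm_ill = longterm_ill,
    motiv_1 = motiv[, 1], motiv_2 = motiv[, 2], motiv_3 = motiv[, 3],
    motiv_4 = motiv[, 4], motiv_5 = motiv[, 5], motiv_6 = motiv[, 6],
    screen_tv = screen[, 1], screen_games = screen[, 2],
    screen_net = screen[, 3], screen_social = screen[, 4],
    bed_weekday = per_day$weekday$bed, bed_weekend = per_day$weekend$bed,
    wake_weekday = per_day$weekday$wake, wake_weekend = per_day$weekend$wake,
    fall_asleep = fall_asleep, night_waking = night_waking,
    has_diary = has_diary,
    stringsAsFactors = FALSE
  )

  ## -- diaries for the diary subsample ------------------------------------
  idx <- which(has_diary)
  diaries <- list()
  for (d in day_types) {
    wd <- config$wake_diary[[d]]
    wake_slot <- pmin(pmax(round(wd[["mean_slot"]] + wd[["sd"]] *
                             load_latent(-U[idx], ld$wake_diary,
                                         length(idx))), 7L), 90L)
    onset_slot <- pmax(per_day[[d]]$onset_slot[idx], wake_slot + 12L)
    part <- per_day[[d]]$part[idx]
    n_dig <- ifelse(part == 1L,
                    pmax(1L, round(per_day[[d]]$hours[idx] * 6)), 0L)
    abut <- per_day[[d]]$abut[idx] == 1L
    mat <- matrix("OTHER", nrow = length(idx), ncol = n_slots,
                  dimnames = list(cohort$person_id[idx], NULL))
    for (i in seq_along(idx)) {
      mat[i, ] <- build_diary_slots(wake_slot[i], onset_slot[i],
                                    n_dig[i], abut[i])
    }
    diaries[[d]] <- mat
  }

  cohort <- apply_missingness(cohort, config)
  structure(list(cohort = cohort, diaries = diaries, config = config),
            class = "sca_cohort")
}

# Lay out one diary day. `onset_slot` in 1..145 (145 = no sleep onset before
# 4 AM). Digital time fills at most two contiguous episodes: an optional one
# ending right before sleep onset (before-bed use) and a main evening-weighted
# episode. When `abut` is FALSE a 3-slot buffer keeps the 30-minute before-bed
# window free of digital codes.
build_diary_slots <- function(wake_slot, onset_slot, n_digital, abut) {
  slots <- rep("OTHER", n_slots)
  if (wake_slot > 1) slots[seq_len(wake_slot - 1)] <- "SLEEP"
  if (onset_slot <= n_slots) slots[onset_slot:n_slots] <- "SLEEP"
  a0 <- wake_slot
  a1 <- min(onset_slot - 1L, n_slots)
  room <- a1 - a0 + 1L
  if (!abut) room <- max(0L, room - 3L)
  n_digital <- min(n_digital, room)
  if (n_digital < 1L) return(slots)

  dig_weights <- c(0.12, 0.22, 0.18, 0.18, 0.30)
  cap <- a1
  if (abut) {
    len1 <- min(n_digital, 1L + rpois(1, 2))
    slots[(a1 - len1 + 1L):a1] <- sample(digital_codes, 1, prob = dig_weights)
    n_digital <- n_digital - len1
    cap <- a1 - len1
  } else {
    cap <- a1 - 3L
  }
  if (n_digital > 0L && cap - a0 + 1L >= n_digital) {
    lo <- a0 + n_digital - 1L
    e_end <- cap - floor((cap - lo) * rbeta(1, 1, 4))
    slots[(e_end - n_digital + 1L):e_end] <-
      sample(digital_codes, 1, prob = dig_weights)
  }
  slots
}

#' Generate a single time-use diary day
#'
#' Draws one 144-slot diary for a person described by their latent traits,
#' using the current RNG state. The diary has exactly one final transition
#' into sleep at the configured onset time (shifted by the person's latents
#' and any configured true effects), Bernoulli digital participation with a
#' right-skewed total duration laid out in contiguous evening-weighted
#' episodes, and with configured probability an episode abutting the onset
#' slot (before-bed use).
#'
#' @param person List with `tech_propensity` and `sleep_propensity`
#'   (standard-normal scale).
#' @param day_type `"weekday"` or `"weekend"`.
#' @param config An [generator_config()] object.
#' @return Character vector of length 144 with codes from [diary_codes].
#' @examples
#' cfg <- generator_config(n_participants = 10)
#' set.seed(1)
#' d <- generate_diary_day(list(tech_propensity = 0, sleep_propensity = 0),
#'                         "weekday", cfg)
#' table(d)
#' @export
generate_diary_day <- function(person, day_type, config) {
  if (!day_type %in% day_types) validation_error("unknown day_type")
  if (!inherits(config, "sca_config"))
    config_error("config must be created by generator_config()")
  T <- person$tech_propensity
  U <- person$sleep_propensity
  if (is.null(T) || is.null(U) || !is.finite(T) || !is.finite(U))
    validation_error("person latents must be finite")
  ld <- config$loadings

  p_d <- config$participation_prob[[day_type]]
  lat_p <- load_latent(T, ld$participation, 1L)
  part <- as.integer(pnorm(lat_p) > 1 - p_d)
  hp <- lognormal_params(config$digital_hours[[day_type]][["mean"]],
                         config$digital_hours[[day_type]][["sd"]])
  hours <- if (part == 1L && p_d > 0)
    qlnorm(min(max((pnorm(lat_p) - (1 - p_d)) / p_d, 1e-12), 1 - 1e-12),
           hp[["meanlog"]], hp[["sdlog"]]) else 0
  q_d <- if (p_d > 0) config$bedtime_use_prob[[day_type]] / p_d else 0
  abut <- binary_from_latent(load_latent(T, ld$abut, 1L), q_d) == 1L

  lo <- ld$onset_sleep
  onset_lat <- config$onset_latent_mu[[day_type]] +
    config$sleep_onset[[day_type]][["sd"]] *
      (lo * U + sqrt(1 - lo^2) * rnorm(1))
  onset_score <- min(round(onset_lat), 138)
  onset_slot <- if (onset_score >= 1) 145L - as.integer(onset_score) else 145L

  wd <- config$wake_diary[[day_type]]
  wake_slot <- min(max(round(wd[["mean_slot"]] + wd[["sd"]] *
                        load_latent(-U, ld$wake_diary, 1L)), 7L), 90L)
  onset_slot <- max(onset_slot, wake_slot + 12L)
  n_dig <- if (part == 1L) max(1L, round(hours * 6)) else 0L
  build_diary_slots(wake_slot, onset_slot, n_dig, abut)
}

#' Apply item-level missingness to a cohort table
#'
#' Independently sets targeted raw items to `NA` at the configured MCAR rate
#' for their covariate block. `person_id` and `has_diary` are never missing.
#'
#' @param cohort Cohort data frame as produced by [generate_cohort()].
#' @param config An [generator_config()] object (uses `missingness_rates`).
#' @return The cohort with missingness applied.
#' @export
apply_missingness <- function(cohort, config) {
  rates <- config$missingness_rates
  if (any(rates < 0 | rates > 1))
    config_error("missingness rates must lie in [0, 1]")
  blocks <- missingness_blocks()
  for (b in names(blocks)) {
    if (!b %in% names(rates)) next   # unset block: no missingness
    r <- rates[[b]]
    if (r == 0) next
    for (col in intersect(blocks[[b]], names(cohort))) {
      hit <- runif(nrow(cohort)) < r
      cohort[[col]][hit] <- NA
    }
  }
  cohort
}

missingness_blocks <- function() {
  list(
    demographics = c("sex", "age", "mother_white"),
    family = c("income", "father_household", "n_siblings"),
    mother = c("word_activity", "nvq", "time_with_child", "kessler"),
    child = c("close_mother", "close_father", "argue_mother", "argue_father",
              "longterm_ill", paste0("motiv_", 1:6)),
    screen = c("screen_tv", "screen_games", "screen_net", "screen_social"),
    sleep = c("bed_weekday", "bed_weekend", "wake_weekday", "wake_weekend",
              "fall_asleep", "night_waking")
  )
}

#' @export
print.sca_cohort <- function(x, ...) {
  cat("<sca_cohort> ", nrow(x$cohort), " adolescents, ",
      nrow(x$diaries$weekday), " with time-use diaries\n", sep = "")
  invisible(x)
}
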