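## Derived sleep, technology and covariate measures.
##
## Recoding conventions follow the source instruments: binned bedtime/wake
## items are mapped to clock hours with a midpoint-of-bin rule; the diary
## sleep-onset score reverses the slot index (s = 145 - slot) so that higher
## scores mean earlier onset; the diary digital-time variable is split
## hurdle-style into participation and time spent.

check_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi | x != floor(x))
  if (any(bad))
    validation_error(sprintf("%s must be an integer in %d..%d or missing",
                             what, lo, hi))
  invisible(x)
}

#' Reverse the retrospective bedtime score
#'
#' The raw item codes later bedtimes with higher scores; the analysed measure
#' is reversed (`6 - score`) so that higher scores mean earlier bedtimes.
#' An involution; missing propagates.
#'
#' @param score Integer vector with values in 1..5 or `NA`.
#' @return Reversed scores.
#' @export
reverse_bedtime_score <- function(score) {
  check_range(score, 1L, 5L, "bedtime score")
  6L - as.integer(score)
}

#' Convert a bedtime score to clock hours
#'
#' Midpoint-of-bin recoding: `score + 7.5` PM-decimal hours, so category 1
#' ("before 9 PM") becomes 8.5 and category 4 ("11-midnight") becomes 11.5.
#'
#' @param score Integer vector with values in 1..5 (raw, unreversed item).
#' @return Clock hours (PM-decimal); `NA` propagates.
#' @export
bedtime_to_clock <- function(score) {
  check_range(score, 1L, 5L, "bedtime score")
  score + 7.5
}

#' Hours slept before midnight
#'
#' `12 - bedtime_to_clock(score)`; negative when bedtime falls after
#' midnight.
#'
#' @inheritParams bedtime_to_clock
#' @return Signed hours.
#' @export
sleep_before_midnight <- function(score) {
  12 - bedtime_to_clock(score)
}

#' Convert a wake-up score to clock hours
#'
#' Midpoint-of-bin recoding: weekday scores (1..5) map to `score + 4.5` and
#' weekend scores (1..6) to `score + 6.5` AM-decimal hours.
#'
#' @param score Integer vector.
#' @param day_type `"weekday"` or `"weekend"`.
#' @return Clock hours (AM-decimal); `NA` propagates.
#' @export
wake_to_clock <- function(score, day_type) {
  day_type <- match.arg(day_type, day_types)
  if (day_type == "weekday") {
    check_range(score, 1L, 5L, "weekday wake score")
    score + 4.5
  } else {
    check_range(score, 1L, 6L, "weekend wake score")
    score + 6.5
  }
}

#' Total retrospective sleep time
#'
#' Sum of hours slept before midnight (from the bedtime item) and after
#' midnight (from the wake item): `wake_to_clock(wake) + 12 -
#' bedtime_to_clock(bed)`.
#'
#' @param bed_score Raw bedtime score (1..5).
#' @param wake_score Wake score (1..5 weekday, 1..6 weekend).
#' @inheritParams wake_to_clock
#' @return Hours of sleep; `NA` propagates.
#' @export
total_sleep_retro <- function(bed_score, wake_score, day_type) {
  sleep_before_midnight(bed_score) + wake_to_clock(wake_score, day_type)
}

#' Composite retrospective screen-engagement score
#'
#' Arithmetic mean of the four screen items (TV/films, electronic games,
#' internet use, social networking), each on the 1..8 banded-hours scale.
#' Missing whenever any of the four items is missing.
#'
#' @param items Numeric matrix or data frame with four columns (or a length-4
#'   vector for a single person), values in 1..8 or `NA`.
#' @return Numeric vector of composite scores.
#' @export
composite_screen <- function(items) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 4) validation_error("composite needs exactly 4 items")
  check_range(as.vector(items), 1L, 8L, "screen item")
  out <- rowMeans(items)              # NA if any item NA
  out
}

check_diary <- function(slots) {
  if (length(slots) != n_slots)
    validation_error("a diary must contain exactly 144 slots")
  if (!all(slots %in% diary_codes))
    validation_error("diary contains codes outside the allowed set")
  invisible(slots)
}

#' Diary sleep-onset score
#'
#' Locates the last slot at which the activity changes from a non-sleep code
#' to `SLEEP` and returns the reversed slot index `s = 145 - slot`, so higher
#' scores mean earlier onset (score 30 is an onset at 11 PM). Diaries with no
#' sleep onset at all receive the 4 AM fallback score (`fallback`, default 1,
#' the scale minimum); diaries that are asleep from slot 1 and never wake
#' return `NA` (no onset is identifiable).
#'
#' @param slots Character vector of 144 activity codes.
#' @param fallback Score for diaries without any sleep onset (default 1).
#' @return Onset score in 1..144, or `NA`.
#' @export
diary_sleep_onset <- function(slots, fallback = 1) {
  check_diary(slots)
  is_sleep <- slots == "SLEEP"
  trans <- which(is_sleep[-1] & !is_sleep[-n_slots]) + 1L
  if (length(trans) > 0) return(145L - max(trans))
  if (all(is_sleep)) return(NA_real_)
  fallback
}

#' Convert an onset score to clock time
#'
#' The onset score `s` corresponds to slot `145 - s` of a day starting at
#' 4 AM; the slot start is `(240 + (144 - s) * 10) mod 1440` minutes after
#' midnight. Strictly decreasing in the score up to the single midnight wrap.
#'
#' @param score Onset score in `[1, 144]` (fractional values allowed, e.g.
#'   sample means).
#' @return Minutes after midnight (possibly fractional). Use
#'   [format_clock()] for an `HH:MM` rendering.
#' @examples
#' format_clock(score_to_clock(30.22))  # ~11 PM
#' @export
score_to_clock <- function(score) {
  if (any(!is.na(score) & (score < 1 | score > n_slots)))
    validation_error("onset score must lie in [1, 144]")
  (240 + (n_slots - score) * 10) %% 1440
}

#' @rdname score_to_clock
#' @param minutes Minutes after midnight.
#' @export
format_clock <- function(minutes) {
  sprintf("%02d:%02d", floor(minutes / 60) %% 24, round(minutes %% 60))
}

#' Diary digital participation
#'
#' 1 if any slot carries one of the five digital codes, else 0.
#'
#' @inheritParams diary_sleep_onset
#' @return 0/1.
#' @export
diary_participation <- function(slots) {
  check_diary(slots)
  as.integer(any(slots %in% digital_codes))
}

#' Diary time spent on digital devices
#'
#' Total digital time in hours (10 minutes per digital slot) among
#' participants; missing (not zero) for diaries with no digital engagement,
#' following the hurdle-style participation / time-spent split.
#'
#' @inheritParams diary_sleep_onset
#' @return Hours, or `NA` for non-participants.
#' @export
diary_time_spent <- function(slots) {
  check_diary(slots)
  k <- sum(slots %in% digital_codes)
  if (k == 0) return(NA_real_)
  k * 10 / 60
}

#' Diary before-bed technology use
#'
#' 1 if any of the three complete 10-minute slots strictly before the sleep
#' onset slot carries a digital code (a 30-minute before-bed window), else 0.
#' The onset slot itself is excluded: the diary codes a single primary
#' activity per slot.
#'
#' @inheritParams diary_sleep_onset
#' @param onset_slot Slot index of sleep onset (`145 - onset score`).
#' @return 0/1.
#' @export
diary_bedtime_use <- function(slots, onset_slot) {
  check_diary(slots)
  window <- intersect((onset_slot - 3L):(onset_slot - 1L), seq_len(n_slots))
  if (length(window) == 0) return(0L)
  as.integer(any(slots[window] %in% digital_codes))
}

#' Closeness-to-parents score
#'
#' Mean of the four four-level closeness items after reverse-coding the two
#' "argue" items (`5 - score`), so higher always means closer. Missing if any
#' item is missing (including adolescents without a mother or father figure,
#' whose items are coded `NA` upstream).
#'
#' @param close_mother,close_father Closeness items, 1..4.
#' @param argue_mother,argue_father Argue items, 1..4 (reverse-coded).
#' @return Numeric score in `[1, 4]` or `NA`.
#' @export
closeness_score <- function(close_mother, close_father,
                            argue_mother, argue_father) {
  for (x in list(close_mother, close_father, argue_mother, argue_father))
    check_range(x, 1L, 4L, "closeness item")
  (close_mother + close_father + (5 - argue_mother) + (5 - argue_father)) / 4
}

#' Educational motivation score
#'
#' Mean of the six school-motivation items after reversing the first two
#' ("try your best", "find school interesting"). Missing if any item is
#' missing.
#'
#' @param items Matrix/data frame with six columns (1..4 scale), or a
#'   length-6 vector for one person.
#' @param levels Number of response levels (default 4).
#' @return Numeric score or `NA`.
#' @export
educational_motivation <- function(items, levels = 4L) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1)
  items <- as.matrix(items)
  if (ncol(items) != 6) validation_error("motivation needs exactly 6 items")
  check_range(as.vector(items), 1L, levels, "motivation item")
  items[, 1:2] <- (levels + 1L) - items[, 1:2]
  rowMeans(items)
}

## Covariate sets ----------------------------------------------------------

#' The five nested covariate sets
#'
#' Demographics (child sex and age, mother's ethnicity) are included in every
#' set; the child, mother and family blocks extend them, and `all` is the
#' union of the four blocks.
#'
#' @return Named list of column-name vectors on the derived-measures table.
#' @export
covariate_sets <- function() {
  demo <- c("sex", "age", "mother_white")
  child <- c("closeness", "longterm_ill", "motivation")
  mother <- c("word_activity", "nvq", "time_with_child", "kessler")
  family <- c("income", "father_household", "n_siblings")
  list(
    "demographics" = demo,
    "demographics+child" = c(demo, child),
    "demographics+mother" = c(demo, mother),
    "demographics+family" = c(demo, family),
    "all" = c(demo, child, mother, family)
  )
}

#' @rdname covariate_sets
#' @param table Derived-measures data frame; validated to contain every
#'   covariate column.
#' @export
build_covariate_sets <- function(table) {
  sets <- covariate_sets()
  missing_cols <- setdiff(unique(unlist(sets)), names(table))
  if (length(missing_cols) > 0)
    validation_error(paste("table lacks covariate columns:",
                           paste(missing_cols, collapse = ", ")))
  sets
}

## Vectorised diary measures (shared by the pipeline) ----------------------

diary_onset_scores <- function(mat, fallback = 1) {
  stopifnot(ncol(mat) == n_slots)
  is_sleep <- mat == "SLEEP"
  trans <- is_sleep[, -1, drop = FALSE] & !is_sleep[, -n_slots, drop = FALSE]
  # column j of `trans` is a transition at slot j + 1; reversing columns makes
  # max.col(..., "first") return the onset score 145 - slot directly
  rev_trans <- trans[, (n_slots - 1L):1L, drop = FALSE]
  s <- max.col(rev_trans, ties.method = "first")
  none <- rowSums(trans) == 0L
  s[none] <- fallback
  s[none & rowSums(is_sleep) == n_slots] <- NA_real_
  as.numeric(s)
}

diary_digital_counts <- function(mat) {
  rowSums(matrix(mat %in% digital_codes, nrow = nrow(mat)))
}

diary_bedtime_use_vec <- function(mat, onset_slots) {
  out <- integer(nrow(mat))
  is_dig <- matrix(mat %in% digital_codes, nrow = nrow(mat))
  for (k in 1:3) {
    col <- onset_slots - k
    ok <- which(!is.na(col) & col >= 1 & col <= n_slots)
    if (length(ok) > 0)
      out[ok] <- pmax(out[ok], is_dig[cbind(ok, col[ok])])
  }
  out
}

## Derived-measures table --------------------------------------------------

#' Build the derived-measures table
#'
#' Constructs every analysed measure from a raw cohort table and its diaries:
#' one row per person per day type, holding the three sleep measures, the
#' four technology measures, the two sleep-difficulty items and the coded
#' covariates. Diary-based columns are `NA` for adolescents without diaries.
#'
#' @param sim An `sca_cohort` from [generate_cohort()], or a list with
#'   elements `cohort` and `diaries` following the same layout.
#' @param fallback Onset fallback score (see [diary_sleep_onset()]).
#' @return Data frame keyed by `person_id` x `day_type`.
#' @export
derive_measures <- function(sim, fallback = 1) {
  cohort <- sim$cohort
  diaries <- sim$diaries
  n <- nrow(cohort)

  comp <- composite_screen(cohort[, c("screen_tv", "screen_games",
                                      "screen_net", "screen_social")])
  closeness <- closeness_score(cohort$close_mother, cohort$close_father,
                               cohort$argue_mother, cohort$argue_father)
  motivation <- educational_motivation(
    cohort[, paste0("motiv_", 1:6)])

  base <- data.frame(
    person_id = cohort$person_id,
    has_diary = cohort$has_diary,
    time_spent_retro = comp,
    fall_asleep_time = cohort$fall_asleep,
    night_waking = cohort$night_waking,
    sex = cohort$sex, age = cohort$age, mother_white = cohort$mother_white,
    closeness = closeness, longterm_ill = cohort$longterm_ill,
    motivation = motivation,
    word_activity = cohort$word_activity,
    nvq = factor(cohort$nvq, levels = 1:5),
    time_with_child = cohort$time_with_child, kessler = cohort$kessler,
    income = cohort$income, father_household = cohort$father_household,
    n_siblings = cohort$n_siblings,
    stringsAsFactors = FALSE
  )

  rows <- list()
  for (d in day_types) {
    bed <- cohort[[paste0("bed_", d)]]
    wake <- cohort[[paste0("wake_", d)]]
    day <- base
    day$day_type <- d
    day$bedtime_retro <- reverse_bedtime_score(bed)
    day$total_sleep_retro <- total_sleep_retro(bed, wake, d)

    onset <- rep(NA_real_, n)
    part <- rep(NA_integer_, n)
    spent <- rep(NA_real_, n)
    beduse <- rep(NA_integer_, n)
    mat <- diaries[[d]]
    if (!is.null(mat) && nrow(mat) > 0) {
      di <- match(rownames(mat), cohort$person_id)
      s <- diary_onset_scores(mat, fallback)
      onset[di] <- s
      cnt <- diary_digital_counts(mat)
      part[di] <- as.integer(cnt > 0)
      spent[di] <- ifelse(cnt > 0, cnt * 10 / 60, NA_real_)
      beduse[di] <- diary_bedtime_use_vec(mat, 145L - s)
    }
    day$bedtime_diary <- onset
    day$participation <- part
    day$time_spent_diary <- spent
    day$bedtime_use <- beduse
    rows[[d]] <- day
  }
  out <- rbind(rows$weekday, rows$weekend)
  out$day_type <- factor(out$day_type, levels = day_types)
  front <- c("person_id", "day_type", "has_diary", "bedtime_retro",
             "bedtime_diary", "total_sleep_retro", "participation",
             "bedtime_use", "time_spent_diary", "time_spent_retro",
             "fall_asleep_time", "night_waking")
  out <- out[, c(front, setdiff(names(out), front))]
  rownames(out) <- NULL
  out
}
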