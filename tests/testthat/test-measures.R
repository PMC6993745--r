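test_that("bedtime recodings follow the midpoint rules", {
  expect_equal(reverse_bedtime_score(5L), 1L)
  expect_equal(reverse_bedtime_score(3L), 3L)
  expect_equal(reverse_bedtime_score(reverse_bedtime_score(2L)), 2L)
  expect_true(is.na(reverse_bedtime_score(NA)))
  expect_error(reverse_bedtime_score(6), class = "sleepsca_validation_error")

  expect_equal(bedtime_to_clock(1), 8.5)
  expect_equal(bedtime_to_clock(4), 11.5)
  expect_equal(bedtime_to_clock(5), 12.5)
  expect_equal(sleep_before_midnight(4), 0.5)
  expect_equal(sleep_before_midnight(1), 3.5)
  expect_equal(sleep_before_midnight(5), -0.5)

  expect_equal(wake_to_clock(3, "weekday"), 7.5)
  expect_equal(wake_to_clock(1, "weekend"), 7.5)
  expect_equal(wake_to_clock(6, "weekend"), 12.5)
  expect_error(wake_to_clock(6, "weekday"),
               class = "sleepsca_validation_error")
})

test_that("total retrospective sleep sums the two halves of the night", {
  expect_equal(total_sleep_retro(3, 3, "weekday"), 9.0)
  expect_equal(total_sleep_retro(5, 1, "weekday"), 5.0)
  expect_equal(total_sleep_retro(1, 6, "weekend"), 16.0)
  expect_true(is.na(total_sleep_retro(NA, 3, "weekday")))
  # identity over the full score grid
  for (d in day_types) {
    wk <- if (d == "weekday") 1:5 else 1:6
    for (b in 1:5) for (w in wk)
      expect_equal(total_sleep_retro(b, w, d),
                   wake_to_clock(w, d) + 12 - bedtime_to_clock(b))
  }
})

test_that("screen composite is the four-item mean with strict missingness", {
  expect_equal(composite_screen(c(4, 4, 6, 6)), 5.0)
  expect_equal(composite_screen(c(8, 8, 8, 8)), 8.0)
  expect_true(is.na(composite_screen(c(4, NA, 6, 6))))
  m <- rbind(c(1, 2, 3, 4), c(2, 2, NA, 2))
  expect_equal(composite_screen(m), c(2.5, NA))
  expect_error(composite_screen(c(0, 2, 3, 4)),
               class = "sleepsca_validation_error")
  expect_error(composite_screen(c(1, 2, 3)),
               class = "sleepsca_validation_error")
})

test_that("diary sleep onset finds the last transition into sleep", {
  expect_equal(diary_sleep_onset(make_diary(onset = 115)), 30)
  expect_equal(diary_sleep_onset(make_diary()), 1)          # no sleep at all
  expect_equal(diary_sleep_onset(make_diary(), fallback = 0), 0)
  two <- make_diary(onset = 120, wake = 10)
  two[20:25] <- "SLEEP"                                     # earlier nap
  expect_equal(diary_sleep_onset(two), 25)
  expect_true(is.na(diary_sleep_onset(rep("SLEEP", 144))))  # asleep all day
  # morning sleep only, never returns to sleep: 4 AM fallback
  expect_equal(diary_sleep_onset(make_diary(wake = 20)), 1)
  expect_error(diary_sleep_onset(rep("OTHER", 100)),
               class = "sleepsca_validation_error")
  bad <- make_diary(onset = 120); bad[5] <- "NAP"
  expect_error(diary_sleep_onset(bad), class = "sleepsca_validation_error")
})

test_that("onset score to clock mapping matches the printed anchors", {
  expect_equal(round(score_to_clock(30.22) / 60), 23)   # ~11 PM
  expect_lt(abs(score_to_clock(27.74) - (23 * 60 + 20)), 5)  # ~11:20 PM
  expect_equal(score_to_clock(144), 240)                # 4 AM, scale endpoint
  expect_equal(format_clock(score_to_clock(144)), "04:00")
  expect_error(score_to_clock(0), class = "sleepsca_validation_error")
  # strictly decreasing up to the single midnight wrap
  s <- seq(1, 144, by = 0.5)
  m <- score_to_clock(s)
  unwrapped <- ifelse(m < 240, m + 1440, m)
  expect_true(all(diff(unwrapped) < 0))
  # score 145 - i lands on the start of slot i
  for (i in c(1, 60, 115, 144))
    expect_equal(score_to_clock(145 - i), (240 + (i - 1) * 10) %% 1440)
})

test_that("participation, time spent and before-bed use follow the hurdle coding", {
  none <- make_diary(onset = 120, wake = 20)
  expect_equal(diary_participation(none), 0L)
  expect_true(is.na(diary_time_spent(none)))
  one <- make_diary(onset = 120, wake = 20, digital = 80)
  expect_equal(diary_participation(one), 1L)
  expect_equal(diary_time_spent(make_diary(digital = 50:61, onset = 120)), 2)
  alldig <- rep("DIG_GAMES", 144)
  expect_equal(diary_participation(alldig), 1L)
  expect_equal(diary_time_spent(alldig), 24)

  d <- make_diary(onset = 120, wake = 20, digital = 119)
  expect_equal(diary_bedtime_use(d, 120), 1L)
  d2 <- make_diary(onset = 120, wake = 20, digital = 116)
  expect_equal(diary_bedtime_use(d2, 120), 0L)   # outside the 30-min window
  expect_equal(diary_bedtime_use(make_diary(onset = 2), 1), 0L)  # empty window
})

test_that("closeness and motivation composites reverse the stated items", {
  expect_equal(closeness_score(4, 4, 1, 1), 4.0)
  expect_equal(closeness_score(1, 1, 4, 4), 1.0)
  expect_true(is.na(closeness_score(3, NA, 2, 2)))
  expect_error(closeness_score(5, 1, 1, 1),
               class = "sleepsca_validation_error")

  expect_equal(educational_motivation(c(3, 3, 2, 2, 2, 2)), 2.0)
  expect_equal(educational_motivation(c(4, 3, 2, 1, 3, 2)),
               mean(c(1, 2, 2, 1, 3, 2)))
  expect_true(is.na(educational_motivation(c(4, 3, NA, 1, 3, 2))))
})

test_that("covariate sets are the five nested blocks", {
  sets <- covariate_sets()
  expect_named(sets, c("demographics", "demographics+child",
                       "demographics+mother", "demographics+family", "all"))
  expect_setequal(sets$demographics, c("sex", "age", "mother_white"))
  expect_true(all(c("closeness", "longterm_ill", "motivation") %in%
                    sets[["demographics+child"]]))
  for (s in sets) expect_true(all(sets$demographics %in% s))
  expect_setequal(sets$all, unique(unlist(sets)))
  expect_false(anyDuplicated(sets$all) > 0)
  expect_error(build_covariate_sets(data.frame(sex = 1)),
               class = "sleepsca_validation_error")
})

test_that("vectorised diary measures agree with the scalar operations", {
  sim <- small_sim(n = 300, seed = 13)
  mat <- sim$diaries$weekday
  s_vec <- sleepsca:::diary_onset_scores(mat, fallback = 1)
  cnt <- sleepsca:::diary_digital_counts(mat)
  bu_vec <- sleepsca:::diary_bedtime_use_vec(mat, 145L - s_vec)
  for (i in seq_len(nrow(mat))) {
    slots <- mat[i, ]
    expect_identical(s_vec[i], as.numeric(diary_sleep_onset(slots)))
    expect_identical(as.integer(cnt[i] > 0), diary_participation(slots))
    expect_identical(bu_vec[i], diary_bedtime_use(slots, 145L - s_vec[i]))
  }
})

test_that("derived table respects the missingness propagation rules", {
  sim <- small_sim(n = 500, seed = 21)
  d <- derive_measures(sim)
  expect_equal(nrow(d), 2 * 500)
  dd <- d[d$has_diary, ]
  expect_true(all(is.na(dd$time_spent_diary) == (dd$participation == 0)))
  expect_true(all(is.na(d$bedtime_diary[!d$has_diary])))
  expect_true(all(d$bedtime_diary >= 1 & d$bedtime_diary <= 144, na.rm = TRUE))
  # composite missing iff any screen item missing
  co <- sim$cohort
  any_na <- is.na(co$screen_tv) | is.na(co$screen_games) |
    is.na(co$screen_net) | is.na(co$screen_social)
  wd <- d[d$day_type == "weekday", ]
  expect_identical(is.na(wd$time_spent_retro), unname(any_na))
  # reversal applied: derived bedtime_retro = 6 - raw
  ok <- !is.na(co$bed_weekday)
  expect_equal(wd$bedtime_retro[ok], 6L - co$bed_weekday[ok])
})
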