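test_that("events_to_intervals implements hold-to-report with last-key-wins", {
  # no events
  expect_equal(nrow(events_to_intervals(make_trial())), 0)
  # single hold
  one <- events_to_intervals(make_trial(c("b", 2, 5)))
  expect_equal(one, iv(c("happy", 2, 5)))
  # overlapping holds: the newer press truncates the open interval
  ov <- events_to_intervals(make_trial(c("b", 1, 6), c("m", 4, 9)))
  expect_equal(ov, iv(c("happy", 1, 4), c("neutral", 4, 9)))
  # the earlier key resumes when the later one is released
  res <- events_to_intervals(make_trial(c("b", 1, 10), c("m", 3, 5)))
  expect_equal(res, iv(c("happy", 1, 3), c("neutral", 3, 5), c("happy", 5, 10)))
  # clipping to [0, duration]
  clip <- events_to_intervals(make_trial(c("b", 12, NA)))
  expect_equal(clip, iv(c("happy", 12, 15)))
})

test_that("the toggle dialect switches on every press and ignores releases", {
  tr <- make_trial(c("b", 1, 2), c("m", 4, 5))
  expect_equal(events_to_intervals(tr, report = "toggle"),
               iv(c("happy", 1, 4), c("neutral", 4, 15)))
})

test_that("initial percept skips mixed intervals and ORT is its onset", {
  expect_equal(initial_percept(iv(c("mixed", 0.5, 2), c("happy", 2, 6))),
               "happy")
  expect_equal(initial_percept(iv(c("mixed", 0, 15))), "none")
  expect_equal(initial_percept(iv()), "none")
  expect_equal(onset_resolution_time(iv(c("happy", 2, 6))), 2)
  expect_equal(onset_resolution_time(iv(c("mixed", 0.5, 2), c("neutral", 2, 6))),
               2)
  expect_true(is.na(onset_resolution_time(iv(c("mixed", 0, 15)))))
})

test_that("cumulative times sum per label and conserve the trial duration", {
  ct <- cumulative_times(iv(c("happy", 0, 5), c("neutral", 5, 15)), 15)
  expect_equal(unname(ct$ct), c(5, 10, 0))
  expect_equal(ct$unreported_s, 0)
  ct0 <- cumulative_times(iv(), 15)
  expect_equal(unname(ct0$ct), c(0, 0, 0))
  expect_equal(ct0$unreported_s, 15)
})

test_that("parser metrics agree with the millisecond rasterization oracle on messy inputs", {
  set.seed(31)
  for (i in 1:60) {
    tr <- random_messy_trial()
    expect_metrics_match_oracle(tr)
  }
})

test_that("metrics are invariant to the input ordering of events", {
  set.seed(11)
  for (i in 1:10) {
    tr <- random_messy_trial(n_events = 8)
    perm <- tr
    set.seed(100 + i)
    perm$events <- perm$events[sample(nrow(perm$events)), ]
    perm <- br_trial(tr$subject_id, tr$mimicry, tr$block, tr$trial,
                     tr$stimulus_id, tr$key_map, tr$duration_s, perm$events)
    expect_equal(trial_metrics(perm), trial_metrics(tr))
  }
})

test_that("conservation holds on every simulated trial", {
  study <- small_study()
  m <- metrics_table(study$sessions)
  total <- m$ct_happy_s + m$ct_neutral_s + m$ct_mixed_s + m$unreported_s
  expect_equal(total, m$duration_s, tolerance = 1e-9)
})

test_that("ORT is the onset of an interval whose label is the IP with no earlier clear interval", {
  set.seed(77)
  for (i in 1:40) {
    tr <- random_messy_trial()
    ivs <- events_to_intervals(tr)
    ip <- initial_percept(ivs)
    ort <- onset_resolution_time(ivs)
    if (ip == "none") {
      expect_true(is.na(ort))
    } else {
      k <- which(ivs$label == ip & ivs$t_on == ort)
      expect_true(length(k) >= 1)
      earlier <- ivs$label[ivs$t_on < ort]
      expect_true(all(earlier == "mixed"))
    }
  }
})

test_that("subject summaries average over coded trials only", {
  # two trials with CT_happy 6 and 8 -> mean 7
  t1 <- make_trial(c("b", 0, 6), subject = "s01")
  t2 <- make_trial(c("b", 2, 10), subject = "s01", trial = 2L)
  uncoded <- make_trial(subject = "s01", trial = 3L)
  m <- metrics_table(list(br_session("s01", trials = list(t1, t2, uncoded))))
  cells <- summarize_subjects(m)
  happy_free <- cells[cells$mimicry == "free" & cells$label == "happy", ]
  expect_equal(happy_free$mean_ct_s, 7)
  expect_equal(happy_free$n_trials_used, 2)

  # IP means: happy@2, happy@4, neutral@3
  trs <- list(make_trial(c("b", 2, 5)),
              make_trial(c("b", 4, 6), trial = 2L),
              make_trial(c("m", 3, 6), trial = 3L))
  cells <- summarize_subjects(metrics_table(list(br_session("s01", trials = trs))))
  free <- cells[cells$mimicry == "free", ]
  expect_equal(free$mean_ort_s[free$label == "happy"], 3)
  expect_equal(free$mean_ort_s[free$label == "neutral"], 3)
  expect_equal(free$ip_count[free$label == "happy"], 2L)
  expect_equal(free$ip_count[free$label == "neutral"], 1L)
})

test_that("ORT exclusions remove exactly the subjects with an incomplete IP design", {
  mk_subject <- function(sid, neutral_ip_free) {
    trials <- list(
      make_trial(c("b", 1, 5), subject = sid, mimicry = "free"),
      make_trial(if (neutral_ip_free) c("m", 2, 5) else c("b", 2, 5),
                 subject = sid, mimicry = "free", trial = 2L),
      make_trial(c("b", 1, 5), subject = sid, mimicry = "blocked", block = 3L),
      make_trial(c("m", 2, 5), subject = sid, mimicry = "blocked", block = 3L,
                 trial = 2L))
    br_session(sid, trials = trials)
  }
  sessions <- list(mk_subject("s01", TRUE), mk_subject("s02", FALSE))
  cells <- summarize_subjects(metrics_table(sessions))
  ex <- apply_ort_exclusions(cells)
  expect_equal(ex$kept, "s01")
  expect_equal(ex$excluded, "s02")
  # all-complete case: nothing excluded
  ex2 <- apply_ort_exclusions(cells[cells$subject == "s01", ])
  expect_equal(ex2$excluded, character(0))
})

test_that("the ORT log transform is the natural log with a 1 ms floor at zero", {
  cells <- tibble::tibble(mean_ort_s = c(2, 1, 0))
  out <- log_transform_ort(cells)
  expect_equal(out$log_ort, c(log(2), 0, log(1e-3)))
  expect_equal(out$mean_ort_s, c(2, 1, 0))  # original retained
  expect_error(log_transform_ort(tibble::tibble(mean_ort_s = -1)), "negative")
})

test_that("the ORT floor leaves analyses unchanged when no zero ORTs exist", {
  study <- small_study()
  cells <- summarize_subjects(metrics_table(study$sessions))
  kept <- apply_ort_exclusions(cells)$cells_kept
  a <- log_transform_ort(kept, floor_s = 1e-3)
  b <- log_transform_ort(kept, floor_s = 1e-6)
  expect_equal(a$log_ort, b$log_ort)
})
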