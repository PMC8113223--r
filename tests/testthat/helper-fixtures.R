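# Shared fixture builders: everything is constructed in code, no files.

default_km <- key_map(happy = "b", neutral = "m", mixed = "n")

# trial from a compact event spec: list of c(key, press, release); release NA
# means held to trial end
make_trial <- function(..., subject = "s01", mimicry = "free", block = 1L,
                       trial = 1L, stimulus = "stim1", duration = 15,
                       km = default_km) {
  specs <- list(...)
  if (length(specs) == 0) {
    ev <- tibble::tibble(key = character(), t_press = double(),
                         t_release = double())
  } else {
    ev <- tibble::tibble(
      key = vapply(specs, function(s) as.character(s[[1]]), character(1)),
      t_press = vapply(specs, function(s) as.numeric(s[[2]]), double(1)),
      t_release = vapply(specs, function(s) as.numeric(s[[3]]), double(1)))
  }
  br_trial(subject_id = subject, mimicry = mimicry, block = block,
           trial = trial, stimulus_id = stimulus, key_map = km,
           duration_s = duration, events = ev)
}

# intervals tibble shorthand
iv <- function(...) {
  rows <- list(...)
  tibble::tibble(
    label = vapply(rows, function(r) as.character(r[[1]]), character(1)),
    t_on = vapply(rows, function(r) as.numeric(r[[2]]), double(1)),
    t_off = vapply(rows, function(r) as.numeric(r[[3]]), double(1)))
}

# random event list exercising overlaps, unreleased holds and out-of-range
# times (pre-clipping); returns a br_trial
random_messy_trial <- function(n_events = NULL, duration = 15) {
  if (is.null(n_events)) n_events <- sample(0:12, 1)
  if (n_events == 0) return(make_trial(duration = duration))
  press <- stats::runif(n_events, 0, duration + 0.5)
  len <- stats::rexp(n_events, 1 / 2.5) + 1e-4
  release <- press + len  # may exceed the trial duration (clipped by parser)
  release[stats::runif(n_events) < 0.15 & press < duration - 0.01] <- NA
  keys <- sample(c("b", "n", "m"), n_events, replace = TRUE)
  make_trial_events(keys, press, release, duration = duration)
}

make_trial_events <- function(keys, press, release, duration = 15) {
  ev <- tibble::tibble(key = keys, t_press = press, t_release = release)
  ev <- ev[order(ev$t_press), ]
  br_trial("s01", "free", 1L, 1L, "stim1", key_map = default_km,
           duration_s = duration, events = ev)
}

# small study used by several pipeline tests (cached per test run)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(
        study_config(n_subjects = 8, seed = 404),
        rivalry_params(blocked_neutral_ct_delta_s = 0))
    }
    cache
  }
})

# TRUE when parser and oracle disagree on IP/ORT only because the first
# clear intervals are narrower than the oracle's grid (sub-millisecond
# slivers can fall between grid midpoints)
ip_mismatch_is_subgrid <- function(trial, m, o, tol) {
  ivs <- events_to_intervals(trial)
  clear <- ivs[ivs$label != "mixed", , drop = FALSE]
  any(clear$t_off - clear$t_on < tol + 1e-3)
}

expect_metrics_match_oracle <- function(trial, tol = NULL) {
  m <- trial_metrics(trial)
  o <- grid_oracle_metrics(trial)
  if (is.null(tol)) tol <- 1e-3 * max(1, nrow(trial$events))
  if (!identical(m$ip, o$ip) || xor(is.na(m$ort_s), is.na(o$ort_s))) {
    expect_true(ip_mismatch_is_subgrid(trial, m, o, tol))
  } else if (!is.na(m$ort_s)) {
    expect_lt(abs(m$ort_s - o$ort_s), tol + 1e-3)
  }
  for (col in c("ct_happy_s", "ct_neutral_s", "ct_mixed_s", "unreported_s")) {
    expect_lt(abs(m[[col]] - o[[col]]), tol)
  }
}
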