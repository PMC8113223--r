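# Generative model of continuous-report rivalry sessions: an alternating
# renewal process with gamma dominance durations, an initial unresolved
# period, optional mixed interludes between dominance epochs, report-latency
# jitter, and an injectable condition-by-percept cumulative-time effect.

#' Parameters of the synthetic rivalry process
#'
#' Defaults are calibrated so that a default study reproduces the summary
#' structure typical of happy-vs-neutral face rivalry over 15-s trials:
#' per-trial cumulative time around 7.5 s for the happy percept and 2.7 s
#' (free) / 3.4 s (blocked) for the neutral percept, a happy bias in initial
#' percepts (about 72% of clear first reports), and onset resolution times
#' around 1-2 s.
#'
#' @param gamma_shape_happy,gamma_scale_happy Shape/scale (seconds) of the
#'   gamma dominance-duration distribution for the happy percept.
#' @param gamma_shape_neutral,gamma_scale_neutral Same for the neutral
#'   percept.
#' @param onset_mu,onset_sigma Lognormal parameters (log-seconds) of the
#'   initial unresolved period, i.e. the latent onset resolution time.
#' @param p_first_happy Probability that the first resolved percept is happy.
#' @param p_mixed_interlude Probability that a perceptual switch passes
#'   through a mixed interval.
#' @param mixed_mu,mixed_sigma Lognormal parameters of the mixed-interlude
#'   duration.
#' @param report_latency_sd SD (seconds) of Gaussian jitter added to press
#'   and release times; jitter never reorders a press/release pair.
#' @param blocked_neutral_ct_delta_s Target increment, in seconds, of the
#'   per-trial mean neutral cumulative time in the blocked condition. Zero
#'   gives the null model. Realized by inflating the neutral duration scale,
#'   with the multiplier found by Monte-Carlo calibration.
#' @param subject_sd Between-subject multiplicative heterogeneity (SD on the
#'   log scale) of the duration scales.
#' @return List of class `rivalry_params`.
#' @export
rivalry_params <- function(gamma_shape_happy = 3,
                           gamma_scale_happy = 1.15,
                           gamma_shape_neutral = 3,
                           gamma_scale_neutral = 0.42,
                           onset_mu = log(1.2), onset_sigma = 0.5,
                           p_first_happy = 0.72,
                           p_mixed_interlude = 0.7,
                           mixed_mu = log(1.0), mixed_sigma = 0.5,
                           report_latency_sd = 0.05,
                           blocked_neutral_ct_delta_s = 0.70,
                           subject_sd = 0.25) {
  p <- list(gamma_shape_happy = gamma_shape_happy,
            gamma_scale_happy = gamma_scale_happy,
            gamma_shape_neutral = gamma_shape_neutral,
            gamma_scale_neutral = gamma_scale_neutral,
            onset_mu = onset_mu, onset_sigma = onset_sigma,
            p_first_happy = p_first_happy,
            p_mixed_interlude = p_mixed_interlude,
            mixed_mu = mixed_mu, mixed_sigma = mixed_sigma,
            report_latency_sd = report_latency_sd,
            blocked_neutral_ct_delta_s = blocked_neutral_ct_delta_s,
            subject_sd = subject_sd)
  stopifnot(gamma_shape_happy > 0, gamma_scale_happy > 0,
            gamma_shape_neutral > 0, gamma_scale_neutral > 0,
            onset_sigma > 0, mixed_sigma > 0,
            p_first_happy >= 0, p_first_happy <= 1,
            p_mixed_interlude >= 0, p_mixed_interlude <= 1,
            report_latency_sd >= 0, blocked_neutral_ct_delta_s >= 0,
            subject_sd >= 0)
  class(p) <- "rivalry_params"
  p
}

#' Study design configuration for the simulator
#'
#' The default design is 28 subjects x 2 mimicry conditions (order
#' counterbalanced across subjects) x 2 blocks x 8 trials of 15 s, with four
#' rival stimuli presented twice per block in random order, the happy/neutral
#' key assignment counterbalanced across blocks (the middle key always codes
#' mixed), and questionnaire totals drawn from the normal range (TAS-20 mean
#' 43.6, SD 11.5; IRI mean 98.75, SD 8).
#'
#' @param n_subjects Number of subjects.
#' @param n_blocks_per_condition Blocks per mimicry condition.
#' @param n_trials_per_block Trials per block.
#' @param duration_s Trial duration in seconds.
#' @param tas_mean,tas_sd,iri_mean,iri_sd Questionnaire population moments.
#' @param rho_tas_emotion Correlation between the TAS-20 score and the
#'   subject-level happy-dominance latent factor (negative: more alexithymic
#'   subjects show less happy dominance).
#' @param seed Master seed; every random draw in the study is derived from
#'   it, so a study is fully reproducible.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_subjects = 28, n_blocks_per_condition = 2,
                         n_trials_per_block = 8, duration_s = 15,
                         tas_mean = 43.6, tas_sd = 11.5,
                         iri_mean = 98.75, iri_sd = 8,
                         rho_tas_emotion = -0.4, seed = 1) {
  stopifnot(n_subjects >= 1, n_blocks_per_condition >= 1,
            n_trials_per_block >= 1, duration_s > 0,
            abs(rho_tas_emotion) <= 1)
  structure(list(n_subjects = n_subjects,
                 n_blocks_per_condition = n_blocks_per_condition,
                 n_trials_per_block = n_trials_per_block,
                 duration_s = duration_s, tas_mean = tas_mean,
                 tas_sd = tas_sd, iri_mean = iri_mean, iri_sd = iri_sd,
                 rho_tas_emotion = rho_tas_emotion, seed = seed),
            class = "study_config")
}

# --- seeded RNG plumbing ----------------------------------------------------
# Each trial / subject / stage gets its own Mersenne-Twister stream seeded by
# mixing the master seed with the indices below (a multiplicative hash mod
# 2^31 - 1), so any single trial is reproducible in isolation and platform
# differences reduce to R's own RNG.

mix_seed <- function(...) {
  parts <- as.numeric(c(...))
  h <- 104729
  for (p in parts) h <- (h * 69069 + abs(p) + 1) %% 2147483629
  as.integer(h)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# per-subject latent state: a happy-dominance factor z scales the happy
# duration distribution and tilts the first-percept odds
subject_state <- function(params, z = 0, z_neutral = 0) {
  list(z = z,
       mult_happy = exp(params$subject_sd * z),
       mult_neutral = exp(params$subject_sd * z_neutral),
       p_first = stats::plogis(stats::qlogis(params$p_first_happy) + 0.4 * z))
}

# latent percept path: alternating gamma renewal with optional mixed
# interludes; returns a list of label/t_on/t_off vectors (untruncated jitter-
# free ground truth, clipped at the trial duration)
simulate_percept_path <- function(params, state, mimicry, duration_s,
                                  neutral_multiplier = 1) {
  scale_h <- params$gamma_scale_happy * state$mult_happy
  scale_n <- params$gamma_scale_neutral * state$mult_neutral *
    (if (mimicry == "blocked") neutral_multiplier else 1)
  t <- stats::rlnorm(1, params$onset_mu, params$onset_sigma)
  lab <- if (stats::runif(1) < state$p_first) "happy" else "neutral"
  labels <- character(0); t_on <- numeric(0); t_off <- numeric(0)
  while (t < duration_s) {
    dur <- if (lab == "happy") {
      stats::rgamma(1, shape = params$gamma_shape_happy, scale = scale_h)
    } else {
      stats::rgamma(1, shape = params$gamma_shape_neutral, scale = scale_n)
    }
    labels <- c(labels, lab)
    t_on <- c(t_on, t)
    t_off <- c(t_off, min(t + dur, duration_s))
    t <- t + dur
    if (t >= duration_s) break
    if (stats::runif(1) < params$p_mixed_interlude) {
      mdur <- stats::rlnorm(1, params$mixed_mu, params$mixed_sigma)
      labels <- c(labels, "mixed")
      t_on <- c(t_on, t)
      t_off <- c(t_off, min(t + mdur, duration_s))
      t <- t + mdur
      if (t >= duration_s) break
    }
    lab <- if (lab == "happy") "neutral" else "happy"
  }
  list(label = labels, t_on = t_on, t_off = t_off)
}

#' Simulate one rivalry trial
#'
#' Draws a latent percept path (initial unresolved period, then alternating
#' gamma-distributed dominance epochs with optional mixed interludes) and
#' serializes it to hold-to-report key events with Gaussian report-latency
#' jitter. Jitter is truncated so a press always precedes its release; an
#' epoch still dominant at trial end is emitted with a missing release (key
#' held to the end). Fully deterministic given `seed`.
#'
#' @param params A [rivalry_params()].
#' @param state Subject latent state (from the internal subject model);
#'   `NULL` for a population-average subject.
#' @param mimicry `"free"` or `"blocked"`.
#' @param neutral_multiplier Neutral duration-scale multiplier applied in the
#'   blocked condition (from [calibrate_neutral_multiplier()]; 1 = null).
#' @param key_map A [key_map()] for serialization.
#' @param subject_id,block,trial,stimulus_id Design labels for the trial.
#' @param duration_s Trial duration in seconds.
#' @param seed Integer seed for this trial's RNG stream (`NULL` uses the
#'   current RNG state).
#' @return A [br_trial()] with the latent path attached as attribute
#'   `"truth"`.
#' @export
simulate_trial <- function(params = rivalry_params(), state = NULL,
                           mimicry = "free", neutral_multiplier = 1,
                           key_map = brivalry::key_map(),
                           subject_id = "s01", block = 1L, trial = 1L,
                           stimulus_id = "stim1", duration_s = 15,
                           seed = NULL) {
  if (is.null(state)) state <- subject_state(params)
  run <- function() {
    path <- simulate_percept_path(params, state, mimicry, duration_s,
                                  neutral_multiplier)
    n <- length(path$label)
    if (n == 0) {
      return(list(path = path, events = empty_events()))
    }
    inv <- stats::setNames(names(key_map), unname(key_map))
    sd <- params$report_latency_sd
    press <- pmax(0, path$t_on + stats::rnorm(n, 0, sd))
    release <- path$t_off + stats::rnorm(n, 0, sd)
    release <- pmax(release, press + 1e-3)
    release[path$t_off >= duration_s] <- NA_real_  # held to trial end
    keep <- press < duration_s
    list(path = path,
         events = tibble::new_tibble(
           list(key = unname(inv[path$label[keep]]),
                t_press = press[keep], t_release = release[keep]),
           nrow = sum(keep)))
  }
  out <- if (is.null(seed)) run() else with_seed(seed, run())
  tr <- br_trial(subject_id = subject_id, mimicry = mimicry, block = block,
                 trial = trial, stimulus_id = stimulus_id, key_map = key_map,
                 duration_s = duration_s, events = out$events)
  attr(tr, "truth") <- out$path
  tr
}

#' Calibrate the blocked-condition neutral scale multiplier
#'
#' Maps a target increment of per-trial mean neutral cumulative time (the
#' injected condition effect) to a multiplier on the neutral gamma scale, by
#' bisection on a Monte-Carlo estimate of mean neutral CT computed with
#' common random numbers (the same per-trial seeds at every multiplier, so
#' the objective is a deterministic, effectively monotone function).
#'
#' @param params A [rivalry_params()].
#' @param delta_s Target increment in seconds (defaults to the value stored
#'   in `params`).
#' @param n_trials Monte-Carlo trials per objective evaluation.
#' @param duration_s Trial duration.
#' @param seed Seed for the common random numbers.
#' @return The multiplier (1 when `delta_s` is 0).
#' @export
calibrate_neutral_multiplier <- function(params,
                                         delta_s = params$blocked_neutral_ct_delta_s,
                                         n_trials = 8000, duration_s = 15,
                                         seed = 202601) {
  if (delta_s <= 0) return(1)
  key <- paste(c(unlist(params), delta_s, n_trials, duration_s, seed),
               collapse = "|")
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  mean_neutral_ct <- function(m) {
    tot <- 0
    for (i in seq_len(n_trials)) {
      tot <- tot + with_seed(mix_seed(seed, 7, i), {
        st <- subject_state(params, z = stats::rnorm(1), z_neutral = stats::rnorm(1))
        path <- simulate_percept_path(params, st, "blocked", duration_s, m)
        sum((path$t_off - path$t_on)[path$label == "neutral"])
      })
    }
    tot / n_trials
  }
  base <- mean_neutral_ct(1)
  target <- base + delta_s
  lo <- 1; hi <- 2
  while (mean_neutral_ct(hi) < target && hi < 16) hi <- hi * 1.5
  for (i in 1:24) {
    mid <- (lo + hi) / 2
    if (mean_neutral_ct(mid) < target) lo <- mid else hi <- mid
  }
  m <- (lo + hi) / 2
  .calibration_cache[[key]] <- m
  m
}

.calibration_cache <- new.env(parent = emptyenv())

#' Simulate a full counterbalanced rivalry study
#'
#' Generates keypress-level sessions for the whole design: condition order
#' alternates across subjects, the happy/neutral key assignment alternates
#' across blocks, each block presents the four rival stimuli twice in random
#' order, and per-subject latent happy-dominance factors drive both the
#' rivalry process and (via `rho_tas_emotion`) the TAS-20 scores. Stimulus
#' valence/arousal ratings are generated per condition with happy rated more
#' positive and more arousing than neutral.
#'
#' @param config A [study_config()].
#' @param params A [rivalry_params()].
#' @param neutral_multiplier Multiplier realizing the injected blocked-
#'   condition neutral CT effect; `NULL` (default) calibrates it from
#'   `params$blocked_neutral_ct_delta_s` via
#'   [calibrate_neutral_multiplier()].
#' @return List with `sessions` (list of [br_session()]) and `truth`, a
#'   ground-truth record of all latent parameters (per-subject factors,
#'   multiplier, params, config).
#' @export
simulate_study <- function(config = study_config(),
                           params = rivalry_params(),
                           neutral_multiplier = NULL) {
  if (is.null(neutral_multiplier)) {
    neutral_multiplier <- calibrate_neutral_multiplier(params)
  }
  seed <- config$seed
  rho <- config$rho_tas_emotion
  n_cond_blocks <- config$n_blocks_per_condition
  sessions <- vector("list", config$n_subjects)
  subj_truth <- vector("list", config$n_subjects)
  stimuli <- paste0("stim", 1:4)
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("s%02d", i)
    lat <- with_seed(mix_seed(seed, 1, i), {
      z <- stats::rnorm(1); z2 <- stats::rnorm(1)
      e_tas <- stats::rnorm(1); e_iri <- stats::rnorm(1)
      list(z = z, z2 = z2,
           tas = config$tas_mean +
             config$tas_sd * (rho * z + sqrt(1 - rho^2) * e_tas),
           iri = config$iri_mean + config$iri_sd * e_iri)
    })
    st <- subject_state(params, lat$z, lat$z2)
    order_free_first <- i %% 2 == 1
    cond_of_block <- function(b) {
      first <- if (order_free_first) "free" else "blocked"
      second <- setdiff(MIMICRY_LEVELS, first)
      if (b <= n_cond_blocks) first else second
    }
    trials <- list()
    for (b in seq_len(2 * n_cond_blocks)) {
      mim <- cond_of_block(b)
      km <- if (b %% 2 == 1) key_map(happy = "b", neutral = "m", mixed = "n")
            else key_map(happy = "m", neutral = "b", mixed = "n")
      stim_seq <- with_seed(mix_seed(seed, 4, i, b), {
        s <- rep(stimuli, length.out = config$n_trials_per_block)
        sample(s)
      })
      for (k in seq_len(config$n_trials_per_block)) {
        trials[[length(trials) + 1]] <- simulate_trial(
          params, st, mimicry = mim,
          neutral_multiplier = neutral_multiplier, key_map = km,
          subject_id = sid, block = b, trial = k,
          stimulus_id = stim_seq[k], duration_s = config$duration_s,
          seed = mix_seed(seed, 2, i, b, k))
      }
    }
    ratings <- with_seed(mix_seed(seed, 3, i), {
      grid <- tidyr::expand_grid(mimicry = MIMICRY_LEVELS,
                                 stimulus_id = stimuli,
                                 expression = c("happy", "neutral"))
      happy <- grid$expression == "happy"
      grid$valence <- round(pmin(3, pmax(-3, stats::rnorm(
        nrow(grid), ifelse(happy, 2.15, -0.63), ifelse(happy, 1.12, 0.98)))))
      grid$arousal <- round(pmin(7, pmax(1, stats::rnorm(
        nrow(grid), ifelse(happy, 4.97, 2.74), ifelse(happy, 1.63, 1.54)))))
      grid
    })
    sessions[[i]] <- br_session(
      subject_id = sid,
      condition_order = if (order_free_first) "free-first" else "blocked-first",
      trials = trials, tas20_total = lat$tas, iri_total = lat$iri,
      ratings = ratings)
    subj_truth[[i]] <- tibble::tibble(
      subject = sid, z_happy_dominance = lat$z, mult_happy = st$mult_happy,
      mult_neutral = st$mult_neutral, p_first = st$p_first,
      tas20 = lat$tas, iri = lat$iri)
  }
  list(sessions = sessions,
       truth = list(params = unclass(params), config = unclass(config),
                    neutral_multiplier = neutral_multiplier,
                    subjects = dplyr::bind_rows(subj_truth)))
}

#' Rasterization oracle for trial metrics
#'
#' Computes IP/ORT/CT by brute force on a fixed time grid: at each grid cell
#' the dominant label is that of the most recent still-held press (hold
#' convention) or of the most recent press (toggle convention). Entirely
#' independent of the interval sweep in [events_to_intervals()]; intended as
#' a test oracle, accurate to one grid step per event.
#'
#' @param trial A [br_trial()].
#' @param resolution Grid step in seconds (default 1 ms).
#' @param report `"hold"` or `"toggle"`.
#' @return One-row tibble with columns `ip`, `ort_s`, `ct_happy_s`,
#'   `ct_neutral_s`, `ct_mixed_s`, `unreported_s`.
#' @export
grid_oracle_metrics <- function(trial, resolution = 1e-3,
                                report = c("hold", "toggle")) {
  report <- match.arg(report)
  dur <- trial$duration_s
  n <- as.integer(round(dur / resolution))
  mid <- (seq_len(n) - 0.5) * resolution
  ev <- trial$events
  cell_lab <- rep(NA_character_, n)
  if (nrow(ev) > 0) {
    press <- pmax(0, ev$t_press)
    release <- ev$t_release
    release[is.na(release)] <- dur
    release <- pmin(release, dur)
    labels <- unname(trial$key_map[ev$key])
    best <- rep(-Inf, n)
    for (j in seq_len(nrow(ev))) {
      cover <- if (report == "hold") {
        mid >= press[j] & mid < release[j]
      } else {
        mid >= press[j]
      }
      upd <- cover & press[j] >= best
      cell_lab[upd] <- labels[j]
      best[upd] <- press[j]
    }
  }
  ct <- stats::setNames(numeric(3), PERCEPT_LABELS)
  for (lab in PERCEPT_LABELS) {
    ct[lab] <- sum(cell_lab == lab, na.rm = TRUE) * resolution
  }
  clear_idx <- which(!is.na(cell_lab) & cell_lab != "mixed")
  if (length(clear_idx) == 0) {
    ip <- "none"; ort <- NA_real_
  } else {
    ip <- cell_lab[clear_idx[1]]
    ort <- (clear_idx[1] - 1) * resolution
  }
  tibble::tibble(ip = ip, ort_s = ort,
                 ct_happy_s = unname(ct[["happy"]]),
                 ct_neutral_s = unname(ct[["neutral"]]),
                 ct_mixed_s = unname(ct[["mixed"]]),
                 unreported_s = dur - sum(ct))
}
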