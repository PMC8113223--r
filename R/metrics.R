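# Reduction of keypress events to percept-dominance intervals and the three
# rivalry components: initial percept (IP), onset resolution time (ORT) and
# per-percept cumulative time (CT).

#' Convert a trial's key events into percept-dominance intervals
#'
#' Under the default hold-to-report convention a percept is dominant while
#' its key is held; when several keys are held at once the most recent press
#' wins (a new press truncates the currently open interval, and an earlier
#' still-held key resumes when the later one is released). Gaps between holds
#' are unreported time. Under the toggle convention each press switches the
#' reported percept until the next press and releases are ignored. Events are
#' clipped to `[0, duration]`; zero-length intervals are dropped and adjacent
#' intervals with the same label are merged.
#'
#' @param trial A [br_trial()].
#' @param report `"hold"` (default) or `"toggle"`.
#' @return Tibble with columns `label`, `t_on`, `t_off`; non-overlapping and
#'   time-ordered. Zero rows for an uncoded trial.
#' @export
events_to_intervals <- function(trial, report = c("hold", "toggle")) {
  report <- match.arg(report)
  core <- intervals_core(trial, report)
  tibble::new_tibble(core, nrow = length(core$label))
}

# plain-vector implementation shared by the public parser and the per-trial
# metrics fast path; returns list(label, t_on, t_off)
intervals_core <- function(trial, report = "hold") {
  ev <- trial$events
  dur <- trial$duration_s
  empty <- list(label = character(0), t_on = double(0), t_off = double(0))
  if (length(ev$key) == 0) return(empty)
  labels <- unname(trial$key_map[ev$key])

  if (report == "toggle") {
    on <- pmax(0, pmin(ev$t_press, dur))
    keep <- on < dur
    on <- on[keep]; lab <- labels[keep]
    o <- order(on)
    on <- on[o]; lab <- lab[o]
    off <- c(on[-1], dur)
    return(coalesce_core(lab, on, off))
  }

  press <- pmax(0, ev$t_press)
  release <- pmin(ev$t_release, dur)
  keep <- press < dur & release > 0 & release > press
  press <- press[keep]; release <- release[keep]; lab <- labels[keep]
  if (length(press) == 0) return(empty)

  bounds <- sort(unique(c(press, release)))
  n_seg <- length(bounds) - 1
  n_out <- 0L
  out_label <- character(n_seg)
  out_on <- double(n_seg)
  out_off <- double(n_seg)
  for (i in seq_len(n_seg)) {
    t0 <- bounds[i]
    held <- which(press <= t0 & release > t0)
    if (length(held) == 0) next
    # most recent press wins; break exact ties by input order (last row)
    winner <- held[max(which(press[held] == max(press[held])))]
    n_out <- n_out + 1L
    out_label[n_out] <- lab[winner]
    out_on[n_out] <- t0
    out_off[n_out] <- bounds[i + 1]
  }
  if (n_out == 0) return(empty)
  coalesce_core(out_label[seq_len(n_out)], out_on[seq_len(n_out)],
                out_off[seq_len(n_out)])
}

# merge adjacent same-label intervals, drop zero-length ones
coalesce_core <- function(lab, on, off) {
  keep <- off > on
  lab <- lab[keep]; on <- on[keep]; off <- off[keep]
  n <- length(lab)
  if (n > 1) {
    new_run <- c(TRUE, lab[-1] != lab[-n] | on[-1] > off[-n] + 1e-12)
    first <- which(new_run)
    last <- c(first[-1] - 1L, n)
    lab <- lab[first]; on <- on[first]; off <- off[last]
  }
  list(label = lab, t_on = on, t_off = off)
}

#' Initial percept of a trial
#'
#' The label of the first non-mixed dominance interval: the first clear
#' (happy or neutral) percept the observer reported. Mixed intervals do not
#' count as an initial percept; `"none"` if the trial contains no clear
#' report.
#'
#' @param intervals Time-ordered intervals from [events_to_intervals()].
#' @return `"happy"`, `"neutral"`, or `"none"`.
#' @export
initial_percept <- function(intervals) {
  clear <- intervals$label != "mixed"
  if (!any(clear)) return("none")
  unname(intervals$label[which(clear)[1]])
}

#' Onset resolution time of a trial
#'
#' Seconds from trial onset to the first clear (non-mixed) report: the time
#' the visual system took to resolve the initial perceptual ambiguity. A
#' preceding mixed report does not stop the clock.
#'
#' @inheritParams initial_percept
#' @return Onset time in seconds, or `NA_real_` when no clear percept was
#'   reported.
#' @export
onset_resolution_time <- function(intervals) {
  clear <- intervals$label != "mixed"
  if (!any(clear)) return(NA_real_)
  intervals$t_on[which(clear)[1]]
}

#' Cumulative dominance time per percept
#'
#' Sums interval durations per label; whatever the observer did not report is
#' returned as `unreported_s`, so the four quantities always add up to the
#' trial duration.
#'
#' @inheritParams initial_percept
#' @param duration Trial duration in seconds.
#' @return List with `ct` (named numeric over happy/neutral/mixed) and
#'   `unreported_s`.
#' @export
cumulative_times <- function(intervals, duration) {
  ct <- stats::setNames(numeric(3), PERCEPT_LABELS)
  if (length(intervals$label) > 0) {
    dur <- intervals$t_off - intervals$t_on
    for (lab in PERCEPT_LABELS) ct[[lab]] <- sum(dur[intervals$label == lab])
  }
  list(ct = ct, unreported_s = duration - sum(ct))
}

#' All three rivalry components for one trial
#'
#' @param trial A [br_trial()].
#' @param report Report convention, see [events_to_intervals()].
#' @return One-row tibble: `subject`, `mimicry`, `block`, `trial`,
#'   `stimulus`, `coded`, `ip`, `ort_s`, `ct_happy_s`, `ct_neutral_s`,
#'   `ct_mixed_s`, `unreported_s`.
#' @export
trial_metrics <- function(trial, report = "hold") {
  tibble::as_tibble(trial_metrics_row(trial, report))
}

# plain-list fast path used by metrics_table() to avoid per-trial tibbles
trial_metrics_row <- function(trial, report = "hold") {
  iv <- intervals_core(trial, report)
  cts <- cumulative_times(iv, trial$duration_s)
  list(subject = trial$subject_id, mimicry = trial$mimicry,
       block = trial$block, trial = trial$trial,
       stimulus = trial$stimulus_id, coded = length(trial$events$key) > 0,
       ip = initial_percept(iv), ort_s = onset_resolution_time(iv),
       ct_happy_s = unname(cts$ct[["happy"]]),
       ct_neutral_s = unname(cts$ct[["neutral"]]),
       ct_mixed_s = unname(cts$ct[["mixed"]]),
       unreported_s = cts$unreported_s,
       duration_s = trial$duration_s)
}

#' Trial-level metrics table for a set of sessions
#'
#' @param sessions List of [br_session()] objects.
#' @inheritParams trial_metrics
#' @return Tibble with one row per trial (uncoded trials included, flagged
#'   by `coded = FALSE`).
#' @export
metrics_table <- function(sessions, report = "hold") {
  rows <- unlist(lapply(sessions, function(s) {
    lapply(s$trials, trial_metrics_row, report = report)
  }), recursive = FALSE)
  if (length(rows) == 0) {
    return(trial_metrics(br_trial("x", "free", 1, 1, "s"))[0, ])
  }
  field <- function(nm) unlist(lapply(rows, `[[`, nm), use.names = FALSE)
  tibble::tibble(
    subject = field("subject"), mimicry = field("mimicry"),
    block = field("block"), trial = field("trial"),
    stimulus = field("stimulus"), coded = field("coded"),
    ip = field("ip"), ort_s = field("ort_s"),
    ct_happy_s = field("ct_happy_s"), ct_neutral_s = field("ct_neutral_s"),
    ct_mixed_s = field("ct_mixed_s"), unreported_s = field("unreported_s"),
    duration_s = field("duration_s"))
}

#' Subject-level aggregation of trial metrics
#'
#' One row per subject x mimicry condition x percept label. Mean CT is taken
#' over all coded trials in the cell; mean ORT over the trials whose initial
#' percept equals the label (so it is defined for happy/neutral only and may
#' be `NA` when the subject never had that IP); `ip_count` counts those
#' trials. Uncoded trials are excluded from every denominator.
#'
#' @param metrics Tibble from [metrics_table()].
#' @return Tibble with columns `subject`, `mimicry`, `label`, `mean_ct_s`,
#'   `mean_ort_s`, `ip_count`, `n_trials_used`.
#' @export
summarize_subjects <- function(metrics) {
  coded <- metrics[metrics$coded, , drop = FALSE]
  cells <- tidyr::expand_grid(
    subject = unique(metrics$subject),
    mimicry = MIMICRY_LEVELS,
    label = PERCEPT_LABELS)
  ct_col <- c(happy = "ct_happy_s", neutral = "ct_neutral_s",
              mixed = "ct_mixed_s")
  stats_one <- function(sub, mim, lab) {
    rows <- coded[coded$subject == sub & coded$mimicry == mim, , drop = FALSE]
    n_used <- nrow(rows)
    mean_ct <- if (n_used > 0) mean(rows[[ct_col[[lab]]]]) else NA_real_
    if (lab == "mixed") {
      list(mean_ct_s = mean_ct, mean_ort_s = NA_real_, ip_count = NA_integer_,
           n_trials_used = n_used)
    } else {
      hit <- rows$ip == lab
      list(mean_ct_s = mean_ct,
           mean_ort_s = if (any(hit)) mean(rows$ort_s[hit]) else NA_real_,
           ip_count = sum(hit), n_trials_used = n_used)
    }
  }
  res <- unname(Map(stats_one, cells$subject, cells$mimicry, cells$label))
  cells$mean_ct_s <- vapply(res, `[[`, double(1), "mean_ct_s")
  cells$mean_ort_s <- vapply(res, `[[`, double(1), "mean_ort_s")
  cells$ip_count <- vapply(res, `[[`, integer(1), "ip_count")
  cells$n_trials_used <- vapply(res, `[[`, integer(1), "n_trials_used")
  cells
}

#' Exclude subjects without a complete initial-percept design from ORT
#'
#' ORT enters a mimicry x IP repeated-measures ANOVA, which needs every
#' subject to contribute all four cells (2 conditions x 2 clear percepts). A
#' subject missing any IP in any condition (`ip_count = 0`) is excluded from
#' the ORT analysis only; CT analyses keep all subjects.
#'
#' @param cells Tibble from [summarize_subjects()].
#' @return List with `kept` and `excluded` character vectors of subject ids,
#'   and `cells_kept`, the ORT-relevant rows (happy/neutral labels) of the
#'   kept subjects.
#' @export
apply_ort_exclusions <- function(cells) {
  ort_cells <- cells[cells$label %in% c("happy", "neutral"), , drop = FALSE]
  bad <- unique(ort_cells$subject[ort_cells$ip_count == 0 |
                                    is.na(ort_cells$mean_ort_s)])
  kept <- setdiff(unique(cells$subject), bad)
  list(kept = kept, excluded = bad,
       cells_kept = ort_cells[ort_cells$subject %in% kept, , drop = FALSE])
}

#' Attach log-transformed ORT for analysis
#'
#' Natural log of the mean ORT in seconds (`log_ort` column); the original
#' value is retained. An exact zero (a clear report at trial onset) is
#' floored at `floor_s` before the log; negative values are an error since
#' they cannot arise from valid intervals.
#'
#' @param cells Tibble with a `mean_ort_s` column.
#' @param floor_s Floor in seconds applied before the log (default 1 ms).
#' @return `cells` with an added `log_ort` column.
#' @export
log_transform_ort <- function(cells, floor_s = 1e-3) {
  x <- cells$mean_ort_s
  if (any(x < 0, na.rm = TRUE)) {
    stop("negative mean ORT encountered; intervals are invalid", call. = FALSE)
  }
  cells$log_ort <- log(pmax(x, floor_s))
  cells
}
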