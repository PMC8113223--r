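# Data model for continuous-report binocular rivalry sessions:
# keypress events -> trials -> sessions, plus CSV/JSON readers and writers.

PERCEPT_LABELS <- c("happy", "neutral", "mixed")
MIMICRY_LEVELS <- c("free", "blocked")

#' Key-to-percept mapping for a rivalry trial
#'
#' Observers report the currently dominant percept by holding one of three
#' adjacent keys. A `key_map` records which physical key codes which percept.
#' Exactly one key maps to each of the three labels (`happy`, `neutral`,
#' `mixed`); in the canonical layout the middle key always codes the mixed
#' percept while the outer two are counterbalanced across blocks.
#'
#' @param happy,neutral,mixed Single-character key symbols.
#' @return A named character vector of class `key_map`: names are key
#'   symbols, values are percept labels.
#' @examples
#' key_map(happy = "b", neutral = "m", mixed = "n")
#' @export
key_map <- function(happy = "b", neutral = "m", mixed = "n") {
  keys <- c(happy = happy, neutral = neutral, mixed = mixed)
  if (anyDuplicated(keys)) {
    stop("key_map: the three keys must be distinct", call. = FALSE)
  }
  km <- stats::setNames(names(keys), unname(keys))
  class(km) <- "key_map"
  km
}

#' A single rivalry trial
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param mimicry `"free"` or `"blocked"` facial-mimicry condition.
#' @param block Block index within the session (1-based).
#' @param trial Trial index within the block (1-based).
#' @param stimulus_id Identifier of the rival stimulus pair.
#' @param key_map A [key_map()].
#' @param duration_s Trial duration in seconds (default 15).
#' @param events Tibble with columns `key`, `t_press`, `t_release` (seconds
#'   from trial onset). `t_release` may be `NA` for a key still held at trial
#'   end; it is imputed at `duration_s`. Rows are sorted by `t_press`.
#' @return An object of class `br_trial`.
#' @export
br_trial <- function(subject_id, mimicry, block, trial, stimulus_id,
                     key_map = brivalry::key_map(), duration_s = 15,
                     events = empty_events()) {
  mimicry <- match.arg(mimicry, MIMICRY_LEVELS)
  stopifnot(duration_s > 0)
  events <- tibble::as_tibble(events)
  stopifnot(all(c("key", "t_press", "t_release") %in% names(events)))
  if (nrow(events) > 0) {
    bad <- setdiff(unique(events$key), names(key_map))
    if (length(bad) > 0) {
      stop("br_trial: unknown key symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    events$t_release[is.na(events$t_release)] <- duration_s
    if (any(events$t_press < 0)) {
      stop("br_trial: negative press time", call. = FALSE)
    }
    if (any(events$t_release <= events$t_press)) {
      stop("br_trial: t_release must exceed t_press", call. = FALSE)
    }
    events <- events[order(events$t_press), , drop = FALSE]
  }
  structure(
    list(subject_id = as.character(subject_id), mimicry = mimicry,
         block = as.integer(block), trial = as.integer(trial),
         stimulus_id = as.character(stimulus_id), key_map = key_map,
         duration_s = duration_s, events = events),
    class = "br_trial"
  )
}

empty_events <- function() {
  tibble::tibble(key = character(), t_press = double(), t_release = double())
}

#' A rivalry session (one subject's full run)
#'
#' @param subject_id Subject identifier.
#' @param condition_order `"free-first"` or `"blocked-first"`.
#' @param trials List of [br_trial()] objects.
#' @param tas20_total Toronto Alexithymia Scale total score (or `NA`).
#' @param iri_total Interpersonal Reactivity Index total score (or `NA`).
#' @param ratings Tibble with columns `mimicry`, `stimulus_id`, `valence`
#'   (-3..+3), `arousal` (1..7), `expression` (`happy`/`neutral`), or `NULL`.
#' @return An object of class `br_session`.
#' @export
br_session <- function(subject_id, condition_order = "free-first",
                       trials = list(), tas20_total = NA_real_,
                       iri_total = NA_real_, ratings = NULL) {
  condition_order <- match.arg(condition_order, c("free-first", "blocked-first"))
  stopifnot(all(vapply(trials, inherits, logical(1), "br_trial")))
  structure(
    list(subject_id = as.character(subject_id),
         condition_order = condition_order, trials = trials,
         tas20_total = tas20_total, iri_total = iri_total,
         ratings = ratings),
    class = "br_session"
  )
}

#' @export
print.br_session <- function(x, ...) {
  cat(sprintf("<br_session %s: %d trials, order %s, TAS-20 %s, IRI %s>\n",
              x$subject_id, length(x$trials), x$condition_order,
              format(x$tas20_total), format(x$iri_total)))
  invisible(x)
}

#' @export
print.br_trial <- function(x, ...) {
  cat(sprintf("<br_trial %s %s block %d trial %d (%s): %d events / %gs>\n",
              x$subject_id, x$mimicry, x$block, x$trial, x$stimulus_id,
              nrow(x$events), x$duration_s))
  invisible(x)
}

#' Event-log dialect
#'
#' Describes how an on-disk event log maps onto the internal schema: column
#' names, the time unit, and the report convention used to turn keypresses
#' into dominance intervals.
#'
#' @param columns Named character vector mapping internal field names to file
#'   column names. Internal fields: `subject`, `mimicry`, `block`, `trial`,
#'   `stimulus`, `duration`, `key`, `t_press`, `t_release`, `key_happy`,
#'   `key_neutral`, `key_mixed`, `tas20`, `iri`.
#' @param time_unit `"s"` or `"ms"`; times are converted to seconds on load.
#' @param report `"hold"` (a percept is dominant while its key is held; the
#'   default) or `"toggle"` (each press switches the reported percept until
#'   the next press; releases are ignored).
#' @return A list of class `event_dialect`.
#' @export
event_dialect <- function(columns = NULL, time_unit = c("s", "ms"),
                          report = c("hold", "toggle")) {
  default <- c(subject = "subject", mimicry = "mimicry", block = "block",
               trial = "trial", stimulus = "stimulus",
               duration = "duration_s", key = "key", t_press = "t_press",
               t_release = "t_release", key_happy = "key_happy",
               key_neutral = "key_neutral", key_mixed = "key_mixed",
               tas20 = "tas20", iri = "iri")
  if (!is.null(columns)) default[names(columns)] <- columns
  structure(list(columns = default, time_unit = match.arg(time_unit),
                 report = match.arg(report)),
            class = "event_dialect")
}

#' Read a long-format rivalry event log
#'
#' One row per key event. A trial that was presented but never coded
#' ("uncoded") is declared by a single row with an empty `key` and missing
#' times; it is kept in the session so that validation can flag it. A missing
#' `t_release` on a coded row means the key was still held at trial end and
#' is imputed at the trial duration. Row order is irrelevant: events are
#' sorted by press time on load.
#'
#' @param path CSV (`.csv`) or JSON (`.json`) event log.
#' @param dialect An [event_dialect()].
#' @param ratings_path Optional CSV of stimulus ratings with columns
#'   `subject`, `mimicry`, `stimulus`, `expression`, `valence`, `arousal`.
#' @return A list of [br_session()] objects, sorted by subject id.
#' @export
read_event_log <- function(path, dialect = event_dialect(),
                           ratings_path = NULL) {
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  cols <- dialect$columns
  missing_cols <- setdiff(unname(cols[c("subject", "mimicry", "block", "trial",
                                        "key", "t_press")]), names(raw))
  if (length(missing_cols) > 0) {
    stop("event log is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  get <- function(field, default = NULL) {
    cn <- cols[[field]]
    if (cn %in% names(raw)) raw[[cn]] else default
  }
  n <- nrow(raw)
  tab <- tibble::tibble(
    row = seq_len(n),
    subject = as.character(get("subject")),
    mimicry = as.character(get("mimicry")),
    block = as.integer(get("block")),
    trial = as.integer(get("trial")),
    stimulus = as.character(get("stimulus", "stim")),
    duration = as.numeric(get("duration", 15)),
    key = as.character(get("key")),
    t_press = as.numeric(get("t_press")),
    t_release = as.numeric(get("t_release", NA_real_)),
    key_happy = as.character(get("key_happy", "b")),
    key_neutral = as.character(get("key_neutral", "m")),
    key_mixed = as.character(get("key_mixed", "n")),
    tas20 = as.numeric(get("tas20", NA_real_)),
    iri = as.numeric(get("iri", NA_real_))
  )
  if (dialect$time_unit == "ms") {
    tab$t_press <- tab$t_press / 1000
    tab$t_release <- tab$t_release / 1000
  }
  bad_mim <- !tab$mimicry %in% MIMICRY_LEVELS
  if (any(bad_mim)) {
    stop("unknown mimicry condition in row(s) ",
         paste(utils::head(tab$row[bad_mim], 5), collapse = ", "), call. = FALSE)
  }

  sessions <- lapply(split(tab, tab$subject), build_session_from_rows)
  sessions <- sessions[order(names(sessions))]
  if (!is.null(ratings_path)) {
    rt <- readr::read_csv(ratings_path, show_col_types = FALSE, progress = FALSE)
    for (i in seq_along(sessions)) {
      sid <- sessions[[i]]$subject_id
      sub <- rt[as.character(rt$subject) == sid, , drop = FALSE]
      if (nrow(sub) > 0) {
        sessions[[i]]$ratings <- tibble::tibble(
          mimicry = as.character(sub$mimicry),
          stimulus_id = as.character(sub$stimulus),
          expression = as.character(sub$expression),
          valence = as.numeric(sub$valence),
          arousal = as.numeric(sub$arousal))
      }
    }
  }
  unname(sessions)
}

build_session_from_rows <- function(rows) {
  key_groups <- split(rows, list(rows$mimicry, rows$block, rows$trial),
                      drop = TRUE)
  trials <- lapply(key_groups, function(g) {
    meta <- unique(g[, c("stimulus", "duration", "key_happy", "key_neutral",
                         "key_mixed")])
    if (nrow(meta) > 1) {
      stop(sprintf(
        "integrity error: conflicting metadata for subject %s, %s block %d trial %d",
        g$subject[1], g$mimicry[1], g$block[1], g$trial[1]), call. = FALSE)
    }
    km <- key_map(happy = meta$key_happy, neutral = meta$key_neutral,
                  mixed = meta$key_mixed)
    coded <- g[!is.na(g$t_press) & !is.na(g$key) & g$key != "", , drop = FALSE]
    if (nrow(coded) > 0) {
      unknown <- !coded$key %in% names(km)
      if (any(unknown)) {
        stop("format error: unknown key symbol in row(s) ",
             paste(coded$row[unknown], collapse = ", "), call. = FALSE)
      }
      bad_rel <- !is.na(coded$t_release) & coded$t_release <= coded$t_press
      if (any(bad_rel)) {
        stop("record error: t_release <= t_press in row(s) ",
             paste(coded$row[bad_rel], collapse = ", "), call. = FALSE)
      }
    }
    br_trial(subject_id = g$subject[1], mimicry = g$mimicry[1],
             block = g$block[1], trial = g$trial[1],
             stimulus_id = meta$stimulus, key_map = km,
             duration_s = meta$duration,
             events = tibble::tibble(key = coded$key, t_press = coded$t_press,
                                     t_release = coded$t_release))
  })
  ord <- order(vapply(trials, function(t) t$block, integer(1)),
               vapply(trials, function(t) t$trial, integer(1)))
  trials <- unname(trials[ord])
  first_block_mim <- trials[[which.min(vapply(trials, `[[`, integer(1), "block"))]]$mimicry
  br_session(
    subject_id = rows$subject[1],
    condition_order = if (first_block_mim == "free") "free-first" else "blocked-first",
    trials = trials,
    tas20_total = rows$tas20[1], iri_total = rows$iri[1])
}

#' Write sessions back to the long event-log format
#'
#' Inverse of [read_event_log()]: uncoded trials are emitted as a placeholder
#' row with an empty key so that the round trip is the identity on sessions.
#'
#' @param sessions List of [br_session()] objects.
#' @param path Output CSV path.
#' @param ratings_path Optional output CSV for stimulus ratings.
#' @return Invisibly, `path`.
#' @export
write_event_log <- function(sessions, path, ratings_path = NULL) {
  rows <- lapply(sessions, function(s) {
    lapply(s$trials, function(tr) {
      inv <- stats::setNames(names(tr$key_map), unname(tr$key_map))
      base <- tibble::tibble(
        subject = tr$subject_id, mimicry = tr$mimicry, block = tr$block,
        trial = tr$trial, stimulus = tr$stimulus_id,
        duration_s = tr$duration_s,
        key_happy = inv[["happy"]], key_neutral = inv[["neutral"]],
        key_mixed = inv[["mixed"]],
        tas20 = s$tas20_total, iri = s$iri_total)
      if (nrow(tr$events) == 0) {
        cbind(base, tibble::tibble(key = "", t_press = NA_real_,
                                   t_release = NA_real_))
      } else {
        cbind(base[rep(1, nrow(tr$events)), ], tr$events)
      }
    })
  })
  tab <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  tab <- tab[, c("subject", "mimicry", "block", "trial", "stimulus",
                 "duration_s", "key", "t_press", "t_release",
                 "key_happy", "key_neutral", "key_mixed", "tas20", "iri")]
  readr::write_csv(tab, path, progress = FALSE)
  if (!is.null(ratings_path)) {
    rt <- dplyr::bind_rows(lapply(sessions, function(s) {
      if (is.null(s$ratings)) return(NULL)
      cbind(tibble::tibble(subject = s$subject_id), s$ratings)
    }))
    if (!is.null(rt) && nrow(rt) > 0) {
      names(rt)[names(rt) == "stimulus_id"] <- "stimulus"
      readr::write_csv(rt, ratings_path, progress = FALSE)
    }
  }
  invisible(path)
}

#' Validate a session against the design invariants
#'
#' Reports rather than repairs: returns one row per issue with a severity.
#' Trials with no key events are flagged as `"uncoded"` warnings (they stay
#' in the session but are excluded from metric denominators); out-of-range
#' event times, rating-scale violations and over-long sessions are errors.
#'
#' @param session A [br_session()].
#' @return Tibble with columns `severity` (`"warning"`/`"error"`), `trial`
#'   (label or `NA` for session-level issues), `message`. Zero rows iff the
#'   session is clean.
#' @export
validate_session <- function(session) {
  issues <- list()
  add <- function(severity, trial, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      severity = severity, trial = trial, message = message)
  }
  if (length(session$trials) > 32) {
    add("error", NA_character_,
        sprintf("session has %d trials; design maximum is 32",
                length(session$trials)))
  }
  for (tr in session$trials) {
    lab <- sprintf("%s/block%d/trial%d", tr$mimicry, tr$block, tr$trial)
    if (nrow(tr$events) == 0) {
      add("warning", lab, "uncoded trial (no key events)")
      next
    }
    if (any(tr$events$t_press > tr$duration_s) ||
        any(tr$events$t_release > tr$duration_s)) {
      add("error", lab, "event time exceeds trial duration")
    }
    if (any(tr$events$t_press < 0)) add("error", lab, "negative press time")
  }
  if (!is.null(session$ratings)) {
    r <- session$ratings
    if (any(r$valence < -3 | r$valence > 3, na.rm = TRUE)) {
      add("error", NA_character_, "valence rating outside [-3, 3]")
    }
    if (any(r$arousal < 1 | r$arousal > 7, na.rm = TRUE)) {
      add("error", NA_character_, "arousal rating outside [1, 7]")
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(severity = character(), trial = character(),
                   message = character())
  } else {
    dplyr::bind_rows(issues)
  }
}

#' Write tidy trial-level and subject-level tables
#'
#' @param sessions List of sessions (used for provenance columns).
#' @param metrics Trial-level metrics table from [metrics_table()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of written file paths.
#' @export
write_tidy_tables <- function(sessions, metrics, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  trial_path <- file.path(out_dir, "trial_metrics.csv")
  subject_path <- file.path(out_dir, "subject_cells.csv")
  readr::write_csv(metrics, trial_path, progress = FALSE)
  cells <- summarize_subjects(metrics)
  readr::write_csv(cells, subject_path, progress = FALSE)
  invisible(c(trial_metrics = trial_path, subject_cells = subject_path))
}
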