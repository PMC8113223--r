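# Full-study analysis pipeline: ratings -> initial percept -> onset
# resolution time -> cumulative time -> exploratory questionnaire
# correlations, with reproducible output artifacts.

#' Configuration for a full analysis run
#'
#' Exactly one input source must be given: pre-loaded `sessions`, event-log
#' `paths`, or a `simulator` specification.
#'
#' @param sessions List of [br_session()] objects, or `NULL`.
#' @param paths List with `events` (and optionally `ratings`) file paths, or
#'   `NULL`.
#' @param simulator List with elements `config` ([study_config()]) and
#'   `params` ([rivalry_params()]), or `NULL`.
#' @param dialect [event_dialect()] used for file input and for the report
#'   convention when parsing events.
#' @param sided Sidedness of the post-hoc paired contrasts (`"two"`/`"one"`).
#' @param bf_rscale Cauchy prior scale for the JZS Bayes factors.
#' @param posthoc_family Explicit Bonferroni family size for the cumulative-
#'   time post-hoc contrasts (default 3: one contrast per reported content).
#' @param ort_exclusions Apply the complete-IP-design exclusion rule to the
#'   onset-resolution-time ANOVA (default `TRUE`).
#' @param ort_floor_s Floor (seconds) applied to mean ORT before the log.
#' @param out_dir Output directory for tables, JSON results and the run
#'   manifest; `NULL` writes nothing.
#' @param seed Seed recorded in the manifest and forwarded to the simulator
#'   (overrides the seed in `simulator$config` when non-`NULL`).
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(sessions = NULL, paths = NULL, simulator = NULL,
                            dialect = event_dialect(), sided = "two",
                            bf_rscale = sqrt(2) / 2, posthoc_family = 3,
                            ort_exclusions = TRUE, ort_floor_s = 1e-3,
                            out_dir = NULL, seed = NULL) {
  n_src <- sum(!is.null(sessions), !is.null(paths), !is.null(simulator))
  if (n_src != 1) {
    stop("analysis_config: exactly one of sessions, paths, simulator must be given",
         call. = FALSE)
  }
  structure(list(sessions = sessions, paths = paths, simulator = simulator,
                 dialect = dialect, sided = sided, bf_rscale = bf_rscale,
                 posthoc_family = posthoc_family,
                 ort_exclusions = ort_exclusions, ort_floor_s = ort_floor_s,
                 out_dir = out_dir, seed = seed),
            class = "analysis_config")
}

#' Run the full rivalry analysis
#'
#' Executes, in order: (1) valence and arousal rating ANOVAs (mimicry x
#' expression) with a follow-up happy-vs-neutral paired t; (2) the initial-
#' percept stage: frequency table and random-intercept logistic regression of
#' IP on mimicry; (3) the onset-resolution-time stage: complete-design
#' exclusions, log transform, 2x2 repeated-measures ANOVA (mimicry x IP);
#' (4) the cumulative-time stage: 2x3 repeated-measures ANOVA (mimicry x
#' reported content) with Greenhouse-Geisser correction, Bonferroni-adjusted
#' blocked-vs-free post-hoc contrasts per content, and a JZS Bayes factor per
#' contrast; (5) exploratory Pearson correlations of TAS-20 and IRI with ORT
#' and CT per condition and percept, flagged as exploratory and uncorrected.
#' Missing questionnaire scores skip stage 5 with a warning. When `out_dir`
#' is set, each stage's results are written as they complete (so partial
#' output survives a failing stage), together with tidy tables and a run
#' manifest.
#'
#' @param config An [analysis_config()].
#' @return List of class `br_analysis` with elements `sessions`, `metrics`,
#'   `cells`, `ratings`, `ip`, `ort`, `ct`, `correlations`, `manifest`.
#' @export
run_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  res <- list()

  inp <- stage("input", {
    if (!is.null(config$sessions)) {
      list(sessions = config$sessions)
    } else if (!is.null(config$paths)) {
      list(sessions = read_event_log(config$paths$events, config$dialect,
                                     ratings_path = config$paths$ratings))
    } else {
      sim <- config$simulator
      cfg <- if (is.null(sim$config)) study_config() else sim$config
      if (!is.null(config$seed)) cfg$seed <- config$seed
      prm <- if (is.null(sim$params)) rivalry_params() else sim$params
      study <- simulate_study(cfg, prm)
      list(sessions = study$sessions, truth = study$truth)
    }
  })
  sessions <- inp$sessions
  res$truth <- inp$truth
  res$sessions <- sessions

  out_dir <- config$out_dir
  emit <- function(name, obj) {
    if (is.null(out_dir)) return(invisible(NULL))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }

  res$metrics <- stage("metrics", metrics_table(sessions, config$dialect$report))
  res$cells <- stage("metrics", summarize_subjects(res$metrics))
  if (!is.null(out_dir)) {
    write_tidy_tables(sessions, res$metrics, out_dir)
  }

  res$ratings <- stage("ratings", ratings_stage(sessions))
  emit("ratings", res$ratings)

  res$ip <- stage("initial_percept", ip_stage(res$metrics))
  emit("initial_percept", res$ip)

  res$ort <- stage("onset_resolution_time",
                   ort_stage(res$cells, config$ort_exclusions,
                             config$ort_floor_s))
  emit("onset_resolution_time", res$ort)

  res$ct <- stage("cumulative_time",
                  ct_stage(res$cells, sided = config$sided,
                           bf_rscale = config$bf_rscale,
                           family = config$posthoc_family))
  emit("cumulative_time", res$ct)

  res$correlations <- stage("questionnaires",
                            questionnaire_stage(sessions, res$cells))
  emit("questionnaires", res$correlations)

  res$manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    n_subjects = length(sessions),
    n_trials = sum(vapply(sessions, function(s) length(s$trials), integer(1))),
    report_convention = config$dialect$report,
    sided = config$sided, bf_rscale = config$bf_rscale,
    posthoc_family = config$posthoc_family,
    config_hash = rlang::hash(config[setdiff(names(config), c("sessions", "out_dir"))]),
    package_version = as.character(utils::packageVersion("brivalry")),
    r_version = R.version.string)
  emit("manifest", res$manifest)

  class(res) <- "br_analysis"
  res
}

# stage 1: valence/arousal ANOVAs on subject x mimicry x expression means
# (averaged over the individual stimuli) plus the happy-vs-neutral contrast
ratings_stage <- function(sessions) {
  have <- vapply(sessions, function(s) !is.null(s$ratings), logical(1))
  if (!any(have)) {
    warning("no stimulus ratings present; skipping ratings stage",
            call. = FALSE)
    return(NULL)
  }
  tab <- dplyr::bind_rows(lapply(sessions[have], function(s) {
    cbind(tibble::tibble(subject = s$subject_id), s$ratings)
  }))
  agg <- dplyr::summarise(
    dplyr::group_by(tab, .data$subject, .data$mimicry, .data$expression),
    valence = mean(.data$valence), arousal = mean(.data$arousal),
    .groups = "drop")
  av_val <- rm_anova(agg, "valence", within = c("mimicry", "expression"))
  av_aro <- rm_anova(agg, "arousal", within = c("mimicry", "expression"))
  by_expr <- dplyr::summarise(
    dplyr::group_by(agg, .data$subject, .data$expression),
    valence = mean(.data$valence), arousal = mean(.data$arousal),
    .groups = "drop")
  wide_v <- tidyr::pivot_wider(by_expr[, c("subject", "expression", "valence")],
                               names_from = "expression", values_from = "valence")
  wide_a <- tidyr::pivot_wider(by_expr[, c("subject", "expression", "arousal")],
                               names_from = "expression", values_from = "arousal")
  list(table = agg, anova_valence = av_val, anova_arousal = av_aro,
       t_valence = paired_t(wide_v$happy, wide_v$neutral),
       t_arousal = paired_t(wide_a$happy, wide_a$neutral))
}

# stage 2: IP frequencies and the mixed-effects logistic fit
ip_stage <- function(metrics) {
  coded <- metrics[metrics$coded & metrics$ip != "none", , drop = FALSE]
  freq <- dplyr::count(coded, .data$mimicry, .data$ip, name = "n_trials")
  fit <- fit_ip_logistic(coded[, c("subject", "mimicry", "ip")])
  list(frequencies = freq, logistic = fit)
}

# stage 3: ORT exclusions, log transform, 2x2 mimicry x IP ANOVA
ort_stage <- function(cells, apply_exclusions = TRUE, floor_s = 1e-3) {
  if (apply_exclusions) {
    ex <- apply_ort_exclusions(cells)
  } else {
    ort_cells <- cells[cells$label %in% c("happy", "neutral"), , drop = FALSE]
    ex <- list(kept = unique(cells$subject), excluded = character(0),
               cells_kept = ort_cells[!is.na(ort_cells$mean_ort_s), ,
                                      drop = FALSE])
  }
  tab <- log_transform_ort(ex$cells_kept, floor_s)
  anova <- if (length(unique(tab$subject)) >= 2) {
    rm_anova(tab, "log_ort", within = c("mimicry", "label"))
  } else {
    NULL
  }
  list(excluded_subjects = ex$excluded, kept_subjects = ex$kept,
       cells = tab, anova = anova)
}

# stage 4: 2x3 CT ANOVA with GG correction + per-content post-hocs with
# Bonferroni adjustment and JZS Bayes factors
ct_stage <- function(cells, sided = "two", bf_rscale = sqrt(2) / 2,
                     family = 3) {
  complete <- stats::aggregate(is.na(mean_ct_s) ~ subject, data = cells, FUN = sum)
  keep <- complete$subject[complete[[2]] == 0]
  dropped <- setdiff(unique(cells$subject), keep)
  tab <- cells[cells$subject %in% keep, , drop = FALSE]
  anova <- rm_anova(tab, "mean_ct_s", within = c("mimicry", "label"))
  posthoc <- dplyr::bind_rows(lapply(PERCEPT_LABELS, function(lab) {
    w <- tidyr::pivot_wider(
      tab[tab$label == lab, c("subject", "mimicry", "mean_ct_s")],
      names_from = "mimicry", values_from = "mean_ct_s")
    tt <- paired_t(w$blocked, w$free, sided = sided)
    bf <- jzs_bf10_paired(tt$t, tt$n, rscale = bf_rscale)
    cbind(tibble::tibble(label = lab), tt,
          tibble::tibble(bf10 = bf$bf10, bf_rscale = bf$rscale))
  }))
  posthoc$p_bonferroni <- bonferroni_adjust(posthoc$p, m = family)
  means <- dplyr::summarise(
    dplyr::group_by(tab, .data$mimicry, .data$label),
    sd_ct_s = stats::sd(.data$mean_ct_s), mean_ct_s = mean(.data$mean_ct_s),
    .groups = "drop")
  means <- means[, c("mimicry", "label", "mean_ct_s", "sd_ct_s")]
  list(anova = anova, posthoc = posthoc, cell_means = means,
       dropped_subjects = dropped)
}

# stage 5: exploratory questionnaire correlations (uncorrected, flagged)
questionnaire_stage <- function(sessions, cells) {
  scores <- tibble::tibble(
    subject = vapply(sessions, `[[`, character(1), "subject_id"),
    tas20 = vapply(sessions, `[[`, double(1), "tas20_total"),
    iri = vapply(sessions, `[[`, double(1), "iri_total"))
  if (all(is.na(scores$tas20)) && all(is.na(scores$iri))) {
    warning("no questionnaire scores present; skipping correlation stage",
            call. = FALSE)
    return(NULL)
  }
  grid <- tidyr::expand_grid(questionnaire = c("tas20", "iri"),
                             metric = c("ct", "ort"),
                             mimicry = MIMICRY_LEVELS,
                             label = c("happy", "neutral"))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cc <- cells[cells$mimicry == g$mimicry & cells$label == g$label, ,
                drop = FALSE]
    cc <- dplyr::left_join(cc, scores, by = "subject")
    y <- if (g$metric == "ct") cc$mean_ct_s else cc$mean_ort_s
    x <- cc[[g$questionnaire]]
    out <- tryCatch(pearson_cor(x, y), error = function(e) {
      tibble::tibble(r = NA_real_, df = NA_real_, p = NA_real_, n = NA_integer_)
    })
    cbind(g, out)
  })
  res <- dplyr::bind_rows(rows)
  res$exploratory <- TRUE
  res$corrected <- FALSE
  res
}

#' @export
print.br_analysis <- function(x, ...) {
  cat("<br_analysis>\n")
  cat(sprintf("  %d subjects, %d trials (%s report convention)\n",
              x$manifest$n_subjects, x$manifest$n_trials,
              x$manifest$report_convention))
  if (!is.null(x$ip)) {
    cat(sprintf("  IP logistic: beta = %.3f (SE %.3f), OR = %.3f\n",
                x$ip$logistic$beta, x$ip$logistic$se,
                x$ip$logistic$odds_ratio))
  }
  if (!is.null(x$ct)) {
    ia <- x$ct$anova[x$ct$anova$effect == "mimicry:label", ]
    cat(sprintf("  CT mimicry x content: F(%.2f, %.2f) = %.2f, p(GG) = %.4f\n",
                ia$df_num_gg, ia$df_den_gg, ia$F, ia$p_gg))
  }
  invisible(x)
}
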