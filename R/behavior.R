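#' Persistence-of-response criterion
#'
#' Mean, over the supplied FR5 sessions that contain a signalled pellet-free
#' period, of the number of active-lever responses emitted during that
#' 10-minute non-reinforced window. Responses in reinforced periods are never
#' counted. The study design aggregates three consecutive FR5 sessions; any
#' number of sessions with a pellet-free period is accepted.
#'
#' @param logs A `session_log` or list of session logs.
#' @return A single numeric score (responses).
#' @export
persistence_score <- function(logs) {
  logs <- as_log_list(logs)
  pf <- purrr::keep(logs, \(l) session_schedule(l) == "FR5_pellet_free")
  if (!length(pf)) abort("no sessions with a pellet-free period provided")
  mean(map_dbl(pf, \(l) sum(l$lever == "active" & l$period == "pellet_free")))
}

#' Progressive-ratio breaking point (motivation criterion)
#'
#' The ladder value of the last fully completed response requirement of a
#' progressive-ratio session; 0 when no requirement was completed. One pellet
#' is delivered per completed requirement, so the breaking point is the ladder
#' value indexed by the pellet count.
#'
#' @param log A `session_log` from a `PR` session.
#' @param ladder The response-requirement ladder, see [pr_ladder()].
#' @return A single numeric value (responses per pellet).
#' @export
#' @examples
#' breaking_point(session_from_responses(numeric(0), "PR"))
breaking_point <- function(log, ladder = pr_ladder()) {
  if (!identical(session_schedule(log), "PR")) {
    abort("breaking_point() requires a PR session log")
  }
  n_completed <- sum(log$outcome == "pellet")
  if (n_completed > length(ladder)) {
    abort("more completed requirements than ladder steps")
  }
  if (n_completed == 0L) 0 else as.numeric(ladder[n_completed])
}

#' Compulsion-like behavior (shock-test criterion)
#'
#' Total number of footshocks taken in the 50-min shock-test session. Both
#' shock-only (4th response of a cycle) and shock-plus-pellet (5th response)
#' events count one shock each.
#'
#' @param log A `session_log` from a `SHOCK` session.
#' @return Shock count.
#' @export
compulsion_score <- function(log) {
  if (!identical(session_schedule(log), "SHOCK")) {
    abort("compulsion_score() requires a SHOCK session log")
  }
  sum(log$outcome %in% c("shock", "shock_pellet"))
}

#' Phenotypic trait scores
#'
#' Computes the four addiction-related phenotypic traits from a mouse's probe
#' sessions:
#' * `impulsivity` — mean active responses during post-pellet time-out windows
#'   of FR5-family sessions;
#' * `flexibility_errors` — responses on the previously-active lever in the
#'   reversal session (perseveration);
#' * `appetitive_reactivity` — active responses in the window after the
#'   non-contingent cue light minus the equal-length window just before it;
#' * `aversive_reactivity` — non-reinforced active responses in the
#'   grid-extinction session.
#'
#' A missing probe session yields `NA` for its trait (with a warning), never a
#' silent 0.
#'
#' @param logs A list of session logs for one mouse.
#' @return A one-row tibble with the four trait columns.
#' @export
trait_scores <- function(logs) {
  logs <- as_log_list(logs)
  sched <- map_chr(logs, session_schedule)

  fr5 <- logs[sched %in% c("FR5", "FR5_pellet_free")]
  impulsivity <- if (length(fr5)) {
    mean(map_dbl(fr5, \(l) sum(l$lever == "active" & l$period == "timeout")))
  } else {
    warn("no FR5 sessions: impulsivity is NA")
    NA_real_
  }

  rev <- logs[sched == "REVERSAL"]
  flexibility_errors <- if (length(rev)) {
    sum(map_dbl(rev, \(l) sum(l$lever == "inactive")))
  } else {
    warn("no reversal session: flexibility_errors is NA")
    NA_real_
  }

  cue <- logs[sched == "CUE_PROBE"]
  appetitive_reactivity <- if (length(cue)) {
    l <- cue[[1L]]
    cue_t <- attr(l, "duration_s") / 2
    w <- min(cue_t, attr(l, "end_time") - cue_t)
    post <- sum(l$lever == "active" & l$time_s >= cue_t & l$time_s < cue_t + w)
    pre <- sum(l$lever == "active" & l$time_s >= cue_t - w & l$time_s < cue_t)
    post - pre
  } else {
    warn("no cue-probe session: appetitive_reactivity is NA")
    NA_real_
  }

  grid <- logs[sched == "GRID_EXTINCTION"]
  aversive_reactivity <- if (length(grid)) {
    sum(map_dbl(grid, \(l) sum(l$lever == "active")))
  } else {
    warn("no grid-extinction session: aversive_reactivity is NA")
    NA_real_
  }

  tibble(impulsivity = impulsivity,
         flexibility_errors = flexibility_errors,
         appetitive_reactivity = appetitive_reactivity,
         aversive_reactivity = aversive_reactivity)
}

#' Score a whole cohort of session logs
#'
#' Applies [persistence_score()], [breaking_point()], [compulsion_score()] and
#' [trait_scores()] per mouse.
#'
#' @param cohort_logs Named list: one list of session logs per mouse (as
#'   returned by [simulate_cohort()]`$logs`).
#' @return A tibble with one row per mouse: `mouse_id`, the three criterion
#'   columns (`persistence`, `breaking_point`, `shocks`) and the four trait
#'   columns.
#' @export
score_cohort <- function(cohort_logs) {
  stopifnot(is.list(cohort_logs), !is.null(names(cohort_logs)))
  imap(cohort_logs, function(logs, id) {
    logs <- as_log_list(logs)
    sched <- map_chr(logs, session_schedule)
    pr <- logs[sched == "PR"]
    shock <- logs[sched == "SHOCK"]
    tibble(
      mouse_id = id,
      persistence = persistence_score(logs),
      breaking_point = if (length(pr)) breaking_point(pr[[1L]]) else NA_real_,
      shocks = if (length(shock)) compulsion_score(shock[[1L]]) else NA_real_
    ) |>
      bind_cols(suppressWarnings(trait_scores(logs)))
  }) |>
    list_rbind()
}

as_log_list <- function(logs) {
  if (inherits(logs, "session_log")) list(logs) else logs
}
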