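#' Reinforcement schedules understood by the simulator and scorers
#'
#' `FR1`/`FR5` are fixed-ratio schedules (one pellet per 1 or 5 active
#' responses, pellet paired with a cue light and followed by a 10-s time-out).
#' `FR5_pellet_free` is an FR5 session containing a signalled 10-minute window
#' in which responses are never reinforced (the persistence-of-response probe).
#' `PR` escalates the response requirement through [pr_ladder()] and stops at a
#' 5-h cap, a 1-h response gap on both levers, or ladder exhaustion. `SHOCK` is
#' the 50-min compulsion test: the 4th active response of each cycle yields a
#' footshock only, the 5th a footshock plus pellet; an unfinished cycle resets
#' after 1 min. `CUE_PROBE` presents a non-contingent cue light at mid-session
#' (appetitive cue reactivity); `GRID_EXTINCTION` is a non-reinforced session
#' on the shock-context grid floor (aversive cue reactivity); `REVERSAL` swaps
#' the lever contingency (cognitive flexibility).
#'
#' @return Character vector of schedule names.
#' @export
schedules <- function() {
  c("FR1", "FR5", "FR5_pellet_free", "PR", "SHOCK",
    "CUE_PROBE", "GRID_EXTINCTION", "REVERSAL")
}

#' The progressive-ratio ladder
#'
#' The 35 escalating response requirements used by the motivation test. The
#' last fully completed requirement is the breaking point.
#'
#' @return Integer vector of length 35, strictly increasing from 1 to 5500.
#' @export
pr_ladder <- function() {
  c(1L, 5L, 12L, 21L, 33L, 51L, 75L, 90L, 120L, 155L, 180L, 225L, 260L,
    300L, 350L, 410L, 465L, 540L, 630L, 730L, 850L, 1000L, 1200L, 1500L,
    1800L, 2100L, 2400L, 2700L, 3000L, 3400L, 3800L, 4200L, 4600L, 5000L,
    5500L)
}

# default timing parameters of the operant boxes; durations in seconds
session_options <- function(fr_timeout_s = 10,
                            pellet_free_start_s = 1200,
                            pellet_free_dur_s = 600,
                            shock_reset_s = 60,
                            shock_ma = 0.18,
                            shock_dur_s = 2,
                            pr_max_s = 5 * 3600,
                            pr_gap_s = 3600) {
  as.list(environment())
}

default_duration <- function(schedule) {
  switch(schedule,
    FR1 = 3600, FR5 = 3600, FR5_pellet_free = 3600,
    PR = 5 * 3600, SHOCK = 50 * 60,
    CUE_PROBE = 1800, GRID_EXTINCTION = 1800, REVERSAL = 3600,
    abort(paste0("unknown schedule: ", schedule)))
}

new_session_log <- function(events, schedule, duration_s, end_time,
                            mouse_id = NA_character_, seed = NA_integer_,
                            opts = session_options()) {
  log <- as_tibble(events)
  attr(log, "schedule") <- schedule
  attr(log, "duration_s") <- duration_s
  attr(log, "end_time") <- end_time
  attr(log, "mouse_id") <- mouse_id
  attr(log, "seed") <- seed
  # shock parameters are recorded as metadata only; the simulator has no
  # physical shock intensity
  attr(log, "shock_ma") <- opts$shock_ma
  attr(log, "shock_dur_s") <- opts$shock_dur_s
  class(log) <- c("session_log", class(log))
  log
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log> schedule=%s mouse=%s end=%.0fs events=%d\n",
              attr(x, "schedule"), attr(x, "mouse_id"),
              attr(x, "end_time"), nrow(x)))
  NextMethod()
}

session_schedule <- function(log) attr(log, "schedule")

#' Write / read a session log as TSV
#'
#' Events are written as a plain TSV (`time_s, lever, outcome, cue_light,
#' period`) preceded by `#`-comment metadata lines carrying the schedule,
#' duration, end time, mouse id and shock parameters.
#'
#' @param log A `session_log` (see [simulate_session()]).
#' @param path File path.
#' @return `write_session_log()` returns `path` invisibly;
#'   `read_session_log()` returns a `session_log`.
#' @export
write_session_log <- function(log, path) {
  meta <- c(schedule = attr(log, "schedule"),
            duration_s = attr(log, "duration_s"),
            end_time = attr(log, "end_time"),
            mouse_id = attr(log, "mouse_id"),
            seed = attr(log, "seed"),
            shock_ma = attr(log, "shock_ma"),
            shock_dur_s = attr(log, "shock_dur_s"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  writeLines(paste(c("time_s", "lever", "outcome", "cue_light", "period"),
                   collapse = "\t"), con)
  if (nrow(log)) {
    writeLines(sprintf("%.6f\t%s\t%s\t%d\t%s", log$time_s, log$lever,
                       log$outcome, as.integer(log$cue_light), log$period), con)
  }
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- setNames(
    sub("^# [^:]+: ", "", meta_lines),
    sub("^# ([^:]+):.*$", "\\1", meta_lines)
  )
  meta[meta == "NA"] <- NA_character_
  events <- readr::read_tsv(I(lines[!startsWith(lines, "# ")]),
                            col_types = readr::cols(
                              time_s = readr::col_double(),
                              lever = readr::col_character(),
                              outcome = readr::col_character(),
                              cue_light = readr::col_integer(),
                              period = readr::col_character()))
  events$cue_light <- as.logical(events$cue_light)
  new_session_log(events,
                  schedule = meta[["schedule"]],
                  duration_s = as.numeric(meta[["duration_s"]]),
                  end_time = as.numeric(meta[["end_time"]]),
                  mouse_id = meta[["mouse_id"]],
                  seed = suppressWarnings(as.integer(meta[["seed"]])))
}
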