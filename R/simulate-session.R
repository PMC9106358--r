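#' Behavioral agent parameters
#'
#' Parametrizes one simulated mouse. Response emission is a thinned Poisson
#' process per lever; schedule context modulates the active-lever rate
#' multiplicatively. Vulnerable phenotypes are characterized by elevated
#' persistence and motivation and blunted punishment/aversive-cue control.
#'
#' @param active_rate Active-lever responses per minute under reinforcement.
#' @param inactive_rate Inactive-lever responses per minute.
#' @param persistence_bias Rate multiplier during the signalled pellet-free
#'   period (persistence of food seeking when reward is unavailable).
#' @param motivation_cap Maximum responses the agent will emit for a single
#'   pellet; in a progressive-ratio session the agent disengages once the next
#'   ladder requirement exceeds this cap.
#' @param punishment_sensitivity Per-shock multiplicative decrement in `(0, 1]`
#'   applied to the active rate within a shock session (smaller = stronger
#'   suppression).
#' @param timeout_bias Rate multiplier during post-pellet time-out windows
#'   (impulsive responding).
#' @param reversal_bias Rate multiplier on the previously-active lever in a
#'   reversal session (perseveration).
#' @param cue_gain Rate multiplier after the non-contingent cue-light
#'   presentation in a cue-probe session.
#' @param aversive_suppression Rate multiplier in the grid-extinction session
#'   (1 = the aversive context does not control behavior at all).
#' @param phenotype Latent label, `"vulnerable"` or `"resilient"`.
#' @return An `agent_params` list.
#' @export
#' @examples
#' agent_params(active_rate = 2)
agent_params <- function(active_rate = 2,
                         inactive_rate = 0.2,
                         persistence_bias = 0.6,
                         motivation_cap = 100,
                         punishment_sensitivity = 0.6,
                         timeout_bias = 0.5,
                         reversal_bias = 0.5,
                         cue_gain = 1.3,
                         aversive_suppression = 0.3,
                         phenotype = c("resilient", "vulnerable")) {
  phenotype <- match.arg(phenotype)
  check_that(
    "active_rate must be a non-negative number" =
      is.numeric(active_rate) && active_rate >= 0,
    "inactive_rate must be a non-negative number" =
      is.numeric(inactive_rate) && inactive_rate >= 0,
    "persistence_bias must be non-negative" = persistence_bias >= 0,
    "motivation_cap must be non-negative" = motivation_cap >= 0,
    "punishment_sensitivity must be in (0, 1]" =
      punishment_sensitivity > 0 && punishment_sensitivity <= 1,
    "timeout_bias must be non-negative" = timeout_bias >= 0,
    "reversal_bias must be non-negative" = reversal_bias >= 0,
    "cue_gain must be non-negative" = cue_gain >= 0,
    "aversive_suppression must be non-negative" = aversive_suppression >= 0
  )
  structure(
    list(active_rate = active_rate, inactive_rate = inactive_rate,
         persistence_bias = persistence_bias, motivation_cap = motivation_cap,
         punishment_sensitivity = punishment_sensitivity,
         timeout_bias = timeout_bias, reversal_bias = reversal_bias,
         cue_gain = cue_gain, aversive_suppression = aversive_suppression,
         phenotype = phenotype),
    class = "agent_params")
}

# Core schedule state machine. `cand` is a tibble of candidate lever events
# (time, lever, u) in time order; an event is kept when u < rate(t)/M for its
# lever. With thin = FALSE every candidate is a real response. Returns the
# event tibble plus the session end time.
run_schedule <- function(cand, agent, schedule, duration_s, opts,
                         ladder = pr_ladder(), thin = TRUE,
                         m_active = NULL, m_inactive = NULL) {
  ratio <- c(FR1 = 1L, FR5 = 5L, FR5_pellet_free = 5L, REVERSAL = 5L)
  n <- nrow(cand)
  in_cycle <- 0L; shocks <- 0L; pellets <- 0L
  timeout_until <- -Inf; last4 <- -Inf
  ladder_idx <- 1L; disengaged <- FALSE
  last_resp <- 0
  end_time <- duration_s
  ended <- FALSE
  cue_time <- if (schedule == "CUE_PROBE") duration_s / 2 else NA_real_
  pf_start <- opts$pellet_free_start_s
  pf_end <- pf_start + opts$pellet_free_dur_s

  t_out <- numeric(n); lev_out <- character(n); out_out <- character(n)
  cue_out <- logical(n); per_out <- character(n); k <- 0L

  for (i in seq_len(n)) {
    t <- cand$time[i]; lev <- cand$lever[i]
    if (schedule == "PR" && t - last_resp > opts$pr_gap_s) {
      end_time <- last_resp + opts$pr_gap_s
      ended <- TRUE
      break
    }
    if (t > end_time) { ended <- TRUE; break }

    period <- "reinforced"
    if (schedule == "FR5_pellet_free" && t >= pf_start && t < pf_end) {
      period <- "pellet_free"
    } else if (t < timeout_until) {
      period <- "timeout"
    } else if (schedule == "CUE_PROBE") {
      period <- if (t < cue_time) "pre_cue" else "post_cue"
    } else if (schedule == "GRID_EXTINCTION") {
      period <- "extinction"
    }

    if (thin) {
      if (lev == "active") {
        m <- switch(period,
          pellet_free = agent$persistence_bias,
          timeout = agent$timeout_bias,
          post_cue = agent$cue_gain,
          extinction = agent$aversive_suppression,
          1)
        if (schedule == "SHOCK") m <- m * agent$punishment_sensitivity^shocks
        if (disengaged) m <- 0
        if (cand$u[i] >= agent$active_rate * m / m_active) next
      } else {
        r <- if (schedule == "REVERSAL") {
          agent$active_rate * agent$reversal_bias
        } else {
          agent$inactive_rate
        }
        if (disengaged) r <- 0
        if (cand$u[i] >= r / m_inactive) next
      }
    }

    last_resp <- t
    outcome <- "none"; cue_flag <- FALSE
    stop_after <- FALSE
    if (lev == "active" && period == "reinforced") {
      if (schedule %in% names(ratio)) {
        in_cycle <- in_cycle + 1L
        if (in_cycle >= ratio[[schedule]]) {
          outcome <- "pellet"; cue_flag <- TRUE; pellets <- pellets + 1L
          timeout_until <- t + opts$fr_timeout_s; in_cycle <- 0L
        }
      } else if (schedule == "SHOCK") {
        if (in_cycle == 4L && t - last4 > opts$shock_reset_s) in_cycle <- 0L
        in_cycle <- in_cycle + 1L
        if (in_cycle == 4L) {
          outcome <- "shock"; shocks <- shocks + 1L; last4 <- t
        } else if (in_cycle == 5L) {
          outcome <- "shock_pellet"; cue_flag <- TRUE
          shocks <- shocks + 1L; pellets <- pellets + 1L
          timeout_until <- t + opts$fr_timeout_s; in_cycle <- 0L
        }
      } else if (schedule == "PR") {
        in_cycle <- in_cycle + 1L
        if (in_cycle >= ladder[ladder_idx]) {
          outcome <- "pellet"; cue_flag <- TRUE; pellets <- pellets + 1L
          timeout_until <- t + opts$fr_timeout_s; in_cycle <- 0L
          if (ladder_idx == length(ladder)) {
            # ladder exhausted: session ends with this pellet
            end_time <- t
            stop_after <- TRUE
          } else {
            ladder_idx <- ladder_idx + 1L
            if (ladder[ladder_idx] > agent$motivation_cap) disengaged <- TRUE
          }
        }
      }
    }
    k <- k + 1L
    t_out[k] <- t; lev_out[k] <- lev; out_out[k] <- outcome
    cue_out[k] <- cue_flag; per_out[k] <- period
    if (stop_after) { ended <- TRUE; break }
  }

  # a PR session whose remaining candidates were all thinned away still ends
  # at the 1-h response gap (or the 5-h cap, whichever comes first)
  if (schedule == "PR" && !ended) {
    end_time <- min(duration_s, last_resp + opts$pr_gap_s)
  }

  events <- tibble(time_s = t_out[seq_len(k)], lever = lev_out[seq_len(k)],
                   outcome = out_out[seq_len(k)],
                   cue_light = cue_out[seq_len(k)],
                   period = per_out[seq_len(k)])
  if (schedule == "CUE_PROBE" && end_time >= cue_time) {
    events <- bind_rows(events,
                        tibble(time_s = cue_time, lever = "none",
                               outcome = "cue_on", cue_light = TRUE,
                               period = "post_cue")) |>
      arrange(.data$time_s)
  }
  list(events = events, end_time = end_time)
}

#' Simulate one operant session
#'
#' Emits lever responses as a thinned Poisson process per lever and replays
#' them through the named schedule's contingency rules (see [schedules()]).
#' The same `(agent, schedule, seed)` triple always yields an identical log.
#'
#' @param agent An [agent_params()] object.
#' @param schedule One of [schedules()].
#' @param duration_s Session duration in seconds; defaults to the schedule's
#'   standard duration (50 min for `SHOCK`, 5-h cap for `PR`, 1 h for FR
#'   sessions, 30 min for the probe sessions). For `PR` the stopping rules
#'   (ladder exhaustion, 1-h response gap, 5-h cap) govern the true end time.
#' @param seed Integer seed.
#' @param opts Timing parameters from `session_options()` (time-out length,
#'   pellet-free window, shock-cycle reset, PR caps).
#' @return A `session_log`: a tibble of events with columns `time_s`, `lever`
#'   (`active`/`inactive`/`none`), `outcome` (`none`, `pellet`, `shock`,
#'   `shock_pellet`, `cue_on`), `cue_light`, `period` (`reinforced`,
#'   `pellet_free`, `timeout`, `pre_cue`, `post_cue`, `extinction`), plus
#'   schedule metadata attributes.
#' @export
#' @examples
#' log <- simulate_session(agent_params(), "FR5", seed = 1)
#' table(log$outcome)
simulate_session <- function(agent, schedule, duration_s = NULL, seed = 1L,
                             opts = session_options()) {
  stopifnot(inherits(agent, "agent_params"))
  if (!is.character(schedule) || length(schedule) != 1L ||
      !schedule %in% schedules()) {
    abort(paste0("unknown schedule: ", paste(schedule, collapse = ",")))
  }
  duration_s <- duration_s %||% default_duration(schedule)
  if (schedule == "PR") duration_s <- min(duration_s, opts$pr_max_s)
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("duration_s must be positive")
  }

  # dominating rates for thinning (per second)
  m_active <- agent$active_rate / 60 *
    max(1, agent$persistence_bias, agent$timeout_bias, agent$cue_gain,
        agent$aversive_suppression)
  m_inactive <- max(agent$inactive_rate,
                    if (schedule == "REVERSAL")
                      agent$active_rate * agent$reversal_bias else 0) / 60

  withr::with_seed(seed, {
    n_a <- if (m_active > 0) rpois(1L, m_active * duration_s) else 0L
    t_a <- if (n_a > 0) sort(runif(n_a, 0, duration_s)) else numeric(0)
    n_i <- if (m_inactive > 0) rpois(1L, m_inactive * duration_s) else 0L
    t_i <- if (n_i > 0) sort(runif(n_i, 0, duration_s)) else numeric(0)
    cand <- tibble(time = c(t_a, t_i),
                   lever = rep(c("active", "inactive"), c(n_a, n_i))) |>
      arrange(.data$time)
    cand$u <- runif(nrow(cand))
    res <- run_schedule(cand, agent, schedule, duration_s, opts,
                        thin = TRUE,
                        m_active = m_active * 60, m_inactive = m_inactive * 60)
  })
  new_session_log(res$events, schedule, duration_s, res$end_time,
                  seed = as.integer(seed), opts = opts)
}

#' Build a session log from explicit response times
#'
#' Replays a deterministic sequence of lever responses through the same
#' schedule state machine used by [simulate_session()]. Useful for
#' constructing worked examples (e.g. a progressive-ratio session that
#' completes an exact number of ladder steps) and for oracle tests.
#'
#' @param active_times Numeric vector of active-lever response times (s).
#' @param schedule One of [schedules()].
#' @param inactive_times Numeric vector of inactive-lever response times (s).
#' @param duration_s Session duration (defaults as in [simulate_session()]).
#' @param opts Timing parameters, see `session_options()`.
#' @return A `session_log`.
#' @export
#' @examples
#' # complete the first two PR requirements (1 + 5 responses), then silence
#' log <- session_from_responses(seq_len(6) * 20, "PR")
#' breaking_point(log)
session_from_responses <- function(active_times, schedule,
                                   inactive_times = numeric(0),
                                   duration_s = NULL,
                                   opts = session_options()) {
  if (!schedule %in% schedules()) {
    abort(paste0("unknown schedule: ", schedule))
  }
  duration_s <- duration_s %||% default_duration(schedule)
  if (schedule == "PR") duration_s <- min(duration_s, opts$pr_max_s)
  cand <- tibble(
    time = c(active_times, inactive_times),
    lever = rep(c("active", "inactive"),
                c(length(active_times), length(inactive_times)))) |>
    arrange(.data$time)
  cand$u <- rep(-1, nrow(cand))
  res <- run_schedule(cand, agent_params(), schedule, duration_s, opts,
                      thin = FALSE)
  new_session_log(res$events, schedule, duration_s, res$end_time, opts = opts)
}
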