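#' Cohort specification for the behavioral simulator
#'
#' Defines the study conditions for a simulated palatable-food-trained cohort:
#' number of mice, latent vulnerable fraction, per-phenotype agent-parameter
#' distributions, and the session plan every mouse runs. Defaults mirror the
#' study design: 51 mice with roughly a quarter latently vulnerable, and a
#' session plan of three FR5 sessions with a pellet-free period (persistence
#' and impulsivity), one progressive-ratio, one shock test, one reversal, one
#' cue probe and one grid-extinction session.
#'
#' The per-phenotype effect sizes are frozen constants chosen once so that
#' default cohorts yield approximately a quarter classified-addicted animals;
#' they are documented in the methods vignette.
#'
#' @param n_mice Number of mice.
#' @param vulnerable_fraction Probability that a mouse is latently vulnerable.
#' @param seed Integer seed.
#' @param params Named list with elements `resilient` and `vulnerable`, each a
#'   named list of `c(mean, sd)` pairs for the [agent_params()] fields.
#' @param session_plan Tibble with columns `schedule` and `duration_s`
#'   (`NA` = schedule default).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_mice = 51L,
                        vulnerable_fraction = 0.25,
                        seed = 1L,
                        params = default_phenotype_params(),
                        session_plan = default_session_plan()) {
  check_that(
    "n_mice must be a positive integer" = is_count(n_mice) && n_mice >= 1,
    "vulnerable_fraction must be in [0, 1]" =
      vulnerable_fraction >= 0 && vulnerable_fraction <= 1,
    "session_plan must not be empty" =
      is.data.frame(session_plan) && nrow(session_plan) > 0
  )
  structure(list(n_mice = as.integer(n_mice),
                 vulnerable_fraction = vulnerable_fraction,
                 seed = as.integer(seed), params = params,
                 session_plan = session_plan),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_session_plan <- function() {
  tibble(schedule = c("FR5_pellet_free", "FR5_pellet_free", "FR5_pellet_free",
                      "PR", "SHOCK", "REVERSAL", "CUE_PROBE",
                      "GRID_EXTINCTION"),
         duration_s = NA_real_)
}

#' @rdname cohort_spec
#' @export
default_phenotype_params <- function() {
  list(
    resilient = list(
      active_rate = c(2.0, 0.4), inactive_rate = c(0.2, 0.05),
      persistence_bias = c(0.5, 0.15), motivation_cap = c(60, 25),
      punishment_sensitivity = c(0.55, 0.08), timeout_bias = c(0.4, 0.1),
      reversal_bias = c(0.4, 0.1), cue_gain = c(1.2, 0.2),
      aversive_suppression = c(0.25, 0.08)
    ),
    vulnerable = list(
      active_rate = c(2.4, 0.4), inactive_rate = c(0.2, 0.05),
      persistence_bias = c(1.2, 0.2), motivation_cap = c(400, 150),
      punishment_sensitivity = c(0.88, 0.05), timeout_bias = c(0.9, 0.15),
      reversal_bias = c(0.9, 0.15), cue_gain = c(1.9, 0.25),
      aversive_suppression = c(0.6, 0.12)
    )
  )
}

draw_agent <- function(p, phenotype) {
  g <- function(nm, lo = 0, hi = Inf) {
    v <- rnorm(1L, p[[nm]][1L], p[[nm]][2L])
    min(max(v, lo), hi)
  }
  agent_params(
    active_rate = g("active_rate"),
    inactive_rate = g("inactive_rate"),
    persistence_bias = g("persistence_bias"),
    motivation_cap = g("motivation_cap"),
    punishment_sensitivity = g("punishment_sensitivity", 1e-3, 1),
    timeout_bias = g("timeout_bias"),
    reversal_bias = g("reversal_bias"),
    cue_gain = g("cue_gain"),
    aversive_suppression = g("aversive_suppression"),
    phenotype = phenotype)
}

#' Simulate a behavioral cohort
#'
#' Draws a latent phenotype and agent parameters per mouse and runs the full
#' session plan through [simulate_session()]. Latent labels are returned
#' separately from any downstream classification.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `logs` (named list: per mouse, a list of session logs)
#'   and `mice` (tibble `mouse_id`, `phenotype` plus the drawn agent
#'   parameters).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_mice = 2))
#' cohort$mice
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- sprintf("m%03d", seq_len(spec$n_mice))
  withr::with_seed(spec$seed, {
    phen <- ifelse(runif(spec$n_mice) < spec$vulnerable_fraction,
                   "vulnerable", "resilient")
    agents <- map2(phen, ids, \(ph, id) draw_agent(spec$params[[ph]], ph))
    session_seeds <- matrix(
      sample.int(2147483646L, spec$n_mice * nrow(spec$session_plan)),
      nrow = spec$n_mice)
  })
  logs <- map(seq_len(spec$n_mice), function(i) {
    map(seq_len(nrow(spec$session_plan)), function(j) {
      d <- spec$session_plan$duration_s[j]
      log <- simulate_session(agents[[i]], spec$session_plan$schedule[j],
                              duration_s = if (is.na(d)) NULL else d,
                              seed = session_seeds[i, j])
      attr(log, "mouse_id") <- ids[i]
      log
    })
  })
  names(logs) <- ids
  mice <- tibble(mouse_id = ids, phenotype = phen) |>
    bind_cols(list_rbind(map(agents, \(a)
      as_tibble(a[setdiff(names(a), "phenotype")]))))
  list(logs = logs, mice = mice)
}
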