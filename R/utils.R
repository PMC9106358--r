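# Internal helpers shared across modules.

#' Derive a stage-specific seed from a global seed
#'
#' Stage seeds are a stable function of the global seed and the stage *name*,
#' so adding or reordering pipeline stages never shifts the random stream of
#' existing stages.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer in `[0, 2^31 - 1)` usable with [set.seed()].
#' @export
#' @examples
#' stage_seed(1L, "cohort")
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # polynomial rolling hash of the stage name, kept in double precision
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(seed) + h) %% 2147483647)
}

# stop unless all named conditions hold; messages name the failing argument
check_that <- function(...) {
  conds <- list(...)
  for (nm in names(conds)) {
    if (!isTRUE(conds[[nm]])) abort(nm, class = "addictomir_error")
  }
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

# fast row variance for a numeric matrix
row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}
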