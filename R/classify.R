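criterion_cols <- c("persistence", "breaking_point", "shocks")

#' Rule constants of the addiction classification
#'
#' The DSM-5 calls a substance use disorder severe when 6 or more of its 11
#' criteria are met; the mouse model analogously calls an animal addicted when
#' 2 or more of its 3 addiction-like criteria are positive.
#'
#' @return A tibble with columns `rule`, `numerator`, `denominator`,
#'   `fraction_pct`.
#' @export
addiction_rules <- function() {
  tibble(rule = c("dsm5_severe", "mouse_addicted"),
         numerator = c(6L, 2L),
         denominator = c(11L, 3L)) |>
    mutate(fraction_pct = 100 * .data$numerator / .data$denominator)
}

#' Per-criterion positivity thresholds
#'
#' Computes, per addiction-like criterion, the cohort quantile used as the
#' positivity threshold (default the 75th percentile, linear interpolation
#' between order statistics). A mouse is positive for a criterion when its
#' score is strictly above the threshold.
#'
#' @param scores Data frame with one row per mouse containing the criterion
#'   columns.
#' @param q Quantile in `[0, 1]`, default 0.75.
#' @param criteria Criterion column names.
#' @return A tibble `criterion`, `threshold`.
#' @export
#' @examples
#' criterion_thresholds(tibble::tibble(
#'   persistence = 1:8, breaking_point = 1:8, shocks = 1:8))
criterion_thresholds <- function(scores, q = 0.75,
                                 criteria = criterion_cols) {
  check_that(
    "scores must contain the criterion columns" =
      all(criteria %in% names(scores)),
    "need at least 4 mice to place a quantile threshold" = nrow(scores) >= 4,
    "q must be in [0, 1]" = is.numeric(q) && q >= 0 && q <= 1
  )
  vals <- scores[criteria]
  if (!all(vapply(vals, is.numeric, logical(1L)))) {
    abort("criterion scores must be numeric")
  }
  tibble(criterion = criteria,
         threshold = map_dbl(criteria,
                             \(cc) quantile(scores[[cc]], q, na.rm = TRUE,
                                            names = FALSE, type = 7)))
}

#' Classify a cohort with the 2-of-3 rule
#'
#' Marks each criterion positive when the mouse's score is strictly above the
#' cohort threshold, counts positive criteria and labels mice achieving 2 or 3
#' criteria `addicted`, otherwise `nonaddicted`. Mice with a missing criterion
#' value are excluded with a warning.
#'
#' @param scores Cohort score tibble (see [score_cohort()]).
#' @param thresholds Optional thresholds tibble from [criterion_thresholds()];
#'   computed from `scores` at quantile `q` when `NULL`. Supply thresholds
#'   explicitly to threshold an experimental arm against its own control arm.
#' @param q Quantile used when `thresholds` is `NULL`.
#' @return The input tibble plus logical columns `<criterion>_pos`, integer
#'   `n_criteria` and `label` (`addicted`/`nonaddicted`).
#' @export
classify_cohort <- function(scores, thresholds = NULL, q = 0.75) {
  thresholds <- thresholds %||% criterion_thresholds(scores, q = q)
  crit <- thresholds$criterion
  keep <- complete.cases(scores[crit])
  if (!all(keep)) {
    warn(sprintf("excluding %d mice with missing criterion values: %s",
                 sum(!keep),
                 paste(scores$mouse_id[!keep], collapse = ", ")))
    scores <- scores[keep, ]
  }
  out <- scores
  for (i in seq_along(crit)) {
    out[[paste0(crit[i], "_pos")]] <- out[[crit[i]]] > thresholds$threshold[i]
  }
  pos <- as.matrix(out[paste0(crit, "_pos")])
  out$n_criteria <- as.integer(rowSums(pos))
  out$label <- ifelse(out$n_criteria >= 2L, "addicted", "nonaddicted")
  attr(out, "thresholds") <- thresholds
  class(out) <- c("addiction_classification", class(out))
  out
}

#' Severity scale and extreme-subgroup selection
#'
#' Builds the quantitative gradual addiction-severity scale — the mean of the
#' three within-cohort fractional ranks of the criterion scores, in `[0, 1]`
#' and monotone in each criterion — and selects the extreme subgroups at both
#' ends of the resulting inverted-U ordering: the `k` highest-severity
#' addicted mice and `k` lowest-severity nonaddicted mice form the discovery
#' sample, the next `k` per side the replica sample. Ties are broken by
#' persistence, breaking point and shock count (in that order), then mouse id.
#'
#' @param classified An `addiction_classification` from [classify_cohort()].
#' @param k Extreme-set size per side per sample (default 6).
#' @return The input tibble plus `severity`, `extreme_set`
#'   (`discovery`/`replica`/`none`) and `extreme_side`
#'   (`vulnerable`/`resilient`/`NA`).
#' @export
severity_and_extremes <- function(classified, k = 6L) {
  stopifnot(inherits(classified, "addiction_classification"))
  n <- nrow(classified)
  frank <- function(x) {
    if (n == 1L) return(0.5)
    (rank(x, ties.method = "average") - 1) / (n - 1)
  }
  out <- classified
  out$severity <- rowMeans(vapply(criterion_cols,
                                  \(cc) frank(out[[cc]]), numeric(n)))

  out$extreme_set <- "none"
  out$extreme_side <- NA_character_
  assign_side <- function(out, side) {
    if (side == "vulnerable") {
      idx <- which(out$label == "addicted")
      ord <- order(-out$severity[idx], -out$persistence[idx],
                   -out$breaking_point[idx], -out$shocks[idx],
                   out$mouse_id[idx])
    } else {
      idx <- which(out$label == "nonaddicted")
      ord <- order(out$severity[idx], out$persistence[idx],
                   out$breaking_point[idx], out$shocks[idx],
                   out$mouse_id[idx])
    }
    idx <- idx[ord]
    if (length(idx) < 2L * k) {
      warn(sprintf("only %d mice on the %s side; extreme sets will be smaller than %d",
                   length(idx), side, 2L * k))
    }
    disc <- head(idx, k)
    repl <- head(idx[-seq_along(disc)], k)
    out$extreme_set[disc] <- "discovery"
    out$extreme_set[repl] <- "replica"
    out$extreme_side[c(disc, repl)] <- side
    out
  }
  out <- assign_side(out, "vulnerable")
  out <- assign_side(out, "resilient")
  out
}

#' Chi-squared comparison of addicted percentages between groups
#'
#' Pearson chi-squared test (df = 1, no continuity correction by default) on a
#' 2x2 table of addicted/nonaddicted counts by group.
#'
#' @param counts 2x2 matrix or data frame of non-negative integer counts,
#'   rows = groups, columns = addicted/nonaddicted.
#' @param correct Apply the Yates continuity correction.
#' @return A tibble `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' group_chi2(matrix(c(6, 6, 3, 16), nrow = 2, byrow = TRUE))
group_chi2 <- function(counts, correct = FALSE) {
  m <- as.matrix(counts)
  check_that(
    "counts must be a 2x2 table" = all(dim(m) == c(2L, 2L)),
    "counts must be non-negative integers" =
      all(m >= 0) && all(m == floor(m)),
    "every margin of the table must be positive" =
      all(rowSums(m) > 0) && all(colSums(m) > 0)
  )
  ct <- suppressWarnings(chisq.test(m, correct = correct))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p_value = ct$p.value)
}
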