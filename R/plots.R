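#' Severity-curve plot of a classified cohort
#'
#' Orders mice by the gradual addiction-severity scale and marks the
#' discovery/replica extreme subgroups at both tails — the working view used
#' to pick extreme vulnerable and resilient animals.
#'
#' @param object An `addiction_classification`, ideally after
#'   [severity_and_extremes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.addiction_classification <- function(object, ...) {
  dat <- as_tibble(object)
  if (!"severity" %in% names(dat)) {
    dat$severity <- severity_and_extremes(object)$severity
    dat$extreme_set <- "none"
  }
  dat <- arrange(dat, .data$severity) |>
    mutate(order = row_number())
  ggplot(dat, aes(x = .data$order, y = .data$severity,
                  colour = .data$label, shape = .data$extreme_set)) +
    geom_point(size = 2) +
    labs(x = "mice ordered by severity", y = "severity (mean fractional rank)",
         colour = NULL, shape = "extreme set") +
    theme_minimal()
}

#' Heatmap of miRNA-score correlations
#'
#' @param correlations Output of [mirna_correlations()].
#' @param q_cutoff Correlations with `q_value` below this are starred.
#' @return A ggplot.
#' @export
plot_correlations <- function(correlations, q_cutoff = 0.05) {
  dat <- mutate(correlations,
                sig = !is.na(.data$q_value) & .data$q_value < q_cutoff)
  ggplot(dat, aes(x = .data$score, y = .data$mirna, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = ifelse(.data$sig, "*", "")), size = 5) +
    facet_wrap(~ .data$stratum) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Pearson r") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
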