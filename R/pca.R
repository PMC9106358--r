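#' Principal-component profile of criteria and traits
#'
#' PCA of the standardized (zero-mean, unit-variance) per-mouse feature table
#' — the three addiction-like criteria plus the four phenotypic traits — with
#' variance explained in percent and flags for variables whose absolute
#' loading exceeds 0.7 (the conventional "mainly contributing" cut-off).
#' Zero-variance features are dropped with a warning.
#'
#' @param features Data frame with one row per mouse; an optional `mouse_id`
#'   column is ignored, every other column must be numeric and complete.
#' @param high_loading Absolute-loading threshold for flagging, default 0.7.
#' @return A `pca_profile` object with elements `loadings` (variables x
#'   components, unit-norm columns), `var_explained_pct`, `high_loading`
#'   (logical matrix) and `n`. Use [tidy()] / [glance()] / [autoplot()].
#' @export
pca_profile <- function(features, high_loading = 0.7) {
  x <- features[setdiff(names(features), "mouse_id")]
  check_that(
    "need at least 3 mice" = nrow(x) >= 3,
    "all feature columns must be numeric" =
      all(vapply(x, is.numeric, logical(1L))),
    "features must be complete (no missing values)" =
      all(complete.cases(x))
  )
  sds <- vapply(x, sd, numeric(1L))
  if (any(sds == 0)) {
    warn(paste("dropping zero-variance features:",
               paste(names(x)[sds == 0], collapse = ", ")))
    x <- x[sds > 0]
  }
  fit <- prcomp(as.matrix(x), center = TRUE, scale. = TRUE)
  var_pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  structure(list(loadings = fit$rotation,
                 var_explained_pct = var_pct,
                 high_loading = abs(fit$rotation) > high_loading,
                 high_loading_cutoff = high_loading,
                 n = nrow(x)),
            class = "pca_profile")
}

#' @export
print.pca_profile <- function(x, ...) {
  cat(sprintf("<pca_profile> %d variables, n = %d\n", nrow(x$loadings), x$n))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%s %.1f%%", colnames(x$loadings)[1:2],
                            x$var_explained_pct[1:2]), collapse = ", ")))
  invisible(x)
}

#' Tidy a PCA profile into a long loadings table
#'
#' @param x A `pca_profile`.
#' @param ... Unused.
#' @return Tibble `variable`, `component`, `loading`, `high_loading`.
#' @export
tidy.pca_profile <- function(x, ...) {
  as_tibble(x$loadings, rownames = "variable") |>
    pivot_longer(-"variable", names_to = "component", values_to = "loading") |>
    mutate(high_loading = abs(.data$loading) > x$high_loading_cutoff)
}

#' One-row-per-component summary of a PCA profile
#'
#' @param x A `pca_profile`.
#' @param ... Unused.
#' @return Tibble `component`, `var_explained_pct`, `cumulative_pct`.
#' @export
glance.pca_profile <- function(x, ...) {
  tibble(component = colnames(x$loadings),
         var_explained_pct = x$var_explained_pct,
         cumulative_pct = cumsum(x$var_explained_pct))
}

#' @export
autoplot.pca_profile <- function(object, components = c("PC1", "PC2"), ...) {
  dat <- tidy(object) |>
    filter(.data$component %in% components)
  ggplot(dat, aes(x = stats::reorder(.data$variable, -abs(.data$loading)),
                  y = .data$loading, fill = .data$high_loading)) +
    geom_col() +
    geom_hline(yintercept = c(-1, 1) * object$high_loading_cutoff,
               linetype = "dashed") +
    facet_wrap(~ .data$component) +
    labs(x = NULL, y = "loading", fill = "|loading| > cutoff") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
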