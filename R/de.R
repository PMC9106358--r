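#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: for each sample, the median over
#' features (restricted to features with all-positive counts) of the ratio of
#' the count to the feature's geometric mean across samples, rescaled so the
#' factors have geometric mean 1.
#'
#' @param counts Integer matrix, features x samples (rownames = feature ids).
#' @return Named numeric vector of size factors.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
#'             dimnames = list(paste0("f", 1:3), c("a", "b")))
#' size_factors(m)  # ratio 2 between samples
size_factors <- function(counts) {
  m <- as.matrix(counts)
  check_that(
    "counts must have at least 2 samples" = ncol(m) >= 2,
    "counts must be non-negative" = all(m >= 0)
  )
  log_geo <- rowMeans(log(m))
  ok <- is.finite(log_geo)
  if (!any(ok)) abort("no feature has positive counts in every sample")
  log_f <- apply(log(m[ok, , drop = FALSE]) - log_geo[ok], 2, median)
  exp(log_f - mean(log_f))
}

# Vectorized per-feature, per-group NB mean fit with fixed dispersion and
# size-factor offsets: mu_ij = exp(eta_i) * s_j. Newton steps on eta use
# score sum_j (y - mu)/(1 + a*mu) and Fisher information sum_j mu/(1 + a*mu).
# Returns eta and the Fisher information at the optimum.
nb_fit_group <- function(y, sf, alpha, max_iter = 100L, tol = 1e-10) {
  # floor group means at half a normalized count so all-zero groups stay finite
  eta <- log(pmax(rowMeans(sweep(y, 2, sf, "/")), 0.5 / (ncol(y) * mean(sf))))
  for (it in seq_len(max_iter)) {
    mu <- exp(eta) %o% sf
    denom <- 1 + sweep(mu, 1, alpha, "*")
    score <- rowSums((y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    eta <- pmin(pmax(eta + step, -30), 30)
    if (max(abs(step)) < tol) break
  }
  mu <- exp(eta) %o% sf
  denom <- 1 + sweep(mu, 1, alpha, "*")
  list(eta = eta, info = rowSums(mu / denom))
}

# method-of-moments dispersion per feature from normalized counts, pooled
# across groups and floored
mom_dispersion <- function(q, group_idx, sf, floor = 1e-4, cap = 50) {
  num <- 0; den <- 0
  for (idx in group_idx) {
    n_g <- length(idx)
    if (n_g < 2L) next
    qg <- q[, idx, drop = FALSE]
    m <- rowMeans(qg)
    v <- row_vars(qg)
    # Var(y/s) = mu * mean(1/s) + alpha * mu^2
    a_g <- (v - m * mean(1 / sf[idx])) / pmax(m, 1e-12)^2
    num <- num + (n_g - 1L) * a_g
    den <- den + (n_g - 1L)
  }
  pmin(pmax(num / den, floor), cap)
}

nb_wald_stats <- function(y, sf, g_idx, alpha) {
  fit_r <- nb_fit_group(y[, g_idx$resilient, drop = FALSE],
                        sf[g_idx$resilient], alpha)
  fit_v <- nb_fit_group(y[, g_idx$vulnerable, drop = FALSE],
                        sf[g_idx$vulnerable], alpha)
  beta <- fit_v$eta - fit_r$eta
  se <- sqrt(1 / pmax(fit_v$info, 1e-12) + 1 / pmax(fit_r$info, 1e-12))
  list(beta = beta, stat = beta / se)
}

#' Negative-binomial two-group differential expression
#'
#' Per-feature NB model with median-of-ratios size-factor offsets, a
#' method-of-moments dispersion estimate (floored), and a Wald test on the
#' group log-fold-change, with p-values referred to a t distribution with
#' `n - 2` degrees of freedom to account for the estimated dispersion.
#' Alternatively, a label-permutation p-value (`mode = "perm"`). Features with
#' total count below `min_total` are removed before testing. Multiple testing
#' is corrected with [bh_fdr()].
#'
#' @param counts Integer matrix, features x samples.
#' @param groups Character/factor vector per sample with the two levels;
#'   `contrast[1]` is the numerator (default `vulnerable` vs `resilient`).
#' @param contrast Length-2 character: `c(numerator, denominator)`.
#' @param min_total Minimum total raw count across samples for a feature to be
#'   tested (default 10).
#' @param mode `"wald"` or `"perm"` (label permutations of the Wald
#'   statistic).
#' @param n_perm Number of permutations in `"perm"` mode.
#' @param dispersion_floor Lower bound for the dispersion estimate.
#' @param seed Seed for the permutation mode.
#' @return An `nb_de` tibble: `feature`, `base_mean`, `log2fc` (numerator vs
#'   denominator), `dispersion`, `stat`, `pvalue`, `qvalue`, `direction`
#'   (`up`/`down`). Size factors and settings are kept as attributes.
#' @export
nb_test <- function(counts, groups,
                    contrast = c("vulnerable", "resilient"),
                    min_total = 10, mode = c("wald", "perm"),
                    n_perm = 1000L, dispersion_floor = 1e-4, seed = 1L) {
  mode <- match.arg(mode)
  y <- as.matrix(counts)
  groups <- as.character(groups)
  check_that(
    "groups must label every sample" = length(groups) == ncol(y),
    "counts must be non-negative" = all(y >= 0),
    "contrast levels must appear in groups" = all(contrast %in% groups)
  )
  g_idx <- list(vulnerable = which(groups == contrast[1L]),
                resilient = which(groups == contrast[2L]))
  if (any(lengths(g_idx) < 2L)) {
    abort("both groups need at least 2 samples")
  }
  if (is.null(rownames(y))) rownames(y) <- sprintf("f%05d", seq_len(nrow(y)))
  y <- y[rowSums(y) >= min_total, , drop = FALSE]
  if (nrow(y) == 0L) abort("no features pass the min_total filter")

  sf <- size_factors(y)
  q <- sweep(y, 2, sf, "/")
  alpha <- mom_dispersion(q, g_idx, sf, floor = dispersion_floor)
  obs <- nb_wald_stats(y, sf, g_idx, alpha)
  df <- length(groups) - 2L

  if (mode == "wald") {
    pval <- 2 * pt(-abs(obs$stat), df = df)
  } else {
    idx_all <- c(g_idx$vulnerable, g_idx$resilient)
    n_v <- length(g_idx$vulnerable)
    exceed <- rep(0L, nrow(y))
    withr::with_seed(seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample(idx_all)
        pg <- list(vulnerable = perm[seq_len(n_v)],
                   resilient = perm[-seq_len(n_v)])
        st <- nb_wald_stats(y, sf, pg, alpha)$stat
        exceed <- exceed + (abs(st) >= abs(obs$stat))
      }
    })
    pval <- (1 + exceed) / (1 + n_perm)
  }
  pval <- pmin(pmax(pval, 0), 1)

  out <- tibble(
    feature = rownames(y),
    base_mean = rowMeans(q),
    log2fc = obs$beta / log(2),
    dispersion = alpha,
    stat = obs$stat,
    pvalue = pval,
    qvalue = bh_fdr(pval),
    direction = ifelse(obs$beta >= 0, "up", "down"))
  attr(out, "size_factors") <- sf
  attr(out, "mode") <- mode
  attr(out, "contrast") <- contrast
  attr(out, "min_total") <- min_total
  class(out) <- c("nb_de", class(out))
  out
}

#' @export
glance.nb_de <- function(x, ...) {
  tibble(n_features = nrow(x),
         n_significant = sum(x$qvalue < 0.05),
         mode = attr(x, "mode"),
         median_dispersion = median(x$dispersion))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: in decreasing p order,
#' `q = cummin(p * n / rank)`, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be in [0, 1] and non-missing")
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * n / seq(n, 1)))
  q[order(o)]
}

#' Volcano plot of an NB differential-expression result
#'
#' @param object An `nb_de` tibble from [nb_test()].
#' @param q_cutoff Significance cut-off drawn on the plot.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nb_de <- function(object, q_cutoff = 0.05, ...) {
  dat <- mutate(as_tibble(object),
                significant = .data$qvalue < q_cutoff)
  ggplot(dat, aes(x = .data$log2fc, y = -log10(pmax(.data$pvalue, 1e-300)),
                  colour = .data$significant)) +
    geom_point(alpha = 0.6, size = 1) +
    labs(x = "log2 fold change", y = "-log10 p",
         colour = sprintf("q < %.2g", q_cutoff)) +
    theme_minimal()
}
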