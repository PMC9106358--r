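mk_scores <- function(p, b, s) {
  tibble::tibble(mouse_id = sprintf("m%02d", seq_along(p)),
                 persistence = p, breaking_point = b, shocks = s)
}

test_that("thresholds use linear-interpolation quantiles and strict positivity", {
  sc <- mk_scores(1:8, 1:8, 1:8)
  th <- criterion_thresholds(sc)
  expect_equal(th$threshold, rep(6.25, 3))
  expect_equal(th$threshold[1], oracle_quantile7(1:8, 0.75))
  # random cross-check against the independent formula
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- runif(sample(4:30, 1), 0, 100)
      q <- runif(1)
      got <- criterion_thresholds(mk_scores(x, x, x), q = q)$threshold[1]
      expect_equal(got, oracle_quantile7(x, q))
    }
  })
  # all-equal scores: nobody exceeds the threshold strictly
  cl <- classify_cohort(mk_scores(rep(3, 6), rep(3, 6), rep(3, 6)))
  expect_true(all(cl$n_criteria == 0))
  # q = 0: threshold is the minimum, scores above it are positive
  th0 <- criterion_thresholds(sc, q = 0)
  expect_equal(th0$threshold, rep(1, 3))
  expect_error(criterion_thresholds(mk_scores(1:3, 1:3, 1:3)), "4 mice")
})

test_that("the 2-of-3 rule labels mice addicted", {
  sc <- mk_scores(c(9, 9, 1, 1), c(9, 1, 1, 2), c(1, 1, 1, 3))
  th <- tibble::tibble(criterion = c("persistence", "breaking_point", "shocks"),
                       threshold = c(5, 5, 5))
  cl <- classify_cohort(sc, thresholds = th)
  expect_equal(cl$label, c("addicted", "nonaddicted", "nonaddicted",
                           "nonaddicted"))
  expect_equal(cl$n_criteria, c(2L, 1L, 0L, 0L))
})

test_that("classification is invariant to strictly monotone criterion transforms", {
  withr::with_seed(8, {
    sc <- mk_scores(runif(30), runif(30), runif(30))
    cl1 <- classify_cohort(sc)
    sc2 <- dplyr::mutate(sc, persistence = exp(persistence),
                         breaking_point = breaking_point^3,
                         shocks = 10 * shocks + 2)
    cl2 <- classify_cohort(sc2)
    expect_identical(cl1$label, cl2$label)
    expect_identical(cl1$n_criteria, cl2$n_criteria)
  })
})

test_that("independent continuous criteria yield the closed-form addicted fraction", {
  # P(>= 2 of 3 positive) = 3 q^2 (1 - q) + q^3 = 0.15625 at q = 0.25
  withr::with_seed(123, {
    n <- 10000
    cl <- classify_cohort(mk_scores(runif(n), runif(n), runif(n)))
    expect_lt(abs(mean(cl$label == "addicted") - 0.15625), 0.02)
  })
})

test_that("mice with missing criteria are excluded with a warning", {
  sc <- mk_scores(c(1:5, NA), 1:6, 1:6)
  expect_warning(cl <- classify_cohort(sc), "excluding 1")
  expect_equal(nrow(cl), 5)
})

test_that("severity is a mean fractional rank: median mouse scores 0.5", {
  sc <- mk_scores(1:9, 1:9, 1:9)
  cl <- suppressWarnings(severity_and_extremes(classify_cohort(sc), k = 2))
  expect_equal(cl$severity[5], 0.5)
  expect_equal(min(cl$severity), 0)
  expect_equal(max(cl$severity), 1)
  # monotone in each criterion by construction of ranks
  expect_true(all(diff(cl$severity) > 0))
})

test_that("severity is invariant to row order and a dominant mouse is discovery-vulnerable", {
  withr::with_seed(9, {
    sc <- mk_scores(runif(20), runif(20), runif(20))
    sc$persistence[7] <- 2; sc$breaking_point[7] <- 2; sc$shocks[7] <- 2
    cl <- suppressWarnings(severity_and_extremes(classify_cohort(sc), k = 2))
    perm <- sample(20)
    clp <- suppressWarnings(
      severity_and_extremes(classify_cohort(sc[perm, ]), k = 2))
    expect_equal(clp$severity[match(cl$mouse_id, clp$mouse_id)], cl$severity)
    dom <- cl[cl$mouse_id == "m07", ]
    expect_equal(dom$severity, max(cl$severity))
    expect_equal(dom$extreme_set, "discovery")
    expect_equal(dom$extreme_side, "vulnerable")
  })
})

test_that("discovery and replica sets are disjoint with at most k mice each", {
  cohort <- simulate_cohort(cohort_spec(seed = 4))
  cl <- suppressWarnings(
    severity_and_extremes(classify_cohort(score_cohort(cohort$logs)), k = 6))
  tab <- table(cl$extreme_set, cl$extreme_side)
  expect_true(all(tab["discovery", ] <= 6))
  expect_true(all(tab["replica", ] <= 6))
  # per-mouse assignment is unique by construction; sides never mix sets
  expect_true(all(cl$label[cl$extreme_side %in% "vulnerable"] == "addicted"))
  expect_true(all(cl$label[cl$extreme_side %in% "resilient"] == "nonaddicted"))
})

test_that("PCA profile reports unit-norm loadings and complete variance", {
  withr::with_seed(10, {
    x <- tibble::tibble(a = rnorm(40), b = rnorm(40), c = rnorm(40),
                        d = rnorm(40), e = rnorm(40), f = rnorm(40),
                        g = rnorm(40))
    prof <- pca_profile(x)
    expect_equal(sum(prof$var_explained_pct), 100)
    expect_true(all(diff(prof$var_explained_pct) <= 1e-9))
    expect_equal(unname(colSums(prof$loadings^2)), rep(1, 7))
    # two identical features load together on one component
    x2 <- x; x2$b <- x2$a
    prof2 <- suppressWarnings(pca_profile(x2))
    l1 <- prof2$loadings[c("a", "b"), 1]
    expect_equal(l1[["a"]], l1[["b"]], tolerance = 1e-6)
    # sign-flipping one variable flips only its loadings
    x3 <- x; x3$c <- -x3$c
    prof3 <- pca_profile(x3)
    expect_equal(prof3$var_explained_pct, prof$var_explained_pct)
    expect_equal(abs(prof3$loadings), abs(prof$loadings), tolerance = 1e-8)
  })
})

test_that("pca tidiers and zero-variance handling behave", {
  withr::with_seed(12, {
    x <- tibble::tibble(a = rnorm(10), b = rnorm(10), z = rep(1, 10))
    expect_warning(prof <- pca_profile(x), "zero-variance")
    expect_equal(nrow(prof$loadings), 2)
    td <- tidy(prof)
    expect_named(td, c("variable", "component", "loading", "high_loading"))
    gl <- glance(prof)
    expect_equal(gl$cumulative_pct[nrow(gl)], 100)
  })
})

test_that("group chi-squared matches the textbook formula and its symmetries", {
  m <- matrix(c(6, 6, 3, 16), nrow = 2, byrow = TRUE)
  got <- group_chi2(m)
  expect_equal(got$statistic, oracle_chi2(m))
  expect_equal(got$df, 1)
  expect_lt(got$p_value, 0.05)
  # swapping rows changes nothing
  expect_equal(group_chi2(m[2:1, ])$statistic, got$statistic)
  # identical proportions give zero
  expect_equal(group_chi2(matrix(c(5, 10, 10, 20), 2))$statistic, 0)
  expect_error(group_chi2(matrix(c(0, 0, 3, 16), nrow = 2, byrow = TRUE)),
               "margin")
  yates <- group_chi2(m, correct = TRUE)
  expect_lt(yates$statistic, got$statistic)
})
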