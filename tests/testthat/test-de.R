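null_spec <- function(n_feat, seed, dispersion = 0.1) {
  omics_spec(n_features_mirna = n_feat,
             planted = tibble::tibble(feature = character(0),
                                      lfc = numeric(0)),
             dispersion = dispersion, seed = seed)
}

test_that("size factors reproduce hand-evaluated median-of-ratios values", {
  a <- c(10, 20, 40, 80)
  m <- cbind(a = a, b = a)
  rownames(m) <- paste0("f", 1:4)
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- cbind(a = a, b = 2 * a)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(size_factors(m2))[2] / unname(size_factors(m2))[1], 2)

  # global rescaling leaves ratios unchanged
  sf1 <- size_factors(m2)
  sf2 <- size_factors(10 * m2)
  expect_equal(sf2 / sf1, rep(1, 2), ignore_attr = TRUE)

  expect_error(size_factors(cbind(c(0, 1), c(1, 0))), "positive counts")
})

test_that("BH q-values match the hand-evaluated step-up example and oracles", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  withr::with_seed(14, {
    max_dev_oracle <- 0; max_dev_padjust <- 0
    monotone_ok <- TRUE; dominates_ok <- TRUE
    for (i in seq_len(1000)) {
      p <- runif(sample(1:60, 1))^sample(1:3, 1)
      q <- bh_fdr(p)
      max_dev_oracle <- max(max_dev_oracle, abs(q - oracle_bh(p)))
      max_dev_padjust <- max(max_dev_padjust,
                             abs(q - stats::p.adjust(p, method = "BH")))
      dominates_ok <- dominates_ok && all(q >= p - 1e-12)
      monotone_ok <- monotone_ok &&
        all(diff(q[order(p)]) >= -1e-12)
    }
    expect_lt(max_dev_oracle, 1e-12)
    expect_lt(max_dev_padjust, 1e-12)
    expect_true(dominates_ok)
    expect_true(monotone_ok)
  })
})

test_that("all-null NB simulation is calibrated at nominal 0.05", {
  fr <- vapply(1:3, function(s) {
    sim <- simulate_counts(null_spec(2000, s))
    mean(nb_test(sim$mirna, sim$meta$group)$pvalue < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.05), 0.01)
})

test_that("false positives at q < 0.05 stay below 5% when nothing is planted", {
  fp <- vapply(1:5, function(s) {
    sim <- simulate_counts(null_spec(600, s))
    de <- nb_test(sim$mirna, sim$meta$group)
    mean(de$qvalue < 0.05)
  }, numeric(1))
  expect_lte(median(fp), 0.05)
})

test_that("per-feature power at nominal 0.05 exceeds 0.7 under the planted design", {
  # |log2FC| = 1, n = 6 vs 6, dispersion 0.1
  pw <- vapply(1:20, function(s) {
    sim <- simulate_counts(omics_spec(dispersion = 0.1, seed = s))
    de <- nb_test(sim$mirna, sim$meta$group)
    planted <- sim$truth$feature[sim$truth$layer == "mirna"]
    mean(de$pvalue[de$feature %in% planted] < 0.05)
  }, numeric(1))
  expect_gte(median(pw), 0.7)
})

test_that("a feature with identical counts everywhere gives p ~ 1 and zero lfc", {
  withr::with_seed(3, {
    # all rows constant across samples, so size factors are exactly 1
    m <- matrix(rep(10 + (1:50) * 3, 8), nrow = 50)
    rownames(m) <- paste0("f", 1:50)
    de <- nb_test(m, rep(c("vulnerable", "resilient"), each = 4))
    expect_true(all(abs(de$log2fc) < 1e-8))
    expect_true(all(de$pvalue > 0.999))
  })
})

test_that("log2FC sign agrees with the normalized group-mean ratio beyond the null zone", {
  # the MLE weights samples by information, the plain group mean equally;
  # their signs can differ only where the effect is negligible
  withr::with_seed(17, {
    sim <- simulate_counts(omics_spec(seed = 99))
    de <- nb_test(sim$mirna, sim$meta$group)
    sf <- attr(de, "size_factors")
    q <- sweep(sim$mirna[de$feature, ], 2, sf, "/")
    vuln <- sim$meta$group == "vulnerable"
    ratio <- (log(rowMeans(q[, vuln]) + 1e-9) -
                log(rowMeans(q[, !vuln]) + 1e-9)) / log(2)
    informative <- abs(ratio) > 0.1 | abs(de$log2fc) > 0.1
    expect_true(any(informative))
    expect_equal(sum(sign(de$log2fc[informative]) !=
                       sign(ratio[informative])), 0)
  })
})

test_that("features below the min_total filter are not tested", {
  withr::with_seed(4, {
    m <- matrix(rnbinom(30 * 6, mu = 40, size = 10), nrow = 30)
    rownames(m) <- paste0("f", 1:30)
    m[5, ] <- c(1, 0, 0, 1, 0, 0)
    de <- nb_test(m, rep(c("vulnerable", "resilient"), each = 3))
    expect_false("f5" %in% de$feature)
  })
})

test_that("permutation and Wald p-values are rank-concordant", {
  sim <- simulate_counts(omics_spec(n_features_mirna = 150, seed = 8))
  wald <- nb_test(sim$mirna, sim$meta$group, mode = "wald")
  perm <- nb_test(sim$mirna, sim$meta$group, mode = "perm", n_perm = 300,
                  seed = 5)
  rho <- cor(wald$pvalue, perm$pvalue, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("the NB engine agrees with an established DE tool on a planted design", {
  sim <- simulate_counts(omics_spec(n_features_mirna = 300, seed = 21))
  de <- nb_test(sim$mirna, sim$meta$group)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$mirna[de$feature, ],
      S4Vectors::DataFrame(condition = factor(sim$meta$group,
                                              c("resilient", "vulnerable"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  expect_gt(cor(de$log2fc, res$log2FoldChange, use = "complete.obs"), 0.95)
  expect_gt(cor(de$stat, res$stat, use = "complete.obs",
                method = "spearman"), 0.9)
  planted <- sim$truth$feature[sim$truth$layer == "mirna"]
  top_mine <- head(de$feature[order(de$pvalue)], 11)
  expect_gte(length(intersect(top_mine, planted)), 9)
})
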