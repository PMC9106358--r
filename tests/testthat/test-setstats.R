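test_that("hypergeometric overlap matches the worked enumeration example", {
  got <- hypergeom_overlap(letters[1:4], letters[1:5], letters[1:10])
  expect_equal(got$p_value, 5 / 210)  # = C(5,4)C(5,0)/C(10,4) = C(4,4)C(6,1)/C(10,5)
  expect_equal(got$p_value, oracle_hyper_tail(4, 4, 5, 10))
  expect_equal(got$overlap, 4)

  # certain events and empty overlaps have p = 1
  u <- letters[1:6]
  expect_equal(hypergeom_overlap(u, u, u)$p_value, 1)
  expect_equal(hypergeom_overlap(letters[1:2], letters[3:4], u)$p_value, 1)
  expect_error(hypergeom_overlap(c("a", "zz"), "a", u), "subset")
})

test_that("hypergeometric tails match exhaustive enumeration for all universes <= 12", {
  max_dev <- 0
  for (n_u in 2:12) {
    for (m in 1:n_u) {
      for (s in 1:n_u) {
        uni <- as.character(seq_len(n_u))
        for (k in 0:min(m, s)) {
          p_pkg <- stats::phyper(k - 1, m, n_u - m, s, lower.tail = FALSE)
          max_dev <- max(max_dev, abs(p_pkg - oracle_hyper_tail(k, m, s, n_u)))
        }
        # and the full result row at the realized overlap
        row <- hypergeom_overlap(uni[seq_len(m)], uni[seq_len(s)], uni)
        expect_equal(row$overlap, min(m, s))
      }
    }
  }
  expect_lt(max_dev, 1e-12)
})

mk_de <- function(features, pvals, lfc) {
  out <- tibble::tibble(feature = features, base_mean = 10, log2fc = lfc,
                        dispersion = 0.05, stat = 0, pvalue = pvals,
                        qvalue = bh_fdr(pvals),
                        direction = ifelse(lfc >= 0, "up", "down"))
  class(out) <- c("nb_de", class(out))
  out
}

test_that("identical DE tables self-replicate with minimal overlap p", {
  feats <- sprintf("f%03d", 1:100)
  p <- c(rep(1e-6, 8), runif(92, 0.2, 1))
  lfc <- c(rep(-2, 8), rnorm(92, 0, 0.1))
  de <- mk_de(feats, p, lfc)
  ro <- replication_overlap(de, de)
  expect_equal(sort(ro$replicated$feature), sort(feats[1:8]))
  down <- ro$overlap[ro$overlap$set == "down", ]
  expect_equal(down$overlap, 8)
  # minimal attainable p for this configuration: the full-overlap tail
  expect_equal(down$p_value,
               stats::phyper(7, 8, 92, 8, lower.tail = FALSE))
})

test_that("replication requires direction consistency", {
  feats <- sprintf("f%03d", 1:50)
  p <- c(rep(1e-5, 5), runif(45, 0.3, 1))
  d1 <- mk_de(feats, p, c(rep(-2, 5), rnorm(45, 0, 0.1)))
  d2 <- mk_de(feats, p, c(rep(2, 5), rnorm(45, 0, 0.1)))
  ro <- replication_overlap(d1, d2)
  expect_equal(nrow(ro$replicated), 0)
  ro2 <- replication_overlap(d1, d2, direction_consistent = FALSE)
  expect_equal(nrow(ro2$replicated), 5)
})

test_that("a null replica sample yields no spurious replicated features", {
  sizes <- vapply(1:8, function(s) {
    sp <- omics_spec(seed = s)
    disc <- simulate_counts(sp, seed = 100 + s)
    null_rep <- simulate_counts(
      omics_spec(planted = tibble::tibble(feature = character(0),
                                          lfc = numeric(0)), seed = s),
      seed = 200 + s)
    ro <- replication_overlap(nb_test(disc$mirna, disc$meta$group),
                              nb_test(null_rep$mirna, null_rep$meta$group))
    nrow(ro$replicated)
  }, numeric(1))
  expect_lte(median(sizes), 1)
})

test_that("the default planted design replicates the down-regulated miRNAs", {
  res <- lapply(1:5, function(s) {
    sp <- omics_spec(seed = s)
    disc <- simulate_counts(sp, seed = 2 * s + 1)
    repl <- simulate_counts(sp, seed = 2 * s + 2)
    replication_overlap(nb_test(disc$mirna, disc$meta$group),
                        nb_test(repl$mirna, repl$meta$group))
  })
  n_down <- vapply(res, \(r) sum(r$replicated$direction == "down"), numeric(1))
  expect_gte(median(n_down), 7)
  p_down <- vapply(res, \(r)
    r$overlap$p_value[r$overlap$set == "down"], numeric(1))
  expect_lt(median(p_down), 0.05)
})

test_that("GMT files round-trip and validate", {
  db <- target_set_db(list(mirA = c("g1", "g2"), mirB = c("g2", "g3", "g4")),
                      universe = paste0("g", 1:10),
                      descriptions = c(mirA = "set A", mirB = "set B"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(db, path)
  back <- read_gmt(path, universe = paste0("g", 1:10))
  expect_identical(back$sets, db$sets)
  expect_identical(unname(back$descriptions["mirA"]), "set A")
  expect_error(target_set_db(list(mirA = "outside"), universe = "g1"),
               "outside the universe")
})

test_that("target enrichment flags coupled target sets and spares decoys", {
  sim <- simulate_counts(omics_spec(seed = 6), seed = 6)
  de <- nb_test(sim$mrna, sim$meta$group)
  genes <- de$feature[de$qvalue < 0.05]
  en <- target_enrichment(genes, sim$targets, de$feature)
  planted <- sim$truth$feature[sim$truth$layer == "mirna"]
  expect_true(all(en$q_value[en$set %in% planted] < 0.05))
  # with coupling off, mRNAs carry no signal
  sim0 <- simulate_counts(omics_spec(coupling = 0, seed = 6), seed = 6)
  de0 <- nb_test(sim0$mrna, sim0$meta$group)
  expect_lte(sum(de0$qvalue < 0.05), 2)
})

test_that("uniformly random DE genes rarely enrich any target set", {
  withr::with_seed(33, {
    uni <- sprintf("g%04d", 1:2000)
    db <- target_set_db(setNames(lapply(1:20, \(i) sample(uni, 40)),
                                 paste0("mir", 1:20)), uni)
    hits <- vapply(1:10, function(i) {
      de_genes <- sample(uni, 100)
      sum(target_enrichment(de_genes, db, uni)$q_value < 0.05)
    }, numeric(1))
    expect_lte(mean(hits / 20), 0.05)
  })
})

test_that("empty intersected target sets are reported with k = 0, not dropped", {
  uni <- paste0("g", 1:100)
  db <- target_set_db(list(mirA = paste0("g", 1:5), mirB = paste0("g", 90:99)),
                      uni)
  en <- target_enrichment(paste0("g", 1:10), db, paste0("g", 1:50))
  expect_equal(nrow(en), 2)
  expect_equal(en$overlap[en$set == "mirB"], 0)
  expect_equal(en$p_value[en$set == "mirB"], 1)
})

test_that("network export conserves edges and computes degrees", {
  uni <- paste0("g", 1:20)
  db <- target_set_db(list(mirA = c("g1", "g2"), mirB = c("g2", "g5")), uni)
  net <- export_network(c("mirA", "mirB"), db, de_genes = "g2")
  expect_equal(nrow(net$edges), 4)  # sum of intersected set sizes
  expect_equal(net$degrees$degree[net$degrees$node == "g2"], 2)
  expect_identical(net$edges$gene_is_de, c(FALSE, TRUE, TRUE, FALSE))
  # empty DE set: nothing flagged
  net0 <- export_network("mirA", db)
  expect_false(any(net0$edges$gene_is_de))
  expect_error(export_network("mirZ", db), "no target set")
})
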