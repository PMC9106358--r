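#' Pipeline run configuration
#'
#' One configuration object drives the full mouse and human runs: a global
#' seed (per-stage seeds are derived via [stage_seed()], so adding a stage
#' never shifts earlier stages' randomness), the three simulation specs, and
#' the analysis thresholds with their study defaults (75th-percentile
#' positivity, 2-of-3 rule via [classify_cohort()], extreme-set size 6,
#' DE q < 0.05).
#'
#' @param seed Global integer seed.
#' @param cohort A [cohort_spec()].
#' @param omics An [omics_spec()].
#' @param human A [human_cohort_spec()].
#' @param q Positivity quantile for [criterion_thresholds()].
#' @param de_q_cutoff Significance cut-off for DE-derived sets.
#' @param extremes_k Extreme-set size per side.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       cohort = cohort_spec(),
                       omics = omics_spec(),
                       human = human_cohort_spec(),
                       q = 0.75,
                       de_q_cutoff = 0.05,
                       extremes_k = 6L) {
  stopifnot(inherits(cohort, "cohort_spec"), inherits(omics, "omics_spec"),
            inherits(human, "human_cohort_spec"))
  structure(list(seed = as.integer(seed), cohort = cohort, omics = omics,
                 human = human, q = q, de_q_cutoff = de_q_cutoff,
                 extremes_k = as.integer(extremes_k)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys `seed`, `q`, `de_q_cutoff`, `extremes_k` plus optional
#' sections `cohort`, `omics` and `human` whose entries override the
#' corresponding spec constructor arguments.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(fn, args) do.call(fn, args %||% list())
  omics_args <- y$omics %||% list()
  if (!is.null(omics_args$planted)) {
    omics_args$planted <- as_tibble(omics_args$planted)
  }
  human_args <- y$human %||% list()
  if (!is.null(human_args$planted)) {
    human_args$planted <- as_tibble(human_args$planted)
  }
  run_config(
    seed = y$seed %||% 1L,
    cohort = build(cohort_spec, y$cohort),
    omics = build(omics_spec, omics_args),
    human = build(human_cohort_spec, human_args),
    q = y$q %||% 0.75,
    de_q_cutoff = y$de_q_cutoff %||% 0.05,
    extremes_k = y$extremes_k %||% 6L)
}

write_manifest <- function(out_dir, seed, files, extra = list()) {
  files <- sort(files)
  manifest <- c(list(
    package = "addictomir",
    version = as.character(utils::packageVersion("addictomir")),
    seed = seed,
    files = map(setNames(files, files), \(f)
      unname(tools::md5sum(file.path(out_dir, f))))),
    extra)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run the full mouse pipeline
#'
#' Simulate cohort -> score sessions -> classify (75th percentile, 2-of-3) ->
#' severity scale and discovery/replica extreme sets -> simulate discovery and
#' replica miRNA count matrices (plus the discovery mRNA matrix) for the
#' extreme animals -> NB Wald differential expression -> direction-consistent
#' replication overlap -> miRNA-target enrichment -> network export. All
#' tabular outputs are written under `out_dir` and listed with content hashes
#' in `manifest.json`; re-running with the same config reproduces identical
#' outputs. A cohort without enough mice on one side completes with empty
#' extreme sets and skips the omics stages with a warning.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main result tables (`mice`, `scores`,
#'   `classification`, `de_mirna_discovery`, `de_mirna_replica`,
#'   `replication`, `de_mrna`, `enrichment`, `network`), the written `files`
#'   and the `manifest` path.
#' @export
run_mouse_pipeline <- function(config = run_config(), out_dir = tempfile("run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    inform(line)
    log_lines <<- c(log_lines, line)
  }

  cfg <- config
  cfg$cohort$seed <- stage_seed(config$seed, "cohort")

  say("stage cohort: %d mice", cfg$cohort$n_mice)
  cohort <- simulate_cohort(cfg$cohort)

  say("stage score: %d mice", length(cohort$logs))
  scores <- score_cohort(cohort$logs)

  say("stage classify: q = %.2f", config$q)
  classified <- classify_cohort(scores, q = config$q)
  classified <- severity_and_extremes(classified, k = config$extremes_k)
  n_add <- sum(classified$label == "addicted")
  say("stage classify: %d/%d addicted (%.1f%%)", n_add, nrow(classified),
      100 * n_add / nrow(classified))

  files <- c("mice.csv", "scores.csv", "classification.csv")
  readr::write_csv(cohort$mice, file.path(out_dir, "mice.csv"))
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(as_tibble(classified), file.path(out_dir, "classification.csv"))

  extreme_meta <- function(set) {
    dat <- filter(as_tibble(classified), .data$extreme_set == set)
    tibble(sample_id = dat$mouse_id,
           group = ifelse(dat$extreme_side == "vulnerable",
                          "vulnerable", "resilient"))
  }
  results <- list(mice = cohort$mice, scores = scores,
                  classification = classified)

  disc_meta <- extreme_meta("discovery")
  repl_meta <- extreme_meta("replica")
  enough <- function(meta) {
    all(table(factor(meta$group, c("vulnerable", "resilient"))) >= 2L)
  }
  if (!enough(disc_meta) || !enough(repl_meta)) {
    warn("extreme sets too small for differential expression; omics stages skipped")
  } else {
    say("stage counts: discovery %d + replica %d samples",
        nrow(disc_meta), nrow(repl_meta))
    disc <- simulate_counts(cfg$omics, labels = disc_meta,
                            seed = stage_seed(config$seed, "counts_discovery"))
    repl <- simulate_counts(cfg$omics, labels = repl_meta,
                            seed = stage_seed(config$seed, "counts_replica"))

    say("stage de: NB Wald test, miRNA")
    de_disc <- nb_test(disc$mirna, disc$meta$group)
    de_repl <- nb_test(repl$mirna, repl$meta$group)
    replication <- replication_overlap(de_disc, de_repl,
                                       q_cutoff = config$de_q_cutoff)
    say("stage de: %d direction-consistent replicated miRNAs",
        nrow(replication$replicated))

    say("stage de: NB Wald test, mRNA (discovery)")
    de_mrna <- nb_test(disc$mrna, disc$meta$group)
    de_genes <- de_mrna$feature[de_mrna$qvalue < config$de_q_cutoff]
    expressed <- de_mrna$feature
    enrichment <- target_enrichment(de_genes, disc$targets, expressed)
    network <- export_network(
      intersect(replication$replicated$feature, names(disc$targets$sets)),
      disc$targets, de_genes)

    de_files <- c("de_mirna_discovery.tsv", "de_mirna_replica.tsv",
                  "replication_overlap.tsv", "replicated_mirnas.tsv",
                  "de_mrna_discovery.tsv", "target_enrichment.tsv",
                  "network_edges.tsv", "truth_mirna.tsv", "targets.gmt")
    readr::write_tsv(as_tibble(de_disc), file.path(out_dir, "de_mirna_discovery.tsv"))
    readr::write_tsv(as_tibble(de_repl), file.path(out_dir, "de_mirna_replica.tsv"))
    readr::write_tsv(replication$overlap, file.path(out_dir, "replication_overlap.tsv"))
    readr::write_tsv(replication$replicated, file.path(out_dir, "replicated_mirnas.tsv"))
    readr::write_tsv(as_tibble(de_mrna), file.path(out_dir, "de_mrna_discovery.tsv"))
    readr::write_tsv(enrichment, file.path(out_dir, "target_enrichment.tsv"))
    readr::write_tsv(network$edges, file.path(out_dir, "network_edges.tsv"))
    readr::write_tsv(disc$truth, file.path(out_dir, "truth_mirna.tsv"))
    write_gmt(disc$targets, file.path(out_dir, "targets.gmt"))
    files <- c(files, de_files)
    results <- c(results, list(
      de_mirna_discovery = de_disc, de_mirna_replica = de_repl,
      replication = replication, de_mrna = de_mrna,
      enrichment = enrichment, network = network))
  }

  manifest <- write_manifest(out_dir, config$seed, files,
                             extra = list(pipeline = "mouse"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(c(results, list(files = files, manifest = manifest,
                            out_dir = out_dir)))
}

#' Run the human pipeline
#'
#' Simulate the questionnaire cohort -> YFAS 2.0 scoring -> hallmark-composite
#' group comparisons (Mann-Whitney, sex-stratified when both strata have both
#' groups) -> sex-stratified miRNA-composite Pearson correlations. Outputs and
#' a hashed manifest are written under `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `subjects`, `yfas_scores`,
#'   `group_comparison`, `correlations`, `files`, `manifest`.
#' @export
run_human_pipeline <- function(config = run_config(), out_dir = tempfile("run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_h <- config$human
  cfg_h$seed <- stage_seed(config$seed, "human_cohort")
  subjects <- simulate_human(cfg_h)
  yfas <- score_yfas(subjects)

  comparison <- tryCatch(
    group_compare(yfas, stratify_sex = TRUE),
    error = function(e) {
      warn(paste("sex-stratified group comparison unavailable:",
                 conditionMessage(e), "- falling back to pooled"))
      tryCatch(group_compare(yfas, stratify_sex = FALSE),
               error = function(e2) {
                 warn("group comparison skipped: too few subjects per group")
                 tibble()
               })
    })

  mirna_cols <- intersect(unique(cfg_h$planted$mirna), names(subjects))
  correlations <- mirna_correlations(
    yfas, mirna_cols,
    score_cols = c("persistence_sum", "motivation_sum", "compulsion_sum",
                   "reward_sensitivity"),
    stratify_sex = TRUE)
  if (any(correlations$status == "undefined")) {
    warn("some correlation strata had fewer than 3 usable pairs")
  }

  files <- c("subjects.csv", "yfas_scores.csv", "group_comparison.tsv",
             "correlations.tsv")
  readr::write_csv(subjects, file.path(out_dir, "subjects.csv"))
  readr::write_csv(yfas, file.path(out_dir, "yfas_scores.csv"))
  readr::write_tsv(comparison, file.path(out_dir, "group_comparison.tsv"))
  readr::write_tsv(correlations, file.path(out_dir, "correlations.tsv"))

  manifest <- write_manifest(out_dir, config$seed, files,
                             extra = list(pipeline = "human"))
  invisible(list(subjects = subjects, yfas_scores = yfas,
                 group_comparison = comparison, correlations = correlations,
                 files = files, manifest = manifest, out_dir = out_dir))
}
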