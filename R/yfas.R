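#' YFAS 2.0 severity bands
#'
#' A diagnosed subject (>= 2 symptom criteria plus clinically significant
#' impairment) is categorized by symptom count: 2-3 mild, 4-5 moderate,
#' 6-11 severe.
#'
#' @return Tibble `band`, `min_symptoms`, `max_symptoms`.
#' @export
yfas_severity_bands <- function() {
  tibble(band = c("mild", "moderate", "severe"),
         min_symptoms = c(2L, 4L, 6L),
         max_symptoms = c(3L, 5L, 11L))
}

#' Item-to-criterion scoring map for the 35-item YFAS 2.0
#'
#' Maps each of the 35 ordinal items (frequency codes 0-7) to one of the 11
#' diagnostic symptom criteria or the clinical-significance (impairment)
#' criterion, together with the item's positivity threshold, and assigns each
#' symptom criterion to one of the three addiction hallmarks (persistence of
#' response, motivation, compulsion-like behavior) or `other`. An item meets
#' its criterion when its code is at or above the threshold; a criterion is
#' positive when any of its items meets it.
#'
#' The shipped default (`yfas2_item_map_synthetic.csv`) is a *synthetic
#' reconstruction* with the published instrument's structure (11 symptom
#' criteria of 3 items each plus 2 clinical-significance items), not the
#' copyrighted scoring key; studies using real questionnaire data should
#' supply their own map with the same columns.
#'
#' @param path CSV with columns `item`, `criterion`, `threshold`, `hallmark`.
#' @return Tibble with those columns.
#' @export
yfas_item_map <- function(path = system.file("extdata",
                                             "yfas2_item_map_synthetic.csv",
                                             package = "addictomir")) {
  map <- readr::read_csv(path, col_types = "ccic")
  check_that(
    "map needs columns item, criterion, threshold, hallmark" =
      all(c("item", "criterion", "threshold", "hallmark") %in% names(map)),
    "items must be unique" = !anyDuplicated(map$item),
    "hallmark must be persistence/motivation/compulsion/other" =
      all(map$hallmark %in% c("persistence", "motivation", "compulsion",
                              "other"))
  )
  map
}

yfas_symptom_criteria <- function(map) {
  setdiff(unique(map$criterion), "clinical_significance")
}

#' Score the YFAS 2.0 instrument
#'
#' Computes, per subject: the 11 symptom-criterion flags, the symptom count,
#' the impairment flag (clinical-significance criterion), the diagnosis
#' (`none`, or the [yfas_severity_bands()] category when the symptom count is
#' at least 2 and impairment is present), and the three hallmark composites —
#' raw item-code sums over the items mapped to the persistence, motivation and
#' compulsion hallmarks. A criterion whose items are all missing scores
#' `FALSE` with a warning. Raising any item code never lowers the symptom
#' count.
#'
#' @param subjects Data frame with the 35 item columns (`y1`..`y35`, codes
#'   0-7) and optionally `subject_id` plus any covariates, which are carried
#'   through.
#' @param map Item map, see [yfas_item_map()].
#' @return A tibble per subject: carried-through covariates, `crit_*` flags,
#'   `symptom_count`, `impairment`, `diagnosis`, `persistence_sum`,
#'   `motivation_sum`, `compulsion_sum`.
#' @export
score_yfas <- function(subjects, map = yfas_item_map()) {
  check_that(
    "subjects must contain every mapped item column" =
      all(map$item %in% names(subjects))
  )
  items <- as.matrix(subjects[map$item])
  if (any(items < 0 | items > 7, na.rm = TRUE) ||
      any(items != floor(items), na.rm = TRUE)) {
    abort("item codes must be integers in 0..7")
  }
  if (anyNA(items)) {
    warn("missing item codes: criteria with no scoreable item are set FALSE")
  }
  met <- sweep(items, 2, map$threshold, ">=")

  crit_ids <- unique(map$criterion)
  flags <- vapply(crit_ids, function(cr) {
    cols <- which(map$criterion == cr)
    apply(met[, cols, drop = FALSE], 1, \(v) isTRUE(any(v, na.rm = TRUE)))
  }, logical(nrow(items)))
  flags <- matrix(flags, nrow = nrow(items),
                  dimnames = list(NULL, crit_ids))

  symptoms <- yfas_symptom_criteria(map)
  symptom_count <- as.integer(rowSums(flags[, symptoms, drop = FALSE]))
  impairment <- if ("clinical_significance" %in% crit_ids) {
    flags[, "clinical_significance"]
  } else {
    rep(FALSE, nrow(items))
  }

  bands <- yfas_severity_bands()
  diagnosis <- rep("none", nrow(items))
  diagnosed <- symptom_count >= 2L & impairment
  for (i in seq_len(nrow(bands))) {
    in_band <- diagnosed & symptom_count >= bands$min_symptoms[i] &
      symptom_count <= bands$max_symptoms[i]
    diagnosis[in_band] <- bands$band[i]
  }

  composite <- function(hm) {
    cols <- map$item[map$hallmark == hm & map$criterion != "clinical_significance"]
    rowSums(items[, cols, drop = FALSE], na.rm = TRUE)
  }

  covars <- subjects[setdiff(names(subjects), map$item)]
  flag_tbl <- as_tibble(flags[, symptoms, drop = FALSE])
  names(flag_tbl) <- paste0("crit_", symptoms)
  bind_cols(
    as_tibble(covars),
    flag_tbl,
    tibble(symptom_count = symptom_count,
           impairment = impairment,
           diagnosis = diagnosis,
           persistence_sum = composite("persistence"),
           motivation_sum = composite("motivation"),
           compulsion_sum = composite("compulsion")))
}

#' Compare hallmark composites between diagnostic groups
#'
#' Two-sided Mann-Whitney U test (normal approximation with tie correction)
#' per hallmark composite, comparing diagnosed (food-addicted) against
#' non-diagnosed subjects, optionally within each sex.
#'
#' @param scores Tibble from [score_yfas()]; needs `diagnosis` and, when
#'   stratifying, `sex`.
#' @param composites Composite column names to test.
#' @param stratify_sex Run the tests within each sex stratum.
#' @return Tibble `composite`, `stratum`, `n_addicted`, `n_nonaddicted`,
#'   `statistic`, `p_value`.
#' @export
group_compare <- function(scores,
                          composites = c("persistence_sum", "motivation_sum",
                                         "compulsion_sum"),
                          stratify_sex = FALSE) {
  strata <- if (stratify_sex) split(scores, scores$sex) else list(all = scores)
  imap(strata, function(dat, stratum) {
    addicted <- dat$diagnosis != "none"
    if (sum(addicted) < 2L || sum(!addicted) < 2L) {
      abort(sprintf("stratum '%s' needs >= 2 subjects per group", stratum))
    }
    map(composites, function(comp) {
      wt <- suppressWarnings(
        wilcox.test(dat[[comp]][addicted], dat[[comp]][!addicted],
                    exact = FALSE))
      tibble(composite = comp, stratum = stratum,
             n_addicted = sum(addicted), n_nonaddicted = sum(!addicted),
             statistic = unname(wt$statistic), p_value = wt$p.value)
    }) |> list_rbind()
  }) |> list_rbind()
}

#' Correlations between circulating miRNAs and questionnaire scores
#'
#' Pearson correlation (t-based two-sided p) for every (miRNA column, score
#' column) pair, optionally within each sex stratum, with BH correction across
#' the whole table. Strata with fewer than 3 complete pairs or a constant
#' column yield an explicit `undefined` status instead of NaN propagation.
#'
#' @param data Subject-level tibble.
#' @param mirna_cols,score_cols Column names to correlate.
#' @param stratify_sex Compute per sex stratum (requires a `sex` column).
#' @return Tibble `mirna`, `score`, `stratum`, `n`, `r`, `p_value`, `q_value`,
#'   `status` (`ok`/`undefined`).
#' @export
mirna_correlations <- function(data, mirna_cols, score_cols,
                               stratify_sex = TRUE) {
  strata <- if (stratify_sex) split(data, data$sex) else list(all = data)
  rows <- list()
  for (stratum in names(strata)) {
    dat <- strata[[stratum]]
    for (m in mirna_cols) for (s in score_cols) {
      ok <- complete.cases(dat[[m]], dat[[s]])
      x <- dat[[m]][ok]; y <- dat[[s]][ok]
      if (length(x) < 3L || sd(x) == 0 || sd(y) == 0) {
        rows[[length(rows) + 1L]] <- tibble(
          mirna = m, score = s, stratum = stratum, n = length(x),
          r = NA_real_, p_value = NA_real_, status = "undefined")
      } else {
        ct <- cor.test(x, y, method = "pearson")
        rows[[length(rows) + 1L]] <- tibble(
          mirna = m, score = s, stratum = stratum, n = length(x),
          r = unname(ct$estimate), p_value = ct$p.value, status = "ok")
      }
    }
  }
  out <- list_rbind(rows)
  out$q_value <- NA_real_
  ok <- out$status == "ok"
  if (any(ok)) out$q_value[ok] <- bh_fdr(out$p_value[ok])
  out
}
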