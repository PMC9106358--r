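#' Human cohort simulation specification
#'
#' Study conditions for the synthetic human questionnaire cohort: by default
#' 51 subjects of whom 12 are food-addicted (diagnosed), roughly balanced
#' sexes, group-dependent BMI, and a planted per-sex correlation structure
#' between circulating miRNA levels and questionnaire composites. The default
#' planted structure is male-specific negative correlations, matching the
#' sex-specific direction of the circulating-miRNA findings the pipeline is
#' built to detect.
#'
#' @param n_subjects Total subjects.
#' @param n_addicted Number of diagnosed (food-addicted) subjects.
#' @param female_fraction Proportion of women.
#' @param planted Tibble `mirna`, `score`, `sex`, `r`: per-sex planted Pearson
#'   correlation of each simulated circulating miRNA with a composite
#'   (`persistence_sum`, `motivation_sum`, `compulsion_sum`) or
#'   `reward_sensitivity`. Unlisted (miRNA, sex) pairs are uncorrelated noise.
#' @param bmi Named list `nonaddicted`/`addicted` of `c(mean, sd)` (kg/m2).
#' @param seed Integer seed.
#' @return A `human_cohort_spec` list.
#' @export
human_cohort_spec <- function(n_subjects = 51L,
                              n_addicted = 12L,
                              female_fraction = 0.5,
                              planted = default_planted_correlations(),
                              bmi = list(nonaddicted = c(24, 3),
                                         addicted = c(30, 4)),
                              seed = 1L) {
  check_that(
    "n_subjects must be a positive integer" = is_count(n_subjects) &&
      n_subjects >= 1,
    "addicted count cannot exceed n_subjects" = n_addicted <= n_subjects,
    "n_addicted must be a non-negative integer" = is_count(n_addicted),
    "planted correlations must be in [-1, 1]" =
      all(abs(planted$r) <= 1),
    "planted sex must be female/male" = all(planted$sex %in%
                                              c("female", "male"))
  )
  structure(list(n_subjects = as.integer(n_subjects),
                 n_addicted = as.integer(n_addicted),
                 female_fraction = female_fraction,
                 planted = planted, bmi = bmi, seed = as.integer(seed)),
            class = "human_cohort_spec")
}

#' @rdname human_cohort_spec
#' @export
default_planted_correlations <- function() {
  tibble(
    mirna = c("hsa_miR_29c_3p", "hsa_miR_665_3p", "hsa_miR_192_5p"),
    score = c("persistence_sum", "motivation_sum", "reward_sensitivity"),
    sex = "male",
    r = c(-0.5, -0.4, -0.45))
}

#' Simulate a human YFAS 2.0 cohort
#'
#' Generates per-subject 35 ordinal item responses so that the implied
#' symptom count matches the subject's assigned group (addicted subjects
#' receive 2-11 flagged criteria plus clinical-significance impairment;
#' nonaddicted subjects fewer than 2 and no impairment), sex, BMI, a
#' sensitivity-to-reward score, and circulating miRNA levels constructed to
#' carry the planted per-sex Pearson correlations with the hallmark
#' composites (sample correlations converge to the planted values as the
#' cohort grows).
#'
#' @param spec A [human_cohort_spec()].
#' @param map Item map, see [yfas_item_map()].
#' @return A tibble, one row per subject: `subject_id`, `sex`, `group`,
#'   `bmi`, items `y1`..`y35`, `reward_sensitivity` and one column per
#'   planted miRNA. The planted structure is attached as attribute
#'   `"planted"`.
#' @export
simulate_human <- function(spec = human_cohort_spec(), map = yfas_item_map()) {
  stopifnot(inherits(spec, "human_cohort_spec"))
  n <- spec$n_subjects
  symptoms <- yfas_symptom_criteria(map)

  withr::with_seed(spec$seed, {
    group <- sample(rep(c("addicted", "nonaddicted"),
                        c(spec$n_addicted, n - spec$n_addicted)))
    sex <- ifelse(runif(n) < spec$female_fraction, "female", "male")
    n_sym <- ifelse(group == "addicted",
                    sample(2:11, n, replace = TRUE,
                           prob = c(4, 4, 3, 3, 2, 2, 1, 1, 1, 1)),
                    sample(0:1, n, replace = TRUE))

    items <- matrix(0L, nrow = n, ncol = nrow(map),
                    dimnames = list(NULL, map$item))
    for (i in seq_len(n)) {
      flagged <- sample(symptoms, n_sym[i])
      for (cr in unique(map$criterion)) {
        cols <- which(map$criterion == cr)
        thr <- map$threshold[cols]
        pos <- cr %in% flagged ||
          (cr == "clinical_significance" && group[i] == "addicted")
        if (pos) {
          hit <- sample(seq_along(cols), 1L)
          for (j in seq_along(cols)) {
            items[i, cols[j]] <- if (j == hit) {
              sample(thr[j]:7L, 1L)
            } else {
              sample(0:7L, 1L)  # free codes; criterion already positive
            }
          }
        } else {
          for (j in seq_along(cols)) {
            items[i, cols[j]] <- sample(0:(thr[j] - 1L), 1L)
          }
        }
      }
    }

    bmi <- ifelse(group == "addicted",
                  rnorm(n, spec$bmi$addicted[1L], spec$bmi$addicted[2L]),
                  rnorm(n, spec$bmi$nonaddicted[1L],
                        spec$bmi$nonaddicted[2L]))
    reward_sensitivity <- rnorm(n, 50, 10) +
      ifelse(group == "addicted", 8, 0)

    subjects <- bind_cols(
      tibble(subject_id = sprintf("h%03d", seq_len(n)), sex = sex,
             group = group, bmi = pmax(bmi, 14)),
      as_tibble(items),
      tibble(reward_sensitivity = reward_sensitivity))

    # composites implied by the generated items
    comp <- score_yfas(subjects, map)

    for (m in unique(spec$planted$mirna)) {
      level <- rnorm(n)  # baseline: standard-normal expression noise
      for (k in which(spec$planted$mirna == m)) {
        srow <- spec$planted[k, ]
        in_sex <- sex == srow$sex
        target <- if (srow$score %in% names(comp)) {
          comp[[srow$score]]
        } else {
          subjects[[srow$score]]
        }
        z <- target[in_sex]
        z <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0
        level[in_sex] <- srow$r * z +
          sqrt(1 - srow$r^2) * rnorm(sum(in_sex))
      }
      subjects[[m]] <- 10 + 2 * level  # arbitrary normalized-expression scale
    }
  })
  attr(subjects, "planted") <- spec$planted
  subjects
}
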