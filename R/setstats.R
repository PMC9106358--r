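#' miRNA target-set database
#'
#' A container mapping miRNA ids to their annotated target-gene sets within a
#' gene universe.
#'
#' @param sets Named list of character vectors (miRNA id -> target genes).
#' @param universe Character vector of all gene ids; every set must be a
#'   subset.
#' @param descriptions Optional named character vector of set descriptions.
#' @return A `target_set_db` list.
#' @export
target_set_db <- function(sets, universe, descriptions = NULL) {
  check_that(
    "sets must be a named list" =
      is.list(sets) && !is.null(names(sets)) && all(nzchar(names(sets))),
    "universe must be non-empty" = length(universe) > 0
  )
  sets <- map(sets, unique)
  stray <- setdiff(unlist(sets), universe)
  if (length(stray)) {
    abort(paste0("target genes outside the universe: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  descriptions <- descriptions %||%
    setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, universe = unique(universe),
                 descriptions = descriptions),
            class = "target_set_db")
}

#' Read / write target sets in GMT dialect
#'
#' One set per line: `mirna_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Because GMT carries no universe, `read_gmt()` takes it as an argument
#' (default: the union of all sets).
#'
#' @param path File path.
#' @param universe Gene universe for [target_set_db()].
#' @param db A `target_set_db`.
#' @return `read_gmt()` a `target_set_db`; `write_gmt()` the path, invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- map_chr(parts, 1L)
  descriptions <- setNames(map_chr(parts, 2L), ids)
  sets <- setNames(map(parts, \(p) unique(p[-(1:2)])), ids)
  target_set_db(sets, universe %||% unique(unlist(sets)), descriptions)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "target_set_db"))
  lines <- map_chr(names(db$sets), \(id)
    paste(c(id, db$descriptions[[id]], db$sets[[id]]), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric overlap of two sets
#'
#' One-sided upper-tail hypergeometric probability of observing an overlap at
#' least as large as `|A` \eqn{\cap} `B|` when a set of size `|B|` is drawn
#' uniformly from the universe, given `|A|`.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector.
#' @param name Label for the result row.
#' @return A one-row tibble `set`, `overlap`, `set_size`, `selected`,
#'   `universe`, `p_value`, `odds_ratio`.
#' @export
#' @examples
#' hypergeom_overlap(letters[1:4], letters[1:5], letters[1:10])
hypergeom_overlap <- function(set_a, set_b, universe, name = "overlap") {
  check_that(
    "universe must be non-empty" = length(universe) > 0,
    "set_a must be a subset of the universe" = all(set_a %in% universe),
    "set_b must be a subset of the universe" = all(set_b %in% universe)
  )
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  k <- length(intersect(set_a, set_b))
  m <- length(set_a); s <- length(set_b); n_u <- length(universe)
  p <- phyper(k - 1, m, n_u - m, s, lower.tail = FALSE)
  # unconditional odds ratio of the 2x2 membership table
  a <- k; b <- m - k; cc <- s - k; d <- n_u - m - s + k
  odds <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
  tibble(set = name, overlap = k, set_size = m, selected = s,
         universe = n_u, p_value = p, odds_ratio = odds)
}

#' Direction-consistent discovery/replica replication test
#'
#' Splits the significant features of two differential-expression tables by
#' direction and tests, per direction, whether the discovery and replica
#' significant sets overlap more than expected by chance, conditioning on the
#' features tested in both samples. A feature is *replicated* when it is
#' significant in both samples with the same direction (when
#' `direction_consistent`).
#'
#' @param de_discovery,de_replica `nb_de` tibbles from [nb_test()].
#' @param q_cutoff Significance cut-off on the q-value (default 0.05).
#' @param direction_consistent Require equal direction for replication.
#' @return A list with `overlap` (tibble, one row per direction, from
#'   [hypergeom_overlap()]) and `replicated` (tibble `feature`, `direction`,
#'   with the discovery/replica log2 fold changes).
#' @export
replication_overlap <- function(de_discovery, de_replica, q_cutoff = 0.05,
                                direction_consistent = TRUE) {
  common <- intersect(de_discovery$feature, de_replica$feature)
  if (!length(common)) abort("no features tested in both samples")
  d <- filter(de_discovery, .data$feature %in% common)
  r <- filter(de_replica, .data$feature %in% common)

  per_direction <- function(dir) {
    a <- d$feature[d$qvalue < q_cutoff & d$direction == dir]
    b <- r$feature[r$qvalue < q_cutoff & r$direction == dir]
    hypergeom_overlap(a, b, common, name = dir)
  }
  overlap <- bind_rows(per_direction("down"), per_direction("up"))

  sig_d <- filter(d, .data$qvalue < q_cutoff)
  sig_r <- filter(r, .data$qvalue < q_cutoff)
  rep_tbl <- inner_join(
    select(sig_d, "feature", direction_discovery = "direction",
           log2fc_discovery = "log2fc"),
    select(sig_r, "feature", direction_replica = "direction",
           log2fc_replica = "log2fc"),
    by = "feature")
  if (direction_consistent) {
    rep_tbl <- filter(rep_tbl,
                      .data$direction_discovery == .data$direction_replica)
  }
  rep_tbl <- rep_tbl |>
    mutate(direction = .data$direction_discovery) |>
    select("feature", "direction", "log2fc_discovery", "log2fc_replica") |>
    arrange(.data$feature)
  list(overlap = overlap, replicated = rep_tbl)
}

#' miRNA target-set enrichment among differentially expressed genes
#'
#' For each miRNA in the database, a one-sided hypergeometric test of whether
#' its target genes (intersected with the expressed universe) are
#' over-represented among the differentially expressed genes, BH-corrected
#' across miRNAs. miRNAs whose intersected target set is empty are reported
#' with an overlap of 0, never dropped.
#'
#' @param de_genes Character vector of differentially expressed gene ids.
#' @param targets A [target_set_db()].
#' @param expressed_universe Character vector of genes considered expressed /
#'   testable; `de_genes` must be a subset.
#' @return Tibble, one row per miRNA, columns as in [hypergeom_overlap()] plus
#'   `q_value`.
#' @export
target_enrichment <- function(de_genes, targets, expressed_universe) {
  stopifnot(inherits(targets, "target_set_db"))
  check_that(
    "de_genes must be a subset of the expressed universe" =
      all(de_genes %in% expressed_universe)
  )
  out <- imap(targets$sets, \(genes, id)
    hypergeom_overlap(intersect(genes, expressed_universe), de_genes,
                      expressed_universe, name = id)) |>
    list_rbind()
  out$q_value <- bh_fdr(out$p_value)
  out
}

#' Export a miRNA-target network edge list
#'
#' @param mirnas Character vector of miRNA ids (e.g. the replicated list).
#' @param targets A [target_set_db()].
#' @param de_genes Character vector of differentially expressed genes.
#' @return A list with `edges` (tibble `mirna`, `gene`, `gene_is_de`, in
#'   deterministic order) and `degrees` (tibble `node`, `type`, `degree`).
#' @export
export_network <- function(mirnas, targets, de_genes = character(0)) {
  stopifnot(inherits(targets, "target_set_db"))
  missing_sets <- setdiff(mirnas, names(targets$sets))
  if (length(missing_sets)) {
    abort(paste0("no target set for: ", paste(missing_sets, collapse = ", ")))
  }
  edges <- map(sort(mirnas), \(m)
    tibble(mirna = m, gene = sort(targets$sets[[m]]))) |>
    list_rbind() |>
    mutate(gene_is_de = .data$gene %in% de_genes)
  degrees <- bind_rows(
    count(edges, node = .data$mirna, name = "degree") |>
      mutate(type = "mirna"),
    count(edges, node = .data$gene, name = "degree") |>
      mutate(type = "gene")) |>
    select("node", "type", "degree") |>
    arrange(.data$type, .data$node)
  list(edges = edges, degrees = degrees)
}
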