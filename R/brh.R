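#' Best hits from one species into another
#'
#' For each gene of `from_species` with at least one hit into `to_species`,
#' the maximal-score target; ties broken by lexicographically smallest
#' target id.
#'
#' @param hits Hit table (see [all_vs_all()]).
#' @param from_species,to_species Distinct species ids.
#' @return Tibble `gene_id`, `best_target`, `score`.
#' @export
best_hits <- function(hits, from_species, to_species) {
  if (from_species == to_species) abort("species must be distinct")
  hits |>
    filter(.data$query_species == from_species,
           .data$target_species == to_species) |>
    arrange(.data$query_id, desc(.data$score), .data$target_id) |>
    group_by(.data$query_id) |>
    slice(1) |>
    ungroup() |>
    select(gene_id = "query_id", best_target = "target_id", "score")
}

#' Best-reciprocal-hit pairs between two species
#'
#' A pair (x, y) is a BRH iff y is x's best hit into `species_b` and x is
#' y's best hit back. BRHs are the candidate orthologs: a best-reciprocal
#' hit acts as a proxy for reconciling the gene tree with the species pair.
#'
#' @inheritParams best_hits
#' @param species_a,species_b Distinct species ids.
#' @return Tibble `gene_a`, `species_a`, `gene_b`, `species_b`, `score_ab`,
#'   `score_ba`, with `gene_a < gene_b` lexicographically.
#' @export
brh_pairs <- function(hits, species_a, species_b) {
  ab <- best_hits(hits, species_a, species_b)
  ba <- best_hits(hits, species_b, species_a)
  rec <- inner_join(ab, ba, by = c(best_target = "gene_id"),
                    suffix = c("_ab", "_ba")) |>
    filter(.data$gene_id == .data$best_target_ba)
  if (!nrow(rec)) {
    return(tibble(gene_a = character(), species_a = character(),
                  gene_b = character(), species_b = character(),
                  score_ab = numeric(), score_ba = numeric()))
  }
  flip <- rec$gene_id > rec$best_target
  tibble(
    gene_a = ifelse(flip, rec$best_target, rec$gene_id),
    species_a = ifelse(flip, species_b, species_a),
    gene_b = ifelse(flip, rec$gene_id, rec$best_target),
    species_b = ifelse(flip, species_a, species_b),
    score_ab = ifelse(flip, rec$score_ba, rec$score_ab),
    score_ba = ifelse(flip, rec$score_ab, rec$score_ba)
  ) |>
    arrange(.data$gene_a, .data$gene_b)
}

#' All BRH pairs across every species pair
#'
#' @param hits Hit table.
#' @param species Optional species subset (default: all species in `hits`).
#' @return Row-bound [brh_pairs()] tables for every unordered species pair.
#' @export
all_brh_pairs <- function(hits, species = NULL) {
  if (is.null(species)) {
    species <- sort(unique(c(hits$query_species, hits$target_species)))
  } else {
    species <- sort(species)
  }
  out <- list()
  if (length(species) >= 2) {
    for (i in seq_len(length(species) - 1)) {
      for (j in (i + 1):length(species)) {
        out[[length(out) + 1L]] <- brh_pairs(hits, species[i], species[j])
      }
    }
  }
  res <- bind_rows(out)
  if (!nrow(res)) {
    return(tibble(gene_a = character(), species_a = character(),
                  gene_b = character(), species_b = character(),
                  score_ab = numeric(), score_ba = numeric()))
  }
  arrange(res, .data$gene_a, .data$gene_b)
}

#' Attach in-paralogs to BRH anchors at a level
#'
#' Recent within-species duplicates (in-paralogs) are co-orthologous to the
#' partner species' genes and belong in the ancestral OG. A gene `g` that is
#' itself in no BRH at this level is attached to a same-species anchor `m`
#' participating in a BRH iff `score(g, m) >=` the maximum score between `m`
#' and any of its BRH partners at this level, i.e. the duplicates are closer
#' to each other than `m` is to its cross-species orthologs. Requires
#' within-species hits in the hit table (`all_vs_all(...,
#' cross_species_only = FALSE)`).
#'
#' @param hits Hit table including within-species hits.
#' @param brh BRH table restricted to the level (see [all_brh_pairs()]).
#' @return Tibble `gene_id`, `anchor_id`, `score` with one row per
#'   qualifying (gene, anchor) pair.
#' @export
attach_inparalogs <- function(hits, brh) {
  empty <- tibble(gene_id = character(), anchor_id = character(),
                  score = numeric())
  if (!nrow(brh)) return(empty)
  brh_genes <- unique(c(brh$gene_a, brh$gene_b))
  # per anchor, the max score to any of its BRH partners (directed scores
  # from the anchor's side)
  anchor_best <- bind_rows(
    tibble(anchor_id = brh$gene_a, s = brh$score_ab),
    tibble(anchor_id = brh$gene_b, s = brh$score_ba)
  ) |>
    group_by(.data$anchor_id) |>
    summarise(best_brh = max(.data$s), .groups = "drop")
  within <- hits |>
    filter(.data$query_species == .data$target_species,
           !.data$query_id %in% brh_genes,
           .data$target_id %in% brh_genes)
  if (!nrow(within)) return(empty)
  within |>
    inner_join(anchor_best, by = c(target_id = "anchor_id")) |>
    filter(.data$score >= .data$best_brh) |>
    select(gene_id = "query_id", anchor_id = "target_id", "score") |>
    arrange(.data$gene_id, .data$anchor_id)
}
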