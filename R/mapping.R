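#' Reference intra-OG score
#'
#' Median local-alignment score over all member-member pairs of an OG, used
#' to calibrate mapping acceptance. When an OG has more than `max_pairs`
#' member pairs a seeded random subsample of `max_pairs` pairs is scored
#' instead, so the calibration stays cheap and reproducible for huge groups.
#'
#' @param member_seqs Character vector of member sequences (>= 2).
#' @param params [align_params()].
#' @param max_pairs Subsample cap (default 50).
#' @param seed Seed for the subsample (default 1).
#' @return Median pairwise score (numeric).
#' @export
og_reference_score <- function(member_seqs, params = align_params(),
                               max_pairs = 50, seed = 1) {
  n <- length(member_seqs)
  if (n < 2) abort("need >= 2 member sequences")
  pairs <- utils::combn(n, 2)
  if (ncol(pairs) > max_pairs) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  scores <- vapply(seq_len(ncol(pairs)), function(i) {
    score_pair(member_seqs[pairs[1, i]], member_seqs[pairs[2, i]], params)
  }, numeric(1))
  median(scores)
}

# save/restore the global RNG state so seeded subroutines do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Map a novel proteome onto precomputed OGs
#'
#' Places genes of a newly sequenced species into an existing per-level OG
#' set without re-running ab-initio delineation, so lower-quality inputs
#' (e.g. incomplete transcriptome gene sets) cannot skew the precomputed
#' orthology. Each novel gene is scored against OG member sequences passing
#' the k-mer prefilter; it is assigned to the OG of its best-scoring anchor
#' iff `score >= accept_ratio *` the OG's reference score
#' ([og_reference_score()]), otherwise left unassigned. Ties on score break
#' by lexicographically smallest anchor id.
#'
#' @param novel Gene table of the novel species (single species, not among
#'   the OG member species).
#' @param ogs OG membership tibble (one level's OGs; columns `og_id`,
#'   `gene_id`).
#' @param member_genes Gene table resolving the OG member sequences.
#' @param params [align_params()].
#' @param accept_ratio Acceptance threshold as a fraction of the reference
#'   intra-OG score (default 0.5). Raising it can only reduce the number of
#'   assigned genes.
#' @param seed Seed for reference-score subsampling (default 1).
#' @return Tibble `gene_id`, `og_id` (`"unassigned"` when rejected),
#'   `anchor_id`, `score`, `acceptance_ratio`.
#' @export
map_genes <- function(novel, ogs, member_genes, params = align_params(),
                      accept_ratio = 0.5, seed = 1) {
  novel <- as_gene_table(novel)
  member_genes <- as_gene_table(member_genes, check_alphabet = FALSE)
  if (!nrow(ogs)) abort("empty OG set")
  if (length(unique(ogs$level)) > 1) {
    abort("map_genes expects OGs from a single level")
  }
  members <- ogs |>
    inner_join(member_genes, by = "gene_id") |>
    select("og_id", "gene_id", "sequence")
  if (any(novel$species_id %in% member_genes$species_id)) {
    abort("novel species is already among the OG member species")
  }
  # one reference score per OG
  ref <- members |>
    group_by(.data$og_id) |>
    summarise(ref_score = og_reference_score(.data$sequence, params,
                                             seed = seed),
              .groups = "drop")
  # candidate (novel gene, member) pairs via the shared-k-mer prefilter
  ids <- c(novel$gene_id, members$gene_id)
  seqs <- c(novel$sequence, members$sequence)
  nn <- nrow(novel)
  cand <- kmer_candidates(ids, seqs, params$kmer_size,
                          params$min_shared_kmers) |>
    mutate(qi = pmin(.data$i, .data$j), mi = pmax(.data$i, .data$j)) |>
    filter(.data$qi <= nn, .data$mi > nn)
  unassigned_row <- function(g) {
    tibble(gene_id = g, og_id = "unassigned", anchor_id = NA_character_,
           score = NA_real_, acceptance_ratio = NA_real_)
  }
  if (!nrow(cand)) {
    return(bind_rows(purrr::map(sort(novel$gene_id), unassigned_row)))
  }
  all_seq <- tibble(gene_id = ids, sequence = seqs)
  pair_tbl <- tibble(i = cand$qi, j = cand$mi)
  sc <- score_candidates(all_seq, pair_tbl, params)
  scored <- tibble(
    gene_id = ids[cand$qi],
    anchor_id = ids[cand$mi],
    score = sc
  ) |>
    inner_join(members |> select("og_id", anchor_id = "gene_id"),
               by = "anchor_id") |>
    arrange(.data$gene_id, desc(.data$score), .data$anchor_id) |>
    group_by(.data$gene_id) |>
    slice(1) |>
    ungroup() |>
    inner_join(ref, by = "og_id") |>
    mutate(acceptance_ratio = .data$score / .data$ref_score,
           og_id = if_else(.data$score >= accept_ratio * .data$ref_score,
                           .data$og_id, "unassigned")) |>
    select("gene_id", "og_id", "anchor_id", "score", "acceptance_ratio")
  missing <- setdiff(novel$gene_id, scored$gene_id)
  bind_rows(scored, bind_rows(purrr::map(missing, unassigned_row))) |>
    arrange(.data$gene_id)
}

#' Write mapping results
#'
#' @param mapping Result of [map_genes()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  readr::write_tsv(mapping, path)
  invisible(path)
}
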