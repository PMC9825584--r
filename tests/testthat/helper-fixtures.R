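AA20_tst <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_aa <- function(len) {
  paste(sample(AA20_tst, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# point-mutate a protein sequence at a given per-site rate
mutate_aa <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20_tst, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

# dense random score table between two species as a hit table tibble
random_hit_table <- function(n_a, n_b, p_hit = 0.7, max_score = 100) {
  rows <- list()
  a_ids <- sprintf("a%02d", seq_len(n_a))
  b_ids <- sprintf("b%02d", seq_len(n_b))
  scores <- matrix(NA_real_, n_a, n_b, dimnames = list(a_ids, b_ids))
  for (x in a_ids) {
    for (y in b_ids) {
      if (runif(1) < p_hit) scores[x, y] <- sample.int(max_score, 1)
    }
  }
  idx <- which(!is.na(scores), arr.ind = TRUE)
  hits <- tibble::tibble(
    query_id = c(a_ids[idx[, 1]], b_ids[idx[, 2]]),
    query_species = rep(c("A", "B"), each = nrow(idx)),
    target_id = c(b_ids[idx[, 2]], a_ids[idx[, 1]]),
    target_species = rep(c("B", "A"), each = nrow(idx)),
    score = c(scores[idx], scores[idx])
  )
  list(hits = hits, scores = scores)
}

# small three-species gene table: `n_fam` families derived from common
# ancestors by light mutation, plus optional unrelated singleton genes
family_genes <- function(n_fam = 5, species = c("A", "B", "C"),
                         len = 120, p_mut = 0.05, n_orphans = 0) {
  rows <- list()
  for (f in seq_len(n_fam)) {
    anc <- random_aa(len)
    for (sp in species) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = sprintf("%s_f%02d", sp, f),
        species_id = sp,
        sequence = mutate_aa(anc, p_mut)
      )
    }
  }
  for (o in seq_len(n_orphans)) {
    sp <- species[1 + (o - 1) %% length(species)]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      gene_id = sprintf("%s_orph%02d", sp, o),
      species_id = sp,
      sequence = random_aa(len)
    )
  }
  dplyr::bind_rows(rows)
}

# memoized pipelines shared across acceptance blocks (the easy and strict
# recovery regimes are expensive to recompute per test)
.regime_cache <- new.env()

regime_pipeline <- function(regime = c("easy", "strict"), seed = 20260928) {
  regime <- match.arg(regime)
  key <- paste0(regime, "_", seed)
  if (!is.null(.regime_cache[[key]])) return(.regime_cache[[key]])
  tree <- demo_species_tree()
  rate <- if (regime == "easy") 0.05 else 0
  cfg <- sim_config(seed = seed, tree = tree, n_families = 100,
                    dup_rate = rate, loss_rate = rate, sub_scale = rate)
  sim <- simulate_families(cfg)
  hits <- all_vs_all(sim$genes)
  del <- delineate_ogs(sim$genes, hits, tree, mode = "levels")
  res <- list(tree = tree, sim = sim, hits = hits, del = del)
  .regime_cache[[key]] <- res
  res
}
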