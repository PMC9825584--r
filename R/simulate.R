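AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Parameters of the gene duplication-loss-divergence simulator. Gene
#' families evolve independently along the branches of a species tree with
#' branch lengths: on a branch of length t each existing gene copy is lost
#' with probability `1 - exp(-loss_rate * t)`; each survivor duplicates
#' (one extra copy) with probability `1 - exp(-dup_rate * t)`; every
#' resulting copy then mutates independently, each site substituting with
#' probability `1 - exp(-sub_scale * t)` uniformly among the 19 other
#' residues. These three rates operationalize the axes along which real
#' gene families vary in difficulty: duplication, loss and sequence
#' divergence. Losses are applied before duplications within a branch so a
#' copy cannot duplicate and vanish in the same step.
#'
#' @param seed Integer RNG seed; the simulation is fully reproducible
#'   from it.
#' @param tree Species tree with branch lengths ([parse_newick()]).
#' @param n_families Number of independent families (default 100).
#' @param dup_rate,loss_rate Duplication/loss rates per gene per unit
#'   branch length (default 0).
#' @param sub_scale Expected substitutions per site per unit branch length
#'   (default 0).
#' @param root_length_mean,root_length_sd Root sequence length
#'   distribution in residues (default 300 / 50, truncated at
#'   `min_length`).
#' @param min_length Minimum root length (default 50).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed, tree, n_families = 100, dup_rate = 0,
                       loss_rate = 0, sub_scale = 0,
                       root_length_mean = 300, root_length_sd = 50,
                       min_length = 50) {
  if (is.null(tree$edge.length)) {
    abort("simulation requires a species tree with branch lengths")
  }
  if (dup_rate < 0 || loss_rate < 0 || sub_scale < 0) {
    abort("rates must be >= 0")
  }
  if (n_families < 1) abort("n_families must be >= 1")
  structure(
    list(seed = as.integer(seed), tree = tree,
         n_families = as.integer(n_families),
         dup_rate = dup_rate, loss_rate = loss_rate, sub_scale = sub_scale,
         root_length_mean = root_length_mean,
         root_length_sd = root_length_sd, min_length = min_length),
    class = "sim_config"
  )
}

mutate_seq <- function(seq, p) {
  if (p <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < p)
  if (length(hit)) {
    cur <- match(chars[hit], AA20)
    new <- sample.int(19L, length(hit), replace = TRUE)
    new <- new + (new >= cur)
    chars[hit] <- AA20[new]
    seq <- paste(chars, collapse = "")
  }
  seq
}

#' A small balanced species tree for demonstrations and simulations
#'
#' Five species, all branch lengths equal: `((A,B)ab,(C,(D,E)de)cde)root`.
#'
#' @param branch_length Length of every branch (default 1).
#' @return `ape::phylo`.
#' @export
demo_species_tree <- function(branch_length = 1) {
  b <- format(branch_length)
  parse_newick(sprintf(
    "((A:%s,B:%s)ab:%s,(C:%s,(D:%s,E:%s)de:%s)cde:%s)root;",
    b, b, b, b, b, b, b, b))
}

#' Simulate gene families with known ortholog truth
#'
#' Evolves `n_families` independent families along the species tree (see
#' [sim_config()] for the model) and records, at every internal node, the
#' true orthologous groups: the sets of extant genes descending from each
#' single gene copy present at that node. These truth sets are exactly what
#' BRH-based delineation tries to recover, so the simulator provides
#' end-to-end validation with known answers.
#'
#' @param config [sim_config()].
#' @return Object of class `og_simulation`: list with
#'   * `genes` — gene table (`gene_id`, `species_id`, `sequence`) plus
#'     `family` and `copy_id` provenance columns;
#'   * `truth` — tibble `og_id`, `level`, `gene_id`, `species_id`,
#'     `family` of true OGs at every internal level (including
#'     single-gene groups);
#'   * `tree`, `config`.
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- config$tree
  n_tip <- length(tree$tip.label)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  env <- new.env()
  env$copy_counter <- 0L
  env$truth <- list()
  env$genes <- list()

  new_copy_id <- function(fam) {
    env$copy_counter <- env$copy_counter + 1L
    sprintf("f%04d_c%06d", fam, env$copy_counter)
  }

  branch_len <- function(parent, child) {
    tree$edge.length[tree$edge[, 1] == parent & tree$edge[, 2] == child]
  }

  # copies: list(copy_id = character, sequence = character), identities AT
  # `node`; returns extant genes tibble(gene_id, species_id, sequence,
  # copy_id, origin) with origin = ancestor copy id at `node`
  evolve <- function(node, copies, fam) {
    if (node <= n_tip) {
      sp_name <- tree$tip.label[node]
      if (!length(copies$copy_id)) {
        return(tibble(gene_id = character(), species_id = character(),
                      sequence = character(), copy_id = character(),
                      origin = character()))
      }
      ids <- vapply(copies$copy_id, function(cid) {
        cnt <- (env$gene_counter[[sp_name]] %||% 0L) + 1L
        env$gene_counter[[sp_name]] <- cnt
        sprintf("%s_g%05d", sp_name, cnt)
      }, "")
      return(tibble(gene_id = unname(ids), species_id = sp_name,
                    sequence = copies$sequence, copy_id = copies$copy_id,
                    origin = copies$copy_id))
    }
    kids <- tree_children(tree, node)
    level <- tree$node.label[node - n_tip]
    res <- list()
    for (child in kids) {
      t <- branch_len(node, child)
      n0 <- length(copies$copy_id)
      if (!n0) {
        child_genes <- evolve(child, list(copy_id = character(),
                                          sequence = character()), fam)
        res[[length(res) + 1L]] <- child_genes
        next
      }
      # loss, then duplication, then per-copy mutation
      survive <- runif(n0) < exp(-config$loss_rate * t)
      origin_at_node <- copies$copy_id[survive]
      seqs <- copies$sequence[survive]
      n1 <- length(seqs)
      dup <- if (n1) runif(n1) < (1 - exp(-config$dup_rate * t)) else logical(0)
      origin_at_node <- c(origin_at_node, origin_at_node[dup])
      seqs <- c(seqs, seqs[dup])
      p <- 1 - exp(-config$sub_scale * t)
      seqs <- vapply(seqs, mutate_seq, "", p = p, USE.NAMES = FALSE)
      new_ids <- vapply(seq_along(seqs), function(i) new_copy_id(fam), "")
      child_genes <- evolve(child, list(copy_id = new_ids, sequence = seqs),
                            fam)
      # map the child's origins (copy ids at `child`) back to copy ids at
      # `node`
      back <- setNames(origin_at_node, new_ids)
      child_genes$origin <- unname(back[child_genes$origin])
      res[[length(res) + 1L]] <- child_genes
    }
    out <- bind_rows(res)
    if (nrow(out)) {
      env$truth[[length(env$truth) + 1L]] <- out |>
        select("gene_id", "species_id", "origin") |>
        mutate(level = level, family = fam)
    }
    out
  }

  env$gene_counter <- list()
  for (fam in seq_len(config$n_families)) {
    len <- max(config$min_length,
               round(stats::rnorm(1, config$root_length_mean,
                                  config$root_length_sd)))
    root_seq <- paste(sample(AA20, len, replace = TRUE), collapse = "")
    root_copy <- new_copy_id(fam)
    g <- evolve(n_tip + 1L, list(copy_id = root_copy, sequence = root_seq),
                fam)
    g$family <- fam
    env$genes[[fam]] <- g
  }

  genes <- bind_rows(env$genes) |>
    select("gene_id", "species_id", "sequence", "family", "copy_id")
  truth_raw <- bind_rows(env$truth)
  truth <- truth_raw |>
    group_by(.data$level, .data$origin) |>
    mutate(.size = n(), .min_gene = min(.data$gene_id)) |>
    ungroup()
  # og ids per level by (descending size, then smallest member gene id)
  ids <- truth |>
    distinct(.data$level, .data$origin, .data$.size, .data$.min_gene) |>
    arrange(.data$level, desc(.data$.size), .data$.min_gene) |>
    group_by(.data$level) |>
    mutate(og_id = sprintf("og%dat%s", row_number(), .data$level)) |>
    ungroup() |>
    select("level", "origin", "og_id")
  truth <- truth |>
    inner_join(ids, by = c("level", "origin")) |>
    select("og_id", "level", "gene_id", "species_id", "family") |>
    arrange(.data$level, .data$og_id, .data$gene_id)

  structure(list(genes = genes, truth = truth, tree = tree,
                 config = config),
            class = "og_simulation")
}

#' @export
print.og_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset: %d genes in %d species, %d families (seed %d)\n",
    nrow(x$genes), length(unique(x$genes$species_id)),
    x$config$n_families, x$config$seed))
  invisible(x)
}

#' True OG partition at a level
#'
#' @param sim `og_simulation`.
#' @param level Internal level label.
#' @param min_species Drop truth groups spanning fewer species (default 1:
#'   keep all).
#' @return Tibble `og_id`, `level`, `gene_id`, `species_id`.
#' @export
truth_ogs <- function(sim, level, min_species = 1) {
  tr <- sim$truth |> filter(.data$level == !!level)
  if (min_species > 1) {
    keep <- tr |>
      group_by(.data$og_id) |>
      summarise(nsp = dplyr::n_distinct(.data$species_id),
                .groups = "drop") |>
      filter(.data$nsp >= min_species)
    tr <- tr |> semi_join(keep, by = "og_id")
  }
  tr |> select("og_id", "level", "gene_id", "species_id")
}

#' Write a simulated dataset to disk
#'
#' Writes one protein FASTA per species, one truth OG TSV per internal
#' level (OG-table schema), a refOG TSV derived from root-level truth
#' (restricted to groups with >= 2 genes spanning >= 2 species, the groups
#' a delineation method can in principle reconstruct), the species tree in
#' Newick, and a JSON config carrying the seed and rates. Re-running with
#' the same seed reproduces byte-identical files.
#'
#' @param sim `og_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (sp in sort(unique(sim$genes$species_id))) {
    p <- file.path(dir, paste0(sp, ".fasta"))
    sim$genes |>
      filter(.data$species_id == sp) |>
      arrange(.data$gene_id) |>
      write_fasta(p)
    paths[[paste0("fasta_", sp)]] <- p
  }
  root_label <- sim$tree$node.label[1]
  for (l in unique(sim$truth$level)) {
    p <- file.path(dir, paste0("truth_", l, ".tsv"))
    write_og_table(truth_ogs(sim, l), p)
    paths[[paste0("truth_", l)]] <- p
  }
  ref <- truth_ogs(sim, root_label, min_species = 2) |>
    group_by(.data$og_id) |>
    filter(n() >= 2) |>
    ungroup() |>
    select(refog_id = "og_id", "gene_id") |>
    arrange(.data$refog_id, .data$gene_id)
  paths$refogs <- file.path(dir, "refogs.tsv")
  readr::write_tsv(ref, paths$refogs)
  paths$tree <- file.path(dir, "species_tree.nwk")
  write_newick(sim$tree, paths$tree)
  cfg <- sim$config
  paths$config <- file.path(dir, "sim_config.json")
  jsonlite::write_json(
    list(seed = cfg$seed, n_families = cfg$n_families,
         dup_rate = cfg$dup_rate, loss_rate = cfg$loss_rate,
         sub_scale = cfg$sub_scale,
         root_length_mean = cfg$root_length_mean,
         root_length_sd = cfg$root_length_sd,
         min_length = cfg$min_length,
         tree = write_newick(cfg$tree)),
    paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
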