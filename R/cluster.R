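empty_ogs <- function() {
  tibble(og_id = character(), level = character(),
         gene_id = character(), species_id = character())
}

empty_unassigned <- function() {
  tibble(level = character(), gene_id = character(),
         species_id = character(), reason = character())
}

# order components by (descending size, then smallest member gene id) and
# assign "og{n}at{level}" ids
label_components <- function(comps, level) {
  if (!length(comps)) return(empty_ogs())
  comps <- lapply(comps, sort)
  sizes <- lengths(comps)
  mins <- vapply(comps, `[`, "", 1)
  ord <- order(-sizes, mins)
  comps <- comps[ord]
  tibble(
    og_id = rep(sprintf("og%dat%s", seq_along(comps), level), lengths(comps)),
    level = level,
    gene_id = unlist(comps, use.names = FALSE)
  )
}

components_of <- function(vertices, edges_a, edges_b) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges_a, to = edges_b),
    directed = FALSE, vertices = data.frame(name = vertices)
  )
  cm <- igraph::components(g)$membership
  split(names(cm), cm)
}

#' Delineate orthologous groups at one level
#'
#' OGs at a level are the connected components of the graph whose vertices
#' are the genes of the level's species and whose edges are the BRH pairs
#' between species pairs within the level, plus in-paralog attachments.
#' Components touching a single species are discarded: an OG represents a
#' gene of the last common ancestor of at least two of the level's species.
#'
#' @param genes Gene table.
#' @param hits Hit table (with within-species hits if
#'   `attach_inparalogs = TRUE`).
#' @param tree Species tree from [parse_newick()].
#' @param level Level (internal node) label with >= 2 species.
#' @param attach_inparalogs Attach unplaced within-species duplicates to BRH
#'   anchors (default `TRUE`).
#' @param brh Precomputed [all_brh_pairs()] table (optional, recomputed from
#'   `hits` when `NULL`).
#' @return List with `ogs` (tibble `og_id`, `level`, `gene_id`,
#'   `species_id`) and `unassigned` (tibble `level`, `gene_id`,
#'   `species_id`, `reason`).
#' @export
cluster_level <- function(genes, hits, tree, level, attach_inparalogs = TRUE,
                          brh = NULL) {
  genes <- as_gene_table(genes, check_alphabet = FALSE)
  level_sp <- species_under(tree, level)
  if (length(level_sp) < 2) abort(paste0("level '", level, "' has < 2 species"))
  if (is.null(brh)) brh <- all_brh_pairs(hits, species = level_sp)
  brh_l <- brh |>
    filter(.data$species_a %in% level_sp, .data$species_b %in% level_sp)
  att <- if (attach_inparalogs) {
    hits_l <- hits |>
      filter(.data$query_species %in% level_sp,
             .data$target_species %in% level_sp)
    orthogs::attach_inparalogs(hits_l, brh_l)
  } else {
    tibble(gene_id = character(), anchor_id = character(), score = numeric())
  }
  lg <- genes |> filter(.data$species_id %in% level_sp)
  comps <- components_of(lg$gene_id,
                         c(brh_l$gene_a, att$gene_id),
                         c(brh_l$gene_b, att$anchor_id))
  sp <- setNames(lg$species_id, lg$gene_id)
  multi <- vapply(comps, function(m) length(unique(sp[m])) >= 2, logical(1))
  ogs <- label_components(comps[multi], level) |>
    mutate(species_id = unname(sp[.data$gene_id]))
  left_out <- unlist(comps[!multi], use.names = FALSE)
  in_edge <- unique(c(brh_l$gene_a, brh_l$gene_b, att$gene_id, att$anchor_id))
  left_out <- sort(left_out)
  unassigned <- tibble(
    level = rep(level, length(left_out)),
    gene_id = left_out,
    species_id = unname(sp[left_out]),
    reason = as.character(ifelse(left_out %in% in_edge,
                                 "single_species_component",
                                 "no_brh_support"))
  )
  list(ogs = ogs, unassigned = unassigned)
}

tree_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

# hierarchical tree-mode clustering; returns list(ogs, unassigned, parents)
cluster_tree_rec <- function(node, genes, brh, hits, tree, attach, min_cross,
                             acc) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) {
    sp_name <- tree$tip.label[node]
    g <- genes$gene_id[genes$species_id == sp_name]
    return(tibble(gene_id = g, unit = g, og = NA_character_))
  }
  kids <- tree_children(tree, node)
  child_units <- purrr::map(seq_along(kids), function(i) {
    cluster_tree_rec(kids[i], genes, brh, hits, tree, attach, min_cross,
                     acc) |>
      mutate(child = i)
  }) |> bind_rows()
  level <- tree$node.label[node - n_tip]
  level_sp <- species_under(tree, level)
  sp <- setNames(genes$species_id, genes$gene_id)
  unit_of <- setNames(child_units$unit, child_units$gene_id)
  child_of <- setNames(child_units$child, child_units$unit)

  brh_l <- brh |>
    filter(.data$species_a %in% level_sp, .data$species_b %in% level_sp)
  # unit-level edges from BRHs crossing different child subtrees
  ue <- tibble(ua = unname(unit_of[brh_l$gene_a]),
               ub = unname(unit_of[brh_l$gene_b])) |>
    filter(child_of[.data$ua] != child_of[.data$ub]) |>
    mutate(lo = pmin(.data$ua, .data$ub), hi = pmax(.data$ua, .data$ub)) |>
    count(.data$lo, .data$hi, name = "m") |>
    filter(.data$m >= min_cross)
  if (attach) {
    hits_l <- hits |>
      filter(.data$query_species %in% level_sp,
             .data$target_species %in% level_sp)
    att <- orthogs::attach_inparalogs(hits_l, brh_l)
    if (nrow(att)) {
      ue <- bind_rows(ue, tibble(lo = unname(unit_of[att$gene_id]),
                                 hi = unname(unit_of[att$anchor_id]), m = 1L))
    }
  }
  ucomp <- components_of(unique(child_units$unit), ue$lo, ue$hi)
  # expand unit components to gene components; OGs must span >= 2 species
  gene_comps <- lapply(ucomp, function(us) {
    child_units$gene_id[child_units$unit %in% us]
  })
  multi <- vapply(gene_comps, function(m) length(unique(sp[m])) >= 2,
                  logical(1))
  ogs <- label_components(gene_comps[multi], level) |>
    mutate(species_id = unname(sp[.data$gene_id]))
  acc$ogs[[level]] <- ogs
  left_out <- sort(unlist(gene_comps[!multi], use.names = FALSE))
  in_edge <- unique(c(brh_l$gene_a, brh_l$gene_b))
  acc$unassigned[[level]] <- tibble(
    level = rep(level, length(left_out)),
    gene_id = left_out, species_id = unname(sp[left_out]),
    reason = as.character(ifelse(left_out %in% in_edge,
                                 "single_species_component",
                                 "no_brh_support"))
  )
  # parent links: child OG -> containing OG at this level
  og_of <- setNames(ogs$og_id, ogs$gene_id)
  child_ogs <- child_units |>
    filter(!is.na(.data$og)) |>
    distinct(.data$og, .data$gene_id) |>
    group_by(.data$og) |>
    slice(1) |>
    ungroup()
  if (nrow(child_ogs)) {
    acc$parents[[level]] <- tibble(
      og_id = child_ogs$og,
      parent_og_id = unname(og_of[child_ogs$gene_id])
    ) |> filter(!is.na(.data$parent_og_id))
  }
  # units carried upward: OGs at this level, plus unmerged singleton genes
  new_unit <- ifelse(is.na(og_of[child_units$gene_id]),
                     child_units$gene_id,
                     unname(og_of[child_units$gene_id]))
  tibble(gene_id = child_units$gene_id, unit = unname(new_unit),
         og = unname(og_of[child_units$gene_id]))
}

#' Delineate OGs at every level of the species tree
#'
#' Two modes. `"levels"` runs [cluster_level()] independently at each
#' requested level (ab-initio per-level delineation). `"tree"` traverses the
#' species tree in postorder, merging child-level OGs that are connected by
#' at least `min_cross_edges` BRH edges crossing between different child
#' subtrees; the resulting per-level OG sets are nested by construction
#' (every OG is contained in exactly one OG at each ancestral level), so
#' orthologs are more finely resolved for more closely related species and
#' earlier duplicates split into distinct groups at shallower levels.
#'
#' @inheritParams cluster_level
#' @param levels Level labels to delineate (default: every internal level
#'   with >= 2 species).
#' @param mode `"levels"` or `"tree"`.
#' @param min_cross_edges Tree mode: minimum number of crossing BRH edges
#'   required to merge two child units (default 1).
#' @return An `og_delineation` object: list with `ogs`, `unassigned`,
#'   `parents` (tree mode; tibble `og_id`, `parent_og_id`), `mode`,
#'   `levels`. Supports [tidy()], [glance()] and `print()`.
#' @export
delineate_ogs <- function(genes, hits, tree, levels = NULL,
                          mode = c("levels", "tree"),
                          attach_inparalogs = TRUE, min_cross_edges = 1) {
  mode <- match.arg(mode)
  genes <- as_gene_table(genes, check_alphabet = FALSE)
  all_levels <- tree_levels(tree)$level
  if (is.null(levels)) levels <- all_levels
  unknown <- setdiff(levels, all_levels)
  if (length(unknown)) {
    abort(paste0("unknown or single-species level(s): ",
                 paste(unknown, collapse = ", ")))
  }
  brh <- all_brh_pairs(hits)
  if (mode == "levels") {
    res <- purrr::map(levels, function(l) {
      cluster_level(genes, hits, tree, l,
                    attach_inparalogs = attach_inparalogs, brh = brh)
    })
    ogs <- bind_rows(purrr::map(res, "ogs"))
    unassigned <- bind_rows(purrr::map(res, "unassigned"))
    parents <- NULL
  } else {
    acc <- new.env()
    acc$ogs <- list()
    acc$unassigned <- list()
    acc$parents <- list()
    n_tip <- length(tree$tip.label)
    cluster_tree_rec(n_tip + 1L, genes, brh, hits, tree,
                     attach = attach_inparalogs, min_cross = min_cross_edges,
                     acc = acc)
    ogs <- bind_rows(acc$ogs) |> filter(.data$level %in% levels)
    unassigned <- bind_rows(acc$unassigned) |>
      filter(.data$level %in% levels)
    parents <- bind_rows(acc$parents)
  }
  if (!nrow(ogs)) ogs <- empty_ogs()
  if (!nrow(unassigned)) unassigned <- empty_unassigned()
  structure(
    list(ogs = arrange(ogs, .data$level, .data$og_id, .data$gene_id),
         unassigned = arrange(unassigned, .data$level, .data$gene_id),
         parents = parents, mode = mode, levels = levels),
    class = "og_delineation"
  )
}

#' @export
print.og_delineation <- function(x, ...) {
  cat("OG delineation (mode: ", x$mode, ")\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @export
tidy.og_delineation <- function(x, ...) x$ogs

#' @export
glance.og_delineation <- function(x, ...) {
  per_level <- x$ogs |>
    group_by(.data$level) |>
    summarise(n_ogs = dplyr::n_distinct(.data$og_id),
              n_genes = n(), .groups = "drop")
  una <- x$unassigned |> count(.data$level, name = "n_unassigned")
  out <- tibble(level = x$levels) |>
    left_join(per_level, by = "level") |>
    left_join(una, by = "level") |>
    mutate(across(c("n_ogs", "n_genes", "n_unassigned"),
                  ~ tidyr::replace_na(.x, 0L)))
  out
}

#' Write / read OG membership tables
#'
#' The on-disk schema is one TSV row per (og, gene):
#' `og_id`, `level`, `gene_id`, `species_id`, sorted by `og_id` then
#' `gene_id` — one file per delineation, mirroring per-level bulk-download
#' flat files. Unassigned genes go to a sidecar TSV with a `reason` column.
#'
#' @param x `og_delineation` or an OG membership tibble.
#' @param path Output TSV.
#' @param unassigned_path Optional sidecar TSV for unassigned genes.
#' @return `path`, invisibly.
#' @export
write_og_table <- function(x, path, unassigned_path = NULL) {
  ogs <- if (inherits(x, "og_delineation")) x$ogs else x
  ogs |>
    arrange(.data$og_id, .data$gene_id) |>
    select("og_id", "level", "gene_id", "species_id") |>
    readr::write_tsv(path)
  if (!is.null(unassigned_path)) {
    una <- if (inherits(x, "og_delineation")) x$unassigned else empty_unassigned()
    readr::write_tsv(arrange(una, .data$level, .data$gene_id),
                     unassigned_path)
  }
  invisible(path)
}

#' @rdname write_og_table
#' @export
read_og_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c")) |>
    select("og_id", "level", "gene_id", "species_id")
}
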