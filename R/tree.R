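#' Parse a rooted species tree from Newick text
#'
#' Reads a single rooted tree whose tip labels are species identifiers and
#' whose internal node labels name levels of orthology (taxonomy nodes).
#' Internal nodes lacking a label are given deterministic synthetic labels
#' `"nd1"`, `"nd2"`, ... in preorder, so that every level is addressable by
#' name (OG identifiers embed the level label).
#'
#' @param text Newick string, terminated by `';'`. Branch lengths are
#'   optional; multifurcations are accepted as-is.
#' @return A rooted `ape::phylo` with unique tip labels and a complete,
#'   unique `node.label` vector.
#' @examples
#' tr <- parse_newick("((A,B)L1,C)root;")
#' species_under(tr, "L1")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse failed: ", conditionMessage(e)))
  )
  if (is.null(tr)) abort("Newick parse failed: no tree found in text")
  if (inherits(tr, "multiPhylo")) abort("expected a single tree, found several")
  finalize_species_tree(tr)
}

# Light syntactic scan so malformed input fails with a character offset,
# before handing off to ape's parser.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("Newick parse failed: unbalanced ')' at character %d", i))
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf(
      "Newick parse failed: %d unclosed '(' at character %d",
      depth, length(chars)
    ))
  }
  if (!grepl(";", text, fixed = TRUE)) {
    abort(sprintf(
      "Newick parse failed: missing ';' terminator at character %d",
      length(chars)
    ))
  }
  invisible(TRUE)
}

# Validate invariants and fill synthetic preorder labels for unlabeled
# internal nodes.
finalize_species_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
    abort(paste0("duplicate leaf labels: ", paste(dup, collapse = ", ")))
  }
  n_tip <- length(tr$tip.label)
  n_node <- tr$Nnode
  labs <- tr$node.label
  if (is.null(labs)) labs <- rep("", n_node)
  labs[is.na(labs)] <- ""
  # preorder over internal nodes: root first, then order of first appearance
  # as a child in the cladewise edge list
  trc <- ape::reorder.phylo(tr, "cladewise")
  kids <- trc$edge[, 2]
  internal_pre <- c(n_tip + 1L, kids[kids > n_tip])
  taken <- c(tr$tip.label, labs[labs != ""])
  counter <- 0L
  for (nd in internal_pre) {
    idx <- nd - n_tip
    if (labs[idx] == "") {
      repeat {
        counter <- counter + 1L
        cand <- paste0("nd", counter)
        if (!cand %in% taken) break
      }
      labs[idx] <- cand
      taken <- c(taken, cand)
    }
  }
  if (anyDuplicated(labs)) {
    dup <- unique(labs[duplicated(labs)])
    abort(paste0("duplicate internal node labels: ", paste(dup, collapse = ", ")))
  }
  clash <- intersect(labs, tr$tip.label)
  if (length(clash)) {
    abort(paste0("labels used for both a leaf and an internal node: ",
                 paste(clash, collapse = ", ")))
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    abort("negative branch lengths are not allowed")
  }
  tr$node.label <- labs
  tr
}

#' Write a species tree to Newick
#'
#' Inverse of [parse_newick()]: topology, labels and branch lengths
#' round-trip.
#'
#' @param tree `ape::phylo`.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

node_id_of <- function(tree, label) {
  n_tip <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, tree$node.label)
  if (!is.na(j)) return(n_tip + j)
  abort(paste0("unknown tree label: '", label, "'"))
}

#' Species under a level of the species tree
#'
#' Returns the set of species (tip labels) in the subtree rooted at the node
#' named `level_label`. A leaf label yields the singleton set. The species
#' under a level define which genes are eligible for OGs built at that level:
#' an OG groups the descendants of a single gene of the last common ancestor
#' of exactly these species.
#'
#' @param tree `ape::phylo` from [parse_newick()].
#' @param level_label Tip or internal node label.
#' @return Character vector of species ids, sorted.
#' @export
species_under <- function(tree, level_label) {
  nd <- node_id_of(tree, level_label)
  n_tip <- length(tree$tip.label)
  if (nd <= n_tip) return(tree$tip.label[nd])
  sort(ape::extract.clade(tree, nd)$tip.label)
}

#' All named levels of a species tree
#'
#' @param tree `ape::phylo`.
#' @param min_species Keep only levels with at least this many species
#'   (OGs require >= 2); use 1 to list leaves too.
#' @return Tibble with columns `level` and `n_species`, in preorder
#'   (root first).
#' @export
tree_levels <- function(tree, min_species = 2) {
  n_tip <- length(tree$tip.label)
  trc <- ape::reorder.phylo(tree, "cladewise")
  kids <- trc$edge[, 2]
  pre <- c(n_tip + 1L, kids)
  labs <- c(tree$tip.label, tree$node.label)[pre]
  counts <- vapply(labs, function(l) length(species_under(tree, l)), integer(1))
  tibble(level = unname(labs), n_species = unname(counts)) |>
    filter(.data$n_species >= min_species)
}

#' Cross-check proteomes against the species tree
#'
#' Report-only validation: species present in the gene table but absent from
#' the tree (and vice versa), and gene ids duplicated across species. Callers
#' decide whether to abort on `severity == "error"` rows.
#'
#' @param genes Gene table (`gene_id`, `species_id`, `sequence`); see
#'   [read_proteomes()].
#' @param tree `ape::phylo`.
#' @return Tibble with columns `severity` (`"error"`/`"warning"`), `item`,
#'   `message`; zero rows when the dataset is consistent.
#' @export
validate_dataset <- function(genes, tree) {
  genes <- as_gene_table(genes)
  rep_rows <- list()
  sp_have <- unique(genes$species_id)
  sp_tree <- tree$tip.label
  for (sp in setdiff(sp_tree, sp_have)) {
    rep_rows[[length(rep_rows) + 1L]] <- tibble(
      severity = "warning", item = sp,
      message = paste0("missing proteome: ", sp)
    )
  }
  for (sp in setdiff(sp_have, sp_tree)) {
    rep_rows[[length(rep_rows) + 1L]] <- tibble(
      severity = "warning", item = sp,
      message = paste0("species not in tree: ", sp)
    )
  }
  dup <- genes |>
    count(.data$gene_id) |>
    filter(.data$n > 1)
  for (g in dup$gene_id) {
    rep_rows[[length(rep_rows) + 1L]] <- tibble(
      severity = "error", item = g,
      message = paste0("duplicate gene_id across proteomes: ", g)
    )
  }
  if (!length(rep_rows)) {
    return(tibble(severity = character(), item = character(),
                  message = character()))
  }
  bind_rows(rep_rows)
}
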