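hit_rows <- function(...) {
  # each argument: c(query, qsp, target, tsp, score)
  rows <- list(...)
  tibble::tibble(
    query_id = vapply(rows, `[[`, "", 1),
    query_species = vapply(rows, `[[`, "", 2),
    target_id = vapply(rows, `[[`, "", 3),
    target_species = vapply(rows, `[[`, "", 4),
    score = as.numeric(vapply(rows, `[[`, "", 5))
  )
}

test_that("best_hits takes the max-score target with lexicographic ties", {
  hits <- hit_rows(
    c("a1", "A", "b1", "B", "100"),
    c("a1", "A", "b2", "B", "50")
  )
  bh <- best_hits(hits, "A", "B")
  expect_equal(bh$best_target, "b1")

  tie <- hit_rows(
    c("a1", "A", "b2", "B", "70"),
    c("a1", "A", "b1", "B", "70")
  )
  expect_equal(best_hits(tie, "A", "B")$best_target, "b1")
})

test_that("brh_pairs requires reciprocity", {
  hits <- hit_rows(
    c("a1", "A", "b1", "B", "100"),
    c("b1", "B", "a1", "A", "100"),
    c("a1", "A", "b2", "B", "50")
  )
  br <- brh_pairs(hits, "A", "B")
  expect_equal(nrow(br), 1)
  expect_equal(br$gene_a, "a1")
  expect_equal(br$gene_b, "b1")

  # a1's best is b1 but b1's best is a2 -> excluded
  broken <- hit_rows(
    c("a1", "A", "b1", "B", "100"),
    c("b1", "B", "a2", "A", "200"),
    c("b1", "B", "a1", "A", "100"),
    c("a2", "A", "b1", "B", "200")
  )
  br2 <- brh_pairs(broken, "A", "B")
  expect_false(any(br2$gene_a == "a1"))
  expect_true(any(br2$gene_a == "a2" & br2$gene_b == "b1"))
})

test_that("best_hits and brh_pairs match the exhaustive argmax oracle", {
  set.seed(301)
  for (rep in 1:20) {
    rt <- random_hit_table(sample(5:20, 1), sample(5:20, 1))
    impl <- brh_pairs(rt$hits, "A", "B")
    impl_pairs <- unname(Map(c, impl$gene_a, impl$gene_b))
    oracle <- oracle_brh(rt$scores)
    expect_setequal(
      vapply(impl_pairs, paste, "", collapse = "|"),
      vapply(oracle, paste, "", collapse = "|")
    )
    # best_hits agrees with per-row argmax (lexicographic ties)
    bh <- best_hits(rt$hits, "A", "B")
    for (x in rownames(rt$scores)) {
      row <- rt$scores[x, ]
      if (all(is.na(row))) {
        expect_false(x %in% bh$gene_id)
      } else {
        mx <- max(row, na.rm = TRUE)
        expect_equal(bh$best_target[bh$gene_id == x],
                     sort(names(row)[which(!is.na(row) & row == mx)])[1])
      }
    }
  }
})

test_that("in-paralogs attach iff closer to the anchor than its best BRH", {
  brh <- tibble::tibble(
    gene_a = "a1", species_a = "A", gene_b = "b1", species_b = "B",
    score_ab = 150, score_ba = 150
  )
  base <- hit_rows(
    c("a1", "A", "b1", "B", "150"),
    c("b1", "B", "a1", "A", "150")
  )
  close_dup <- dplyr::bind_rows(base, hit_rows(
    c("a2", "A", "a1", "A", "200"),
    c("a1", "A", "a2", "A", "200")
  ))
  att <- attach_inparalogs(close_dup, brh)
  expect_equal(att$gene_id, "a2")
  expect_equal(att$anchor_id, "a1")

  far_dup <- dplyr::bind_rows(base, hit_rows(
    c("a2", "A", "a1", "A", "100"),
    c("a1", "A", "a2", "A", "100")
  ))
  expect_equal(nrow(attach_inparalogs(far_dup, brh)), 0)
})

test_that("cluster_level forms one OG from a fully connected family", {
  tr <- parse_newick("((A,B)ab,C)root;")
  genes <- tibble::tibble(
    gene_id = c("a1", "b1", "c1"), species_id = c("A", "B", "C"),
    sequence = rep("M", 3)
  )
  hits <- hit_rows(
    c("a1", "A", "b1", "B", "100"), c("b1", "B", "a1", "A", "100"),
    c("a1", "A", "c1", "C", "90"), c("c1", "C", "a1", "A", "90"),
    c("b1", "B", "c1", "C", "80"), c("c1", "C", "b1", "B", "80")
  )
  res <- cluster_level(genes, hits, tr, "root")
  expect_equal(dplyr::n_distinct(res$ogs$og_id), 1)
  expect_setequal(res$ogs$gene_id, c("a1", "b1", "c1"))
  expect_equal(unique(res$ogs$og_id), "og1atroot")
})

test_that("larger families get lower OG numbers; singletons are unassigned", {
  tr <- parse_newick("((A,B)ab,C)root;")
  genes <- tibble::tibble(
    gene_id = c("a1", "b1", "c1", "a2", "b2", "a3"),
    species_id = c("A", "B", "C", "A", "B", "A"),
    sequence = rep("M", 6)
  )
  hits <- hit_rows(
    c("a1", "A", "b1", "B", "100"), c("b1", "B", "a1", "A", "100"),
    c("a1", "A", "c1", "C", "90"), c("c1", "C", "a1", "A", "90"),
    c("a2", "A", "b2", "B", "80"), c("b2", "B", "a2", "A", "80")
  )
  res <- cluster_level(genes, hits, tr, "root")
  tab <- split(res$ogs$gene_id, res$ogs$og_id)
  expect_setequal(tab$og1atroot, c("a1", "b1", "c1"))
  expect_setequal(tab$og2atroot, c("a2", "b2"))
  expect_equal(res$unassigned$gene_id, "a3")
  expect_equal(res$unassigned$reason, "no_brh_support")
})

test_that("cluster_level partitions match a BFS components oracle", {
  set.seed(302)
  tr <- parse_newick("((A,B)ab,C)root;")
  for (rep in 1:20) {
    n_per <- sample(3:8, 1)
    ids <- c(sprintf("a%02d", 1:n_per), sprintf("b%02d", 1:n_per),
             sprintf("c%02d", 1:n_per))
    genes <- tibble::tibble(
      gene_id = ids,
      species_id = rep(c("A", "B", "C"), each = n_per),
      sequence = "M"
    )
    # random cross-species matching edges, one best partner per gene so the
    # edge set is its own BRH set
    edges <- list()
    for (sp_pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      perm <- sample(n_per)
      keep <- runif(n_per) < 0.6
      for (i in which(keep)) {
        g1 <- sprintf("%s%02d", sp_pair[1], i)
        g2 <- sprintf("%s%02d", sp_pair[2], perm[i])
        s <- as.character(sample(50:100, 1))
        edges[[length(edges) + 1L]] <-
          hit_rows(c(g1, toupper(sp_pair[1]), g2, toupper(sp_pair[2]), s),
                   c(g2, toupper(sp_pair[2]), g1, toupper(sp_pair[1]), s))
      }
    }
    hits <- dplyr::bind_rows(edges)
    res <- cluster_level(genes, hits, tr, "root", attach_inparalogs = FALSE)
    brh <- all_brh_pairs(hits)
    oracle <- oracle_components(ids, brh$gene_a, brh$gene_b)
    sp <- setNames(genes$species_id, genes$gene_id)
    oracle_multi <- Filter(function(cp) length(unique(sp[cp])) >= 2, oracle)
    impl <- unname(lapply(split(res$ogs$gene_id, res$ogs$og_id), sort))
    expect_setequal(
      vapply(impl, paste, "", collapse = "|"),
      vapply(oracle_multi, paste, "", collapse = "|")
    )
  }
})

test_that("tree mode nests OGs and keeps unmatched subtrees intact", {
  tr <- parse_newick("((A,B)ab,C)root;")
  genes <- tibble::tibble(
    gene_id = c("a1", "b1", "c1"), species_id = c("A", "B", "C"),
    sequence = rep("M", 3)
  )
  # BRH a1-b1 only; no hits to C
  hits <- hit_rows(
    c("a1", "A", "b1", "B", "100"), c("b1", "B", "a1", "A", "100")
  )
  del <- delineate_ogs(genes, hits, tr, mode = "tree")
  ab <- del$ogs[del$ogs$level == "ab", ]
  root <- del$ogs[del$ogs$level == "root", ]
  expect_setequal(ab$gene_id, c("a1", "b1"))
  expect_setequal(root$gene_id, c("a1", "b1"))
  expect_equal(del$parents$parent_og_id[del$parents$og_id == "og1atab"],
               "og1atroot")
  expect_true("c1" %in% del$unassigned$gene_id[del$unassigned$level == "root"])
})

test_that("two species with one BRH give a single root OG", {
  tr <- parse_newick("(A,B)root;")
  genes <- tibble::tibble(gene_id = c("a1", "b1"),
                          species_id = c("A", "B"), sequence = "M")
  hits <- hit_rows(
    c("a1", "A", "b1", "B", "100"), c("b1", "B", "a1", "A", "100")
  )
  del <- delineate_ogs(genes, hits, tr, mode = "tree")
  expect_equal(unique(del$ogs$og_id), "og1atroot")
  expect_setequal(del$ogs$gene_id, c("a1", "b1"))
})

test_that("OG tables round-trip and unassigned genes get a sidecar", {
  tr <- parse_newick("((A,B)ab,C)root;")
  genes <- tibble::tibble(
    gene_id = c("a1", "b1", "solo"), species_id = c("A", "B", "C"),
    sequence = "M"
  )
  hits <- hit_rows(
    c("a1", "A", "b1", "B", "100"), c("b1", "B", "a1", "A", "100")
  )
  del <- delineate_ogs(genes, hits, tr, levels = "root")
  f <- withr::local_tempfile(fileext = ".tsv")
  fu <- withr::local_tempfile(fileext = ".tsv")
  write_og_table(del, f, fu)
  back <- read_og_table(f)
  expect_equal(back, del$ogs |>
                 dplyr::arrange(og_id, gene_id) |>
                 dplyr::select(og_id, level, gene_id, species_id))
  una <- readr::read_tsv(fu, show_col_types = FALSE)
  expect_equal(una$gene_id, "solo")
  expect_equal(una$reason, "no_brh_support")
})

test_that("no gene belongs to two OGs at the same level", {
  set.seed(303)
  pipe <- local({
    tr <- demo_species_tree()
    cfg <- sim_config(seed = 11, tree = tr, n_families = 15,
                      dup_rate = 0.1, loss_rate = 0.05, sub_scale = 0.05)
    sim <- simulate_families(cfg)
    hits <- all_vs_all(sim$genes)
    list(del = delineate_ogs(sim$genes, hits, tr))
  })
  dup <- pipe$del$ogs |>
    dplyr::count(level, gene_id) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0)
})
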