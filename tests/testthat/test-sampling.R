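test_that("sketches are deterministic and reverse-complement invariant", {
  set.seed(601)
  g <- random_dna(3000)
  s1 <- sketch_genome(g, "g1", k = 21, s = 200, seed = 42)
  s2 <- sketch_genome(g, "g1b", k = 21, s = 200, seed = 42)
  expect_equal(s1$hashes, s2$hashes)
  expect_true(all(diff(s1$hashes) > 0)) # strictly increasing
  src <- sketch_genome(revcomp(g), "g1rc", k = 21, s = 200, seed = 42)
  expect_equal(s1$hashes, src$hashes)
  # different hash seed, different sketch
  s3 <- sketch_genome(g, "g1c", k = 21, s = 200, seed = 43)
  expect_false(identical(s1$hashes, s3$hashes))
})

test_that("sketch equals the hash-all-kmers-and-sort oracle", {
  set.seed(602)
  g <- random_dna(5000)
  for (s_size in c(50, 500)) {
    impl <- sketch_genome(g, "g", k = 21, s = s_size, seed = 42)
    expect_equal(impl$hashes, oracle_minhash(g, 21, s_size, 42))
  }
  # k-mers containing N are skipped
  gn <- paste0(substr(g, 1, 1000), "N", substr(g, 1002, 5000))
  withN <- sketch_genome(gn, "gn", k = 21, s = 100, seed = 42)
  expect_equal(withN$hashes, oracle_minhash(gn, 21, 100, 42))
})

test_that("mash distance follows the Poisson identity formula", {
  mk <- function(id, hashes) {
    structure(list(genome_id = id, k = 21L, s = length(hashes),
                   seed = 42, hashes = sort(hashes)),
              class = "minhash_sketch")
  }
  # identical sketches: j = 1, d = 0, identity 100
  a <- mk("a", 1:1000)
  same <- mash_distance(a, mk("b", 1:1000))
  expect_equal(same$jaccard, 1)
  expect_equal(same$distance, 0)
  expect_equal(same$identity_pct, 100)
  # disjoint sketches: j = 0, distance capped at 1, identity 0
  far <- mash_distance(a, mk("c", 2001:3000))
  expect_equal(far$jaccard, 0)
  expect_equal(far$identity_pct, 0)
  # j = 0.9 at k = 21: d = -(1/21) ln(1.8/1.9)
  b <- mk("d", c(1:900, 2001:2100))
  m <- mash_distance(a, b)
  expect_equal(m$jaccard, 0.9)
  expect_equal(m$distance, -(1 / 21) * log(1.8 / 1.9), tolerance = 1e-9)
  expect_equal(m$distance, 0.002573, tolerance = 1e-3)
  # symmetric; mismatched k errors
  expect_equal(mash_distance(b, a)$distance, m$distance)
  bad <- mk("e", 1:100); bad$k <- 15L
  expect_error(mash_distance(a, bad), "different k")
})

test_that("identity increases with the Jaccard estimate", {
  mk <- function(id, hashes) {
    structure(list(genome_id = id, k = 21L, s = length(hashes),
                   seed = 42, hashes = sort(hashes)),
              class = "minhash_sketch")
  }
  a <- mk("a", 1:1000)
  idents <- vapply(seq(100, 1000, 100), function(n_shared) {
    b <- mk("b", c(1:n_shared, 10000 + seq_len(1000 - n_shared)))
    mash_distance(a, b)$identity_pct
  }, numeric(1))
  expect_true(all(diff(idents) > 0))
})

test_that("single-linkage clustering chains near-identical genomes", {
  set.seed(603)
  base <- random_dna(4000)
  mut <- function(g, p) {
    chars <- strsplit(g, "")[[1]]
    hit <- which(runif(length(chars)) < p)
    for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[i]), 1)
    paste(chars, collapse = "")
  }
  gA <- base
  gB <- mut(base, 0.01)   # ~99% identical to A
  gC <- mut(gB, 0.01)     # chained to B, further from A
  gD <- random_dna(4000)  # unrelated
  sk <- list(
    sketch_genome(gA, "gA"), sketch_genome(gB, "gB"),
    sketch_genome(gC, "gC"), sketch_genome(gD, "gD")
  )
  cl <- cluster_genomes(sk, identity_threshold_pct = 96)
  byc <- split(cl$genome_id, cl$cluster_id)
  expect_setequal(byc$gA, c("gA", "gB", "gC"))
  expect_setequal(byc$gD, "gD")
  # all below threshold -> every genome its own cluster
  cl2 <- cluster_genomes(sk, identity_threshold_pct = 99.9)
  expect_equal(dplyr::n_distinct(cl2$cluster_id), 4)
  # lowering the threshold never increases the number of clusters
  ncl <- vapply(c(99.9, 99, 98, 96, 90, 50, 0), function(t) {
    dplyr::n_distinct(cluster_genomes(sk, t)$cluster_id)
  }, numeric(1))
  expect_true(all(diff(ncl) <= 0))
})

test_that("genome clusters match a BFS components oracle", {
  set.seed(604)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    ids <- sprintf("g%02d", seq_len(n))
    # random symmetric identity matrix
    idm <- matrix(runif(n * n, 80, 100), n, n, dimnames = list(ids, ids))
    idm[lower.tri(idm)] <- t(idm)[lower.tri(idm)]
    # synthetic sketches are irrelevant here; test the edge rule directly
    edges <- which(idm > 96 & upper.tri(idm), arr.ind = TRUE)
    oracle <- oracle_components(ids, ids[edges[, 1]], ids[edges[, 2]])
    impl <- orthogs:::components_of(ids, ids[edges[, 1]], ids[edges[, 2]])
    expect_setequal(
      vapply(lapply(impl, sort), paste, "", collapse = "|"),
      vapply(oracle, paste, "", collapse = "|")
    )
  }
})

test_that("representatives maximize completeness, then annotation, then id", {
  records <- tibble::tibble(
    genome_id = c("gA", "gB", "gC"),
    annotation_score = c(100L, 500L, 500L),
    completeness_pct = c(99, 95, 95)
  )
  expect_equal(select_representative(c("gA", "gB"), records), "gA")
  tie <- records
  tie$completeness_pct <- c(95, 95, 95)
  expect_equal(select_representative(c("gA", "gB"), tie), "gB")
  expect_equal(select_representative(c("gB", "gC"), tie), "gB")
  expect_error(select_representative(c("gA", "gZ"), records), "gZ")
  # annotation-first priority is available
  alt <- records
  alt$annotation_score <- c(100L, 500L, 500L)
  expect_equal(
    select_representative(c("gA", "gB"), alt,
                          priority = c("annotation", "completeness")),
    "gB")
})

test_that("sketches round-trip through JSON", {
  set.seed(605)
  sk <- sketch_genome(random_dna(2000), "gX", k = 15, s = 64, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_sketch(sk, f)
  back <- read_sketch(f)
  expect_equal(back, sk)
})
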