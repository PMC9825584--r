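test_that("prf matches the worked examples exactly", {
  expect_equal(unname(prf(letters[1:5], letters[1:5])), c(1, 1, 1))
  refog <- sprintf("g%d", 1:10)
  m1 <- prf(refog, c(sprintf("g%d", 1:8), "x1", "x2"))
  expect_equal(unname(m1), c(0.8, 0.8, 0.8), tolerance = 1e-9)
  m2 <- prf(refog, c(refog, sprintf("x%d", 1:10)))
  expect_equal(unname(m2), c(0.5, 1.0, 2 / 3), tolerance = 1e-9)
  expect_equal(unname(prf(refog, character())), c(0, 0, 0))
})

test_that("best_combination solves the three-OG worked example", {
  refog <- sprintf("g%d", 1:10)
  ogs <- list(P1 = sprintf("g%d", 1:6), P2 = c("g7", "g8"),
              P3 = c("g9", "x1", "x2"))
  combo <- best_combination(refog, ogs)
  oracle <- oracle_best_combo(refog, ogs)
  expect_equal(combo$og_ids, oracle$og_ids)
  expect_equal(combo$f1, oracle$f1, tolerance = 1e-12)
  # a perfect single OG wins with F1 = 1
  exact <- best_combination(refog, list(P1 = refog, P2 = c("x1", "g1")))
  expect_equal(exact$og_ids, "P1")
  expect_equal(exact$f1, 1)
})

test_that("exhaustive search matches the subset-enumeration oracle", {
  set.seed(701)
  for (rep in 1:25) {
    universe <- sprintf("g%03d", 1:40)
    refog <- sample(universe, sample(5:15, 1))
    # random disjoint partition of the universe into OGs
    shuffled <- sample(universe)
    sizes <- diff(sort(c(0, sample(1:39, sample(3:7, 1)), 40)))
    ogs <- split(shuffled, rep(seq_along(sizes), sizes))
    names(ogs) <- sprintf("og%02d", seq_along(ogs))
    combo <- best_combination(refog, ogs)
    oracle <- oracle_best_combo(refog, ogs)
    expect_equal(combo$og_ids, oracle$og_ids)
    expect_equal(combo$f1, oracle$f1, tolerance = 1e-12)
  }
})

test_that("greedy search (many candidates) never loses to a single OG", {
  set.seed(702)
  universe <- sprintf("g%03d", 1:200)
  refog <- sample(universe, 60)
  shuffled <- sample(universe)
  ogs <- split(shuffled, rep(1:20, each = 10))
  names(ogs) <- sprintf("og%02d", 1:20)
  combo <- best_combination(refog, ogs, exhaustive_limit = 5)
  singles <- vapply(ogs, function(g) prf(refog, g)[["f1"]], numeric(1))
  expect_gte(combo$f1, max(singles))
})

test_that("exact / akin / other classification follows the stated rules", {
  refog <- sprintf("g%d", 1:10)
  exact <- best_combination(refog, list(P1 = refog))
  expect_equal(classify_refog(refog, exact), "exact")
  # single OG with high F1 but not identical -> akin
  akin <- best_combination(refog, list(P1 = c(refog, "x1")))
  expect_gte(akin$f1, 0.9)
  expect_equal(classify_refog(refog, akin), "akin")
  # below the akin threshold -> other
  weak <- best_combination(refog, list(P1 = sprintf("g%d", 1:6)))
  expect_equal(classify_refog(refog, weak), "other")
  # multi-OG combinations can never be exact or akin
  multi <- best_combination(refog, list(P1 = sprintf("g%d", 1:5),
                                        P2 = sprintf("g%d", 6:10)))
  expect_equal(multi$f1, 1)
  expect_equal(classify_refog(refog, multi), "other")
})

test_that("split events count contributing OGs beyond the first", {
  refog <- sprintf("g%d", 1:12)
  one <- split_stats(refog, list(P1 = refog))
  expect_false(one$is_split)
  expect_equal(one$events, 0)
  three <- split_stats(refog, list(P1 = sprintf("g%d", 1:4),
                                   P2 = sprintf("g%d", 5:8),
                                   P3 = sprintf("g%d", 9:12)))
  expect_true(three$is_split)
  expect_equal(three$events, 2)
  # single-gene overlap does not contribute at min_overlap = 2
  graze <- split_stats(refog, list(P1 = sprintf("g%d", 1:8),
                                   P2 = c("g9", "x1", "x2")))
  expect_false(graze$is_split)
  expect_equal(graze$events, 0)
})

test_that("VI is zero on identity and ln 2 on the worked example", {
  x <- setNames(c("a", "a", "b", "b"), sprintf("g%d", 1:4))
  expect_equal(variation_of_information(x, x), 0)
  y <- setNames(rep("all", 4), sprintf("g%d", 1:4))
  expect_equal(variation_of_information(x, y), log(2), tolerance = 1e-9)
  expect_error(
    variation_of_information(x, setNames("a", "other_gene")),
    "share no genes")
})

test_that("VI is a metric: symmetry and triangle inequality", {
  set.seed(703)
  for (rep in 1:40) {
    genes <- sprintf("g%02d", 1:30)
    rand_part <- function() {
      setNames(sample(letters[1:sample(2:6, 1)], 30, replace = TRUE), genes)
    }
    x <- rand_part(); y <- rand_part(); z <- rand_part()
    vxy <- variation_of_information(x, y)
    expect_equal(vxy, variation_of_information(y, x), tolerance = 1e-12)
    expect_equal(vxy, oracle_vi(x, y), tolerance = 1e-9)
    expect_lte(vxy,
               variation_of_information(x, z) +
                 variation_of_information(z, y) + 1e-9)
    expect_gte(vxy, 0)
  }
})

test_that("cumulative curves count strictly-greater values and decrease", {
  all_one <- cumulative_curve(rep(1, 7), thresholds = 0.99)
  expect_equal(all_one$count, 7)
  two <- cumulative_curve(c(0.5, 0.9), thresholds = 0.7)
  expect_equal(two$count, 1)
  set.seed(704)
  cc <- cumulative_curve(runif(50))
  expect_true(all(diff(cc$count) <= 0))
})

test_that("a prediction equal to the reference yields a perfect report", {
  refogs <- list(r1 = sprintf("a%d", 1:5), r2 = sprintf("b%d", 1:4),
                 r3 = sprintf("c%d", 1:3))
  bm <- benchmark_report(refogs, setNames(refogs, c("og1", "og2", "og3")))
  expect_true(all(bm$per_refog$category == "exact"))
  expect_equal(bm$summary$n_exact, 3)
  expect_equal(bm$summary$n_split_refogs, 0)
  expect_equal(bm$vi, 0)
})

test_that("summary counts are monotone in the metric threshold", {
  set.seed(705)
  refogs <- lapply(1:6, function(i) sprintf("r%d_g%d", i, 1:6))
  names(refogs) <- sprintf("ref%d", 1:6)
  # perturbed predictions: drop one gene here, add noise there
  preds <- list(
    og1 = refogs$ref1, og2 = refogs$ref2[-1],
    og3 = c(refogs$ref3, "x1", "x2"), og4 = refogs$ref4[1:3],
    og5 = c(refogs$ref5[1:4], "x3"), og6 = refogs$ref6
  )
  bm85 <- benchmark_report(refogs, preds, metric_threshold = 0.85)
  bm80 <- benchmark_report(refogs, preds, metric_threshold = 0.80)
  expect_gte(bm80$summary$n_f1_ge, bm85$summary$n_f1_ge)
  expect_gte(bm80$summary$n_precision_ge, bm85$summary$n_precision_ge)
  expect_gte(bm80$summary$n_recall_ge, bm85$summary$n_recall_ge)
})

test_that("benchmark outputs tidy into tables and plots", {
  refogs <- list(r1 = sprintf("a%d", 1:5), r2 = sprintf("b%d", 1:4))
  bm <- benchmark_report(refogs, list(og1 = refogs$r1,
                                      og2 = c(refogs$r2, "x1")))
  expect_equal(nrow(tidy(bm)), 2)
  expect_equal(nrow(glance(bm)), 1)
  p <- autoplot(bm)
  expect_s3_class(p, "ggplot")
  d <- withr::local_tempdir()
  paths <- write_benchmark(bm, file.path(d, "bench"))
  expect_true(all(file.exists(file.path(d, c("bench_per_refog.tsv",
                                             "bench_summary.json",
                                             "bench_curve.tsv")))))
})
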