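#' Precision, recall and F1 of a gene-set reconstruction
#'
#' Compares a combined predicted gene set against a reference OG:
#' `P = |intersection| / |combined|`, `R = |intersection| / |refog|`, F1 the
#' harmonic mean (0 when P + R = 0). An empty combined set scores (0, 0, 0).
#'
#' @param refog Character vector of reference gene ids.
#' @param combined Character vector of predicted gene ids.
#' @return Named numeric: `precision`, `recall`, `f1`.
#' @export
prf <- function(refog, combined) {
  if (!length(combined)) {
    return(c(precision = 0, recall = 0, f1 = 0))
  }
  inter <- length(intersect(refog, combined))
  p <- inter / length(unique(combined))
  r <- inter / length(unique(refog))
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

f1_from_counts <- function(inter, csize, rsize) {
  p <- ifelse(csize > 0, inter / csize, 0)
  r <- inter / rsize
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Best combination of predicted OGs for a reference OG
#'
#' Finds the subset of predicted OGs (all with nonzero overlap to the
#' refOG) whose union maximizes F1 against the refOG — the "best OG
#' combination" view of how well a method reconstructs a curated group.
#' With at most `exhaustive_limit` candidate OGs the search is exhaustive
#' over all nonempty subsets (exact since same-level OGs are disjoint, so
#' subset F1 is additive in per-OG overlap and size); with more, candidates
#' are taken greedily in order of decreasing overlap, stopping at the first
#' one that fails to improve F1. Ties break by fewer OGs, then by
#' lexicographic id list.
#'
#' @param refog Character vector of reference gene ids.
#' @param predicted Named list `og_id -> gene ids` (pairwise disjoint), or
#'   an OG membership tibble with columns `og_id`, `gene_id`.
#' @param exhaustive_limit Maximum candidate count for exhaustive search
#'   (default 15).
#' @return List: `og_ids` (chosen, sorted), `genes` (their union),
#'   `precision`, `recall`, `f1`.
#' @export
best_combination <- function(refog, predicted, exhaustive_limit = 15) {
  predicted <- as_og_list(predicted)
  refog <- unique(refog)
  overlaps <- vapply(predicted, function(g) length(intersect(g, refog)),
                     integer(1))
  cand <- names(predicted)[overlaps > 0]
  if (!length(cand)) {
    return(list(og_ids = character(), genes = character(),
                precision = 0, recall = 0, f1 = 0))
  }
  ov <- overlaps[cand]
  sz <- lengths(predicted[cand])
  rsize <- length(refog)
  n <- length(cand)
  if (n <= exhaustive_limit) {
    masks <- seq_len(2^n - 1)
    bits <- vapply(seq_len(n), function(i) bitwAnd(masks, 2^(i - 1)) > 0,
                   logical(length(masks)))
    if (length(masks) == 1) bits <- matrix(bits, nrow = 1)
    inter <- as.vector(bits %*% ov)
    csize <- as.vector(bits %*% sz)
    f1 <- f1_from_counts(inter, csize, rsize)
    tie <- which(f1 >= max(f1) - 1e-12)
    nog_t <- rowSums(bits[tie, , drop = FALSE])
    idstr_t <- vapply(tie, function(m) {
      paste(sort(cand[bits[m, ]]), collapse = ",")
    }, "")
    best <- tie[order(nog_t, idstr_t)[1]]
    chosen <- sort(cand[bits[best, ]])
  } else {
    ordc <- cand[order(-ov, cand)]
    chosen <- ordc[1]
    cur_inter <- ov[chosen]
    cur_size <- sz[chosen]
    cur_f1 <- f1_from_counts(cur_inter, cur_size, rsize)
    for (cg in ordc[-1]) {
      new_f1 <- f1_from_counts(cur_inter + ov[cg], cur_size + sz[cg], rsize)
      if (new_f1 > cur_f1) {
        chosen <- c(chosen, cg)
        cur_inter <- cur_inter + ov[cg]
        cur_size <- cur_size + sz[cg]
        cur_f1 <- new_f1
      } else {
        break
      }
    }
    chosen <- sort(chosen)
  }
  genes <- sort(unique(unlist(predicted[chosen], use.names = FALSE)))
  m <- prf(refog, genes)
  list(og_ids = chosen, genes = genes,
       precision = unname(m["precision"]), recall = unname(m["recall"]),
       f1 = unname(m["f1"]))
}

as_og_list <- function(predicted) {
  if (is.data.frame(predicted)) {
    predicted <- split(predicted$gene_id, predicted$og_id)
  }
  if (is.null(names(predicted)) || any(!nzchar(names(predicted)))) {
    abort("predicted OGs must be named")
  }
  lapply(predicted, unique)
}

#' Classify a refOG reconstruction as exact, akin or other
#'
#' `exact`: the best combination is a single predicted OG identical to the
#' refOG. `akin`: a single OG with F1 at or above `akin_threshold` but not
#' identical. Anything else (including multi-OG combinations, however good)
#' is `other`.
#'
#' @param refog Reference gene ids.
#' @param combo Result of [best_combination()].
#' @param akin_threshold F1 threshold for `akin` (default 0.9).
#' @return `"exact"`, `"akin"` or `"other"`.
#' @export
classify_refog <- function(refog, combo, akin_threshold = 0.9) {
  if (length(combo$og_ids) == 1 && setequal(combo$genes, refog)) {
    return("exact")
  }
  if (length(combo$og_ids) == 1 && combo$f1 >= akin_threshold) {
    return("akin")
  }
  "other"
}

#' Split statistics for a refOG
#'
#' A refOG is split when it is reconstructed by more than one predicted OG.
#' OGs overlapping the refOG by at least `min_overlap` genes (default 2)
#' count as contributing; each contributing OG beyond the first is one
#' split event.
#'
#' @param refog Reference gene ids.
#' @param predicted Named list or OG membership tibble (see
#'   [best_combination()]).
#' @param min_overlap Minimum overlap for an OG to contribute (default 2).
#' @return List: `is_split` (logical), `events` (count >= 0),
#'   `contributing` (og ids).
#' @export
split_stats <- function(refog, predicted, min_overlap = 2) {
  predicted <- as_og_list(predicted)
  ov <- vapply(predicted, function(g) length(intersect(g, refog)),
               integer(1))
  contributing <- sort(names(predicted)[ov >= min_overlap])
  k <- length(contributing)
  list(is_split = k >= 2, events = max(0L, k - 1L),
       contributing = contributing)
}

#' Variation of Information between two partitions
#'
#' Information-theoretic distance `VI = H(X) + H(Y) - 2 I(X; Y)` in nats,
#' computed from the contingency counts of the two clusterings restricted
#' to their common gene universe (genes covered by both). VI is 0 iff the
#' partitions agree, symmetric, and obeys the triangle inequality; lower
#' values mean more similar classifications.
#'
#' @param part_x,part_y Partitions: named vectors `gene_id -> group`, or
#'   tibbles with columns `gene_id` and a group column (`og_id` or
#'   `refog_id`).
#' @return VI in nats.
#' @export
variation_of_information <- function(part_x, part_y) {
  part_x <- as_partition(part_x)
  part_y <- as_partition(part_y)
  common <- intersect(names(part_x), names(part_y))
  if (!length(common)) abort("partitions share no genes")
  x <- part_x[common]
  y <- part_y[common]
  n <- length(common)
  nij <- table(x, y)
  pij <- nij / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  hx <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hy <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  pos <- pij > 0
  mi <- sum(pij[pos] * log(pij[pos] /
                             (pi_[row(pij)[pos]] * p_j[col(pij)[pos]])))
  max(0, hx + hy - 2 * mi)
}

as_partition <- function(p) {
  if (is.data.frame(p)) {
    gcol <- intersect(c("og_id", "refog_id", "group"), names(p))
    if (!length(gcol)) abort("partition tibble needs og_id/refog_id/group")
    return(setNames(as.character(p[[gcol[1]]]), p$gene_id))
  }
  if (is.null(names(p))) abort("partition vector must be named by gene_id")
  setNames(as.character(p), names(p))
}

#' Cumulative metric curve
#'
#' For each threshold x, the number of refOGs whose metric value is greater
#' than x — the per-family view of benchmark quality (a single averaged
#' figure hides the wide spread of difficulty across gene families). The
#' curve is a non-increasing step function.
#'
#' @param values Metric values in \[0, 1\] (one per refOG).
#' @param thresholds Grid of x values (default `seq(0, 1, 0.01)`).
#' @return Tibble `threshold`, `count`.
#' @export
cumulative_curve <- function(values, thresholds = seq(0, 1, 0.01)) {
  tibble(threshold = thresholds,
         count = vapply(thresholds, function(x) sum(values > x), integer(1)))
}

#' Benchmark a predicted OG set against reference OGs
#'
#' For every refOG: best-combination precision/recall/F1
#' ([best_combination()]), exact/akin/other category ([classify_refog()])
#' and split events ([split_stats()]); plus the aggregate summary row
#' (counts of refOGs at or above the metric threshold, exact/akin counts,
#' split refOGs with total events, number of predicted OGs touching any
#' refOG) and the Variation of Information between the predicted and
#' reference partitions on their common gene universe.
#'
#' @param refogs Named list `refog_id -> gene ids`, or a tibble with
#'   `refog_id`, `gene_id`.
#' @param predicted Named list or OG membership tibble (one level).
#' @param akin_threshold F1 for the `akin` category (default 0.9).
#' @param min_overlap Contribution threshold for splits (default 2).
#' @param metric_threshold Summary threshold for P/R/F1 counts, as a
#'   fraction (default 0.85).
#' @param exhaustive_limit See [best_combination()].
#' @return An `og_benchmark` object; see [tidy.og_benchmark()],
#'   [glance.og_benchmark()], [autoplot.og_benchmark()].
#' @export
benchmark_report <- function(refogs, predicted, akin_threshold = 0.9,
                             min_overlap = 2, metric_threshold = 0.85,
                             exhaustive_limit = 15) {
  if (is.data.frame(refogs)) refogs <- split(refogs$gene_id, refogs$refog_id)
  predicted <- as_og_list(predicted)
  per <- purrr::imap(refogs, function(gset, rid) {
    combo <- best_combination(gset, predicted, exhaustive_limit)
    sp <- split_stats(gset, predicted, min_overlap)
    tibble(
      refog_id = rid,
      n_genes = length(unique(gset)),
      n_chosen_ogs = length(combo$og_ids),
      chosen_ogs = paste(combo$og_ids, collapse = ","),
      precision = combo$precision, recall = combo$recall, f1 = combo$f1,
      category = classify_refog(gset, combo, akin_threshold),
      is_split = sp$is_split, split_events = sp$events
    )
  }) |> bind_rows()
  ref_part <- tibble(
    gene_id = unlist(refogs, use.names = FALSE),
    refog_id = rep(names(refogs), lengths(refogs))
  )
  pred_part <- tibble(
    gene_id = unlist(predicted, use.names = FALSE),
    og_id = rep(names(predicted), lengths(predicted))
  )
  vi <- variation_of_information(ref_part, pred_part)
  ref_genes <- unique(ref_part$gene_id)
  touching <- vapply(predicted, function(g) any(g %in% ref_genes),
                     logical(1))
  summary <- tibble(
    n_refogs = length(refogs),
    n_predicted_ogs = sum(touching),
    n_f1_ge = sum(per$f1 >= metric_threshold),
    n_precision_ge = sum(per$precision >= metric_threshold),
    n_recall_ge = sum(per$recall >= metric_threshold),
    n_exact = sum(per$category == "exact"),
    n_akin = sum(per$category == "akin"),
    n_split_refogs = sum(per$is_split),
    total_split_events = sum(per$split_events),
    vi = vi
  )
  structure(
    list(per_refog = per, summary = summary, vi = vi,
         config = list(akin_threshold = akin_threshold,
                       min_overlap = min_overlap,
                       metric_threshold = metric_threshold)),
    class = "og_benchmark"
  )
}

#' @export
print.og_benchmark <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "OG benchmark: %d refOGs (akin F1 >= %.2f, split overlap >= %d, metric threshold %.0f%%)\n",
    nrow(x$per_refog), cfg$akin_threshold, cfg$min_overlap,
    100 * cfg$metric_threshold))
  print(x$summary)
  invisible(x)
}

#' Per-refOG benchmark rows
#' @param x `og_benchmark`.
#' @param ... Unused.
#' @export
tidy.og_benchmark <- function(x, ...) x$per_refog

#' One-row benchmark summary
#' @param x `og_benchmark`.
#' @param ... Unused.
#' @export
glance.og_benchmark <- function(x, ...) x$summary

#' Cumulative benchmark curves
#'
#' Plots, for each of F1, precision and recall, the number of refOGs whose
#' metric exceeds x as a function of x.
#'
#' @param object `og_benchmark`.
#' @param thresholds Grid of x values.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.og_benchmark <- function(object, thresholds = seq(0, 1, 0.01),
                                  ...) {
  per <- object$per_refog
  curves <- bind_rows(
    cumulative_curve(per$f1, thresholds) |> mutate(metric = "F1"),
    cumulative_curve(per$precision, thresholds) |>
      mutate(metric = "precision"),
    cumulative_curve(per$recall, thresholds) |> mutate(metric = "recall")
  )
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$threshold, y = .data$count,
                               colour = .data$metric)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "metric value x",
                  y = "refOGs with metric > x",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Read a reference OG set
#'
#' @param path TSV with columns `refog_id`, `gene_id`.
#' @return Tibble `refog_id`, `gene_id`.
#' @export
read_refogs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c")) |>
    select("refog_id", "gene_id")
}

#' Write benchmark outputs
#'
#' Writes the per-refOG table (TSV), the summary row (JSON) and the
#' cumulative F1 curve (TSV) under a common path prefix.
#'
#' @param x `og_benchmark`.
#' @param prefix Path prefix; files `<prefix>_per_refog.tsv`,
#'   `<prefix>_summary.json`, `<prefix>_curve.tsv`.
#' @return Character vector of the written paths, invisibly.
#' @export
write_benchmark <- function(x, prefix) {
  p1 <- paste0(prefix, "_per_refog.tsv")
  p2 <- paste0(prefix, "_summary.json")
  p3 <- paste0(prefix, "_curve.tsv")
  readr::write_tsv(x$per_refog, p1)
  jsonlite::write_json(c(as.list(x$summary), x$config), p2,
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(cumulative_curve(x$per_refog$f1), p3)
  invisible(c(p1, p2, p3))
}
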