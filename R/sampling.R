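#' MinHash sketch of a genome
#'
#' Bottom-s MinHash sketch over canonical k-mers (each k-mer is read as the
#' lexicographic minimum of itself and its reverse complement, so a genome
#' and its reverse complement sketch identically). K-mers containing
#' non-ACGT characters are skipped. The hash is a seeded splitmix64
#' finalizer of the 2-bit-packed canonical k-mer, truncated to its top 53
#' bits so values are exactly representable as doubles; the seed is recorded
#' in the sketch.
#'
#' @param sequences Character vector of nucleotide sequences, or a DNA
#'   FASTA path.
#' @param genome_id Identifier stored in the sketch.
#' @param k K-mer length (default 21, <= 32).
#' @param s Sketch size: number of smallest distinct hashes kept
#'   (default 1000).
#' @param seed Hash seed (default 42).
#' @return Object of class `minhash_sketch`: list with `genome_id`, `k`,
#'   `s`, `seed`, `hashes` (sorted strictly increasing numeric).
#' @export
sketch_genome <- function(sequences, genome_id, k = 21, s = 1000, seed = 42) {
  if (length(sequences) == 1 && file.exists(sequences)) {
    sequences <- as.character(Biostrings::readDNAStringSet(sequences))
  }
  if (all(nchar(sequences) < k)) {
    abort(sprintf("all sequences shorter than k = %d", k))
  }
  hashes <- minhash_sketch_cpp(toupper(sequences), as.integer(k),
                               as.integer(s), as.numeric(seed))
  structure(
    list(genome_id = genome_id, k = as.integer(k), s = as.integer(s),
         seed = as.numeric(seed), hashes = hashes),
    class = "minhash_sketch"
  )
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("MinHash sketch of '%s': k=%d, s=%d, %d hashes (seed %s)\n",
              x$genome_id, x$k, x$s, length(x$hashes),
              format(x$seed)))
  invisible(x)
}

#' Mash-style distance between two sketches
#'
#' The Jaccard index j of the two k-mer sets is estimated from the s
#' smallest hashes of the merged sketch union (s capped by the sketches'
#' sizes), then converted to a genomic distance
#' `d = -(1/k) * log(2j / (1 + j))`, the expected per-base mutation rate
#' under a Poisson model of k-mer survival. `identity_pct = 100 * (1 - d)`.
#' When j = 0 the distance is capped at 1 (identity 0). Symmetric in its
#' arguments.
#'
#' @param a,b `minhash_sketch` objects with equal `k`.
#' @return One-row tibble: `genome_a`, `genome_b`, `jaccard`, `distance`,
#'   `identity_pct`.
#' @export
mash_distance <- function(a, b) {
  if (a$k != b$k) abort("sketches have different k")
  s <- min(a$s, b$s)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  sampled <- merged[seq_len(min(s, length(merged)))]
  shared <- sum(sampled %in% a$hashes & sampled %in% b$hashes)
  j <- if (length(sampled)) shared / length(sampled) else 0
  if (j <= 0) {
    d <- 1
  } else {
    d <- min(1, -(1 / a$k) * log(2 * j / (1 + j)))
  }
  tibble(genome_a = a$genome_id, genome_b = b$genome_id,
         jaccard = j, distance = d, identity_pct = 100 * (1 - d))
}

#' All pairwise Mash distances
#'
#' @param sketches List of `minhash_sketch` objects.
#' @return Tibble with one row per unordered genome pair.
#' @export
mash_distances <- function(sketches) {
  n <- length(sketches)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        out[[length(out) + 1L]] <- mash_distance(sketches[[i]], sketches[[j]])
      }
    }
  }
  if (!length(out)) {
    return(tibble(genome_a = character(), genome_b = character(),
                  jaccard = numeric(), distance = numeric(),
                  identity_pct = numeric()))
  }
  bind_rows(out)
}

#' Cluster genomes by pairwise identity
#'
#' Groups genomes whose Mash identity exceeds `identity_threshold_pct`
#' (strict `>`). Default linkage is single (connected components of the
#' identity graph): well-sampled clades form chains of near-identical
#' genomes, which single linkage follows. Complete linkage (every within-
#' cluster pair above threshold) is available as an alternative reading.
#' Cluster ids are named after the lexicographically smallest member.
#'
#' @param sketches List of `minhash_sketch` objects.
#' @param identity_threshold_pct Identity threshold (default 96).
#' @param linkage `"single"` (default) or `"complete"`.
#' @return Tibble `cluster_id`, `genome_id`.
#' @export
cluster_genomes <- function(sketches, identity_threshold_pct = 96,
                            linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  if (!length(sketches)) abort("no sketches")
  ids <- vapply(sketches, `[[`, "", "genome_id")
  dists <- mash_distances(sketches)
  if (linkage == "single") {
    edges <- dists |> filter(.data$identity_pct > identity_threshold_pct)
    comps <- components_of(ids, edges$genome_a, edges$genome_b)
  } else {
    if (length(ids) == 1) {
      comps <- list(ids)
    } else {
      m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
      for (r in seq_len(nrow(dists))) {
        m[dists$genome_a[r], dists$genome_b[r]] <- 100 - dists$identity_pct[r]
        m[dists$genome_b[r], dists$genome_a[r]] <- 100 - dists$identity_pct[r]
      }
      hc <- stats::hclust(stats::as.dist(m), method = "complete")
      cut <- stats::cutree(hc, h = (100 - identity_threshold_pct) - 1e-9)
      comps <- split(ids, cut)
    }
  }
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[`, "", 1))]
  tibble(
    cluster_id = rep(vapply(comps, `[`, "", 1), lengths(comps)),
    genome_id = unlist(comps, use.names = FALSE)
  )
}

#' Select a cluster's representative genome
#'
#' The representative is the "best" genome of a near-identical cluster: by
#' default the most complete (BUSCO-style completeness, consumed as an input
#' number), then the most annotated, then the lexicographically smallest id.
#' The priority of the two quality criteria is configurable.
#'
#' @param members Genome ids of one cluster.
#' @param records Tibble `genome_id`, `annotation_score`,
#'   `completeness_pct`.
#' @param priority Order of quality keys (default completeness first).
#' @return The representative `genome_id`.
#' @export
select_representative <- function(members, records,
                                  priority = c("completeness", "annotation")) {
  priority <- match.arg(priority, several.ok = TRUE)
  missing_rec <- setdiff(members, records$genome_id)
  if (length(missing_rec)) {
    abort(paste0("no genome record for: ", paste(missing_rec, collapse = ", ")))
  }
  rec <- records |> filter(.data$genome_id %in% members)
  keys <- list(completeness = -rank(rec$completeness_pct, ties.method = "min"),
               annotation = -rank(rec$annotation_score, ties.method = "min"))
  ord <- do.call(order, c(unname(keys[priority]), list(rec$genome_id)))
  rec$genome_id[ord[1]]
}

#' Sample representative genomes
#'
#' End-to-end genome selection: cluster sketches at the identity threshold
#' and mark each cluster's representative.
#'
#' @inheritParams cluster_genomes
#' @inheritParams select_representative
#' @return Tibble `cluster_id`, `genome_id`, `is_representative`.
#' @export
sample_genomes <- function(sketches, records, identity_threshold_pct = 96,
                           linkage = "single",
                           priority = c("completeness", "annotation")) {
  cl <- cluster_genomes(sketches, identity_threshold_pct, linkage)
  reps <- cl |>
    group_by(.data$cluster_id) |>
    summarise(rep = select_representative(.data$genome_id, records, priority),
              .groups = "drop")
  cl |>
    left_join(reps, by = "cluster_id") |>
    mutate(is_representative = .data$genome_id == .data$rep) |>
    select("cluster_id", "genome_id", "is_representative")
}

#' Write / read a MinHash sketch as JSON
#'
#' @param sketch `minhash_sketch`.
#' @param path JSON path.
#' @return `path` (write) or a `minhash_sketch` (read).
#' @export
write_sketch <- function(sketch, path) {
  jsonlite::write_json(unclass(sketch), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sketch
#' @export
read_sketch <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(genome_id = x$genome_id, k = as.integer(x$k), s = as.integer(x$s),
         seed = as.numeric(x$seed), hashes = as.numeric(x$hashes)),
    class = "minhash_sketch"
  )
}
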