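#' Alignment and search parameters
#'
#' Bundles the scoring scheme of the built-in local aligner and the k-mer
#' prefilter used by [all_vs_all()] and [map_genes()]. Scores are raw
#' substitution-matrix units (BLOSUM62 by default) with affine gaps: a gap of
#' length L costs `gap_open + L * gap_extend`. `X` residues score 0 against
#' everything (neutral handling of masked positions).
#'
#' @param matrix Substitution matrix name from Biostrings (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend Positive gap penalties (defaults 11 and 1).
#' @param kmer_size Word length of the exact-match prefilter (default 4).
#' @param min_shared_kmers Minimum number of distinct shared k-mers for a
#'   pair to be aligned at all (default 2).
#' @param min_score Minimum local-alignment score to record a hit
#'   (default 30).
#' @return List of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                         kmer_size = 4, min_shared_kmers = 2, min_score = 30) {
  if (gap_open <= 0 || gap_extend <= 0) abort("gap penalties must be > 0")
  if (kmer_size < 2) abort("kmer_size must be >= 2")
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         kmer_size = as.integer(kmer_size),
         min_shared_kmers = as.integer(min_shared_kmers),
         min_score = min_score),
    class = "align_params"
  )
}

# BLOSUM-style matrix with the X row/column zeroed.
scoring_matrix <- function(name = "BLOSUM62") {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0L
    m[, "X"] <- 0L
  }
  m
}

check_sequence <- function(seq, what = "sequence") {
  if (!nzchar(seq)) abort(paste0(what, " is empty"))
  bad <- stringr::str_locate(seq, sprintf("[^%s]",
                                          paste(AA_ALPHABET, collapse = "")))[, 1]
  if (!is.na(bad)) {
    abort(sprintf("illegal residue '%s' at position %d of %s",
                  substr(seq, bad, bad), bad, what))
  }
  invisible(TRUE)
}

#' Local alignment score of two protein sequences
#'
#' Maximum Smith-Waterman local alignment score with affine gaps, floored at
#' zero (the empty alignment). Symmetric and deterministic.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @param params [align_params()].
#' @return Numeric score >= 0.
#' @examples
#' score_pair("ACDE", "ACDE") # 24 = 4 + 9 + 6 + 5 on the BLOSUM62 diagonal
#' @export
score_pair <- function(seq_a, seq_b, params = align_params()) {
  check_sequence(seq_a, "seq_a")
  check_sequence(seq_b, "seq_b")
  m <- scoring_matrix(params$matrix)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = m, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = "local", scoreOnly = TRUE
  )
  max(0, s)
}

# distinct k-mers of each sequence, as a long tibble (id, kmer)
kmer_table <- function(ids, seqs, k) {
  purrr::map2(ids, seqs, function(id, s) {
    n <- nchar(s)
    if (n < k) return(NULL)
    km <- unique(substring(s, 1:(n - k + 1), k:n))
    tibble(id = id, kmer = km)
  }) |> bind_rows()
}

# candidate unordered pairs (i < j as row indices into `ids`) sharing at
# least `min_shared` distinct k-mers
kmer_candidates <- function(ids, seqs, k, min_shared) {
  kt <- kmer_table(seq_along(ids), seqs, k)
  if (!nrow(kt)) return(tibble(i = integer(), j = integer(), shared = integer()))
  pairs <- inner_join(kt, kt, by = "kmer", relationship = "many-to-many") |>
    filter(.data$id.x < .data$id.y) |>
    count(i = .data$id.x, j = .data$id.y, name = "shared") |>
    filter(.data$shared >= min_shared)
  pairs
}

# score many (query, target) index pairs against the gene table, batched by
# target so each Biostrings call is vectorized
score_candidates <- function(genes, pairs, params) {
  if (!nrow(pairs)) return(numeric(0))
  m <- scoring_matrix(params$matrix)
  out <- numeric(nrow(pairs))
  for (j in unique(pairs$j)) {
    rows <- which(pairs$j == j)
    qs <- Biostrings::AAStringSet(genes$sequence[pairs$i[rows]])
    s <- Biostrings::pairwiseAlignment(
      qs, Biostrings::AAString(genes$sequence[j]),
      substitutionMatrix = m, gapOpening = params$gap_open,
      gapExtension = params$gap_extend, type = "local", scoreOnly = TRUE
    )
    out[rows] <- pmax(0, s)
  }
  out
}

#' All-vs-all homology search
#'
#' Scores every cross-species gene pair passing the k-mer prefilter (shared
#' distinct k-mers >= `min_shared_kmers`) with the local aligner and records
#' hits with score >= `min_score` in both directions. With
#' `cross_species_only = FALSE` within-species pairs (distinct genes) are
#' scored as well; these are required by the in-paralog rule of
#' [attach_inparalogs()].
#'
#' @param genes Gene table covering >= 2 species.
#' @param params [align_params()].
#' @param cross_species_only Skip within-species pairs (default `FALSE`, so
#'   downstream in-paralog attachment has the scores it needs).
#' @return Hit table: tibble with `query_id`, `query_species`, `target_id`,
#'   `target_species`, `score`, one row per ordered pair, sorted by
#'   (`query_id`, `target_id`). Output is invariant to input row order.
#' @export
all_vs_all <- function(genes, params = align_params(),
                       cross_species_only = FALSE) {
  genes <- as_gene_table(genes) |> arrange(.data$gene_id)
  if (length(unique(genes$species_id)) < 2) abort("need >= 2 species")
  cand <- kmer_candidates(genes$gene_id, genes$sequence,
                          params$kmer_size, params$min_shared_kmers)
  if (cross_species_only && nrow(cand)) {
    cand <- cand |>
      filter(genes$species_id[.data$i] != genes$species_id[.data$j])
  }
  sc <- score_candidates(genes, cand, params)
  keep <- sc >= params$min_score
  cand <- cand[keep, , drop = FALSE]
  sc <- sc[keep]
  hits <- tibble(
    query_id = c(genes$gene_id[cand$i], genes$gene_id[cand$j]),
    query_species = c(genes$species_id[cand$i], genes$species_id[cand$j]),
    target_id = c(genes$gene_id[cand$j], genes$gene_id[cand$i]),
    target_species = c(genes$species_id[cand$j], genes$species_id[cand$i]),
    score = c(sc, sc)
  )
  arrange(hits, .data$query_id, .data$target_id)
}

#' Import pairwise hits from 12-column BLAST tabular output
#'
#' Column 12 (bit score) becomes the hit score; the best-scoring row is kept
#' per ordered (query, target) pair. Scores are only ever compared within
#' one hit table, so bit-score units mix fine with nothing else.
#'
#' @param path BLAST `-outfmt 6` file (qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore).
#' @param genes Gene table used to resolve species and check ids.
#' @param strict Unknown gene ids are an error (`TRUE`, default) or dropped
#'   with a warning.
#' @return Hit table (see [all_vs_all()]).
#' @export
import_hits <- function(path, genes, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    abort(sprintf("expected 12 tab-separated columns, found %d at line %d",
                  nf[bad], bad))
  }
  tab <- tibble(
    query_id = vapply(fields, `[[`, "", 1),
    target_id = vapply(fields, `[[`, "", 2),
    score = as.numeric(vapply(fields, `[[`, "", 12))
  )
  known <- genes$gene_id
  unknown <- setdiff(unique(c(tab$query_id, tab$target_id)), known)
  if (length(unknown)) {
    msg <- paste0("unknown gene id(s) in hits file: ",
                  paste(unknown, collapse = ", "))
    if (strict) abort(msg)
    warn(msg)
    tab <- tab |>
      filter(.data$query_id %in% known, .data$target_id %in% known)
  }
  sp <- setNames(genes$species_id, genes$gene_id)
  if (!nrow(tab)) {
    return(tibble(query_id = character(), query_species = character(),
                  target_id = character(), target_species = character(),
                  score = numeric()))
  }
  tab |>
    group_by(.data$query_id, .data$target_id) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    mutate(query_species = unname(sp[.data$query_id]),
           target_species = unname(sp[.data$target_id])) |>
    select("query_id", "query_species", "target_id", "target_species",
           "score") |>
    arrange(.data$query_id, .data$target_id)
}

#' Export a hit table as 12-column BLAST tabular
#'
#' Only the id and bit-score columns carry information; alignment-detail
#' columns are written as zeros so that `import_hits(export_hits(x))`
#' round-trips ids and scores exactly.
#'
#' @param hits Hit table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_hits <- function(hits, path) {
  df <- tibble(
    q = hits$query_id, t = hits$target_id,
    pident = 0, len = 0L, mm = 0L, go = 0L,
    qs = 0L, qe = 0L, ss = 0L, se = 0L, ev = 0,
    bits = hits$score
  )
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Write / read a hit table as TSV
#'
#' Plain five-column TSV (`query_id`, `query_species`, `target_id`,
#' `target_species`, `score`) used between pipeline stages.
#'
#' @param hits Hit table.
#' @param path TSV path.
#' @return `path` (write) or the hit table (read).
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_tsv(path, col_types = readr::cols(
    query_id = "c", query_species = "c", target_id = "c",
    target_species = "c", score = "d"
  ))
}
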