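# Independent brute-force oracles. These re-derive expected results by the
# most transparent route possible (quadratic DP, exhaustive argmax, queue
# BFS, full subset enumeration, hash-everything-and-sort) and deliberately
# share no code with the implementation paths they check.

# Gotoh local alignment, affine gaps: gap of length L costs open + L * ext.
oracle_sw_score <- function(a, b, mat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1],
                            Y[i - 1, j - 1]) + s)
      X[i, j] <- max(M[i - 1, j] - (open + ext), X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - (open + ext), Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# exhaustive double-argmax BRH oracle over a dense score matrix
# (rows = genes of species a, cols = genes of species b; NA = no hit)
oracle_brh <- function(scores) {
  pairs <- list()
  for (x in rownames(scores)) {
    row <- scores[x, ]
    if (all(is.na(row))) next
    mx <- max(row, na.rm = TRUE)
    bx <- sort(names(row)[which(!is.na(row) & row == mx)])[1]
    col <- scores[, bx]
    if (all(is.na(col))) next
    my <- max(col, na.rm = TRUE)
    by <- sort(names(col)[which(!is.na(col) & col == my)])[1]
    if (by == x) pairs[[length(pairs) + 1L]] <- sort(c(x, bx))
  }
  unique(pairs)
}

# queue-based BFS connected components
oracle_components <- function(vertices, edges_a, edges_b) {
  adj <- lapply(setNames(vector("list", length(vertices)), vertices),
                function(x) character())
  for (k in seq_along(edges_a)) {
    adj[[edges_a[k]]] <- c(adj[[edges_a[k]]], edges_b[k])
    adj[[edges_b[k]]] <- c(adj[[edges_b[k]]], edges_a[k])
  }
  seen <- setNames(rep(FALSE, length(vertices)), vertices)
  comps <- list()
  for (v in vertices) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    comp <- character()
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

oracle_prf <- function(refog, combined) {
  if (!length(combined)) return(c(p = 0, r = 0, f1 = 0))
  i <- length(intersect(refog, combined))
  p <- i / length(combined); r <- i / length(refog)
  c(p = p, r = r, f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

# full enumeration of nonempty OG subsets, with explicit set unions
oracle_best_combo <- function(refog, og_list) {
  cand <- names(og_list)[vapply(og_list, function(g)
    length(intersect(g, refog)) > 0, logical(1))]
  if (!length(cand)) return(list(og_ids = character(), f1 = 0))
  best <- NULL
  for (k in seq_along(cand)) {
    sets <- utils::combn(cand, k, simplify = FALSE)
    for (s in sets) {
      u <- unique(unlist(og_list[s], use.names = FALSE))
      f1 <- oracle_prf(refog, u)[["f1"]]
      key <- list(og_ids = sort(s), f1 = f1, k = k,
                  idstr = paste(sort(s), collapse = ","))
      if (is.null(best) || f1 > best$f1 + 1e-12 ||
          (abs(f1 - best$f1) <= 1e-12 &&
           (k < best$k || (k == best$k && key$idstr < best$idstr)))) {
        best <- key
      }
    }
  }
  best
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# hash every canonical k-mer, deduplicate, sort, keep the s smallest
oracle_minhash <- function(seqs, k, s, seed) {
  hashes <- numeric()
  for (sq in seqs) {
    n <- nchar(sq)
    if (n < k) next
    kms <- substring(sq, 1:(n - k + 1), k:n)
    kms <- kms[!grepl("[^ACGT]", kms)]
    canon <- vapply(kms, function(km) min(km, revcomp(km)), "",
                    USE.NAMES = FALSE)
    hashes <- c(hashes, orthogs:::kmer_hash_cpp(canon, seed))
  }
  hashes <- sort(unique(hashes))
  utils::head(hashes, s)
}

oracle_vi <- function(x, y) {
  common <- intersect(names(x), names(y))
  x <- x[common]; y <- y[common]
  n <- length(common)
  h <- function(groups) {
    p <- table(groups) / n
    -sum(p * log(p))
  }
  hxy <- 0
  for (gx in unique(x)) {
    for (gy in unique(y)) {
      pxy <- sum(x == gx & y == gy) / n
      if (pxy > 0) hxy <- hxy - pxy * log(pxy)
    }
  }
  2 * hxy - h(x) - h(y)
}
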