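AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Coerce and validate a gene table
#'
#' The gene table is the package's proteome container: one row per gene with
#' columns `gene_id` (globally unique), `species_id` and `sequence`
#' (amino acids over `ACDEFGHIKLMNPQRSTVWY` plus `X` for masked residues).
#'
#' @param x Data frame with at least `gene_id`, `species_id`, `sequence`.
#' @param check_alphabet Validate residues (on by default).
#' @return A tibble with the three canonical columns.
#' @export
as_gene_table <- function(x, check_alphabet = TRUE) {
  need <- c("gene_id", "species_id", "sequence")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    abort(paste0("gene table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- as_tibble(x)[, need]
  if (any(!nzchar(out$gene_id))) abort("empty gene_id")
  if (any(!nzchar(out$species_id))) abort("empty species_id")
  if (any(!nzchar(out$sequence))) abort("empty sequence")
  if (check_alphabet) {
    bad <- stringr::str_locate(out$sequence,
                               sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")))[, 1]
    if (any(!is.na(bad))) {
      i <- which(!is.na(bad))[1]
      abort(sprintf("illegal residue '%s' at position %d of gene '%s'",
                    substr(out$sequence[i], bad[i], bad[i]), bad[i],
                    out$gene_id[i]))
    }
  }
  out
}

#' Read a protein FASTA file into a tibble
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Wrapped/unwrapped lines and CRLF endings are accepted.
#'
#' @param path FASTA file.
#' @return Tibble with columns `gene_id`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- stringr::str_split_i(names(aa), "\\s+", 1)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA record ids in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  tibble(gene_id = ids, sequence = unname(toupper(as.character(aa))))
}

#' Write sequences to FASTA
#'
#' @param records Tibble with `gene_id` and `sequence`; an optional `desc`
#'   column is appended to the header after a space.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- records$gene_id
  if ("desc" %in% names(records)) headers <- paste(headers, records$desc)
  aa <- Biostrings::AAStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(aa, path, width = 70)
  invisible(path)
}

#' Read one proteome per species
#'
#' @param species_files Named character vector: `species_id -> fasta path`,
#'   or a data frame with columns `species_id`, `fasta_path` (the species
#'   list TSV schema).
#' @return Validated gene table (see [as_gene_table()]).
#' @export
read_proteomes <- function(species_files) {
  if (is.data.frame(species_files)) {
    species_files <- setNames(species_files$fasta_path,
                              species_files$species_id)
  }
  if (is.null(names(species_files)) || any(!nzchar(names(species_files)))) {
    abort("species_files must be named by species_id")
  }
  tabs <- purrr::imap(species_files, function(p, sp) {
    read_fasta(p) |> mutate(species_id = sp)
  })
  genes <- bind_rows(tabs)
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    abort(paste0("gene ids duplicated across proteomes: ",
                 paste(dup, collapse = ", ")))
  }
  as_gene_table(genes)
}
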