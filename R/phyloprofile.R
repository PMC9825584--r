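#' Phylogenetic profiles of OGs
#'
#' Per-OG evolutionary annotations over the species of the OG's level:
#'
#' * `universality` — fraction of the level's species in which the OG is
#'   present at all (`n_present / n_level_species`);
#' * `duplicability` — among species where the OG is present, the fraction
#'   carrying more than one copy (`n_multi_copy / n_present`);
#' * `single_copy_fraction` — fraction of the level's species with exactly
#'   one copy (`n_single_copy / n_level_species`).
#'
#' High universality with zero duplicability is the signature of universal
#' single-copy genes (essentiality under single-copy control); high
#' duplicability hints at relaxed copy-number selection. Note the
#' duplicability denominator is the species where the gene exists, not all
#' level species — it measures the propensity to duplicate where present.
#'
#' @param ogs OG membership tibble (`og_id`, `level`, `gene_id`,
#'   `species_id`) or an `og_delineation`.
#' @param tree Species tree (used to size each level's species set).
#' @return Tibble: `og_id`, `level`, `n_level_species`, `n_present`,
#'   `n_single_copy`, `n_multi_copy`, `universality`, `duplicability`,
#'   `single_copy_fraction`.
#' @export
compute_profiles <- function(ogs, tree) {
  if (inherits(ogs, "og_delineation")) ogs <- ogs$ogs
  if (!nrow(ogs)) abort("empty OG set")
  level_sizes <- ogs |>
    distinct(.data$level) |>
    mutate(n_level_species = vapply(.data$level, function(l) {
      length(species_under(tree, l))
    }, integer(1), USE.NAMES = FALSE))
  for (l in level_sizes$level) {
    sp_l <- species_under(tree, l)
    bad <- setdiff(unique(ogs$species_id[ogs$level == l]), sp_l)
    if (length(bad)) {
      abort(paste0("OG members outside level '", l, "': species ",
                   paste(bad, collapse = ", ")))
    }
  }
  ogs |>
    count(.data$og_id, .data$level, .data$species_id, name = "copies") |>
    group_by(.data$og_id, .data$level) |>
    summarise(
      n_present = n(),
      n_single_copy = sum(.data$copies == 1L),
      n_multi_copy = sum(.data$copies >= 2L),
      .groups = "drop"
    ) |>
    left_join(level_sizes, by = "level") |>
    mutate(
      universality = .data$n_present / .data$n_level_species,
      duplicability = .data$n_multi_copy / .data$n_present,
      single_copy_fraction = .data$n_single_copy / .data$n_level_species
    ) |>
    select("og_id", "level", "n_level_species", "n_present",
           "n_single_copy", "n_multi_copy", "universality",
           "duplicability", "single_copy_fraction") |>
    arrange(.data$level, .data$og_id)
}

#' Phyloprofile filters
#'
#' Web-style selection of OGs by presence and single-copy thresholds, e.g.
#' "present in >90% of species" and "single-copy in >90% of species".
#' Thresholds are strict (`>`), matching that wording: an OG present in
#' exactly 90% of species does not pass a 90 threshold. Pass 0 to disable a
#' filter. Raising either threshold can only shrink the selection.
#'
#' @param profiles Output of [compute_profiles()].
#' @param min_presence_pct,min_single_copy_pct Percentages in \[0, 100\].
#' @return Character vector of selected `og_id`s.
#' @export
filter_ogs <- function(profiles, min_presence_pct = 0,
                       min_single_copy_pct = 0) {
  if (min_presence_pct < 0 || min_presence_pct > 100 ||
      min_single_copy_pct < 0 || min_single_copy_pct > 100) {
    abort("thresholds must be percentages in [0, 100]")
  }
  keep <- profiles |>
    filter(min_presence_pct == 0 |
             .data$universality * 100 > min_presence_pct,
           min_single_copy_pct == 0 |
             .data$single_copy_fraction * 100 > min_single_copy_pct)
  sort(keep$og_id)
}

#' Export per-OG FASTA files of (near-)single-copy OGs
#'
#' One FASTA per selected OG, record headers `"gene_id species_id og_id"`.
#' If a relaxed filter lets through a species with several copies, the
#' longest member is exported for that species and a warning names the OG
#' and species.
#'
#' @param og_ids OG ids to export (e.g. from [filter_ogs()]).
#' @param ogs OG membership tibble.
#' @param genes Gene table resolving sequences.
#' @param dir Output directory (created if missing).
#' @return Tibble `og_id`, `path`, invisibly.
#' @export
export_single_copy_fasta <- function(og_ids, ogs, genes, dir) {
  if (!length(og_ids)) abort("empty OG selection")
  if (inherits(ogs, "og_delineation")) ogs <- ogs$ogs
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- as_gene_table(genes, check_alphabet = FALSE)
  out <- purrr::map(sort(og_ids), function(og) {
    mem <- ogs |>
      filter(.data$og_id == og) |>
      inner_join(genes, by = c("gene_id", "species_id"))
    multi <- mem |> count(.data$species_id) |> filter(.data$n > 1)
    if (nrow(multi)) {
      warn(paste0("OG ", og, ": multiple copies in ",
                  paste(multi$species_id, collapse = ", "),
                  "; exporting the longest member per species"))
      mem <- mem |>
        arrange(.data$species_id, desc(nchar(.data$sequence)),
                .data$gene_id) |>
        group_by(.data$species_id) |>
        slice(1) |>
        ungroup()
    }
    p <- file.path(dir, paste0(og, ".fasta"))
    mem |>
      arrange(.data$gene_id) |>
      mutate(desc = paste(.data$species_id, og)) |>
      select("gene_id", "sequence", "desc") |>
      write_fasta(p)
    tibble(og_id = og, path = p)
  }) |> bind_rows()
  invisible(out)
}

#' Write phyloprofiles to TSV
#'
#' @param profiles Output of [compute_profiles()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_tsv(profiles, path)
  invisible(path)
}
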