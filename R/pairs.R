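#' Shortlist genomes by genus size and family diversity
#'
#' Applies the two nested study-design criteria to a taxonomy table: keep
#' genomes (1) whose genus has at least `min_genomes_per_genus` members and
#' then (2) whose family still has at least `min_genera_per_family` genera
#' among the surviving genomes.  The genus filter runs first; a family can
#' therefore be discarded because its small genera were removed, even if it
#' had enough genera before filtering.
#'
#' @param taxonomy A taxonomy tibble (see [read_taxonomy()]).
#' @param min_genera_per_family Minimum surviving genera per family. Default 2.
#' @param min_genomes_per_genus Minimum genomes per genus. Default 10.
#' @return The filtered taxonomy tibble (possibly empty).
#' @export
select_genomes <- function(taxonomy, min_genera_per_family = 2L,
                           min_genomes_per_genus = 10L) {
  taxonomy <- validate_taxonomy(taxonomy)
  taxonomy |>
    dplyr::add_count(.data$family, .data$genus, name = ".n_genus") |>
    dplyr::filter(.data$.n_genus >= min_genomes_per_genus) |>
    dplyr::group_by(.data$family) |>
    dplyr::filter(dplyr::n_distinct(.data$genus) >= min_genera_per_family) |>
    dplyr::ungroup() |>
    dplyr::select(-".n_genus")
}

#' Build the within-family genome pair set
#'
#' Enumerates every unordered pair of distinct genomes that share a family
#' (cross-family comparisons are excluded by design, and self-pairs are
#' banned).  Each pair is labeled `same_genus`, the positive class for
#' genus-delineation evaluation.  A family of n genomes contributes
#' n(n-1)/2 pairs; each pair corresponds to two directional alignment jobs.
#'
#' @param taxonomy A taxonomy tibble, typically already passed through
#'   [select_genomes()].
#' @return A tibble with columns `genome_a`, `genome_b`, `family`,
#'   `same_genus`, canonically ordered so that `genome_a < genome_b`.
#' @export
build_pair_set <- function(taxonomy) {
  taxonomy <- validate_taxonomy(taxonomy)
  taxonomy |>
    dplyr::group_by(.data$family) |>
    dplyr::group_modify(~ family_pairs(.x)) |>
    dplyr::ungroup() |>
    dplyr::relocate("genome_a", "genome_b", "family", "same_genus") |>
    dplyr::arrange(.data$family, .data$genome_a, .data$genome_b)
}

family_pairs <- function(members) {
  n <- nrow(members)
  if (n < 2L) {
    return(tibble(genome_a = character(), genome_b = character(),
                  same_genus = logical()))
  }
  idx <- utils::combn(n, 2L)
  i <- idx[1L, ]
  j <- idx[2L, ]
  a <- members$genome_id[i]
  b <- members$genome_id[j]
  swap <- a > b
  tibble(
    genome_a = ifelse(swap, b, a),
    genome_b = ifelse(swap, a, b),
    same_genus = members$genus[i] == members$genus[j]
  )
}

#' Write a pair manifest TSV
#'
#' @param pairs A pair tibble from [build_pair_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_manifest <- function(pairs, path) {
  readr::write_tsv(
    dplyr::select(pairs, "genome_a", "genome_b", "family", "same_genus"),
    path, progress = FALSE
  )
  invisible(path)
}
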