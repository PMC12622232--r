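#' Published GTDB-scale benchmark summary counts
#'
#' Convenience accessors for the confusion-matrix counts and pair counts
#' reported by the GTDB-scale genus-delineation benchmark (4,767 genomes,
#' 35 families, DIAMOND very-sensitive hits, 50% threshold).  These are
#' shipped as plain-text tables and are useful as worked inputs for
#' [mcc()] and for consistency checks; they are published summary
#' statistics, not outputs of this package.
#'
#' @return `gtdb_reference_counts()`: a tibble with columns `scope`
#'   (`"global"` or a family name), `metric` (`"pocp"`/`"pocpu"`), and the
#'   confusion counts `tp`, `fp`, `tn`, `fn` at the 50% threshold.
#'   `gtdb_pair_counts()`: a tibble with columns `class`
#'   (`between_genera`/`within_genus`) and `n_pairs` (unordered pairs).
#' @export
gtdb_reference_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "gtdb_confusion_counts.tsv",
                package = "pocpu", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}

#' @rdname gtdb_reference_counts
#' @export
gtdb_pair_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "gtdb_pair_counts.tsv",
                package = "pocpu", mustWork = TRUE),
    show_col_types = FALSE, progress = FALSE
  )
}
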