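#' Read a proteome from a protein FASTA file
#'
#' Reads one genome's predicted protein sequences (plain or gzip-compressed
#' FASTA) into a tidy proteome table.  The protein id is the first
#' whitespace-delimited token of each FASTA header, which is what alignment
#' tools report as query/subject ids, so hit tables join back without
#' munging.  Sequences are uppercased and `*` (stop) characters are stripped
#' before lengths are computed: Prodigal output commonly carries a trailing
#' `*` and it must not inflate the query length used by the coverage filter.
#'
#' @param path Path to a protein FASTA file (optionally `.gz`).
#' @param genome_id Genome identifier attached to every record.
#'
#' @return A tibble with one row per protein and columns `genome_id`,
#'   `protein_id`, `sequence`, `length`.  The total protein count of the
#'   genome (the denominator term of POCP/POCPu) is `nrow()` of this table;
#'   see [n_proteins()].
#'
#' @details Empty proteomes are an error rather than a zero-protein table:
#'   a genome contributing zero proteins would make the POCP denominator
#'   degenerate.  Duplicate protein ids within one file are an error.
#'
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 hypothetical", "MKVLAT", ">p2", "MNPQRSTV*"), fa)
#' read_proteome(fa, genome_id = "G1")
#' @export
read_proteome <- function(path, genome_id) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (!file.exists(path)) {
    abort(paste0("proteome file not found: ", path))
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    abort(paste0("empty proteome: no FASTA records in ", path))
  }
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0(
      "duplicate protein id(s) in ", path, ": ",
      paste(head(dup, 5L), collapse = ", ")
    ))
  }
  seqs <- gsub("*", "", toupper(as.character(aa)), fixed = TRUE)
  new_proteome(genome_id, ids, seqs)
}

# Assemble and validate the tidy proteome table.
new_proteome <- function(genome_id, protein_id, sequence) {
  if (any(!nzchar(protein_id))) abort("empty protein id")
  if (any(!nzchar(sequence))) {
    abort(paste0(
      "zero-length sequence for protein(s): ",
      paste(head(protein_id[!nzchar(sequence)], 5L), collapse = ", ")
    ))
  }
  tibble(
    genome_id = genome_id,
    protein_id = as.character(protein_id),
    sequence = as.character(sequence),
    length = nchar(sequence)
  )
}

#' Write a proteome table back to FASTA
#'
#' @param proteome A proteome tibble as returned by [read_proteome()].
#' @param path Output FASTA path (`.gz` suffix triggers gzip compression).
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  check_proteome(proteome)
  aa <- Biostrings::AAStringSet(setNames(proteome$sequence, proteome$protein_id))
  Biostrings::writeXStringSet(aa, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Total protein count of a proteome
#'
#' The T term of the POCP/POCPu denominator for one genome.
#'
#' @inheritParams write_proteome
#' @return A single integer.
#' @export
n_proteins <- function(proteome) {
  check_proteome(proteome)
  nrow(proteome)
}

#' Per-protein length lookup
#'
#' Query lengths feed the coverage filter: a hit is conserved only if its
#' aligned region exceeds half the query protein's length.
#'
#' @inheritParams write_proteome
#' @return A named integer vector mapping `protein_id` to residue count.
#' @export
query_lengths <- function(proteome) {
  check_proteome(proteome)
  setNames(as.integer(proteome$length), proteome$protein_id)
}

check_proteome <- function(proteome) {
  if (!is.data.frame(proteome) ||
      !all(c("genome_id", "protein_id", "sequence", "length") %in% names(proteome))) {
    abort("expected a proteome tibble with columns genome_id, protein_id, sequence, length")
  }
  if (nrow(proteome) == 0L) abort("empty proteome")
  if (anyDuplicated(proteome$protein_id)) abort("duplicate protein ids in proteome")
  if (length(unique(proteome$genome_id)) != 1L) {
    abort("a proteome holds exactly one genome_id")
  }
  invisible(proteome)
}

#' Read a genome taxonomy table
#'
#' Accepts either an explicit TSV with header columns `genome_id`, `family`,
#' `genus`, `species`, or a two-column TSV with `genome_id` and a GTDB-style
#' `gtdb_taxonomy` string (`d__...;p__...;c__...;o__...;f__...;g__...;s__...`),
#' which is split on `;` and rank-prefix-stripped.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `genome_id`, `family`, `genus`, `species`.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("gtdb_taxonomy" %in% names(tax)) {
    if (!"genome_id" %in% names(tax)) abort("taxonomy TSV lacks genome_id column")
    tax <- dplyr::mutate(
      tax,
      family = gtdb_rank(.data$gtdb_taxonomy, "f"),
      genus = gtdb_rank(.data$gtdb_taxonomy, "g"),
      species = gtdb_rank(.data$gtdb_taxonomy, "s")
    )
  }
  required <- c("genome_id", "family", "genus")
  missing <- setdiff(required, names(tax))
  if (length(missing)) {
    abort(paste0("taxonomy TSV lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"species" %in% names(tax)) tax$species <- NA_character_
  tax <- dplyr::select(tax, "genome_id", "family", "genus", "species")
  validate_taxonomy(tax)
}

gtdb_rank <- function(taxonomy, prefix) {
  parts <- stringr::str_split(taxonomy, ";")
  purrr::map_chr(parts, function(p) {
    p <- stringr::str_trim(p)
    hit <- p[startsWith(p, paste0(prefix, "__"))]
    if (length(hit) == 0L) NA_character_ else sub("^.__", "", hit[[1L]])
  })
}

validate_taxonomy <- function(tax) {
  if (anyDuplicated(tax$genome_id)) {
    dup <- unique(tax$genome_id[duplicated(tax$genome_id)])
    abort(paste0("duplicate genome_id in taxonomy: ", paste(head(dup, 5L), collapse = ", ")))
  }
  bad <- is.na(tax$family) | !nzchar(tax$family) | is.na(tax$genus) | !nzchar(tax$genus)
  if (any(bad)) {
    abort(paste0(
      "missing family or genus for genome(s): ",
      paste(head(tax$genome_id[bad], 5L), collapse = ", ")
    ))
  }
  as_tibble(tax)
}
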