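#' Conservation filter thresholds
#'
#' The canonical definition of a conserved protein: a query match with an
#' e-value below `1e-5`, a sequence identity above 40%, and an aligned
#' region covering more than half of the query protein length.  All three
#' comparisons are strict, so boundary hits (identity exactly 40, coverage
#' exactly 50%, e-value exactly 1e-5) are excluded.
#'
#' Non-default thresholds are supported for exploration but break
#' comparability with published POCP/POCPu values; results computed with
#' them carry a `nonstandard_thresholds` attribute as a watermark.
#'
#' @param max_evalue Hits must have `evalue` strictly below this. Default `1e-5`.
#' @param min_identity_pct Hits must have percent identity strictly above
#'   this. Default `40`.
#' @param min_query_coverage Hits must span strictly more than this fraction
#'   of the query length. Default `0.5`.
#' @return An object of class `pocp_thresholds`.
#' @export
pocp_thresholds <- function(max_evalue = 1e-5, min_identity_pct = 40,
                            min_query_coverage = 0.5) {
  stopifnot(
    is.numeric(max_evalue), length(max_evalue) == 1L, max_evalue > 0,
    is.numeric(min_identity_pct), length(min_identity_pct) == 1L,
    min_identity_pct >= 0, min_identity_pct <= 100,
    is.numeric(min_query_coverage), length(min_query_coverage) == 1L,
    min_query_coverage > 0, min_query_coverage <= 1
  )
  structure(
    list(max_evalue = max_evalue, min_identity_pct = min_identity_pct,
         min_query_coverage = min_query_coverage),
    class = "pocp_thresholds"
  )
}

#' @export
print.pocp_thresholds <- function(x, ...) {
  cat("Conservation filter thresholds (all strict):\n",
      "  e-value  < ", format(x$max_evalue), "\n",
      "  identity > ", x$min_identity_pct, "%\n",
      "  coverage > ", x$min_query_coverage * 100, "% of query length\n",
      sep = "")
  invisible(x)
}

is_default_thresholds <- function(thresholds) {
  identical(unclass(thresholds), unclass(pocp_thresholds()))
}

#' Keep only conserved-protein hits
#'
#' Applies the conservation filter to a hit table: a row survives iff
#' `evalue < max_evalue` AND `pct_identity > min_identity_pct` AND
#' `aln_length > min_query_coverage * length(query)`.  Row order is
#' preserved.  A query id missing from the length lookup is an error, never
#' silently dropped, since a dropped query would deflate the conserved
#' count.
#'
#' @param hits A hit-table tibble (see [parse_hits()]).
#' @param qlen Query protein lengths: a named integer vector as returned by
#'   [query_lengths()], or a data frame with columns `protein_id`, `length`.
#' @param thresholds A [pocp_thresholds()] object.
#' @return The filtered hit-table tibble.
#' @export
filter_conserved <- function(hits, qlen, thresholds = pocp_thresholds()) {
  check_hits(hits)
  stopifnot(inherits(thresholds, "pocp_thresholds"))
  qlen <- as_length_lookup(qlen)
  if (nrow(hits) == 0L) return(hits)

  missing <- setdiff(unique(hits$query_id), names(qlen))
  if (length(missing)) {
    abort(paste0(
      "query id(s) in hit table absent from the proteome length lookup: ",
      paste(head(missing, 5L), collapse = ", ")
    ))
  }
  lens <- unname(qlen[hits$query_id])
  keep <- hits$evalue < thresholds$max_evalue &
    hits$pct_identity > thresholds$min_identity_pct &
    hits$aln_length > thresholds$min_query_coverage * lens
  hits[keep, , drop = FALSE]
}

as_length_lookup <- function(qlen) {
  if (is.data.frame(qlen)) {
    stopifnot(all(c("protein_id", "length") %in% names(qlen)))
    qlen <- setNames(as.integer(qlen$length), qlen$protein_id)
  }
  if (is.null(names(qlen)) || any(!nzchar(names(qlen)))) {
    abort("query length lookup must be named by protein_id")
  }
  qlen
}

#' Count conserved matches in a filtered hit table
#'
#' Two counts drive the two metrics: `total_matches` is the number of
#' surviving hit rows (a query matching k subjects contributes k -- this is
#' what lets POCP exceed 100% in paralog-rich genomes), while
#' `unique_matches` counts distinct query proteins with at least one
#' surviving hit (each query contributes at most once; the POCPu numerator).
#'
#' @param filtered A hit-table tibble, typically from [filter_conserved()].
#' @return A one-row tibble with columns `total_matches`, `unique_matches`.
#' @export
count_conserved <- function(filtered) {
  check_hits(filtered)
  tibble(
    total_matches = nrow(filtered),
    unique_matches = dplyr::n_distinct(filtered$query_id)
  )
}

#' Compute POCP and POCPu for one genome pair
#'
#' Filters both directional hit tables with the conservation filter, counts
#' total and unique conserved matches in each direction, and evaluates
#'
#' \deqn{POCP = 100 (C_{QS} + C_{SQ}) / (T_Q + T_S)}
#' \deqn{POCPu = 100 (C_{uQS} + C_{uSQ}) / (T_Q + T_S)}
#'
#' where the C terms are the directional conserved counts (total match rows
#' for POCP, distinct matched queries for POCPu) and T the total protein
#' counts of the two genomes.  Values are full floating-point percentages;
#' rounding is presentation-only.
#'
#' @param proteome_a,proteome_b Proteome tibbles for the two genomes.
#' @param hits_ab Hit table with `proteome_a` as query and `proteome_b` as
#'   subject; `hits_ba` the reverse direction.
#' @param hits_ba See `hits_ab`.
#' @param thresholds A [pocp_thresholds()] object.
#' @return A one-row tibble: `genome_a`, `genome_b`, `t_a`, `t_b`, `c_ab`,
#'   `c_ba`, `cu_ab`, `cu_ba`, `pocp`, `pocpu`.  If non-default thresholds
#'   were used the result carries attribute `nonstandard_thresholds`.
#' @export
compute_pair <- function(proteome_a, proteome_b, hits_ab, hits_ba,
                         thresholds = pocp_thresholds()) {
  check_proteome(proteome_a)
  check_proteome(proteome_b)
  check_hits(hits_ab)
  check_hits(hits_ba)
  ga <- proteome_a$genome_id[[1L]]
  gb <- proteome_b$genome_id[[1L]]
  check_genome_pair(ga, gb)
  check_direction(hits_ab, ga, gb)
  check_direction(hits_ba, gb, ga)

  cnt_ab <- count_conserved(
    filter_conserved(hits_ab, query_lengths(proteome_a), thresholds))
  cnt_ba <- count_conserved(
    filter_conserved(hits_ba, query_lengths(proteome_b), thresholds))

  n_a <- nrow(proteome_a)
  n_b <- nrow(proteome_b)
  res <- tibble(
    genome_a = ga, genome_b = gb, t_a = n_a, t_b = n_b,
    c_ab = cnt_ab$total_matches, c_ba = cnt_ba$total_matches,
    cu_ab = cnt_ab$unique_matches, cu_ba = cnt_ba$unique_matches,
    pocp = (.data$c_ab + .data$c_ba) / (n_a + n_b) * 100,
    pocpu = (.data$cu_ab + .data$cu_ba) / (n_a + n_b) * 100
  )
  if (!is_default_thresholds(thresholds)) {
    attr(res, "nonstandard_thresholds") <- unclass(thresholds)
  }
  res
}

check_direction <- function(hits, expect_query, expect_subject) {
  if (nrow(hits) == 0L) return(invisible(NULL))
  if (!all(hits$query_genome == expect_query) ||
      !all(hits$subject_genome == expect_subject)) {
    abort(paste0(
      "hit-table direction mismatch: expected ", expect_query, " -> ",
      expect_subject
    ))
  }
  invisible(NULL)
}

#' Write pair results to TSV
#'
#' One row per unordered genome pair with the counts and both metrics;
#' POCP/POCPu are printed with 4 decimals (computation keeps full
#' precision).
#'
#' @param pairs A tibble of [compute_pair()] rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_tsv <- function(pairs, path) {
  out <- dplyr::mutate(
    pairs,
    pocp = sprintf("%.4f", .data$pocp),
    pocpu = sprintf("%.4f", .data$pocpu)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
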