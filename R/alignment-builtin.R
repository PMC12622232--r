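# Karlin-Altschul constants for gapped BLOSUM62 (gap open 11 / extend 1),
# used only to decide which local alignments are worth reporting.  The
# conservation filter re-applies its own exact e-value cutoff downstream,
# so POCP/POCPu never depend on this approximation.
.ka_lambda <- 0.267
.ka_K <- 0.041
.report_evalue <- 10

#' Align two proteomes with the built-in Smith-Waterman aligner
#'
#' Desk-scale all-vs-all local protein alignment so that POCP/POCPu can be
#' computed without any external binary.  Every query protein is aligned
#' against every subject protein (Smith-Waterman via
#' [Biostrings::pairwiseAlignment()]: BLOSUM62, gap open 11, gap extend 1),
#' and the best local alignment of each query-subject pair is reported as
#' one hit when its approximate Karlin-Altschul e-value (lambda = 0.267,
#' K = 0.041, search space = query length x total subject residues) falls
#' below 10.  Percent identity is identical aligned columns over alignment
#' columns (gaps included), and `aln_length` is the alignment column count
#' including gaps.  Deterministic given its inputs.
#'
#' @param query,subject Proteome tibbles (see [read_proteome()]) with
#'   distinct `genome_id`s.
#' @return A hit-table tibble (see [parse_hits()] for the columns), at most
#'   one row per query-subject protein pair, queries in proteome order.
#' @export
builtin_align <- function(query, subject) {
  check_proteome(query)
  check_proteome(subject)
  qg <- query$genome_id[[1L]]
  sg <- subject$genome_id[[1L]]
  check_genome_pair(qg, sg)

  qset <- Biostrings::AAStringSet(setNames(query$sequence, query$protein_id))
  n_space <- sum(subject$length)

  per_subject <- purrr::map(seq_len(nrow(subject)), function(j) {
    sseq <- Biostrings::AAString(subject$sequence[[j]])
    scores <- Biostrings::pairwiseAlignment(
      qset, sseq, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE
    )
    ev <- .ka_K * query$length * n_space * exp(-.ka_lambda * scores)
    keep <- which(ev < .report_evalue)
    if (length(keep) == 0L) return(NULL)
    aln <- Biostrings::pairwiseAlignment(
      qset[keep], sseq, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1
    )
    width <- Biostrings::nchar(aln)
    tibble(
      query_genome = qg,
      subject_genome = sg,
      query_id = query$protein_id[keep],
      subject_id = subject$protein_id[[j]],
      pct_identity = Biostrings::nmatch(aln) / width * 100,
      aln_length = as.integer(width),
      evalue = ev[keep],
      bitscore = (.ka_lambda * scores[keep] - log(.ka_K)) / log(2)
    )
  })

  hits <- dplyr::bind_rows(per_subject)
  if (nrow(hits) == 0L) return(.empty_hits())
  # one row per pair already; order queries as in the proteome, subjects within
  dplyr::arrange(hits,
                 match(.data$query_id, query$protein_id),
                 match(.data$subject_id, subject$protein_id))
}
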