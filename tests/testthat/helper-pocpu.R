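# Shared fixture builders.  Everything is generated in code; no binary data.

# Minimal hit-table rows with sensible defaults; override per test.
hit_tbl <- function(query_id, subject_id,
                    pct_identity = 60, aln_length = 80L,
                    evalue = 1e-10, bitscore = 100,
                    query_genome = "A", subject_genome = "B") {
  tibble::tibble(
    query_genome = query_genome, subject_genome = subject_genome,
    query_id = query_id, subject_id = subject_id,
    pct_identity = pct_identity, aln_length = as.integer(aln_length),
    evalue = evalue, bitscore = bitscore
  )
}

# A proteome tibble without touching the file system.
proteome_tbl <- function(genome_id, ids, lengths) {
  tibble::tibble(
    genome_id = genome_id,
    protein_id = ids,
    sequence = vapply(lengths, function(n) strrep("A", n), character(1)),
    length = as.integer(lengths)
  )
}

# Random directional hit tables for a genome pair plus matching proteomes.
# Returns list(proteome_a, proteome_b, hits_ab, hits_ba).
random_pair_instance <- function(n_a = 6L, n_b = 6L, n_hits = 15L) {
  ids_a <- sprintf("a%02d", seq_len(n_a))
  ids_b <- sprintf("b%02d", seq_len(n_b))
  len_a <- sample(60:140, n_a, replace = TRUE)
  len_b <- sample(60:140, n_b, replace = TRUE)
  mk_hits <- function(q_ids, s_ids, qg, sg, n) {
    qi <- sample(q_ids, n, replace = TRUE)
    hit_tbl(
      query_id = qi,
      subject_id = sample(s_ids, n, replace = TRUE),
      pct_identity = runif(n, 0, 100),
      aln_length = sample(10:140, n, replace = TRUE),
      evalue = 10^runif(n, -40, 1),
      query_genome = qg, subject_genome = sg
    )
  }
  list(
    proteome_a = proteome_tbl("A", ids_a, len_a),
    proteome_b = proteome_tbl("B", ids_b, len_b),
    hits_ab = mk_hits(ids_a, ids_b, "A", "B", n_hits),
    hits_ba = mk_hits(ids_b, ids_a, "B", "A", n_hits)
  )
}

# Random labeled-value tibbles for the optimizer tests.
random_labeled_values <- function(n, p_within = 0.5) {
  same <- runif(n) < p_within
  if (!any(same)) same[sample(n, 1)] <- TRUE
  if (all(same)) same[sample(n, 1)] <- FALSE
  tibble::tibble(
    value = round(runif(n, 0, 100), sample(0:2, 1)),
    same_genus = same
  )
}

# Independent brute-force oracle for the best achievable MCC: evaluates the
# confusion matrix at every observed value shifted by +/- epsilon plus the
# extremes, using its own confusion counting and its own MCC formula.
brute_force_best_mcc <- function(values) {
  v <- values$value
  same <- values$same_genus
  eps <- 1e-9
  cands <- unique(c(min(v) - 1, sort(unique(v)) - eps, sort(unique(v)) + eps,
                    max(v) + 1, 50))
  mcc_one <- function(t) {
    tp <- as.numeric(sum(v > t & same)); fp <- as.numeric(sum(v > t & !same))
    tn <- as.numeric(sum(v <= t & !same)); fn <- as.numeric(sum(v <= t & same))
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) return(0)
    (tp * tn - fp * fn) / sqrt(den)
  }
  max(vapply(cands, mcc_one, numeric(1)))
}

# Full-stack POCP/POCPu on a generated synthetic pair.
full_stack_pair <- function(pair, thresholds = pocp_thresholds()) {
  compute_pair(
    pair$proteome_a, pair$proteome_b,
    builtin_align(pair$proteome_a, pair$proteome_b),
    builtin_align(pair$proteome_b, pair$proteome_a),
    thresholds
  )
}

extdata <- function(f) system.file("extdata", f, package = "pocpu", mustWork = TRUE)

# Expand a confusion-count row into labeled values that realize it at a
# given threshold (positives at threshold + 10, negatives at threshold - 10).
realize_counts <- function(tp, fp, tn, fn, threshold = 50) {
  tibble::tibble(
    value = c(rep(threshold + 10, tp + fp), rep(threshold - 10, tn + fn)),
    same_genus = c(rep(TRUE, tp), rep(FALSE, fp), rep(FALSE, tn), rep(TRUE, fn))
  )
}
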