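test_that("threshold constructor validates its ranges", {
  t <- pocp_thresholds()
  expect_equal(t$max_evalue, 1e-5)
  expect_equal(t$min_identity_pct, 40)
  expect_equal(t$min_query_coverage, 0.5)
  expect_error(pocp_thresholds(max_evalue = 0))
  expect_error(pocp_thresholds(min_identity_pct = 120))
  expect_error(pocp_thresholds(min_query_coverage = 0))
  expect_error(pocp_thresholds(min_query_coverage = 1.2))
})

test_that("all three conservation comparisons are strict", {
  qlen <- c(q1 = 100L)
  pass <- hit_tbl("q1", "s1", pct_identity = 45, aln_length = 60, evalue = 1e-6)
  expect_equal(nrow(filter_conserved(pass, qlen)), 1L)

  # each boundary value alone must exclude the hit
  at_evalue <- hit_tbl("q1", "s1", pct_identity = 45, aln_length = 60,
                       evalue = 1e-5)
  at_identity <- hit_tbl("q1", "s1", pct_identity = 40, aln_length = 60,
                         evalue = 1e-6)
  at_coverage <- hit_tbl("q1", "s1", pct_identity = 45, aln_length = 50,
                         evalue = 1e-6)
  for (h in list(at_evalue, at_identity, at_coverage)) {
    expect_equal(nrow(filter_conserved(h, qlen)), 0L)
  }
  # just past each boundary the hit survives
  above <- hit_tbl("q1", "s1", pct_identity = 40 + 1e-9, aln_length = 51,
                   evalue = 1e-5 * (1 - 1e-12))
  expect_equal(nrow(filter_conserved(above, qlen)), 1L)
})

test_that("filtering preserves row order and never drops queries silently", {
  qlen <- c(q1 = 100L, q2 = 100L)
  hits <- dplyr::bind_rows(
    hit_tbl("q2", "s1"), hit_tbl("q1", "s2", pct_identity = 10),
    hit_tbl("q1", "s3")
  )
  kept <- filter_conserved(hits, qlen)
  expect_equal(kept$query_id, c("q2", "q1"))
  expect_equal(kept$subject_id, c("s1", "s3"))

  expect_error(filter_conserved(hit_tbl("ghost", "s1"), qlen),
               "absent from the proteome length lookup.*ghost")
})

test_that("filter is idempotent and monotone in its thresholds", {
  withr::local_seed(81)
  for (i in 1:20) {
    inst <- random_pair_instance(n_hits = 25L)
    qlen <- query_lengths(inst$proteome_a)
    strict <- pocp_thresholds(1e-6, 50, 0.6)
    loose <- pocp_thresholds(1e-4, 30, 0.4)
    f1 <- filter_conserved(inst$hits_ab, qlen, strict)
    expect_identical(filter_conserved(f1, qlen, strict), f1)
    f2 <- filter_conserved(inst$hits_ab, qlen, loose)
    key <- function(h) paste(h$query_id, h$subject_id, h$pct_identity, h$evalue)
    expect_true(all(key(f1) %in% key(f2)))
  }
})

test_that("conserved counts separate total rows from unique queries", {
  hits <- dplyr::bind_rows(hit_tbl("p1", "s1"), hit_tbl("p1", "s2"),
                           hit_tbl("p2", "s3"))
  cc <- count_conserved(hits)
  expect_equal(cc$total_matches, 3L)
  expect_equal(cc$unique_matches, 2L)

  empty <- hits[0, ]
  expect_equal(count_conserved(empty)$total_matches, 0L)
  expect_equal(count_conserved(empty)$unique_matches, 0L)

  doubled <- dplyr::bind_rows(hits, hits)
  expect_equal(count_conserved(doubled)$total_matches, 6L)
  expect_equal(count_conserved(doubled)$unique_matches, 2L)
})

test_that("paralog-style hit tables give POCP 75 but POCPu 62.5 on the 4+4 pair", {
  a <- proteome_tbl("A", paste0("p", 1:4), rep(100L, 4))
  b <- proteome_tbl("B", paste0("s", 1:4), rep(100L, 4))
  hits_ab <- dplyr::bind_rows(hit_tbl("p1", "s1"), hit_tbl("p1", "s2"),
                              hit_tbl("p2", "s3"))
  hits_ba <- dplyr::bind_rows(
    hit_tbl("s1", "p1", query_genome = "B", subject_genome = "A"),
    hit_tbl("s2", "p1", query_genome = "B", subject_genome = "A"),
    hit_tbl("s3", "p2", query_genome = "B", subject_genome = "A")
  )
  res <- compute_pair(a, b, hits_ab, hits_ba)
  expect_equal(res$c_ab, 3L)
  expect_equal(res$c_ba, 3L)
  expect_equal(res$pocp, 75)
  # unique matches count distinct query proteins per direction: p1, p2 on
  # one side but s1, s2, s3 on the other (each S query has a hit)
  expect_equal(res$cu_ab, 2L)
  expect_equal(res$cu_ba, 3L)
  expect_equal(res$pocpu, 62.5)
})

test_that("subject-side paralogs push POCP past 100% while POCPu stays bounded", {
  a <- proteome_tbl("A", "q1", 100L)
  b <- proteome_tbl("B", c("s1", "s2"), c(100L, 100L))
  hits_ab <- dplyr::bind_rows(hit_tbl("q1", "s1"), hit_tbl("q1", "s2"))
  hits_ba <- dplyr::bind_rows(
    hit_tbl("s1", "q1", query_genome = "B", subject_genome = "A"),
    hit_tbl("s2", "q1", query_genome = "B", subject_genome = "A")
  )
  res <- compute_pair(a, b, hits_ab, hits_ba)
  expect_equal(res$pocp, 400 / 3)          # 133.33: exceeds the nominal cap
  expect_equal(res$pocpu, 100)             # unique matching restores the bound
  expect_lte(res$pocpu, 100)
})

test_that("a fully and uniquely conserved pair scores 100 on both metrics", {
  n <- 5L
  a <- proteome_tbl("A", paste0("p", 1:n), rep(90L, n))
  b <- proteome_tbl("B", paste0("s", 1:n), rep(90L, n))
  hits_ab <- hit_tbl(paste0("p", 1:n), paste0("s", 1:n))
  hits_ba <- hit_tbl(paste0("s", 1:n), paste0("p", 1:n),
                     query_genome = "B", subject_genome = "A")
  res <- compute_pair(a, b, hits_ab, hits_ba)
  expect_equal(res$pocp, 100)
  expect_equal(res$pocpu, 100)
})

test_that("direction mismatches between hit tables and proteomes are errors", {
  inst <- random_pair_instance()
  expect_error(
    compute_pair(inst$proteome_a, inst$proteome_b, inst$hits_ba, inst$hits_ab),
    "direction mismatch"
  )
})

test_that("POCP/POCPu invariants hold on random hit tables", {
  withr::local_seed(1234)
  for (i in 1:50) {
    inst <- random_pair_instance(n_hits = sample(0:30, 1))
    res <- compute_pair(inst$proteome_a, inst$proteome_b,
                        inst$hits_ab, inst$hits_ba)
    expect_lte(res$pocpu, res$pocp)
    expect_gte(res$pocpu, 0)
    expect_lte(res$pocpu, 100)
    expect_gte(res$pocp, 0)

    # symmetry under direction swap
    swapped <- compute_pair(inst$proteome_b, inst$proteome_a,
                            inst$hits_ba, inst$hits_ab)
    expect_equal(swapped$pocp, res$pocp)
    expect_equal(swapped$pocpu, res$pocpu)

    # duplicating hit rows raises POCP but leaves POCPu unchanged
    if (nrow(inst$hits_ab) > 0) {
      dup <- compute_pair(inst$proteome_a, inst$proteome_b,
                          dplyr::bind_rows(inst$hits_ab, inst$hits_ab),
                          inst$hits_ba)
      expect_equal(dup$pocpu, res$pocpu)
      expect_gte(dup$pocp, res$pocp)
    }
  }
})

test_that("non-default thresholds watermark the result", {
  inst <- random_pair_instance()
  res <- compute_pair(inst$proteome_a, inst$proteome_b,
                      inst$hits_ab, inst$hits_ba)
  expect_null(attr(res, "nonstandard_thresholds"))
  res2 <- compute_pair(inst$proteome_a, inst$proteome_b,
                       inst$hits_ab, inst$hits_ba,
                       pocp_thresholds(min_identity_pct = 30))
  expect_equal(attr(res2, "nonstandard_thresholds")$min_identity_pct, 30)
})

test_that("pair TSV output prints the metrics with four decimals", {
  inst <- random_pair_instance()
  res <- compute_pair(inst$proteome_a, inst$proteome_b,
                      inst$hits_ab, inst$hits_ba)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_pair_tsv(res, out)
  txt <- readr::read_tsv(out, show_col_types = FALSE)
  expect_match(as.character(txt$pocp), "^\\d+\\.\\d{4}$")
  expect_equal(as.numeric(txt$pocpu), round(res$pocpu, 4))
})
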