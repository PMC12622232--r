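#' Parse a BLAST-outfmt-6-style protein hit table
#'
#' Reads tabular alignment output (12 standard columns, no header:
#' `qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`; extra trailing columns are ignored) into the package's
#' tidy hit-table format.  Tool dialects differ only in the identity scale:
#' BLAST and DIAMOND report percent identity on \[0, 100\] while MMseqs2
#' reports a fraction on \[0, 1\], which is rescaled to percent on read so
#' every stored identity shares the percent scale.
#'
#' @param path Path to the TSV file (optionally gzip-compressed).
#' @param dialect One of `"blast"`, `"diamond"`, `"mmseqs2"`.
#' @param query_genome,subject_genome Genome ids of the query and subject
#'   proteomes.  Must differ: self-comparisons are banned.
#'
#' @return A hit-table tibble with columns `query_genome`, `subject_genome`,
#'   `query_id`, `subject_id`, `pct_identity`, `aln_length`, `evalue`,
#'   `bitscore`, rows in file order (duplicates preserved).
#' @export
parse_hits <- function(path, dialect = c("blast", "diamond", "mmseqs2"),
                       query_genome, subject_genome) {
  dialect <- match.arg(dialect)
  check_genome_pair(query_genome, subject_genome)
  if (!file.exists(path)) abort(paste0("hit table not found: ", path))

  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(.empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    abort(paste0(
      "malformed hit table row(s) (fewer than 12 tab-separated columns): line ",
      paste(head(which(nf < 12L), 5L), collapse = ", ")
    ))
  }
  col <- function(i) vapply(fields, `[[`, character(1L), i)
  num <- function(i, what) {
    x <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(x)) {
      abort(paste0(
        "non-numeric ", what, " in hit table: line ",
        paste(head(which(is.na(x)), 5L), collapse = ", ")
      ))
    }
    x
  }

  pident <- num(3L, "pident")
  if (dialect == "mmseqs2") {
    if (any(pident < 0 | pident > 1)) {
      abort("mmseqs2 identity outside [0, 1]; wrong dialect?")
    }
    pident <- pident * 100
  } else if (any(pident < 0 | pident > 100)) {
    abort(paste0(dialect, " identity outside [0, 100]"))
  }

  aln_length <- num(4L, "length")
  if (any(aln_length < 1 | aln_length != round(aln_length))) {
    abort("alignment length must be a positive integer")
  }
  evalue <- num(11L, "evalue")
  if (any(evalue < 0)) abort("negative e-value in hit table")

  tibble(
    query_genome = query_genome,
    subject_genome = subject_genome,
    query_id = col(1L),
    subject_id = col(2L),
    pct_identity = pident,
    aln_length = as.integer(aln_length),
    evalue = evalue,
    bitscore = num(12L, "bitscore")
  )
}

check_genome_pair <- function(query_genome, subject_genome) {
  stopifnot(
    is.character(query_genome), length(query_genome) == 1L, nzchar(query_genome),
    is.character(subject_genome), length(subject_genome) == 1L, nzchar(subject_genome)
  )
  if (query_genome == subject_genome) {
    abort("self-comparison banned: query and subject genome ids are identical")
  }
  invisible(NULL)
}

#' Write a hit table to BLAST outfmt-6 TSV
#'
#' Inverse of [parse_hits()] on the percent identity scale; the columns not
#' carried by the tidy hit table (`mismatch`, `gapopen`, coordinates) are
#' written as zeros.
#'
#' @param hits A hit-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  check_hits(hits)
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = hits$pct_identity, length = hits$aln_length,
    mismatch = 0L, gapopen = 0L, qstart = 0L, qend = 0L,
    sstart = 0L, send = 0L,
    evalue = hits$evalue, bitscore = hits$bitscore
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

check_hits <- function(hits) {
  if (!is.data.frame(hits) || !all(.hit_cols %in% names(hits))) {
    abort(paste0(
      "expected a hit-table tibble with columns ",
      paste(.hit_cols, collapse = ", ")
    ))
  }
  invisible(hits)
}

#' List the shipped alignment tool profiles
#'
#' @return A tibble with columns `profile`, `tool`, `dialect`.
#' @export
list_profiles <- function() {
  cfg <- load_profiles()
  tibble(
    profile = names(cfg),
    tool = purrr::map_chr(cfg, "tool"),
    dialect = purrr::map_chr(cfg, "dialect")
  )
}

load_profiles <- function() {
  yaml::read_yaml(system.file("extdata", "tool_profiles.yaml",
                              package = "pocpu", mustWork = TRUE))
}

#' Run an external alignment tool and ingest its hit table
#'
#' Invokes one of the shipped tool profiles (BLASTP with or without a
#' prebuilt database, DIAMOND at four sensitivities, MMseqs2 at four
#' sensitivities) on a query/subject FASTA pair and parses the resulting
#' tabular output with the profile's dialect.  Every command line executed
#' is appended to the run log.
#'
#' @param query_fasta,subject_fasta Protein FASTA paths.
#' @param tool_profile Profile name; see [list_profiles()].
#' @param query_genome,subject_genome Genome ids for the resulting hit
#'   table; default to the FASTA base names.
#' @param run_log Optional path of a plain-text run log; one line per
#'   command with timestamp, profile, command and exit status.
#' @return A hit-table tibble, as from [parse_hits()].
#' @export
run_external <- function(query_fasta, subject_fasta, tool_profile,
                         query_genome = strip_fasta_ext(query_fasta),
                         subject_genome = strip_fasta_ext(subject_fasta),
                         run_log = NULL) {
  cfg <- load_profiles()
  if (!tool_profile %in% names(cfg)) {
    abort(paste0(
      "unknown tool profile '", tool_profile, "'; available: ",
      paste(names(cfg), collapse = ", ")
    ))
  }
  check_genome_pair(query_genome, subject_genome)
  profile <- cfg[[tool_profile]]
  if (Sys.which(profile$tool) == "") {
    abort(paste0(
      "tool '", profile$tool, "' required by profile '", tool_profile,
      "' was not found on PATH"
    ))
  }
  for (fa in c(query_fasta, subject_fasta)) {
    if (!file.exists(fa)) abort(paste0("FASTA not found: ", fa))
  }

  tmpdir <- tempfile("pocpu_run_")
  dir.create(tmpdir)
  on.exit(unlink(tmpdir, recursive = TRUE), add = TRUE)
  out <- file.path(tmpdir, "hits.tsv")

  for (template in profile$commands) {
    cmd <- fill_template(template, query = query_fasta, subject = subject_fasta,
                         out = out, tmpdir = tmpdir)
    status <- system(paste(cmd, "2>", shQuote(file.path(tmpdir, "stderr.txt"))))
    log_run(run_log, tool_profile, cmd, status)
    if (status != 0L) {
      err <- tryCatch(
        readr::read_file(file.path(tmpdir, "stderr.txt")),
        error = function(e) ""
      )
      abort(paste0(
        "profile '", tool_profile, "' command failed (exit ", status, "): ",
        cmd, "\n", err
      ))
    }
  }
  if (!file.exists(out)) {
    abort(paste0("profile '", tool_profile, "' produced no output table"))
  }
  parse_hits(out, dialect = profile$dialect,
             query_genome = query_genome, subject_genome = subject_genome)
}

strip_fasta_ext <- function(path) {
  sub("\\.(fa|faa|fasta)(\\.gz)?$", "", basename(path))
}

fill_template <- function(template, ...) {
  subs <- list(...)
  for (key in names(subs)) {
    template <- gsub(paste0("{", key, "}"), subs[[key]], template, fixed = TRUE)
  }
  template
}

log_run <- function(run_log, profile, cmd, status) {
  if (is.null(run_log)) return(invisible(NULL))
  line <- paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), profile, cmd,
                paste0("exit=", status), sep = "\t")
  cat(line, "\n", sep = "", file = run_log, append = TRUE)
  invisible(NULL)
}
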