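.aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Specify a synthetic proteome pair
#'
#' Describes a pair of genomes built from a shared ortholog core, optional
#' paralog duplications of core proteins, per-genome accessory proteins,
#' and point substitutions applied to genome b's core copies.  Accessory
#' proteins are i.i.d. uniform-residue sequences whose expected pairwise
#' identity to anything (~5%) sits far below the 40% conservation filter,
#' so they dilute the denominator without contributing matches.
#'
#' @param n_core Number of shared core proteins (>= 0).
#' @param n_acc_a,n_acc_b Accessory proteins private to genome a / b.
#' @param dup_a,dup_b Number of core proteins duplicated (exact paralog
#'   copies of their within-genome template) in genome a / b; at most
#'   `n_core` each.
#' @param sub_rate Per-site substitution probability on \[0, 1) applied to
#'   genome b's core copies (a substituted site changes to a different
#'   residue, drawn uniformly).
#' @param length_range Integer interval for protein lengths, default
#'   `c(80, 120)`: long enough that random identity concentrates well
#'   below the 40% filter.
#' @param seed RNG seed making the pair reproducible.
#' @return An object of class `pocp_pair_spec`.
#' @export
pair_spec <- function(n_core, n_acc_a = 0L, n_acc_b = 0L,
                      dup_a = 0L, dup_b = 0L, sub_rate = 0,
                      length_range = c(80L, 120L), seed = 1L) {
  stopifnot(
    n_core >= 0, n_acc_a >= 0, n_acc_b >= 0,
    dup_a >= 0, dup_b >= 0, dup_a <= n_core, dup_b <= n_core,
    is.numeric(sub_rate), sub_rate >= 0, sub_rate < 1,
    length(length_range) == 2L, length_range[[1L]] >= 1,
    length_range[[1L]] <= length_range[[2L]],
    is.numeric(seed), length(seed) == 1L
  )
  structure(
    list(n_core = as.integer(n_core),
         n_acc_a = as.integer(n_acc_a), n_acc_b = as.integer(n_acc_b),
         dup_a = as.integer(dup_a), dup_b = as.integer(dup_b),
         sub_rate = sub_rate,
         length_range = as.integer(length_range),
         seed = as.integer(seed)),
    class = "pocp_pair_spec"
  )
}

random_protein <- function(len) {
  paste(sample(.aa20, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(seq, sub_rate) {
  if (sub_rate == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- runif(length(chars)) < sub_rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(aa) {
      sample(setdiff(.aa20, aa), 1L)
    }, character(1L))
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic proteome pair with known ground truth
#'
#' Builds the two proteomes described by a [pair_spec()].  Genome a holds
#' the core proteins, `dup_a` exact paralog copies of the first `dup_a`
#' core proteins, and `n_acc_a` random accessory proteins; genome b holds
#' the core proteins with per-site substitutions at `sub_rate`, `dup_b`
#' copies of its own (mutated) templates, and `n_acc_b` accessory.
#' Deterministic under the spec's seed.
#'
#' In the no-mutation case every core copy and every duplicate is a query
#' with a passing unique match, so the expected POCPu has the closed form
#' `100 * (n_core + dup_a + n_core + dup_b) / (t_a + t_b)`; it is returned
#' as `expected_pocpu` for parameter-recovery checks.
#'
#' @param spec A [pair_spec()].
#' @param genome_a,genome_b Genome ids for the two proteomes.
#' @return A list with elements `proteome_a`, `proteome_b` (proteome
#'   tibbles), `expected_pocpu` (closed-form POCPu for `sub_rate = 0`),
#'   and `spec`.
#' @export
generate_pair <- function(spec, genome_a = "synthA", genome_b = "synthB") {
  stopifnot(inherits(spec, "pocp_pair_spec"))
  check_genome_pair(genome_a, genome_b)
  t_a <- spec$n_core + spec$dup_a + spec$n_acc_a
  t_b <- spec$n_core + spec$dup_b + spec$n_acc_b
  if (t_a == 0L || t_b == 0L) {
    abort("spec yields an empty proteome; each genome needs at least one protein")
  }

  # sample() treats a length-one vector as an upper bound, so guard the
  # degenerate fixed-length case explicitly
  sample_lengths <- function(n) {
    range <- spec$length_range[[1L]]:spec$length_range[[2L]]
    if (length(range) == 1L) rep(range, n) else sample(range, n, replace = TRUE)
  }

  withr::with_seed(spec$seed, {
    core <- vapply(sample_lengths(spec$n_core), random_protein, character(1L))

    core_b <- vapply(core, mutate_protein, character(1L),
                     sub_rate = spec$sub_rate, USE.NAMES = FALSE)

    acc <- function(n, prefix) {
      if (n == 0L) return(setNames(character(), character()))
      setNames(vapply(sample_lengths(n), random_protein, character(1L)),
               sprintf("%s%03d", prefix, seq_len(n)))
    }

    seqs_a <- c(
      setNames(core, sprintf("a_core%03d", seq_len(spec$n_core))),
      setNames(core[seq_len(spec$dup_a)],
               sprintf("a_dup%03d", seq_len(spec$dup_a))),
      acc(spec$n_acc_a, "a_acc")
    )
    seqs_b <- c(
      setNames(core_b, sprintf("b_core%03d", seq_len(spec$n_core))),
      setNames(core_b[seq_len(spec$dup_b)],
               sprintf("b_dup%03d", seq_len(spec$dup_b))),
      acc(spec$n_acc_b, "b_acc")
    )

    list(
      proteome_a = new_proteome(genome_a, names(seqs_a), unname(seqs_a)),
      proteome_b = new_proteome(genome_b, names(seqs_b), unname(seqs_b)),
      expected_pocpu = 100 * (spec$n_core + spec$dup_a +
                                spec$n_core + spec$dup_b) / (t_a + t_b),
      spec = spec
    )
  })
}

#' Specify a synthetic family of labeled pair values
#'
#' Describes one bacterial family for direct labeled-value generation:
#' genera with genome counts, and the percent intervals from which
#' within-genus and between-genera POCPu values are drawn.  Disjoint
#' intervals emulate a family whose genera are neatly separable; an
#' overlap emulates families where no threshold delineates perfectly.
#'
#' @param family Family name.
#' @param genera Genome count per genus: a named integer vector
#'   (names = genus) or a data frame with columns `genus`, `n_genomes`.
#' @param within_range,between_range Percent intervals on \[0, 100\] for
#'   within-genus / between-genera values.
#' @param seed RNG seed.
#' @return An object of class `pocp_family_spec`.
#' @export
family_spec <- function(family, genera, within_range = c(70, 90),
                        between_range = c(10, 30), seed = 1L) {
  if (is.data.frame(genera)) {
    stopifnot(all(c("genus", "n_genomes") %in% names(genera)))
    genera <- setNames(as.integer(genera$n_genomes), genera$genus)
  }
  stopifnot(
    is.character(family), nzchar(family),
    length(genera) >= 1L, all(genera >= 1L), !is.null(names(genera)),
    all(nzchar(names(genera))),
    length(within_range) == 2L, length(between_range) == 2L,
    all(within_range >= 0), all(within_range <= 100),
    within_range[[1L]] <= within_range[[2L]],
    all(between_range >= 0), all(between_range <= 100),
    between_range[[1L]] <= between_range[[2L]],
    is.numeric(seed), length(seed) == 1L
  )
  structure(
    list(family = family, genera = genera,
         within_range = as.numeric(within_range),
         between_range = as.numeric(between_range),
         seed = as.integer(seed)),
    class = "pocp_family_spec"
  )
}

#' Generate a labeled multi-family POCPu dataset
#'
#' For each [family_spec()], enumerates the full within-family pair set
#' (via [build_pair_set()] on a synthetic taxonomy) and draws each pair's
#' value uniformly from the within-genus or between-genera interval
#' according to its label.  Deterministic under each spec's seed.
#'
#' @param specs A list of [family_spec()] objects (a single spec is
#'   accepted); an empty list yields an empty tibble.
#' @return A labeled-value tibble with columns `genome_a`, `genome_b`,
#'   `family`, `same_genus`, `value`.
#' @export
generate_family_dataset <- function(specs) {
  if (inherits(specs, "pocp_family_spec")) specs <- list(specs)
  stopifnot(is.list(specs))
  empty <- tibble(genome_a = character(), genome_b = character(),
                  family = character(), same_genus = logical(),
                  value = double())
  if (length(specs) == 0L) return(empty)
  purrr::map(specs, generate_family_values) |>
    dplyr::bind_rows()
}

generate_family_values <- function(spec) {
  stopifnot(inherits(spec, "pocp_family_spec"))
  tax <- purrr::imap(spec$genera, function(n, genus) {
    tibble(
      genome_id = sprintf("%s_%s_%02d", spec$family, genus, seq_len(n)),
      family = spec$family, genus = genus, species = NA_character_
    )
  }) |>
    dplyr::bind_rows()
  pairs <- build_pair_set(tax)
  withr::with_seed(spec$seed, {
    dplyr::mutate(
      pairs,
      value = ifelse(
        .data$same_genus,
        runif(dplyr::n(), spec$within_range[[1L]], spec$within_range[[2L]]),
        runif(dplyr::n(), spec$between_range[[1L]], spec$between_range[[2L]])
      )
    )
  })
}
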