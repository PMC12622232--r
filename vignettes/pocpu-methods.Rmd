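---
title: "POCP and POCPu: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{POCP and POCPu: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocpu)
```

## The metrics

For two genomes *Q* and *S* with `T_Q` and `T_S` predicted proteins, the
percentage of conserved proteins is

$$POCP = \frac{C_{QS} + C_{SQ}}{T_Q + T_S} \times 100\%$$

and its unique-match variant is

$$POCPu = \frac{C_{uQS} + C_{uSQ}}{T_Q + T_S} \times 100\%.$$

A query protein match is *conserved* when it passes all three filter
conditions — e-value < 1e-5, percent identity > 40, aligned region > 50%
of the query protein length. Every comparison is strict: a hit at identity
exactly 40, coverage exactly half, or e-value exactly 1e-5 is excluded.
Many reimplementations silently use `>=`; this package does not, because
the definition is written with strict inequalities and the choice is
visible at the boundary.

The two numerators differ only in counting. `C_QS` is the number of
surviving hit *rows* in the Q→S direction: a query protein matching k
subjects (duplicated genes) contributes k, which is the only reading under
which POCP can exceed 100%, as observed in paralog-rich genomes. `C_uQS`
counts *distinct query proteins* with at least one surviving hit, so each
protein contributes at most once per direction and POCPu is bounded by
100%. `count_conserved()` returns both counts from the same filtered
table; `compute_pair()` assembles both metrics from the two directions
with no intermediate rounding (four-decimal formatting happens only in
`write_pair_tsv()`).

Coverage is computed as `aln_length > 0.5 * query_length`, using the
alignment-column count (gaps included) from the standard tabular format.
"Aligned region" could also be read as the query-span `qend - qstart + 1`;
the length column is preferred because it is the one field the 12-column
format guarantees identically across BLAST, DIAMOND and MMseqs2, so the
filter behaves the same regardless of which tool produced the table.
Query lengths come from the proteome itself, with `*` stop characters
stripped on FASTA read so Prodigal-style trailing stops cannot inflate the
denominator of the coverage ratio.

Empty proteomes are rejected at read time rather than producing zero-count
results: with `T_Q + T_S = 0` both formulas are undefined, and a silent 0
would look like a biological signal.

## Hit tables and identity scales

All hit tables are tidy tibbles with one row per reported query–subject
match and identities stored on the percent scale. `parse_hits()` accepts
the three tool dialects; the only dialect-specific behaviour is the
identity scale, which MMseqs2 reports on [0, 1] and is rescaled to percent
on read. Rows are kept in file order, duplicates included, because POCP's
row counting is sensitive to exactly what the tool reported.

Hit tables are directional. The pair layer, not the aligner, assembles the
two directions of a comparison, mirroring the `C_QS + C_SQ` structure of
the formulas, and `compute_pair()` verifies the declared direction of each
table against the proteomes before counting.

## The built-in aligner

`builtin_align()` performs all-vs-all Smith–Waterman local alignment
(BLOSUM62, gap open 11, gap extend 1, via `Biostrings::pairwiseAlignment`)
and reports at most one hit — the best local alignment — per query–subject
pair. Multiple HSPs per pair are deliberately not emitted: one-per-pair
makes POCP's row counting reproducible and is the simplest contract to
document, whereas external tools differ in HSP handling (a documented
source of non-comparability for POCP, though not for POCPu).

Reportability uses an approximate Karlin–Altschul e-value with gapped
BLOSUM62 constants (λ = 0.267, K = 0.041) and search space = query length
× total subject residues, keeping alignments with E < 10. Two properties
of this approximation are worth knowing:

* it is asymmetric between directions when the two proteomes differ in
  size (the search space term changes), so near-threshold hits may be
  reported in one direction only; with equal protein counts and equal
  lengths reportability is exactly symmetric, which is how the symmetry
  test instantiates it;
* E < 10 is permissive by construction — for ~100-residue random proteins
  the expected best chance score sits near the E ≈ 1–10 region, so a large
  fraction of unrelated pairs is *reportable*. This is harmless: the
  conservation filter re-applies the strict e-value < 1e-5 cutoff (raw
  score ≳ 74 under these constants) together with the identity and
  coverage conditions downstream, and in practice no random hit survives
  it. Filtering therefore never depends on which aligner produced the
  table.

External tools run through `run_external()` with the ten shipped profiles
(BLASTP, BLASTP-with-database, DIAMOND at four sensitivities, MMseqs2 at
four sensitivities), each reporting at e-value ≤ 1e-5 and logging every
command line executed. The profile command templates follow the tools'
documented tabular-output invocations.

## Pair framework

`select_genomes()` applies the two study-design criteria in their stated
order: first drop genomes whose genus has fewer than 10 members, then drop
families left with fewer than 2 genera. The order matters — a family can
lose its second genus to the genus-size rule — and the nested reading
(genus filter first) follows the criteria's own numbering.

`build_pair_set()` enumerates unordered within-family pairs only
(`genome_a < genome_b` canonically), banning self-pairs; cross-family
comparisons are excluded by design to keep the comparison landscape
within the rank where genus boundaries are decided. The positive class for
evaluation is "both genomes belong to the same genus".

## Evaluation layer

`confusion_at_threshold()` implements the decision rule "same genus iff
value > threshold"; a value exactly at the threshold is predicted
negative, matching the > 50% / ≤ 50% split of the reference rule. The MCC
follows the standard formula; when any marginal sum is zero the
coefficient is undefined and the package returns 0, the
random-classification value, as a documented convention. Counts are
converted to doubles before multiplying, which keeps the products exact
far beyond realistic pair counts.

MCC as a function of the threshold is piecewise constant with breakpoints
at the observed values, so `optimize_threshold()`'s default method is an
exact sweep: candidates are the midpoints between consecutive distinct
sorted values, an extreme below the minimum, the maximum itself, and the
default threshold (50). The sweep therefore evaluates one representative
of every equivalence class of thresholds and its maximum is the global
maximum. Ties are broken toward the candidate closest to 50, then toward
the smaller candidate — including 50 among the candidates makes the
tie-break return exactly 50 whenever the default lies on an optimal
plateau. A continuous bounded 1-D maximization mode (`method =
"optimize"`, `stats::optimize` over the value range) is provided for
parity with derivative-free optimization workflows; on a step function it
can stall on plateaus, and by construction it never beats the sweep — a
property the tests assert rather than assume.

`evaluate_per_family()` reports one row per family plus a pooled "global"
row (the global MCC is computed over pooled pairs, not as an average of
family MCCs). Families containing a single class cannot be optimized and
are flagged instead of erroring, so one degenerate family does not abort a
dataset-wide report.

`method_concordance()` regresses the reference method's values on a
candidate method's values by OLS and reports R², slope, intercept and the
F-test p-value; the p-value carries no decision role. Degenerate inputs
(fewer than 3 pairs, zero variance on either side) are errors.

## The synthetic generator

`generate_pair()` emulates the one mechanism that separates the two
metrics — paralogy — plus the two nuisance processes that matter for the
filter: sequence divergence and unshared gene content. A pair consists of
a shared core (identical across genomes before mutation), exact paralog
copies of core templates within each genome, and per-genome accessory
proteins drawn i.i.d. with uniform residue frequencies. Defaults encode
desk-scale study conditions: protein lengths uniform on [80, 120]
(long enough that random identity concentrates far below the 40% filter),
substitution rate 0, no accessory or duplicates unless requested.
Uniform amino-acid frequencies are a deliberate simplification — the
filter's behaviour, not compositional realism, is what the generator must
expose.

Because duplicates are exact copies of their within-genome template and
mutation applies only to the cross-genome core, the no-mutation POCPu has
the closed form `100 (n_core + dup_a + n_core + dup_b) / (T_a + T_b)`,
which the parameter-recovery tests compare against the full stack
(builtin aligner → filter → POCPu). What the generator does *not* emulate:
indels, gene gain/loss along a phylogeny, codon-level evolution, realistic
paralog divergence, or genome-size structure. Passing tests therefore
demonstrate that the metric layer is computed correctly and behaves as
designed under controlled conditions — not that POCPu delineates real
genera, which is an empirical matter settled on real proteomes.

`generate_family_dataset()` skips sequences entirely and draws labeled
POCPu values from family-specific within/between intervals, emulating the
three archetypes seen across real families — neatly distinct, overlapping,
and in between — so the threshold machinery can be tested against known
separation gaps.

## Problem sizes and numerical tolerances

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in a few minutes on one core: property suites use
1,000 random hit-table instances and 200 random labeled-value instances
(up to 1,000 points each); the full-stack recovery grid crosses core sizes
{2, 5, 8} with accessory sizes {0, 3, 6} over 5 seeds, with a ±5
percentage-point band around the closed form to absorb rare accessory
false positives. Exact-arithmetic checks (sweep vs. brute force, metric
identities) use tolerances of 1e-12; statistical reproductions are checked
at the precision the reference values are printed with.

## Known limitations

* POCP values inherit the reporting behaviour of the aligner that produced
  the hits (HSP multiplicity, max-target caps); values computed with
  different aligner settings are not comparable. POCPu is robust to this,
  which is an argument in its favour.
* The built-in aligner's e-value is an acknowledged approximation for
  reportability only; it is not a substitute for BLAST statistics at
  scale.
* Non-default filter thresholds are supported but watermark the output
  (`nonstandard_thresholds` attribute), since published POCP/POCPu values
  assume the canonical filter.
* Family-specific thresholds optimized on the data they are evaluated on
  are optimistic by construction; `delta_mcc` quantifies the improvement
  but not its generalisation.
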