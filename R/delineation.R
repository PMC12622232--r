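#' Confusion matrix for a genus-delineation threshold
#'
#' Applies the decision rule "predict same genus iff the POCP/POCPu value is
#' strictly greater than the threshold" to labeled pair values.  A value
#' exactly at the threshold is predicted different-genus, mirroring the
#' `> 50%` / `<= 50%` split of the reference rule.  The positive event is
#' "both genomes belong to the same genus": a same-genus pair above the
#' threshold is a true positive, a different-genera pair above it a false
#' positive, and so on.
#'
#' @param values A tibble of labeled pair values with columns `value`
#'   (percent, >= 0) and `same_genus` (logical).
#' @param threshold Decision threshold in percent (default 50, the
#'   reference genus boundary).
#' @return A one-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at_threshold <- function(values, threshold = 50) {
  check_labeled_values(values)
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  pred_pos <- values$value > threshold
  tibble(
    tp = sum(pred_pos & values$same_genus),
    fp = sum(pred_pos & !values$same_genus),
    tn = sum(!pred_pos & !values$same_genus),
    fn = sum(!pred_pos & values$same_genus)
  )
}

check_labeled_values <- function(values, require_family = FALSE) {
  if (!is.data.frame(values) || !all(c("value", "same_genus") %in% names(values))) {
    abort("expected a tibble with columns value and same_genus")
  }
  if (nrow(values) == 0L) abort("no labeled values: confusion matrix undefined")
  if (!is.logical(values$same_genus)) abort("same_genus must be logical")
  if (any(values$value < 0)) abort("POCP/POCPu values must be >= 0")
  if (require_family && !"family" %in% names(values)) {
    abort("expected a family column")
  }
  invisible(values)
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#'
#' Ranges over \[-1, 1\]: 1 is perfect classification, 0 random, -1 perfect
#' misclassification.  When any of the four marginal sums is zero the
#' formula is undefined; by convention the denominator is treated as 1 and
#' the result is 0, the random-classification value.  Products are formed
#' in double precision, which is exact for counts up to ~9e15 and therefore
#' far beyond realistic pair counts.
#'
#' @param cm A confusion matrix: a one-row data frame or named vector/list
#'   with entries `tp`, `fp`, `tn`, `fn`.
#' @return A single number in \[-1, 1\].
#' @export
mcc <- function(cm) {
  cm <- as.list(cm)
  need <- c("tp", "fp", "tn", "fn")
  if (!all(need %in% names(cm))) {
    abort("confusion matrix needs entries tp, fp, tn, fn")
  }
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  tn <- as.numeric(cm$tn); fn <- as.numeric(cm$fn)
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  margins <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(margins == 0)) return(0)
  (tp * tn - fp * fn) / sqrt(prod(margins))
}

#' Find the MCC-maximizing genus-delineation threshold
#'
#' MCC as a function of the threshold is a step function that only changes
#' where the threshold crosses an observed value, so the default `"sweep"`
#' method evaluates it exactly: candidate thresholds are the midpoints
#' between consecutive distinct sorted values, plus the extremes (below the
#' minimum and at the maximum) and the reference default, and the global
#' maximum over these candidates is the global maximum over all real
#' thresholds.  Ties are broken toward the candidate closest to the default
#' (50), then toward the smaller candidate.  The `"optimize"` method
#' instead runs continuous bounded 1-D maximization ([stats::optimize()])
#' over the value range; it is provided for compatibility with
#' derivative-free optimization workflows but can stall on plateaus of the
#' step function and by construction never beats the sweep.
#'
#' @param values A labeled-value tibble (columns `value`, `same_genus`)
#'   containing at least one pair of each class.
#' @param default_threshold Reference threshold used for `mcc_at_default`
#'   and tie-breaking. Default 50.
#' @param method `"sweep"` (exact, default) or `"optimize"` (continuous).
#' @param family Label stored on the result (default `"global"`).
#' @return An object of class `pocp_threshold_opt`: a list with elements
#'   `family`, `threshold`, `mcc_at_default`, `mcc_at_threshold`,
#'   `delta_mcc`, `method`, `n`, `n_within`, `n_between`,
#'   `default_threshold`.  Use [generics::tidy()] for a one-row tibble.
#' @export
optimize_threshold <- function(values, default_threshold = 50,
                               method = c("sweep", "optimize"),
                               family = "global") {
  method <- match.arg(method)
  check_labeled_values(values)
  n_within <- sum(values$same_genus)
  n_between <- sum(!values$same_genus)
  if (n_within == 0L || n_between == 0L) {
    abort("cannot optimize with one class: need both same-genus and different-genera pairs")
  }

  mcc_at <- function(t) {
    vapply(t, function(ti) mcc(confusion_at_threshold(values, ti)), numeric(1L))
  }
  mcc_default <- mcc_at(default_threshold)

  if (method == "sweep") {
    v <- sort(unique(values$value))
    candidates <- unique(c(
      default_threshold,
      max(v[[1L]] - 1, 0),
      if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2,
      v[[length(v)]]
    ))
    scores <- mcc_at(candidates)
    best <- max(scores)
    top <- candidates[scores >= best - 1e-12]
    top <- top[order(abs(top - default_threshold), top)]
    threshold <- top[[1L]]
    mcc_best <- best
  } else {
    opt <- optimize(mcc_at, range(values$value), maximum = TRUE,
                    tol = .Machine$double.eps^0.25)
    threshold <- opt$maximum
    mcc_best <- opt$objective
  }

  structure(
    list(
      family = family, threshold = threshold,
      mcc_at_default = mcc_default, mcc_at_threshold = mcc_best,
      delta_mcc = mcc_best - mcc_default,
      method = method, n = nrow(values),
      n_within = n_within, n_between = n_between,
      default_threshold = default_threshold
    ),
    class = "pocp_threshold_opt"
  )
}

#' @export
print.pocp_threshold_opt <- function(x, ...) {
  cat("Genus-delineation threshold (", x$method, ") for ", x$family, ":\n",
      "  threshold  ", sprintf("%.1f", x$threshold), "%\n",
      "  MCC at ", x$default_threshold, "%: ", sprintf("%.2f", x$mcc_at_default),
      "; at optimum: ", sprintf("%.2f", x$mcc_at_threshold),
      " (delta ", sprintf("%+.2f", x$delta_mcc), ")\n",
      "  pairs: ", x$n, " (", x$n_within, " within-genus, ",
      x$n_between, " between-genera)\n", sep = "")
  invisible(x)
}

#' @rdname optimize_threshold
#' @param x A `pocp_threshold_opt` object.
#' @param ... Unused.
#' @export
tidy.pocp_threshold_opt <- function(x, ...) {
  tibble(
    family = x$family, threshold = x$threshold,
    mcc_at_default = x$mcc_at_default, mcc_at_threshold = x$mcc_at_threshold,
    delta_mcc = x$delta_mcc, method = x$method
  )
}

#' @rdname optimize_threshold
#' @export
glance.pocp_threshold_opt <- function(x, ...) {
  tibble(
    n = x$n, n_within = x$n_within, n_between = x$n_between,
    mcc_at_threshold = x$mcc_at_threshold, method = x$method
  )
}

#' Per-family threshold evaluation
#'
#' Runs [optimize_threshold()] within each family and once globally over
#' the pooled pairs (reported as family `"global"`).  Families containing
#' only one class (all within-genus or all between-genera pairs) cannot be
#' optimized; they are reported with `mcc_at_default` only and flagged
#' `"single_class"`.
#'
#' @param values A labeled-value tibble with columns `family`, `value`,
#'   `same_genus`.
#' @param default_threshold Reference threshold. Default 50.
#' @return A tibble with one row per family plus the global row: `family`,
#'   `n_pairs`, `n_within`, `n_between`, `threshold`, `mcc_at_default`,
#'   `mcc_at_threshold`, `delta_mcc`, `flag`.
#' @export
evaluate_per_family <- function(values, default_threshold = 50) {
  check_labeled_values(values, require_family = TRUE)
  one <- function(df, label) {
    n_within <- sum(df$same_genus)
    n_between <- sum(!df$same_genus)
    base <- tibble(
      family = label, n_pairs = nrow(df),
      n_within = n_within, n_between = n_between
    )
    if (n_within == 0L || n_between == 0L) {
      return(dplyr::mutate(
        base,
        threshold = NA_real_,
        mcc_at_default = mcc(confusion_at_threshold(df, default_threshold)),
        mcc_at_threshold = NA_real_, delta_mcc = NA_real_,
        flag = "single_class"
      ))
    }
    opt <- optimize_threshold(df, default_threshold, family = label)
    dplyr::mutate(
      base,
      threshold = opt$threshold, mcc_at_default = opt$mcc_at_default,
      mcc_at_threshold = opt$mcc_at_threshold, delta_mcc = opt$delta_mcc,
      flag = ""
    )
  }
  per_family <- values |>
    dplyr::group_by(.data$family) |>
    dplyr::group_map(~ one(.x, .y$family)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(one(values, "global"), per_family)
}

#' Write the per-family evaluation report
#'
#' @param report Output of [evaluate_per_family()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation_tsv <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}
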