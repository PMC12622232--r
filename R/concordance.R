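#' Concordance of an alignment method against the reference
#'
#' Ordinary least-squares regression of the reference method's POCP (or
#' POCPu) values on a candidate method's values for the same genome pairs.
#' The coefficient of determination R-squared is the interpretable, bounded
#' goodness-of-fit measure used to judge whether a faster aligner can
#' replace the reference; the classical OLS F-test p-value is reported but
#' carries no decision role.
#'
#' @param values_x Candidate-method values (numeric), one per genome pair.
#' @param values_y Reference-method values for the same pairs, same order.
#' @param method Optional label for the candidate method.
#' @return An object of class `pocp_concordance`: a list with `r_squared`,
#'   `slope`, `intercept`, `n`, `p_value`, `method`, and the underlying
#'   `lm` fit as `fit`.  Use [generics::tidy()] / [generics::glance()] for
#'   tibble views.
#' @export
method_concordance <- function(values_x, values_y, method = "method") {
  stopifnot(is.numeric(values_x), is.numeric(values_y))
  if (length(values_x) != length(values_y)) {
    abort("paired value vectors must have equal length")
  }
  if (anyNA(values_x) || anyNA(values_y)) abort("missing values in input")
  n <- length(values_x)
  if (n < 3L) abort("need at least 3 paired values for a regression")
  if (stats::var(values_x) == 0) abort("candidate values have zero variance")
  if (stats::var(values_y) == 0) abort("reference values have zero variance")

  fit <- lm(y ~ x, data = data.frame(x = values_x, y = values_y))
  sm <- summary(fit)
  p_value <- unname(stats::pf(sm$fstatistic[["value"]], sm$fstatistic[["numdf"]],
                              sm$fstatistic[["dendf"]], lower.tail = FALSE))
  structure(
    list(
      r_squared = sm$r.squared,
      slope = unname(coef(fit)[["x"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      n = n, p_value = p_value, method = method, fit = fit
    ),
    class = "pocp_concordance"
  )
}

#' @export
print.pocp_concordance <- function(x, ...) {
  cat("Method concordance (", x$method, " vs reference, n = ", x$n, "):\n",
      "  R-squared = ", sprintf("%.7f", x$r_squared),
      " (p ", if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3g", x$p_value),
      ")\n",
      "  reference ~ ", sprintf("%.4f", x$intercept), " + ",
      sprintf("%.4f", x$slope), " * method\n", sep = "")
  invisible(x)
}

#' @rdname method_concordance
#' @param x A `pocp_concordance` object.
#' @param ... Unused.
#' @export
tidy.pocp_concordance <- function(x, ...) {
  tibble(
    method = x$method,
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname method_concordance
#' @export
glance.pocp_concordance <- function(x, ...) {
  tibble(
    method = x$method, r_squared = x$r_squared, slope = x$slope,
    intercept = x$intercept, n = x$n, p_value = x$p_value
  )
}

#' Write a concordance report TSV
#'
#' @param results A list of `pocp_concordance` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concordance_tsv <- function(results, path) {
  if (inherits(results, "pocp_concordance")) results <- list(results)
  report <- dplyr::bind_rows(purrr::map(results, glance)) |>
    dplyr::select("method", "r_squared", "slope", "intercept", "n")
  readr::write_tsv(report, path, progress = FALSE)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
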