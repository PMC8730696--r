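#' Chi-squared goodness-of-fit test for a Mendelian segregation ratio
#'
#' Tests observed phenotype-class counts against a theoretical segregation
#' ratio (3:1 for an F2 under a monogenic recessive model, 1:1 for a
#' backcross, and so on). The statistic is
#' \deqn{\chi^2 = \sum_i (|O_i - E_i| - c)^2 / E_i}
#' with expected counts \eqn{E_i = N r_i / \sum r} and \eqn{c = 0.5} (the
#' Yates continuity correction) when `correction = TRUE` and the test has one
#' degree of freedom, else \eqn{c = 0}. P-values are right-tail chi-squared
#' with `length(observed) - 1` degrees of freedom.
#'
#' The continuity correction defaults to on for two-class tests, the
#' convention under which published backcross segregation tables for this
#' kind of cross are reproduced exactly. For more than two classes a
#' requested correction is ignored with a warning.
#'
#' @param observed Non-negative integer vector of observed class counts.
#' @param ratio Positive numeric vector of theoretical ratio components,
#'   same length as `observed` (e.g. `c(3, 1)`).
#' @param correction Apply the Yates continuity correction? Only honoured
#'   when `df == 1`. Default `TRUE`.
#' @param labels Optional class labels, recycled into the result.
#'
#' @return An object of class `seg_test`: a list with elements `chisq`,
#'   `df`, `p_value`, `correction`, `observed`, `expected`, `ratio`,
#'   `labels`. Use [tidy()] / [glance()] for a tibble view.
#'
#' @examples
#' # backcross: 46 wild-type vs 42 mutant against 1:1
#' chisq_gof(c(46, 42), c(1, 1))
#' # F2: 150 wild-type vs 41 mutant against 3:1, uncorrected
#' chisq_gof(c(150, 41), c(3, 1), correction = FALSE)
#' @export
chisq_gof <- function(observed, ratio, correction = TRUE, labels = NULL) {
  observed <- as.numeric(observed)
  ratio <- as.numeric(ratio)
  if (length(observed) != length(ratio)) {
    abort("`observed` and `ratio` must have the same number of classes.")
  }
  if (length(observed) < 2) abort("Need at least two classes.")
  if (any(observed < 0) || any(is.na(observed))) {
    abort("`observed` counts must be non-negative and non-missing.")
  }
  if (any(ratio <= 0)) abort("Every `ratio` component must be positive.")
  total <- sum(observed)
  if (total <= 0) abort("Total observed count must be positive.")

  df <- length(observed) - 1L
  if (correction && df > 1L) {
    warn("Continuity correction is only defined for df = 1; ignoring it.")
    correction <- FALSE
  }
  expected <- total * ratio / sum(ratio)
  cc <- if (correction) 0.5 else 0
  dev <- pmax(abs(observed - expected) - cc, 0)
  chisq <- sum(dev^2 / expected)
  structure(
    list(
      chisq = chisq,
      df = df,
      p_value = pchisq(chisq, df, lower.tail = FALSE),
      correction = correction,
      observed = observed,
      expected = expected,
      ratio = ratio,
      labels = labels %||% paste0("class", seq_along(observed))
    ),
    class = "seg_test"
  )
}

#' @export
print.seg_test <- function(x, ...) {
  cat("Segregation goodness-of-fit test\n")
  cat("  observed: ", paste(x$observed, collapse = ":"),
      "  vs ratio ", paste(x$ratio, collapse = ":"), "\n", sep = "")
  cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g%s\n",
              x$chisq, x$df, x$p_value,
              if (x$correction) " (Yates-corrected)" else ""))
  invisible(x)
}

#' @rdname chisq_gof
#' @param x A `seg_test` object.
#' @param ... Unused.
#' @method tidy seg_test
#' @export
tidy.seg_test <- function(x, ...) {
  tibble::tibble(
    class = x$labels,
    observed = x$observed,
    expected = x$expected,
    ratio = x$ratio
  )
}

#' @rdname chisq_gof
#' @method glance seg_test
#' @export
glance.seg_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$chisq,
    df = x$df,
    p_value = x$p_value,
    correction = x$correction
  )
}

#' Classify a segregation test as consistent or not with its ratio
#'
#' A population is called `"consistent"` with the theoretical ratio when the
#' test's p-value strictly exceeds `alpha`, the usual reading of a "P > 0.05"
#' significance column in a segregation table.
#'
#' @param test A `seg_test` from [chisq_gof()].
#' @param alpha Significance level in (0, 1). Default 0.05.
#' @return `"consistent"` or `"inconsistent"`.
#' @examples
#' classify_fit(chisq_gof(c(46, 42), c(1, 1)))
#' @export
classify_fit <- function(test, alpha = 0.05) {
  stopifnot(inherits(test, "seg_test"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value strictly between 0 and 1.")
  }
  if (test$p_value > alpha) "consistent" else "inconsistent"
}

#' Segregation tests for a table of populations
#'
#' Applies [chisq_gof()] row-wise to a tidy table of populations, producing a
#' segregation-table-style summary (one row per population with its total,
#' class counts, ratio, statistic and consistency call).
#'
#' @param data A data frame with one row per population.
#' @param counts Column (tidyselect) holding a list or comma-separated string
#'   of class counts, or the name of a list-column.
#' @param ratio As `counts`, for the theoretical ratio.
#' @param correction,alpha Passed to [chisq_gof()] / [classify_fit()].
#' @return A tibble with columns `size`, `chisq`, `df`, `p_value`, `fit`
#'   appended to the input's non-count columns.
#' @examples
#' pops <- tibble::tibble(
#'   generation = c("F2", "BC1P1"),
#'   counts = list(c(150, 41), c(46, 42)),
#'   ratio = list(c(3, 1), c(1, 1))
#' )
#' segregation_table(pops)
#' @export
segregation_table <- function(data, counts = "counts", ratio = "ratio",
                              correction = TRUE, alpha = 0.05) {
  cnt <- data[[counts]]
  rat <- data[[ratio]]
  if (is.character(cnt)) cnt <- lapply(strsplit(cnt, "[,:]"), as.numeric)
  if (is.character(rat)) rat <- lapply(strsplit(rat, "[,:]"), as.numeric)
  res <- purrr::map2(cnt, rat, function(o, r) {
    t <- chisq_gof(o, r, correction = correction)
    tibble::tibble(
      size = sum(o), chisq = t$chisq, df = t$df, p_value = t$p_value,
      fit = classify_fit(t, alpha)
    )
  })
  dplyr::bind_cols(
    dplyr::select(data, -dplyr::all_of(c(counts, ratio))),
    dplyr::bind_rows(res)
  )
}
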