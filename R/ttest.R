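# t-test result container shared by every statistical comparison in the
# pipeline. The arithmetic is delegated to stats::t.test; this layer fixes
# the (mean_a, mean_b, df) bookkeeping and turns the zero-variance case into
# a typed error instead of an infinite statistic.

new_dm_ttest <- function(fit, mean_a, mean_b, n, method, ...) {
  structure(
    list(
      statistic = unname(fit$statistic),
      df = unname(fit$parameter),
      p_value = unname(fit$p.value),
      mean_a = unname(mean_a),
      mean_b = unname(mean_b),
      n = unname(n),
      method = method,
      ...
    ),
    class = "dm_ttest"
  )
}

# Zero variance of the differences is handled in two ways: exactly identical
# vectors are a well-defined no-effect case (t = 0, p = 1), while a constant
# non-zero difference has an undefined t and raises a typed error carrying
# the sign of the difference, forcing callers to handle it explicitly.
zero_t_result <- function(mean_a, mean_b, n, method) {
  structure(
    list(statistic = 0, df = (if (length(n) > 1L) sum(n) - 2L else n - 1L),
         p_value = 1, mean_a = unname(mean_a), mean_b = unname(mean_b),
         n = unname(n), method = method),
    class = "dm_ttest"
  )
}

check_degenerate <- function(d, what) {
  if (stats::sd(d) == 0 && mean(d) != 0) {
    dm_stop("degenerate_test",
            sprintf("%s: zero variance of the differences (all equal to %.6g)",
                    what, mean(d)),
            sign = sign(mean(d)))
  }
}

#' Paired t-test on two aligned vectors
#'
#' Two-sided paired Student t-test, the workhorse behind every per-probe and
#' per-observer comparison. Zero variance of the differences raises a typed
#' `dotmatch_degenerate_test` error carrying the sign of the mean difference.
#'
#' @param a,b Aligned numeric vectors (same pairing unit order), length >= 2.
#' @param method Label stored in the result.
#' @return A `dm_ttest` object: `statistic`, `df`, `p_value` (two-sided),
#'   `mean_a`, `mean_b`, `n`.
#' @export
paired_t <- function(a, b, method = "paired t-test") {
  if (length(a) != length(b)) {
    dm_stop("validation", "paired vectors must have equal length")
  }
  if (length(a) < 2L) {
    dm_stop("insufficient_data", "paired t-test needs at least 2 pairs")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    dm_stop("validation", "paired t-test inputs must be finite")
  }
  check_degenerate(a - b, method)
  if (stats::sd(a - b) == 0) {
    return(zero_t_result(mean(a), mean(b), length(a), method))
  }
  fit <- stats::t.test(a, b, paired = TRUE)
  new_dm_ttest(fit, mean(a), mean(b), length(a), method)
}

#' Two-sample pooled-variance t-test
#'
#' Classic Student two-sample test (equal variances pooled),
#' `df = n_a + n_b - 2`. Used for the identity-judgement comparison, where
#' multiple selections per observer break the pairing.
#'
#' @param a,b Numeric observation vectors, each of length >= 2.
#' @param method Label stored in the result.
#' @return A `dm_ttest` object.
#' @export
two_sample_t <- function(a, b, method = "two-sample t-test (pooled variance)") {
  if (length(a) < 2L || length(b) < 2L) {
    dm_stop("insufficient_data", "two-sample t-test needs >= 2 observations per group")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    dm_stop("validation", "two-sample t-test inputs must be finite")
  }
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) {
    if (mean(a) == mean(b)) {
      return(zero_t_result(mean(a), mean(b),
                           c(n_a = length(a), n_b = length(b)), method))
    }
    dm_stop("degenerate_test",
            sprintf("%s: zero pooled variance", method),
            sign = sign(mean(a) - mean(b)))
  }
  fit <- stats::t.test(a, b, var.equal = TRUE)
  new_dm_ttest(fit, mean(a), mean(b), c(n_a = length(a), n_b = length(b)), method)
}

format_p <- function(p) {
  if (p < 0.001) "p < 0.001" else sprintf("p = %.3f", p)
}

#' Format a test result in the reporting style of the field
#'
#' Renders "mean_a vs. mean_b units, t(df) = X, p = Y".
#'
#' @param x A `dm_ttest` object.
#' @param units Unit string appended to the means.
#' @return A single character string.
#' @export
format_ttest <- function(x, units = "units") {
  stopifnot(inherits(x, "dm_ttest"))
  sprintf("%.2f vs. %.2f %s, t(%d) = %.2f, %s",
          x$mean_a, x$mean_b, units, as.integer(round(x$df)), x$statistic,
          format_p(x$p_value))
}

#' @export
print.dm_ttest <- function(x, ...) {
  cat(sprintf("<dm_ttest> %s\n  %s\n", x$method, format_ttest(x)))
  invisible(x)
}

ttest_to_list <- function(x, name, notes = "") {
  list(
    name = name,
    statistic = x$statistic,
    df = x$df,
    p_two_sided = x$p_value,
    mean_a = x$mean_a,
    mean_b = x$mean_b,
    n = if (length(x$n) > 1L) as.list(x$n) else x$n,
    notes = notes
  )
}
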