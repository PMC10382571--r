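# Inter-observer consistency statistics: per-probe mean pairwise distance,
# the uniform-within-contour random baseline, and the conservative
# neighbor-probe test.

#' Per-probe inter-observer consistency
#'
#' For each probe, the mean pairwise distance between the responses of
#' different observers. Smaller values mean higher agreement. The table must
#' be aggregated (one response per observer per probe; see
#' [aggregate_repetitions()]).
#'
#' @param table An aggregated [response_table()].
#' @return Data frame with columns `probe_id`, `statistic` (pixels),
#'   `n_observers`, ordered by `probe_id`.
#' @export
per_probe_consistency <- function(table) {
  assert_response_table(table)
  if (!is_aggregated(table)) {
    dm_stop("validation",
            "table has repeated placements; run aggregate_repetitions() first")
  }
  if (!nrow(table)) {
    dm_stop("insufficient_data", "response table is empty")
  }
  if (length(unique(table$cohort)) > 1L || length(unique(table$condition)) > 1L) {
    dm_stop("validation",
            "consistency is defined per cohort and condition; filter with select_responses() first")
  }
  if (anyDuplicated(paste(table$observer_id, table$probe_id))) {
    dm_stop("validation", "more than one response per observer and probe")
  }
  ids <- sort(unique(table$probe_id))
  rows <- lapply(ids, function(pid) {
    g <- table[table$probe_id == pid, , drop = FALSE]
    if (nrow(g) < 2L) {
      dm_stop("insufficient_data",
              sprintf("probe '%s' has %d observer(s); need >= 2", pid, nrow(g)))
    }
    data.frame(probe_id = pid,
               statistic = mean_pairwise_distance(g[, c("x", "y")]),
               n_observers = nrow(g), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Random-response baseline for a test shape
#'
#' Monte-Carlo estimate of the expected distance between two independent
#' uniform locations inside the shape contour: the mean distance over
#' `n_pairs` independently drawn point pairs. Because the mean pairwise
#' distance of any number of i.i.d. uniform points has this same expectation,
#' a single baseline serves cohorts of any size.
#'
#' @param shape A [shape_outline()].
#' @param n_pairs Number of independent point pairs (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Baseline distance in pixels.
#' @export
random_baseline <- function(shape, n_pairs = 1e5, seed = NULL) {
  assert_shape(shape)
  if (!is_count(n_pairs, min = 1L)) {
    dm_stop("validation", "`n_pairs` must be a positive integer")
  }
  pts <- sample_uniform(shape, 2L * as.integer(n_pairs), seed = seed)
  a <- pts[seq_len(n_pairs), , drop = FALSE]
  b <- pts[n_pairs + seq_len(n_pairs), , drop = FALSE]
  mean(sqrt((a[, 1L] - b[, 1L])^2 + (a[, 2L] - b[, 2L])^2))
}

#' Consistency versus the random baseline
#'
#' Paired t-test of the per-probe consistency vector against the constant
#' random baseline (equivalently a one-sample t-test on the differences),
#' `df = n_probes - 1`, two-sided. A strongly negative statistic means
#' observers agree far better than uniformly random placement.
#'
#' @param per_probe Result of [per_probe_consistency()] (or a numeric vector
#'   of per-probe statistics).
#' @param baseline Baseline distance from [random_baseline()].
#' @return A `dm_ttest`; `mean_a` is the mean per-probe consistency and
#'   `mean_b` the baseline.
#' @export
consistency_vs_random_test <- function(per_probe, baseline) {
  x <- if (is.data.frame(per_probe)) per_probe$statistic else as.numeric(per_probe)
  if (length(x) < 2L) {
    dm_stop("insufficient_data", "need >= 2 probes for the paired test")
  }
  if (!is_number(baseline)) dm_stop("validation", "`baseline` must be a number")
  paired_t(x, rep(baseline, length(x)), method = "consistency vs. random baseline")
}

#' Nearest-neighbor map over probes
#'
#' Maps every probe to its nearest other probe by Euclidean distance on the
#' base stimulus; distance ties are broken towards the lexicographically
#' smaller probe id.
#'
#' @param probes A [probe_set()].
#' @return Named character vector: `probe_id -> neighbor probe_id`.
#' @export
neighbor_probe_map <- function(probes) {
  if (!inherits(probes, "probe_set")) {
    dm_stop("validation", "`probes` must be a probe_set")
  }
  loc <- probe_locations(probes)
  ord <- order(rownames(loc))
  loc <- loc[ord, , drop = FALSE]
  d <- as.matrix(stats::dist(loc))
  diag(d) <- Inf
  nb <- apply(d, 1L, function(row) {
    # which.min on the id-sorted matrix realises the lexicographic tie-break
    rownames(loc)[which.min(row)]
  })
  names(nb) <- rownames(loc)
  nb
}

#' Conservative neighbor-probe consistency test
#'
#' Tests whether the responses for each probe are closer to each other than
#' to the median response of its nearest neighboring probe. For probe p,
#' `within(p)` is the mean pairwise distance among responses to p, and
#' `between(p)` the mean distance from each response to the componentwise
#' median of the responses for `neighbor(p)`; the two vectors are compared by
#' a paired t-test over probes (`df = n_probes - 1`).
#'
#' @param table An aggregated [response_table()].
#' @param probes A [probe_set()]; defaults to the table's probe set.
#' @param median_method Median convention for the neighbor reference.
#' @return A `dm_ttest` with an extra `per_probe` data frame
#'   (`probe_id`, `within`, `between`, `neighbor`).
#' @export
neighbor_consistency_test <- function(table, probes = table_probes(table),
                                      median_method = c("componentwise", "geometric")) {
  assert_response_table(table)
  median_method <- match.arg(median_method)
  per <- per_probe_consistency(table)
  present <- per$probe_id
  if (length(present) < 2L) {
    dm_stop("insufficient_data", "neighbor test needs >= 2 probes with responses")
  }
  sub <- probes[probes$probe_id %in% present, , drop = FALSE]
  class(sub) <- class(probes); attr(sub, "stimulus_pair") <- attr(probes, "stimulus_pair")
  nb <- neighbor_probe_map(sub)
  medians <- lapply(split(seq_len(nrow(table)), table$probe_id), function(i) {
    point_median(table[i, c("x", "y")], median_method)
  })
  between <- vapply(per$probe_id, function(pid) {
    g <- table[table$probe_id == pid, c("x", "y"), drop = FALSE]
    mean(dist_to_point(g, medians[[nb[[pid]]]]))
  }, numeric(1L))
  test <- paired_t(per$statistic, unname(between),
                   method = "within-probe vs. neighbor-median distance")
  test$per_probe <- data.frame(probe_id = per$probe_id,
                               within = per$statistic,
                               between = unname(between),
                               neighbor = unname(nb[per$probe_id]),
                               stringsAsFactors = FALSE)
  test
}

#' Full consistency analysis of one cohort and condition
#'
#' Convenience wrapper producing the per-probe consistency vector, its mean,
#' the uniform-within-contour baseline, the paired consistency-vs-random
#' test, and the conservative neighbor-probe test.
#'
#' @param table An aggregated [response_table()] for a single cohort and
#'   condition.
#' @param n_pairs,seed Passed to [random_baseline()].
#' @param median_method Median convention for the neighbor reference.
#' @return An object of class `dm_consistency`: `per_probe`, `aggregate`,
#'   `baseline`, `test`, `neighbor_test`, `n_pairs`, `seed`.
#' @export
consistency_analysis <- function(table, n_pairs = 1e5, seed = NULL,
                                 median_method = c("componentwise", "geometric")) {
  assert_response_table(table)
  median_method <- match.arg(median_method)
  per <- per_probe_consistency(table)
  baseline <- random_baseline(table_shape(table), n_pairs = n_pairs, seed = seed)
  structure(
    list(
      per_probe = per,
      aggregate = mean(per$statistic),
      baseline = baseline,
      test = consistency_vs_random_test(per, baseline),
      neighbor_test = neighbor_consistency_test(table, median_method = median_method),
      n_pairs = n_pairs,
      seed = seed
    ),
    class = "dm_consistency"
  )
}

#' @export
print.dm_consistency <- function(x, ...) {
  cat("<dm_consistency>\n")
  cat(sprintf("  mean per-probe consistency: %.2f units over %d probes\n",
              x$aggregate, nrow(x$per_probe)))
  cat(sprintf("  random baseline:            %.2f units (%g pairs)\n",
              x$baseline, x$n_pairs))
  cat(sprintf("  vs. random:   %s\n", format_ttest(x$test)))
  cat(sprintf("  vs. neighbor: %s\n", format_ttest(x$neighbor_test)))
  invisible(x)
}

#' @export
summary.dm_consistency <- function(object, ...) {
  cat(sprintf("Consistency analysis over %d probes\n", nrow(object$per_probe)))
  print(object$per_probe, row.names = FALSE)
  print(object)
  invisible(object)
}
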