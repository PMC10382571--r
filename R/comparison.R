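# Condition and cohort comparisons: median response maps, proximity-to-
# reference tests, consistency contrasts, and the response-time and
# questionnaire statistics.

#' Median response map of a cohort
#'
#' Per probe, the median of the observers' (aggregated) response locations.
#' Probes present in the table's probe set but without any response are
#' omitted with a warning, so partially-responding cohorts (an expert who
#' declines some probes) still yield a usable map.
#'
#' @param table An aggregated [response_table()].
#' @param method Median convention (componentwise by default).
#' @return Data frame of class `median_map` with columns `probe_id`, `x`,
#'   `y`, `n_observers` and attributes `cohort` / `condition` when unique.
#' @export
median_map <- function(table, method = c("componentwise", "geometric")) {
  assert_response_table(table)
  method <- match.arg(method)
  if (!is_aggregated(table)) {
    dm_stop("validation",
            "table has repeated placements; run aggregate_repetitions() first")
  }
  if (!nrow(table)) dm_stop("insufficient_data", "response table is empty")
  probes <- table_probes(table)
  missing <- setdiff(probes$probe_id, table$probe_id)
  if (length(missing)) {
    dm_warn(sprintf("median map omits %d probe(s) with no responses: %s",
                    length(missing), paste(missing, collapse = ", ")))
  }
  ids <- sort(unique(table$probe_id))
  rows <- lapply(ids, function(pid) {
    g <- table[table$probe_id == pid, , drop = FALSE]
    m <- point_median(g[, c("x", "y")], method)
    data.frame(probe_id = pid, x = m[["x"]], y = m[["y"]],
               n_observers = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cohort") <- if (length(unique(table$cohort)) == 1L) table$cohort[1L] else NA_character_
  attr(out, "condition") <- if (length(unique(table$condition)) == 1L) table$condition[1L] else NA_character_
  class(out) <- c("median_map", "data.frame")
  out
}

map_lookup <- function(map, pid) {
  i <- match(pid, map$probe_id)
  c(map$x[i], map$y[i])
}

#' Proximity of responses to two reference maps
#'
#' For each probe, the mean distance from every observer's response to the
#' "self" reference location is compared with the mean distance to the
#' "other" reference location, then a paired t-test is run over probes
#' (`df = n_common_probes - 1`). This is the statistic behind the
#' between-condition and participant-versus-expert comparisons: a strongly
#' negative t means responses sit much closer to their own reference than to
#' the alternative. Probes missing from either reference map are dropped
#' pairwise with a warning.
#'
#' Note that when `ref_self` is estimated from the same responses being
#' tested, the self distances are biased small; for calibrated null testing
#' use references estimated from independent data (see the methods vignette).
#'
#' @param responses An aggregated [response_table()].
#' @param ref_self,ref_other [median_map()]s (or data frames with
#'   `probe_id`, `x`, `y`).
#' @return Object of class `dm_proximity`: `per_probe` (data frame with
#'   `probe_id`, `self`, `other`), `test` (a `dm_ttest`).
#' @export
proximity_test <- function(responses, ref_self, ref_other) {
  assert_response_table(responses)
  if (!is_aggregated(responses)) {
    dm_stop("validation",
            "table has repeated placements; run aggregate_repetitions() first")
  }
  present <- sort(unique(responses$probe_id))
  common <- intersect(intersect(present, ref_self$probe_id), ref_other$probe_id)
  dropped <- setdiff(present, common)
  if (length(dropped)) {
    dm_warn(sprintf("proximity test drops %d probe(s) missing from a reference map: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  if (length(common) < 2L) {
    dm_stop("insufficient_data", "proximity test needs >= 2 probes common to both maps")
  }
  self <- numeric(length(common)); other <- numeric(length(common))
  for (k in seq_along(common)) {
    g <- responses[responses$probe_id == common[k], c("x", "y"), drop = FALSE]
    self[k] <- mean(dist_to_point(g, map_lookup(ref_self, common[k])))
    other[k] <- mean(dist_to_point(g, map_lookup(ref_other, common[k])))
  }
  test <- paired_t(self, other, method = "proximity to self vs. other reference")
  structure(
    list(per_probe = data.frame(probe_id = common, self = self, other = other,
                                stringsAsFactors = FALSE),
         test = test),
    class = "dm_proximity"
  )
}

#' @export
print.dm_proximity <- function(x, ...) {
  cat(sprintf("<dm_proximity> %d probes\n  %s\n",
              nrow(x$per_probe), format_ttest(x$test)))
  invisible(x)
}

#' Compare two per-probe consistency vectors
#'
#' Paired t-test over probes of two cohorts' (or conditions') per-probe
#' consistency statistics, aligned by probe id.
#'
#' @param per_probe_a,per_probe_b Results of [per_probe_consistency()] or
#'   aligned numeric vectors.
#' @return A `dm_ttest`.
#' @export
cohort_consistency_compare <- function(per_probe_a, per_probe_b) {
  take <- function(p) if (is.data.frame(p)) p[, c("probe_id", "statistic")] else p
  a <- take(per_probe_a); b <- take(per_probe_b)
  if (is.data.frame(a) && is.data.frame(b)) {
    common <- intersect(a$probe_id, b$probe_id)
    if (length(common) < 2L) {
      dm_stop("insufficient_data", "need >= 2 probes common to both vectors")
    }
    av <- a$statistic[match(common, a$probe_id)]
    bv <- b$statistic[match(common, b$probe_id)]
  } else {
    av <- as.numeric(if (is.data.frame(a)) a$statistic else a)
    bv <- as.numeric(if (is.data.frame(b)) b$statistic else b)
  }
  paired_t(av, bv, method = "consistency comparison (a vs. b)")
}

#' Paired response-time comparison between conditions
#'
#' Per observer, the mean response time across all probes and repetitions
#' within each condition; then a paired t-test over observers
#' (`df = n_observers - 1`).
#'
#' @param table_a,table_b [response_table()]s for the two conditions,
#'   covering the same observer set, with response times present.
#' @return A `dm_ttest`; means are in seconds.
#' @export
response_time_test <- function(table_a, table_b) {
  assert_response_table(table_a); assert_response_table(table_b)
  obs_mean <- function(tab, which) {
    if (all(is.na(tab$rt_s))) {
      dm_stop("validation", sprintf("table_%s has no response times", which))
    }
    tapply(tab$rt_s, tab$observer_id, mean, na.rm = TRUE)
  }
  a <- obs_mean(table_a, "a"); b <- obs_mean(table_b, "b")
  missing <- c(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
  if (length(missing)) {
    dm_stop("pairing", sprintf("observer(s) present in only one table: %s",
                               paste(unique(missing), collapse = ", ")))
  }
  obs <- sort(names(a))
  paired_t(as.numeric(a[obs]), as.numeric(b[obs]),
           method = "mean response time per observer (a vs. b)")
}

#' Paired Likert comparison between conditions
#'
#' Paired t-test over observers of the 1-6 coded confidence or similarity
#' responses, pairing each observer's answers across the two conditions
#' within a stimulus pair.
#'
#' @param q A `questionnaire_table` containing both conditions.
#' @param field `"confidence"` or `"similarity"`.
#' @return A `dm_ttest`; `mean_a` is the without-intermediates mean.
#' @export
likert_test <- function(q, field = c("confidence", "similarity")) {
  field <- match.arg(field)
  q <- questionnaire_table(q)
  key <- paste(q$observer_id, q$stimulus_pair, sep = "\r")
  a_rows <- q$condition == dm_conditions[1L]
  b_rows <- q$condition == dm_conditions[2L]
  ka <- key[a_rows]; kb <- key[b_rows]
  if (anyDuplicated(ka) || anyDuplicated(kb)) {
    dm_stop("pairing", "duplicate questionnaire rows for an observer and condition")
  }
  unmatched <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(unmatched)) {
    dm_stop("pairing", sprintf(
      "observer(s) without answers in both conditions: %s",
      paste(unique(sub("\r.*$", "", unmatched)), collapse = ", ")))
  }
  if (length(ka) < 2L) {
    dm_stop("insufficient_data", "need >= 2 paired observers")
  }
  av <- q[[field]][a_rows][order(ka)]
  bv <- q[[field]][b_rows][order(kb)]
  paired_t(as.numeric(av), as.numeric(bv),
           method = sprintf("%s rating (without vs. with intermediates)", field))
}

#' Two-sample identity-judgement comparison
#'
#' Because observers may select several identity choices, the observations
#' are not paired: each selected choice contributes one coded observation,
#' and the two conditions are compared with a pooled-variance two-sample
#' t-test (`df = n_a + n_b - 2`).
#'
#' @param q_a,q_b `questionnaire_table`s (or subsets) for the two conditions.
#' @param coding Named numeric vector covering all four identity choices.
#'   The default ordinal coding is
#'   `c(unrelated = 0, same_class = 1, right_modified_left = 2,
#'   left_modified_right = 2)`.
#' @return A `dm_ttest`.
#' @export
identity_test <- function(q_a, q_b,
                          coding = c(unrelated = 0, same_class = 1,
                                     right_modified_left = 2,
                                     left_modified_right = 2)) {
  if (!all(dm_identity_choices %in% names(coding))) {
    dm_stop("validation", sprintf("`coding` must cover all of: %s",
                                  paste(dm_identity_choices, collapse = ", ")))
  }
  code <- function(q) {
    choices <- unlist(strsplit(as.character(q$identity_choices), "|", fixed = TRUE))
    bad <- setdiff(choices, dm_identity_choices)
    if (length(bad)) {
      dm_stop("parse", sprintf("unknown identity choice(s): %s",
                               paste(unique(bad), collapse = ", ")))
    }
    as.numeric(coding[choices])
  }
  a <- code(q_a); b <- code(q_b)
  two_sample_t(a, b, method = "identity judgements (two-sample, pooled variance)")
}
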