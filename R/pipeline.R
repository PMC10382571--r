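# Orchestration: simulate -> analyze -> report. The analysis configuration
# makes every convention the underlying experiment leaves open (repetition
# aggregation, median type, baseline draws, identity coding, expert grouping)
# explicit, so a reproduction attempt is self-documenting.

#' Analysis configuration
#'
#' @param input_dir Directory containing `responses.csv`, `probes.csv`,
#'   `shape.geojson`, and optionally `questionnaire.csv`.
#' @param out_dir Output directory for `report.json` and per-probe CSVs
#'   (`NULL` = do not write, just return the report).
#' @param aggregation Repetition-collapsing convention: `"median"` or `"mean"`.
#' @param median_type 2-D median convention: `"componentwise"` or
#'   `"geometric"`.
#' @param baseline_n_pairs Point pairs for the uniform resampling baseline.
#' @param baseline_seed Seed for the baseline draw (recorded in the report).
#' @param identity_coding Named numeric coding of the four identity choices.
#' @param expert_groups Named list of expert observer-id vectors (e.g.
#'   `list(group2 = c("expert3", "expert4", "expert5"))`); `NULL` groups all
#'   experts together as `"all_experts"`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(input_dir,
                            out_dir = NULL,
                            aggregation = c("median", "mean"),
                            median_type = c("componentwise", "geometric"),
                            baseline_n_pairs = 1e5,
                            baseline_seed = 20230728L,
                            identity_coding = c(unrelated = 0, same_class = 1,
                                                right_modified_left = 2,
                                                left_modified_right = 2),
                            expert_groups = NULL) {
  aggregation <- match.arg(aggregation)
  median_type <- match.arg(median_type)
  if (!is_count(baseline_n_pairs, min = 1L)) {
    dm_stop("config", "`baseline_n_pairs` must be a positive integer")
  }
  if (!is_count(baseline_seed)) dm_stop("config", "`baseline_seed` must be an integer")
  structure(
    list(input_dir = input_dir, out_dir = out_dir, aggregation = aggregation,
         median_type = median_type, baseline_n_pairs = baseline_n_pairs,
         baseline_seed = as.integer(baseline_seed),
         identity_coding = identity_coding, expert_groups = expert_groups),
    class = "analysis_config"
  )
}

read_config_file <- function(path) {
  if (!file.exists(path)) {
    dm_stop("config", sprintf("config file not found: %s", path))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Read an analysis configuration from YAML or JSON
#'
#' Field names match the arguments of [analysis_config()]; `identity_coding`
#' and `expert_groups` are given as mappings.
#'
#' @param path Config file path.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  raw <- read_config_file(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    dm_warn(sprintf("config %s: ignoring unknown field(s): %s",
                    path, paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  if (!is.null(raw$identity_coding)) raw$identity_coding <- unlist(raw$identity_coding)
  do.call(analysis_config, raw)
}

#' Read a synthetic-experiment configuration from YAML or JSON
#'
#' Field names match the arguments of [synthetic_config()].
#'
#' @param path Config file path.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- read_config_file(path)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    dm_warn(sprintf("config %s: ignoring unknown field(s): %s",
                    path, paste(unknown, collapse = ", ")))
    raw <- raw[intersect(names(raw), known)]
  }
  for (nm in c("rt_lognormal", "likert_means", "identity_probs", "blob_harmonics")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- lapply(raw[[nm]], unlist)
  }
  if (!is.null(raw$condition_shift) && is.list(raw$condition_shift)) {
    raw$condition_shift <- do.call(rbind, raw$condition_shift)
  }
  do.call(synthetic_config, raw)
}

#' Simulate an experiment and write its fixture directory
#'
#' @param config A [synthetic_config()] or the path to a YAML/JSON file of
#'   its fields.
#' @param out Output directory.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config, out) {
  if (is.character(config)) config <- read_synthetic_config(config)
  stopifnot(inherits(config, "synthetic_config"))
  sim <- simulate_experiment(config)
  write_fixtures(sim, out)
  message(sprintf("simulate: wrote %d response rows to %s",
                  nrow(sim$responses), out))
  invisible(out)
}

# run one test, turning typed dotmatch errors into a skipped-entry record
guarded <- function(name, expr, notes = "") {
  tryCatch(
    ttest_to_list(expr, name, notes),
    dotmatch_error = function(e) {
      list(name = name, skipped = TRUE, reason = conditionMessage(e))
    }
  )
}

consistency_block <- function(cohort, condition, res, baseline_seed) {
  list(
    cohort = cohort,
    condition = condition,
    per_probe = res$per_probe,
    aggregate = res$aggregate,
    baseline = res$baseline,
    baseline_n_pairs = res$n_pairs,
    baseline_seed = baseline_seed,
    vs_random = ttest_to_list(res$test, sprintf("%s_%s_vs_random", cohort, condition)),
    vs_neighbor = ttest_to_list(res$neighbor_test,
                                sprintf("%s_%s_vs_neighbor", cohort, condition))
  )
}

#' Run the full analysis pipeline on a data directory
#'
#' Reads the dataset, aggregates repetitions, and computes, for every cohort
#' and condition present: per-probe consistency, the uniform-within-contour
#' baseline, the consistency-versus-random and neighbor-probe paired tests;
#' then the between-condition comparisons (consistency contrast, proximity
#' of without-intermediates responses to their own versus the other
#' condition's median map, response times, Likert ratings, identity
#' judgements); and, when an expert cohort is present, the expert-group
#' median maps and participant-versus-expert proximity tests. Inapplicable
#' tests (e.g. response times for untimed experts) are recorded as skipped
#' with a reason rather than dropped silently.
#'
#' @param config An [analysis_config()] or the path to its YAML/JSON file.
#' @return The report (class `dm_report`, a nested list); also written as
#'   `report.json` plus per-probe CSVs when `out_dir` is set.
#' @export
run_analyze <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  dir <- config$input_dir
  probes <- read_probes(file.path(dir, "probes.csv"))
  shape <- read_shape_geojson(file.path(dir, "shape.geojson"))
  table <- read_responses(file.path(dir, "responses.csv"), probes, shape)
  qpath <- file.path(dir, "questionnaire.csv")
  questionnaire <- if (file.exists(qpath)) read_questionnaire(qpath)
  agg <- aggregate_repetitions(table, location = config$aggregation)
  baseline <- random_baseline(shape, n_pairs = config$baseline_n_pairs,
                              seed = config$baseline_seed)

  slices <- list(
    naive_without = select_responses(agg, "naive", "without_intermediates"),
    naive_with = select_responses(agg, "naive", "with_intermediates"),
    expert = select_responses(agg, "expert", "with_intermediates")
  )
  has <- vapply(slices, function(s) nrow(s) > 0L, logical(1L))

  per_probe <- list()
  p1 <- list()
  for (nm in names(slices)[has]) {
    s <- slices[[nm]]
    res <- list(per_probe = per_probe_consistency(s))
    res$aggregate <- mean(res$per_probe$statistic)
    res$baseline <- baseline
    res$n_pairs <- config$baseline_n_pairs
    res$test <- consistency_vs_random_test(res$per_probe, baseline)
    res$neighbor_test <- neighbor_consistency_test(s, median_method = config$median_type)
    class(res) <- "dm_consistency"
    p1[[nm]] <- consistency_block(s$cohort[1L], s$condition[1L], res,
                                  config$baseline_seed)
    per_probe[[nm]] <- res$per_probe
  }

  p2 <- NULL
  if (has[["naive_without"]] && has[["naive_with"]]) {
    wo <- slices$naive_without; wi <- slices$naive_with
    map_wo <- median_map(wo, method = config$median_type)
    map_wi <- median_map(wi, method = config$median_type)
    p2 <- list(
      consistency_without_vs_with = guarded(
        "consistency_without_vs_with",
        cohort_consistency_compare(per_probe$naive_without, per_probe$naive_with)),
      proximity_without_to_own_vs_with = guarded(
        "proximity_without_to_own_vs_with",
        proximity_test(wo, map_wo, map_wi)$test,
        notes = "self reference estimated from the tested responses (descriptive)"),
      response_time = guarded("response_time_without_vs_with",
                              response_time_test(wo, wi)),
      confidence = if (!is.null(questionnaire)) {
        guarded("confidence_without_vs_with", likert_test(questionnaire, "confidence"))
      },
      similarity = if (!is.null(questionnaire)) {
        guarded("similarity_without_vs_with", likert_test(questionnaire, "similarity"))
      },
      identity = if (!is.null(questionnaire)) {
        guarded("identity_without_vs_with", identity_test(
          questionnaire[questionnaire$condition == "without_intermediates", ],
          questionnaire[questionnaire$condition == "with_intermediates", ],
          coding = config$identity_coding))
      }
    )
    if (is.null(questionnaire)) {
      p2$questionnaire_skipped <- "no questionnaire.csv in the input directory"
    }
  } else {
    p2 <- list(skipped = TRUE,
               reason = "naive cohort not present in both conditions; condition comparisons (incl. response time) skipped")
  }

  p3 <- NULL
  if (has[["expert"]]) {
    experts <- slices$expert
    groups <- config$expert_groups %||%
      list(all_experts = sort(unique(experts$observer_id)))
    group_maps <- list()
    for (g in names(groups)) {
      sub <- experts[experts$observer_id %in% groups[[g]], , drop = FALSE]
      if (!nrow(sub)) {
        dm_warn(sprintf("expert group '%s' matches no observers", g))
        next
      }
      sub <- suppressWarnings(response_table(sub, probes, shape))
      group_maps[[g]] <- suppressWarnings(median_map(sub, method = config$median_type))
    }
    p3 <- list(groups = lapply(groups, as.list))
    if (has[["naive_with"]]) {
      p3$expert_vs_naive_with_consistency <- guarded(
        "expert_vs_naive_with_consistency",
        cohort_consistency_compare(per_probe$expert, per_probe$naive_with))
    }
    for (g in names(group_maps)) {
      for (nm in c("naive_without", "naive_with")) {
        if (!has[[nm]]) next
        s <- slices[[nm]]
        own <- suppressWarnings(median_map(s, method = config$median_type))
        p3[[sprintf("proximity_%s_to_own_vs_%s", nm, g)]] <- guarded(
          sprintf("proximity_%s_to_own_vs_%s", nm, g),
          suppressWarnings(proximity_test(s, own, group_maps[[g]]))$test,
          notes = "self reference estimated from the tested responses (descriptive)")
      }
    }
  }

  report <- structure(
    list(
      p1 = p1, p2 = p2, p3 = p3,
      provenance = list(
        package = "dotmatch",
        version = as.character(utils::packageVersion("dotmatch")),
        input_dir = config$input_dir,
        aggregation = config$aggregation,
        median_type = config$median_type,
        baseline_n_pairs = config$baseline_n_pairs,
        baseline_seed = config$baseline_seed,
        identity_coding = as.list(config$identity_coding),
        n_records = nrow(table)
      )
    ),
    class = "dm_report"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    for (nm in names(per_probe)) {
      utf8_write_csv(per_probe[[nm]],
                     file.path(config$out_dir, sprintf("consistency_%s.csv", nm)))
    }
  }
  report
}

#' Render a report as a human-readable summary
#'
#' Each test is rendered in the reporting style of the field:
#' `mean_a vs. mean_b units, t(df) = X, p = Y`. Regenerating the summary
#' from the same report yields identical text.
#'
#' @param report A `dm_report`, or the path to a `report.json`.
#' @return Character vector of markdown lines, invisibly; also printed.
#' @export
run_report <- function(report) {
  if (is.character(report)) {
    report <- jsonlite::fromJSON(report, simplifyVector = FALSE)
  }
  report <- unclass(report)
  if (is.null(report$provenance)) {
    dm_stop("parse", "not a dotmatch report: missing provenance block")
  }
  fmt_entry <- function(e, label = NULL) {
    label <- label %||% (e$name %||% "test")
    if (isTRUE(e$skipped)) {
      return(sprintf("- %s: skipped (%s)", label, e$reason))
    }
    sprintf("- %s: %.2f vs. %.2f units, t(%d) = %.2f, %s",
            label, e$mean_a, e$mean_b, as.integer(round(e$df)), e$statistic,
            format_p(e$p_two_sided))
  }
  lines <- c("# Dot-matching agreement report", "")
  n_tests <- 0L
  if (length(report$p1)) {
    lines <- c(lines, "## P1: consistency vs. random and neighbor baselines", "")
    for (blk in report$p1) {
      lines <- c(lines,
                 sprintf("### %s / %s", blk$cohort, blk$condition),
                 sprintf("- mean per-probe consistency: %.2f units (baseline %.2f, %g pairs, seed %d)",
                         blk$aggregate, blk$baseline, blk$baseline_n_pairs,
                         blk$baseline_seed),
                 fmt_entry(blk$vs_random), fmt_entry(blk$vs_neighbor), "")
      n_tests <- n_tests + 2L
    }
  }
  for (part in c("p2", "p3")) {
    blk <- report[[part]]
    if (!length(blk)) next
    lines <- c(lines, sprintf("## %s: %s", toupper(part),
                              if (part == "p2") "condition comparisons"
                              else "expert comparisons"), "")
    if (isTRUE(blk$skipped)) {
      lines <- c(lines, sprintf("- skipped: %s", blk$reason), "")
      next
    }
    for (nm in names(blk)) {
      e <- blk[[nm]]
      if (is.character(e) && length(e) == 1L) {
        lines <- c(lines, sprintf("- %s: %s", nm, e))
        next
      }
      if (!is.list(e) || (is.null(e$name) && !isTRUE(e$skipped))) next
      lines <- c(lines, fmt_entry(e, nm))
      n_tests <- n_tests + 1L
    }
    lines <- c(lines, "")
  }
  if (n_tests == 0L) {
    lines <- c(lines, "No analyses were computed (empty report).", "")
  }
  lines <- c(lines, sprintf("provenance: dotmatch %s, aggregation=%s, median=%s",
                            report$provenance$version,
                            report$provenance$aggregation,
                            report$provenance$median_type))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.dm_report <- function(x, ...) {
  run_report(x)
  invisible(x)
}
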