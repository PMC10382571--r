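# Data model, validation, and file I/O for dot-matching experiments.
#
# The central container is the response table: one row per placed dot, with
# the test-shape outline and the probe set attached as attributes so every
# downstream statistic can validate against them.

dm_cohorts <- c("naive", "expert", "repetition_control")
dm_conditions <- c("without_intermediates", "with_intermediates")
dm_identity_choices <- c("same_class", "right_modified_left",
                         "left_modified_right", "unrelated")

response_columns <- c("observer_id", "cohort", "condition", "stimulus_pair",
                      "probe_id", "repetition", "x", "y", "rt_s")

#' Construct a probe set
#'
#' The labeled probe locations marked on the base stimulus (the paper's
#' design uses 10 per stimulus pair). At least two probes are required
#' because the conservative neighbor test needs a neighbor.
#'
#' @param probe_id Character vector of unique probe labels.
#' @param x,y Probe coordinates on the base stimulus (pixels).
#' @param stimulus_pair Label of the base/test stimulus pair.
#' @return A data frame of class `probe_set` with columns `probe_id`, `x`,
#'   `y` and attribute `stimulus_pair`.
#' @export
probe_set <- function(probe_id, x, y, stimulus_pair = "pair") {
  probe_id <- as.character(probe_id)
  if (length(probe_id) < 2L) {
    dm_stop("validation", "a probe set needs at least 2 probes")
  }
  if (anyDuplicated(probe_id)) {
    dm_stop("validation", "probe ids must be unique")
  }
  pts <- as_points(cbind(x, y))
  if (nrow(pts) != length(probe_id)) {
    dm_stop("validation", "probe_id, x and y must have equal length")
  }
  out <- data.frame(probe_id = probe_id, x = pts[, 1L], y = pts[, 2L],
                    stringsAsFactors = FALSE)
  attr(out, "stimulus_pair") <- as.character(stimulus_pair)[1L]
  class(out) <- c("probe_set", "data.frame")
  out
}

probe_locations <- function(probes) {
  m <- as.matrix(probes[, c("x", "y")])
  rownames(m) <- probes$probe_id
  m
}

#' Construct and validate a response table
#'
#' @param records Data frame with columns `observer_id`, `cohort`,
#'   `condition`, `stimulus_pair`, `probe_id`, `repetition`, `x`, `y`,
#'   and optionally `rt_s` (seconds; `NA` allowed).
#' @param probes A [probe_set()]; every record's `probe_id` must occur in it.
#' @param shape A [shape_outline()] of the test stimulus. Responses falling
#'   outside it are kept but flagged with a warning (out-of-shape dots are
#'   meaningful: some experts decline to place a dot on the organ itself).
#' @param max_repetition Upper bound for the repetition index (the study
#'   design uses 3; aggregated tables use 0).
#' @return The records as a data frame of class `response_table`, with
#'   `shape` and `probes` attributes.
#' @export
response_table <- function(records, probes, shape, max_repetition = 3L) {
  if (!inherits(probes, "probe_set")) {
    dm_stop("validation", "`probes` must be a probe_set")
  }
  assert_shape(shape)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- setdiff(response_columns, "rt_s")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    dm_stop("parse", paste("missing required column(s):",
                           paste(missing, collapse = ", ")))
  }
  if (!"rt_s" %in% names(records)) records$rt_s <- NA_real_
  records <- records[, response_columns]
  records$observer_id <- as.character(records$observer_id)
  records$cohort <- as.character(records$cohort)
  records$condition <- as.character(records$condition)
  records$stimulus_pair <- as.character(records$stimulus_pair)
  records$probe_id <- as.character(records$probe_id)
  if (nrow(records)) {
    bad <- which(!records$cohort %in% dm_cohorts)
    if (length(bad)) {
      dm_stop("parse", sprintf("row %d: unknown cohort '%s'",
                               bad[1L], records$cohort[bad[1L]]))
    }
    bad <- which(!records$condition %in% dm_conditions)
    if (length(bad)) {
      dm_stop("parse", sprintf("row %d: unknown condition '%s'",
                               bad[1L], records$condition[bad[1L]]))
    }
    bad <- which(!records$probe_id %in% probes$probe_id)
    if (length(bad)) {
      dm_stop("parse", sprintf("row %d: probe_id '%s' not in the probe set",
                               bad[1L], records$probe_id[bad[1L]]))
    }
    for (col in c("repetition", "x", "y", "rt_s")) {
      suppressWarnings(records[[col]] <- as.numeric(records[[col]]))
    }
    bad <- which(!is.finite(records$x) | !is.finite(records$y))
    if (length(bad)) {
      dm_stop("parse", sprintf("row %d: non-numeric or non-finite coordinates", bad[1L]))
    }
    bad <- which(!is.finite(records$repetition) |
                   records$repetition < 0 |
                   records$repetition > max_repetition |
                   records$repetition != floor(records$repetition))
    if (length(bad)) {
      dm_stop("parse", sprintf("row %d: repetition must be an integer in 0..%d",
                               bad[1L], max_repetition))
    }
    records$repetition <- as.integer(records$repetition)
    bad <- which(!is.na(records$rt_s) & records$rt_s <= 0)
    if (length(bad)) {
      dm_stop("parse", sprintf("row %d: response time must be positive", bad[1L]))
    }
    outside <- !polygon_contains(shape, records[, c("x", "y")])
    if (any(outside)) {
      dm_warn(sprintf("%d of %d responses fall outside the shape outline (kept)",
                      sum(outside), nrow(records)))
    }
  } else {
    records$repetition <- integer(0L)
  }
  rownames(records) <- NULL
  attr(records, "shape") <- shape
  attr(records, "probes") <- probes
  class(records) <- c("response_table", "data.frame")
  records
}

table_shape <- function(table) attr(table, "shape")
table_probes <- function(table) attr(table, "probes")

assert_response_table <- function(table) {
  if (!inherits(table, "response_table")) {
    dm_stop("validation", "expected a response_table")
  }
  table
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf(
    "<response_table> %d records | %d observer(s) | cohorts: %s | conditions: %s\n",
    nrow(x), length(unique(x$observer_id)),
    paste(sort(unique(x$cohort)), collapse = ", "),
    paste(sort(unique(x$condition)), collapse = ", ")))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read a response CSV
#'
#' Expects header columns `observer_id, cohort, condition, stimulus_pair,
#' probe_id, repetition, x, y` and optionally `rt_s`. Unknown columns are
#' dropped with a warning; malformed rows raise a parse error naming the row.
#'
#' @param path CSV path.
#' @param probes A [probe_set()].
#' @param shape A [shape_outline()].
#' @return A [response_table()]; row order preserved.
#' @export
read_responses <- function(path, probes, shape) {
  if (!file.exists(path)) {
    dm_stop("validation", sprintf("response file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- setdiff(response_columns, "rt_s")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    dm_stop("parse", sprintf("%s: missing required column(s): %s",
                             path, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), response_columns)
  if (length(extra)) {
    dm_warn(sprintf("%s: ignoring unknown column(s): %s",
                    path, paste(extra, collapse = ", ")))
    df <- df[, setdiff(names(df), extra), drop = FALSE]
  }
  response_table(df, probes, shape)
}

#' Write a response table to CSV
#'
#' Fixed column order, UTF-8, coordinates at 6 significant digits (the
#' round-trip contract of [read_responses()]).
#'
#' @param table A [response_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(table, path) {
  assert_response_table(table)
  out <- as.data.frame(table)
  for (col in c("x", "y", "rt_s")) out[[col]] <- signif(out[[col]], 6L)
  utf8_write_csv(out, path)
  invisible(path)
}

utf8_write_csv <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
}

#' Read a probe CSV
#'
#' Columns: `probe_id, x, y` and optionally `stimulus_pair` (constant).
#'
#' @param path CSV path.
#' @return A [probe_set()].
#' @export
read_probes <- function(path) {
  if (!file.exists(path)) {
    dm_stop("validation", sprintf("probe file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("probe_id", "x", "y"), names(df))
  if (length(missing)) {
    dm_stop("parse", sprintf("%s: missing required column(s): %s",
                             path, paste(missing, collapse = ", ")))
  }
  pair <- if ("stimulus_pair" %in% names(df)) df$stimulus_pair[1L] else "pair"
  probe_set(df$probe_id, df$x, df$y, stimulus_pair = pair)
}

#' Write a probe set to CSV
#' @param probes A [probe_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probes <- function(probes, path) {
  df <- as.data.frame(probes)
  df$stimulus_pair <- attr(probes, "stimulus_pair")
  df$x <- signif(df$x, 6L); df$y <- signif(df$y, 6L)
  utf8_write_csv(df, path)
  invisible(path)
}

#' Aggregate repetitions into one response per observer and probe
#'
#' Collapses the repeated placements of each (observer, cohort, condition,
#' stimulus pair, probe) group into a single record: the location is the
#' componentwise median (default; robust to one slip) or the mean across
#' repetitions, the response time is the mean, and the repetition index is
#' set to 0. Idempotent: aggregating an aggregated table is a no-op.
#'
#' @param table A [response_table()].
#' @param location `"median"` (default) or `"mean"`.
#' @return An aggregated [response_table()].
#' @export
aggregate_repetitions <- function(table, location = c("median", "mean")) {
  assert_response_table(table)
  location <- match.arg(location)
  if (!nrow(table)) return(table)
  key <- interaction(table$observer_id, table$cohort, table$condition,
                     table$stimulus_pair, table$probe_id, drop = TRUE)
  idx <- split(seq_len(nrow(table)), key)
  rows <- lapply(idx, function(i) {
    g <- table[i, , drop = FALSE]
    loc <- if (location == "median") {
      componentwise_median(g[, c("x", "y")])
    } else {
      c(x = mean(g$x), y = mean(g$y))
    }
    rt <- if (all(is.na(g$rt_s))) NA_real_ else mean(g$rt_s, na.rm = TRUE)
    data.frame(observer_id = g$observer_id[1L], cohort = g$cohort[1L],
               condition = g$condition[1L], stimulus_pair = g$stimulus_pair[1L],
               probe_id = g$probe_id[1L], repetition = 0L,
               x = loc[["x"]], y = loc[["y"]], rt_s = rt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cohort, out$condition, out$observer_id, out$probe_id), ]
  suppressWarnings(
    response_table(out, table_probes(table), table_shape(table))
  )
}

is_aggregated <- function(table) {
  !nrow(table) || all(table$repetition == 0L)
}

#' Filter a response table by cohort and condition
#'
#' @param table A [response_table()].
#' @param cohort,condition Optional filters (`NULL` keeps everything).
#' @return A filtered [response_table()] (possibly empty).
#' @export
select_responses <- function(table, cohort = NULL, condition = NULL) {
  assert_response_table(table)
  keep <- rep(TRUE, nrow(table))
  if (!is.null(cohort)) {
    cohort <- match.arg(cohort, dm_cohorts)
    keep <- keep & table$cohort == cohort
  }
  if (!is.null(condition)) {
    condition <- match.arg(condition, dm_conditions)
    keep <- keep & table$condition == condition
  }
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  suppressWarnings(response_table(out, table_probes(table), table_shape(table)))
}

#' Read a questionnaire CSV
#'
#' Columns: `observer_id, condition, stimulus_pair, identity_choices,
#' confidence, similarity`. `identity_choices` is a `|`-separated non-empty
#' subset of `same_class, right_modified_left, left_modified_right,
#' unrelated`; `confidence` and `similarity` are 6-point codes (1-6).
#'
#' @param path CSV path.
#' @return A validated data frame of class `questionnaire_table`.
#' @export
read_questionnaire <- function(path) {
  if (!file.exists(path)) {
    dm_stop("validation", sprintf("questionnaire file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  questionnaire_table(df)
}

#' Validate a questionnaire table
#' @param df Data frame with the columns documented in [read_questionnaire()].
#' @return The validated table, classed `questionnaire_table`.
#' @export
questionnaire_table <- function(df) {
  required <- c("observer_id", "condition", "stimulus_pair",
                "identity_choices", "confidence", "similarity")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    dm_stop("parse", paste("questionnaire: missing column(s):",
                           paste(missing, collapse = ", ")))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)[, required]
  df$observer_id <- as.character(df$observer_id)
  df$condition <- as.character(df$condition)
  if (nrow(df)) {
    bad <- which(!df$condition %in% dm_conditions)
    if (length(bad)) {
      dm_stop("parse", sprintf("questionnaire row %d: unknown condition '%s'",
                               bad[1L], df$condition[bad[1L]]))
    }
    choices <- strsplit(as.character(df$identity_choices), "|", fixed = TRUE)
    for (i in seq_along(choices)) {
      ch <- choices[[i]]
      if (!length(ch) || any(!ch %in% dm_identity_choices)) {
        dm_stop("parse", sprintf(
          "questionnaire row %d: identity_choices must be a non-empty subset of {%s}",
          i, paste(dm_identity_choices, collapse = ", ")))
      }
    }
    for (col in c("confidence", "similarity")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(!is.finite(v) | v < 1 | v > 6 | v != floor(v))
      if (length(bad)) {
        dm_stop("parse", sprintf("questionnaire row %d: %s must be an integer 1-6",
                                 bad[1L], col))
      }
      df[[col]] <- as.integer(v)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("questionnaire_table", "data.frame")
  df
}

#' Write a questionnaire table to CSV
#' @param q A `questionnaire_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_questionnaire <- function(q, path) {
  utf8_write_csv(as.data.frame(q), path)
  invisible(path)
}

#' Adapter for an external raw-data deposit
#'
#' Maps a directory of deposited CSV files onto the package's data model by
#' renaming columns and recoding factor levels. The deposit layout is never
#' assumed elsewhere in the package: all analysis code consumes the validated
#' [response_table()] this adapter returns. Supply `mapping` to translate the
#' deposit's column names and level codes into the package's vocabulary.
#'
#' @param responses_csv,probes_csv,shape_geojson Paths to the deposit files.
#' @param mapping Named list with entries `columns` (named character vector,
#'   deposit name -> package name), `cohorts` and `conditions` (named
#'   character vectors recoding deposit levels).
#' @return A [response_table()].
#' @export
read_zenodo_deposit <- function(responses_csv, probes_csv, shape_geojson,
                                mapping = list()) {
  probes <- read_probes(probes_csv)
  shape <- read_shape_geojson(shape_geojson)
  df <- utils::read.csv(responses_csv, stringsAsFactors = FALSE)
  cols <- mapping$columns
  if (!is.null(cols)) {
    hit <- names(df) %in% names(cols)
    names(df)[hit] <- unname(cols[names(df)[hit]])
  }
  recode <- function(v, map) {
    if (is.null(map)) return(v)
    hit <- v %in% names(map)
    v[hit] <- unname(map[v[hit]])
    v
  }
  if ("cohort" %in% names(df)) df$cohort <- recode(df$cohort, mapping$cohorts)
  if ("condition" %in% names(df)) {
    df$condition <- recode(df$condition, mapping$conditions)
  }
  response_table(df, probes, shape)
}
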