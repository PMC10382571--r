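make_fixture_bits <- function() {
  shape <- unit_square(100)
  probes <- toy_probes(rbind(c(20, 20), c(80, 30), c(50, 80)))
  rec <- expand.grid(observer_id = c("o1", "o2"), probe_id = probes$probe_id,
                     repetition = 1:3, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  rec$cohort <- "naive"
  rec$condition <- "without_intermediates"
  rec$stimulus_pair <- "s"
  set.seed(5)
  rec$x <- runif(nrow(rec), 10, 90)
  rec$y <- runif(nrow(rec), 10, 90)
  rec$rt_s <- runif(nrow(rec), 3, 9)
  list(shape = shape, probes = probes, records = rec)
}

test_that("response CSV round-trips through write and read", {
  bits <- make_fixture_bits()
  tab <- response_table(bits$records, bits$probes, bits$shape)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(tab, path)
  back <- read_responses(path, bits$probes, bits$shape)
  expect_equal(nrow(back), nrow(tab))
  expect_identical(back$probe_id, tab$probe_id)
  expect_equal(back$x, signif(tab$x, 6))
  expect_equal(back$rt_s, signif(tab$rt_s, 6))
  # a second round trip is the identity
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("response parsing errors name the offending row", {
  bits <- make_fixture_bits()
  path <- withr::local_tempfile(fileext = ".csv")

  df <- bits$records[1:3, ]
  df$probe_id[2] <- "p99"
  write.csv(df, path, row.names = FALSE)
  err <- tryCatch(read_responses(path, bits$probes, bits$shape),
                  dotmatch_parse = function(e) conditionMessage(e))
  expect_match(err, "row 2")
  expect_match(err, "p99")

  df <- bits$records[1:2, ]
  df$x[2] <- "not-a-number"
  write.csv(df, path, row.names = FALSE)
  expect_dm_error(read_responses(path, bits$probes, bits$shape), "parse")

  write.csv(bits$records[0, setdiff(names(bits$records), "x")], path,
            row.names = FALSE)
  expect_dm_error(read_responses(path, bits$probes, bits$shape), "parse")
})

test_that("empty and extra-column inputs are handled", {
  bits <- make_fixture_bits()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(bits$records[0, ], path, row.names = FALSE)
  tab <- read_responses(path, bits$probes, bits$shape)
  expect_identical(nrow(tab), 0L)
  expect_dm_error(per_probe_consistency(tab), "insufficient_data")

  df <- bits$records[1, ]
  df$mystery <- "x"
  write.csv(df, path, row.names = FALSE)
  expect_warning(tab <- read_responses(path, bits$probes, bits$shape),
                 "mystery")
  expect_identical(nrow(tab), 1L)
})

test_that("out-of-shape responses are kept with a warning", {
  bits <- make_fixture_bits()
  df <- bits$records[1:4, ]
  df$x[1] <- 500
  expect_warning(tab <- response_table(df, bits$probes, bits$shape),
                 "outside")
  expect_identical(nrow(tab), 4L)
})

test_that("repetition aggregation uses per-axis median and mean RT, and is idempotent", {
  shape <- unit_square(100)
  probes <- toy_probes(rbind(c(10, 10), c(90, 90)))
  df <- data.frame(observer_id = "o1", cohort = "naive",
                   condition = "without_intermediates", stimulus_pair = "s",
                   probe_id = "p01", repetition = 1:3,
                   x = c(0, 2, 10), y = c(0, 0, 0), rt_s = c(4, 6, 8))
  tab <- suppressWarnings(response_table(df, probes, shape))
  agg <- aggregate_repetitions(tab)
  expect_identical(nrow(agg), 1L)
  expect_equal(agg$x, 2)
  expect_equal(agg$y, 0)
  expect_equal(agg$rt_s, 6)
  expect_identical(agg$repetition, 0L)
  # mean alternative
  agg_mean <- aggregate_repetitions(tab, location = "mean")
  expect_equal(agg_mean$x, 4)
  # idempotent, and a singleton passes through unchanged
  expect_equal(as.data.frame(aggregate_repetitions(agg)), as.data.frame(agg))
  one <- suppressWarnings(response_table(df[1, ], probes, shape))
  agg1 <- aggregate_repetitions(one)
  expect_equal(agg1$x, df$x[1])
  expect_equal(agg1$rt_s, df$rt_s[1])
})

test_that("select_responses filters cohort and condition", {
  bits <- make_fixture_bits()
  rec <- bits$records
  rec2 <- rec
  rec2$condition <- "with_intermediates"
  rec3 <- rec[1:6, ]
  rec3$cohort <- "expert"
  tab <- response_table(rbind(rec, rec2, rec3), bits$probes, bits$shape)
  sel <- select_responses(tab, "naive", "without_intermediates")
  expect_identical(nrow(sel), nrow(rec))
  expect_true(all(sel$condition == "without_intermediates"))
  expect_identical(nrow(select_responses(tab, "expert", "with_intermediates")), 0L)
  # per-observer grouping counts preserved
  sel2 <- select_responses(tab, "naive", "with_intermediates")
  expect_equal(table(sel2$observer_id), table(rec2$observer_id))
  empty <- select_responses(sel2[0, ] |> response_table(bits$probes, bits$shape),
                            "naive", NULL)
  expect_identical(nrow(empty), 0L)
})

test_that("questionnaire validation enforces choice sets and Likert range", {
  q <- data.frame(observer_id = c("o1", "o1"),
                  condition = c("without_intermediates", "with_intermediates"),
                  stimulus_pair = "s",
                  identity_choices = c("same_class|unrelated", "same_class"),
                  confidence = c(4, 5), similarity = c(3, 6))
  expect_s3_class(questionnaire_table(q), "questionnaire_table")
  bad <- q; bad$identity_choices[1] <- ""
  expect_dm_error(questionnaire_table(bad), "parse")
  bad <- q; bad$confidence[1] <- 7
  expect_dm_error(questionnaire_table(bad), "parse")
  bad <- q; bad$identity_choices[2] <- "no_such_choice"
  expect_dm_error(questionnaire_table(bad), "parse")
  path <- withr::local_tempfile(fileext = ".csv")
  write_questionnaire(questionnaire_table(q), path)
  expect_equal(as.data.frame(read_questionnaire(path)),
               as.data.frame(questionnaire_table(q)))
})

test_that("the deposit adapter maps foreign columns and level codes", {
  bits <- make_fixture_bits()
  dir <- withr::local_tempdir()
  write_probes(bits$probes, file.path(dir, "probes.csv"))
  write_shape_geojson(bits$shape, file.path(dir, "shape.geojson"))
  foreign <- data.frame(subject = "s01", group = "control", cond = "two_objects",
                        pair = "waterlily", point = "p01", rep = 1,
                        x = 12.5, y = 40, rt_s = 4.4)
  write.csv(foreign, file.path(dir, "responses.csv"), row.names = FALSE)
  tab <- read_zenodo_deposit(
    file.path(dir, "responses.csv"), file.path(dir, "probes.csv"),
    file.path(dir, "shape.geojson"),
    mapping = list(
      columns = c(subject = "observer_id", group = "cohort", cond = "condition",
                  pair = "stimulus_pair", point = "probe_id", rep = "repetition"),
      cohorts = c(control = "naive"),
      conditions = c(two_objects = "without_intermediates")))
  expect_s3_class(tab, "response_table")
  expect_identical(tab$cohort, "naive")
  expect_identical(tab$condition, "without_intermediates")
})
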