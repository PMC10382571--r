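test_that("median map follows the median convention and omits empty probes", {
  sq <- unit_square(100)
  probes <- toy_probes(rbind(c(10, 10), c(90, 90), c(50, 50)))
  tab <- toy_table(list(p01 = rbind(c(0, 0), c(2, 2), c(10, 0)),
                        p02 = rbind(c(7, 3))),
                   probes, sq)
  expect_warning(mm <- median_map(tab), "p03")
  expect_equal(mm$x[mm$probe_id == "p01"], 2)
  expect_equal(mm$y[mm$probe_id == "p01"], 0)
  # single observer: the map is that observer's response
  expect_equal(unlist(mm[mm$probe_id == "p02", c("x", "y")]),
               c(x = 7, y = 3))
  # cohort plus its point-mirrored copy maps to the mirror centre
  ctr <- c(40, 60)
  pts <- rbind(c(10, 10), c(20, 35), c(33, 70))
  mirrored <- rbind(pts, sweep(-pts, 2, 2 * ctr, "+"))
  tab2 <- toy_table(list(p01 = mirrored, p02 = mirrored), probes, sq)
  mm2 <- suppressWarnings(median_map(tab2))
  expect_equal(unlist(mm2[mm2$probe_id == "p01", c("x", "y")]),
               c(x = ctr[1], y = ctr[2]))
})

test_that("proximity test compares self and other references per probe", {
  sq <- unit_square(1000)
  probes <- toy_probes(rbind(c(100, 100), c(500, 500), c(800, 200)))
  set.seed(41)
  resp <- list(p01 = cbind(rnorm(6, 100, 3), rnorm(6, 100, 3)),
               p02 = cbind(rnorm(6, 500, 3), rnorm(6, 500, 3)),
               p03 = cbind(rnorm(6, 800, 3), rnorm(6, 200, 3)))
  tab <- toy_table(resp, probes, sq)
  own <- median_map(tab)
  # identical references: exactly equal vectors, no effect
  same <- proximity_test(tab, own, own)
  expect_equal(same$per_probe$self, same$per_probe$other)
  expect_equal(same$test$statistic, 0)
  expect_equal(same$test$p_value, 1)
  # displaced other reference: strongly negative
  other <- own
  other$x <- other$x + 50
  shifted <- proximity_test(tab, own, other)
  expect_lt(shifted$test$statistic, 0)
  expect_lt(shifted$test$p_value, 0.01)
  expect_equal(shifted$test$df, 2)
  # responses exactly on ref_self, constant displacement: typed degeneracy
  exact <- toy_table(list(p01 = rbind(c(100, 100), c(100, 100)),
                          p02 = rbind(c(500, 500), c(500, 500)),
                          p03 = rbind(c(800, 200), c(800, 200))),
                     probes, sq)
  ref_self <- data.frame(probe_id = c("p01", "p02", "p03"),
                         x = c(100, 500, 800), y = c(100, 500, 200))
  ref_other <- ref_self
  ref_other$y <- ref_other$y + 25
  err <- tryCatch(proximity_test(exact, ref_self, ref_other),
                  dotmatch_degenerate_test = function(e) e)
  expect_s3_class(err, "dotmatch_degenerate_test")
  expect_identical(err$sign, -1)
  # probes missing from a reference are dropped pairwise
  expect_warning(dropped <- proximity_test(tab, own[1:2, ], own),
                 "drops 1 probe")
  expect_identical(dropped$per_probe$probe_id, c("p01", "p02"))
  expect_dm_error(suppressWarnings(proximity_test(tab, own[1, ], own)),
                  "insufficient_data")
})

test_that("proximity test detects a large injected shift with high power", {
  # truth-map references, 10 observers, 10 probes, sigma = 5, shift = 10 sigma
  runs <- 200
  hits <- 0L
  cfg0 <- synthetic_config(shape_kind = "square", shape_scale = 1000,
                           n_probes = 10, n_observers = 10, n_experts = 0,
                           n_repetitions = 1, sigma_without = 5, sigma_with = 5,
                           sigma_expert = 5, condition_shift = c(0, -50),
                           probe_margin = 30, seed = 1)
  for (r in seq_len(runs)) {
    cfg <- cfg0
    cfg$seed <- 5000L + r
    sim <- simulate_experiment(cfg)
    truth_self <- data.frame(probe_id = rownames(sim$truth$true_map_without),
                             x = sim$truth$true_map_without[, 1],
                             y = sim$truth$true_map_without[, 2])
    truth_other <- data.frame(probe_id = rownames(sim$truth$true_map_with),
                              x = sim$truth$true_map_with[, 1],
                              y = sim$truth$true_map_with[, 2])
    pt <- proximity_test(aggregate_repetitions(sim$responses_without),
                         truth_self, truth_other)
    if (pt$test$p_value < 0.05 && pt$test$statistic < 0) hits <- hits + 1L
  }
  expect_gte(hits / runs, 0.95)
})

test_that("cohort consistency comparison is a paired t aligned by probe", {
  same <- cohort_consistency_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  res <- cohort_consistency_compare(c(1, 2, 3), c(2, 4, 6))
  orc <- oracle_paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(res$statistic, orc$statistic)
  expect_equal(res$statistic, -2 * sqrt(3))
  expect_equal(res$df, 2)
  swapped <- cohort_consistency_compare(c(2, 4, 6), c(1, 2, 3))
  expect_equal(swapped$statistic, -res$statistic)
  # data-frame inputs align on probe_id, not position
  a <- data.frame(probe_id = c("p1", "p2", "p3"), statistic = c(1, 2, 3))
  b <- data.frame(probe_id = c("p3", "p1", "p2"), statistic = c(6, 2, 4))
  res2 <- cohort_consistency_compare(a, b)
  expect_equal(res2$statistic, res$statistic)
})

test_that("response-time test pairs observer means across conditions", {
  sq <- unit_square(100)
  probes <- toy_probes(rbind(c(10, 10), c(90, 90)))
  mk <- function(rts, condition) {
    df <- expand.grid(observer_id = names(rts), probe_id = probes$probe_id,
                      stringsAsFactors = FALSE)
    df$cohort <- "naive"; df$condition <- condition; df$stimulus_pair <- "s"
    df$repetition <- 0L; df$x <- 50; df$y <- 50
    df$rt_s <- unlist(rts)[df$observer_id]
    suppressWarnings(response_table(df, probes, sq))
  }
  a <- mk(c(o1 = 4, o2 = 5, o3 = 6), "without_intermediates")
  b <- mk(c(o1 = 5, o2 = 7, o3 = 9), "with_intermediates")
  res <- response_time_test(a, b)
  expect_equal(res$statistic, -2 * sqrt(3))
  expect_equal(res$df, 2)
  expect_equal(res$mean_a, 5)
  # identical tables: no effect
  same <- response_time_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # adding a constant to all RTs leaves t unchanged
  a2 <- mk(c(o1 = 14, o2 = 15, o3 = 16), "without_intermediates")
  b2 <- mk(c(o1 = 15, o2 = 17, o3 = 19), "with_intermediates")
  expect_equal(response_time_test(a2, b2)$statistic, res$statistic)
  # unmatched observer names the culprit
  c3 <- mk(c(o1 = 5, o2 = 7, o9 = 9), "with_intermediates")
  err <- tryCatch(response_time_test(a, c3),
                  dotmatch_pairing = function(e) conditionMessage(e))
  expect_match(err, "o9")
})

test_that("Likert test pairs observers and respects the scale coding", {
  q <- data.frame(
    observer_id = rep(c("o1", "o2", "o3"), 2),
    condition = rep(c("without_intermediates", "with_intermediates"), each = 3),
    stimulus_pair = "s",
    identity_choices = "same_class",
    confidence = c(1, 2, 3, 2, 4, 6),
    similarity = c(6, 5, 4, 5, 3, 1))
  res <- likert_test(q, "confidence")
  expect_equal(res$statistic, -2 * sqrt(3))
  expect_equal(res$df, 2)
  # reversing the 6-point coding (7 - x) negates t
  q_rev <- q
  q_rev$confidence <- 7 - q_rev$confidence
  expect_equal(likert_test(q_rev, "confidence")$statistic, -res$statistic)
  # similarity column is independent
  expect_equal(likert_test(q, "similarity")$statistic,
               oracle_paired_t(c(6, 5, 4), c(5, 3, 1))$statistic)
  # incomplete pairing
  expect_dm_error(likert_test(q[-2, ], "confidence"), "pairing")
})

test_that("identity test codes choices and uses the pooled two-sample t", {
  mk_q <- function(choices) {
    data.frame(observer_id = sprintf("o%d", seq_along(choices)),
               condition = "without_intermediates", stimulus_pair = "s",
               identity_choices = choices, confidence = 3, similarity = 3)
  }
  coding <- c(unrelated = 1, same_class = 2, right_modified_left = 3,
              left_modified_right = 4)
  # each selected choice contributes one coded observation
  q_a <- mk_q(c("unrelated", "same_class", "right_modified_left"))   # 1,2,3
  q_b <- mk_q(c("left_modified_right|unrelated",                      # 4,1
                "right_modified_left|same_class"))                    # 3,2
  res_ab <- identity_test(q_a, q_b, coding)
  orc_ab <- oracle_two_sample_t(c(1, 2, 3), c(4, 1, 3, 2))
  expect_equal(res_ab$statistic, orc_ab$statistic)
  expect_equal(res_ab$df, orc_ab$df)
  # closed-form pooled case a = [1,2,3] vs b = [4,5,6]: t = -3.6742, df = 4
  res_closed <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res_closed$statistic, -3 / sqrt(2 / 3))
  expect_equal(round(res_closed$statistic, 4), -3.6742)
  expect_equal(res_closed$df, 4)
  # identical observation lists: no effect
  expect_equal(identity_test(q_a, q_a, coding)$statistic, 0)
  # scaling the coding leaves t unchanged
  expect_equal(identity_test(q_a, q_b, coding * 3.7)$statistic,
               res_ab$statistic)
  expect_dm_error(identity_test(q_a[1, ], q_b, coding), "insufficient_data")
  expect_dm_error(identity_test(q_a, q_b, coding[-1]), "validation")
})

test_that("paired and two-sample t match independent oracles on random vectors", {
  set.seed(77)
  for (r in 1:50) {
    n <- sample(3:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    res <- paired_t(a, b)
    orc <- oracle_paired_t(a, b)
    expect_equal(res$statistic, orc$statistic, tolerance = 1e-12)
    expect_equal(res$p_value, orc$p, tolerance = 1e-12)
    m <- sample(2:20, 1)
    c2 <- rnorm(m)
    res2 <- two_sample_t(a, c2)
    orc2 <- oracle_two_sample_t(a, c2)
    expect_equal(res2$statistic, orc2$statistic, tolerance = 1e-12)
    expect_equal(res2$df, orc2$df)
  }
})

test_that("null proximity comparisons with independent references are calibrated", {
  # zero condition shift; references estimated from two cohorts independent of
  # the analysed responses, making self/other exchangeable under the null
  runs <- 200
  rej <- 0L
  cfg0 <- synthetic_config(shape_kind = "square", shape_scale = 1000,
                           n_probes = 10, n_observers = 10, n_experts = 10,
                           n_repetitions = 1, sigma_without = 5, sigma_with = 5,
                           sigma_expert = 5, condition_shift = c(0, 0),
                           probe_margin = 30, seed = 1)
  for (r in seq_len(runs)) {
    cfg <- cfg0
    cfg$seed <- 9000L + r
    sim <- simulate_experiment(cfg)
    ref_self <- median_map(aggregate_repetitions(sim$responses_with))
    ref_other <- median_map(aggregate_repetitions(sim$responses_expert))
    pt <- proximity_test(aggregate_repetitions(sim$responses_without),
                         ref_self, ref_other)
    if (pt$test$p_value < 0.05) rej <- rej + 1L
  }
  expect_lte(rej / runs, 0.05 + 3 * sqrt(0.05 * 0.95 / runs))
})
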