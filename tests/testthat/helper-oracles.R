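# Independent closed-form oracles and fixture builders. The oracles never
# call into the package's statistics, so implementation and check stay on
# separate routes.

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(statistic = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

oracle_two_sample_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, df = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# brute-force pair enumeration
oracle_mean_pairwise <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  acc <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      acc <- c(acc, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
  }
  mean(acc)
}

# expected distance between two uniform points: exact closed forms
SQUARE_PAIR_DIST <- (2 + sqrt(2) + 5 * asinh(1)) / 15  # unit square, 0.521405...
DISC_PAIR_DIST <- 128 / (45 * pi)                      # unit disc,   0.905414...

unit_square <- function(side = 1) {
  shape_outline(rbind(c(0, 0), c(side, 0), c(side, side), c(0, side)),
                label = "square")
}

toy_probes <- function(xy, ids = sprintf("p%02d", seq_len(nrow(xy)))) {
  probe_set(ids, xy[, 1], xy[, 2])
}

# aggregated single-cohort table from a per-probe list of observer responses
toy_table <- function(resp, probes, shape,
                      cohort = "naive", condition = "without_intermediates",
                      rt = NA_real_) {
  rows <- do.call(rbind, lapply(names(resp), function(pid) {
    m <- resp[[pid]]
    data.frame(observer_id = sprintf("o%d", seq_len(nrow(m))),
               cohort = cohort, condition = condition, stimulus_pair = "s",
               probe_id = pid, repetition = 0L, x = m[, 1], y = m[, 2],
               rt_s = rt, stringsAsFactors = FALSE)
  }))
  suppressWarnings(response_table(rows, probes, shape))
}

expect_dm_error <- function(expr, kind) {
  expect_error(expr, class = paste0("dotmatch_", kind))
}
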