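# Synthetic experiment generator: shapes, probes, ground-truth correspondence
# maps, naive and expert cohorts in both conditions, response times, and
# questionnaires, with known ground truth so every pipeline stage can be
# exercised and calibrated (power / type-I) without external data.

#' Configuration for a synthetic dot-matching experiment
#'
#' Defaults emulate the waterlily arm of the study design: 10 probe
#' locations, 10 naive observers who complete both conditions, a small
#' expert cohort, 3 repetitions per probe, isotropic Gaussian placement
#' noise (redrawn until inside the contour), a between-condition shift of
#' the true correspondence locations, lognormal response times, and 6-point
#' Likert plus multiple-choice identity responses. The shape scale puts the
#' uniform baseline near 235 px and the noise SDs are set from the analytic
#' relation consistency = sigma_eff * sqrt(pi) (with sigma_eff = 0.67 sigma
#' after median-of-3 aggregation) so that expected consistencies sit at the
#' published waterlily magnitudes (~43 and ~100 px).
#'
#' @param shape_kind `"square"`, `"disc"`, or `"blob"` (radial-harmonic
#'   polygon).
#' @param shape_scale Characteristic size in pixels (square side / disc or
#'   blob base radius).
#' @param n_probes,n_observers,n_experts,n_repetitions Design counts (>= 1;
#'   `n_experts` may be 0 to omit the expert cohort).
#' @param sigma_without,sigma_with,sigma_expert Isotropic placement-noise SD
#'   per axis, pixels.
#' @param condition_shift Displacement of the true correspondence locations
#'   in the with-intermediates condition: a length-2 vector applied to every
#'   probe, or an `n_probes` x 2 matrix of per-probe vectors.
#' @param rt_lognormal List with per-condition `c(meanlog, sdlog)` for the
#'   lognormal response-time distribution (seconds).
#' @param likert_means List of per-condition latent means for `confidence`
#'   and `similarity` (discretised Gaussian, clipped to 1-6).
#' @param likert_sd Latent SD of the Likert responses.
#' @param identity_probs List of per-condition selection probabilities for
#'   the four identity choices (each selected independently; an empty
#'   selection falls back to the most probable choice).
#' @param blob_harmonics List `amplitude`, `phase`, `order` for the blob
#'   radius r(theta) = scale * (1 + sum a_k cos(k theta + phi_k));
#'   `sum(abs(amplitude))` must stay below 0.5 so the polygon is simple.
#' @param n_vertices Polygon resolution for disc/blob shapes (>= 64 for blobs).
#' @param probe_margin Minimum distance of true locations from the contour
#'   (pixels); defaults to the largest noise SD, capped at a feasible fraction
#'   of the scale. Keeps boundary clipping negligible around the truth.
#' @param stimulus_pair Label for the simulated stimulus pair.
#' @param seed Integer seed; the whole experiment is reproducible from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(shape_kind = c("blob", "square", "disc"),
                             shape_scale = 260,
                             n_probes = 10L,
                             n_observers = 10L,
                             n_experts = 6L,
                             n_repetitions = 3L,
                             sigma_without = 36,
                             sigma_with = 84,
                             sigma_expert = 16,
                             condition_shift = c(0, -150),
                             rt_lognormal = list(
                               without_intermediates = c(meanlog = 1.612, sdlog = 0.5),
                               with_intermediates = c(meanlog = 1.683, sdlog = 0.5)),
                             likert_means = list(
                               confidence = c(without_intermediates = 4.5,
                                              with_intermediates = 4.7),
                               similarity = c(without_intermediates = 3.8,
                                              with_intermediates = 4.5)),
                             likert_sd = 0.9,
                             identity_probs = list(
                               without_intermediates = c(same_class = 0.45,
                                                         right_modified_left = 0.25,
                                                         left_modified_right = 0.15,
                                                         unrelated = 0.25),
                               with_intermediates = c(same_class = 0.55,
                                                      right_modified_left = 0.35,
                                                      left_modified_right = 0.15,
                                                      unrelated = 0.15)),
                             blob_harmonics = list(amplitude = c(0.12, 0.08, 0.05),
                                                   phase = c(0.7, 2.1, 4.4),
                                                   order = c(2L, 3L, 4L)),
                             n_vertices = 128L,
                             probe_margin = NULL,
                             stimulus_pair = "synthetic-pair",
                             seed = 1L) {
  shape_kind <- match.arg(shape_kind)
  for (nm in c("n_probes", "n_observers", "n_repetitions")) {
    if (!is_count(get(nm), min = 1L)) {
      dm_stop("config", sprintf("`%s` must be a positive integer", nm))
    }
  }
  if (!is_count(n_experts, min = 0L)) {
    dm_stop("config", "`n_experts` must be a non-negative integer")
  }
  if (n_probes < 2L) dm_stop("config", "`n_probes` must be >= 2 (neighbor analysis)")
  for (nm in c("sigma_without", "sigma_with", "sigma_expert", "shape_scale",
               "likert_sd")) {
    if (!is_number(get(nm)) || get(nm) <= 0) {
      dm_stop("config", sprintf("`%s` must be a positive number", nm))
    }
  }
  shift <- condition_shift
  if (is.null(dim(shift))) {
    if (length(shift) != 2L) dm_stop("config", "`condition_shift` must have length 2")
    shift <- matrix(rep(as.numeric(shift), each = n_probes), ncol = 2L)
  } else {
    shift <- as.matrix(shift)
    if (!all(dim(shift) == c(n_probes, 2L))) {
      dm_stop("config", "`condition_shift` matrix must be n_probes x 2")
    }
  }
  if (!all(is.finite(shift))) dm_stop("config", "`condition_shift` must be finite")
  if (shape_kind == "blob") {
    h <- blob_harmonics
    if (sum(abs(h$amplitude)) >= 0.5) {
      dm_stop("config", "`blob_harmonics`: sum of |amplitude| must be < 0.5")
    }
    if (n_vertices < 64L) dm_stop("config", "blob shapes need `n_vertices` >= 64")
  }
  if (!is_count(seed)) dm_stop("config", "`seed` must be an integer")
  structure(
    list(shape_kind = shape_kind, shape_scale = shape_scale,
         n_probes = as.integer(n_probes), n_observers = as.integer(n_observers),
         n_experts = as.integer(n_experts), n_repetitions = as.integer(n_repetitions),
         sigma_without = sigma_without, sigma_with = sigma_with,
         sigma_expert = sigma_expert, condition_shift = shift,
         rt_lognormal = rt_lognormal, likert_means = likert_means,
         likert_sd = likert_sd, identity_probs = identity_probs,
         blob_harmonics = blob_harmonics, n_vertices = as.integer(n_vertices),
         probe_margin = probe_margin, stimulus_pair = stimulus_pair,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate the test-shape outline of a synthetic experiment
#'
#' `square`: axis-aligned square of side `shape_scale` with corner at the
#' origin. `disc`: regular `n_vertices`-gon of radius `shape_scale`.
#' `blob`: radial-harmonic polygon r(theta) = scale * (1 + sum a_k
#' cos(k theta + phi_k)); with all amplitudes zero it degenerates to the
#' disc. Disc and blob are centred away from the origin so all coordinates
#' are positive (image convention).
#'
#' @param config A [synthetic_config()].
#' @return A [shape_outline()].
#' @export
make_shape <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  s <- config$shape_scale
  if (config$shape_kind == "square") {
    return(shape_outline(rbind(c(0, 0), c(s, 0), c(s, s), c(0, s)),
                         label = "square"))
  }
  n <- config$n_vertices
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  r <- rep(1, n)
  if (config$shape_kind == "blob") {
    h <- config$blob_harmonics
    for (k in seq_along(h$order)) {
      r <- r + h$amplitude[k] * cos(h$order[k] * theta + h$phase[k])
    }
  }
  r <- r * s
  centre <- 1.6 * s
  shape_outline(cbind(centre + r * cos(theta), centre + r * sin(theta)),
                label = config$shape_kind)
}

default_margin <- function(config, shape) {
  m <- config$probe_margin
  if (is.null(m)) {
    m <- max(config$sigma_without, config$sigma_with, config$sigma_expert)
  }
  # never demand more clearance than the shape can offer
  min(m, 0.35 * sqrt(shape$area / pi))
}

# Sample n true probe locations such that both the location and its shifted
# counterpart lie inside the shape with `margin` clearance from the contour.
# Probes mark deliberately distinct locations in this paradigm, so from a
# pool of eligible candidates the n mutually farthest ones are kept
# (greedy farthest-point selection) rather than n independent uniform draws.
sample_truth <- function(shape, n, shift, margin, max_tries = 10000L) {
  eligible <- function(pts, sh) {
    keep <- polygon_contains(shape, pts)
    if (any(keep)) {
      bd <- vapply(which(keep), function(i) boundary_distance(shape, pts[i, ]),
                   numeric(1L))
      keep[which(keep)] <- bd >= margin
    }
    keep
  }
  # per-probe shifts may differ; candidates are screened against the mean
  # shift first and re-checked per probe after assignment
  pool <- matrix(numeric(0L), ncol = 2L)
  target <- max(200L, 40L * n)
  tries <- 0L
  mean_shift <- colMeans(shift)
  while (nrow(pool) < target && tries < max_tries) {
    tries <- tries + 1L
    cand <- sample_uniform(shape, 256L)
    keep <- eligible(cand, shape) &
      eligible(cand + rep(mean_shift, each = nrow(cand)), shape)
    pool <- rbind(pool, cand[keep, , drop = FALSE])
  }
  if (nrow(pool) < n) {
    dm_stop("config", paste(
      "could not place true probe locations inside the shape;",
      "probe_margin or condition_shift too large for shape_scale"))
  }
  # greedy farthest-point traversal, seeded at the candidate nearest the
  # pool centroid so the layout is spread but reproducible
  ctr <- colMeans(pool)
  sel <- which.min((pool[, 1L] - ctr[1L])^2 + (pool[, 2L] - ctr[2L])^2)
  mind <- sqrt((pool[, 1L] - pool[sel, 1L])^2 + (pool[, 2L] - pool[sel, 2L])^2)
  while (length(sel) < n) {
    nxt <- which.max(mind)
    sel <- c(sel, nxt)
    d <- sqrt((pool[, 1L] - pool[nxt, 1L])^2 + (pool[, 2L] - pool[nxt, 2L])^2)
    mind <- pmin(mind, d)
  }
  out <- pool[sel, , drop = FALSE]
  # enforce the per-probe shift constraint exactly
  for (i in seq_len(n)) {
    q <- out[i, ] + shift[i, ]
    if (!(polygon_contains(shape, q) && boundary_distance(shape, q) >= margin)) {
      ok_q <- eligible(pool + rep(shift[i, ], each = nrow(pool)), shape)
      if (!any(ok_q)) {
        dm_stop("config", paste(
          "could not place true probe locations inside the shape;",
          "probe_margin or condition_shift too large for shape_scale"))
      }
      cand <- which(ok_q)
      d <- sqrt((pool[cand, 1L] - out[i, 1L])^2 + (pool[cand, 2L] - out[i, 2L])^2)
      out[i, ] <- pool[cand[which.min(d)], ]
    }
  }
  colnames(out) <- c("x", "y")
  out
}

# isotropic Gaussian placements around per-row centres, redrawn until inside
# the shape (rejection clipping)
clipped_gaussian <- function(shape, centres, sigma, max_tries = 10000L) {
  n <- nrow(centres)
  out <- matrix(NA_real_, n, 2L)
  todo <- seq_len(n)
  tries <- 0L
  while (length(todo)) {
    tries <- tries + 1L
    if (tries > max_tries) {
      dm_stop("config",
              sprintf("sigma = %g too large for the shape: a response failed %d redraws",
                      sigma, max_tries))
    }
    cand <- centres[todo, , drop = FALSE] +
      matrix(stats::rnorm(2L * length(todo), sd = sigma), ncol = 2L)
    inside <- polygon_contains(shape, cand)
    out[todo[inside], ] <- cand[inside, , drop = FALSE]
    todo <- todo[!inside]
  }
  colnames(out) <- c("x", "y")
  out
}

likert_draw <- function(n, mean, sd) {
  pmin(6L, pmax(1L, as.integer(round(stats::rnorm(n, mean, sd)))))
}

identity_draw <- function(probs) {
  pick <- names(probs)[stats::runif(length(probs)) < probs]
  if (!length(pick)) pick <- names(probs)[which.max(probs)]
  paste(pick, collapse = "|")
}

#' Simulate a complete dot-matching experiment
#'
#' Generates the test shape, true correspondence maps for both conditions
#' (the with-intermediates truth is the without truth displaced by
#' `condition_shift`), naive responses in both conditions, expert responses
#' around the with-intermediates truth, response times, and questionnaires.
#' Every response is the condition's true location plus isotropic Gaussian
#' noise, redrawn until it falls inside the contour. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_experiment`: `responses_without`,
#'   `responses_with`, `responses_expert` (`NULL` when `n_experts = 0`),
#'   `responses` (all rows combined), `questionnaire`, `truth` (list with
#'   `true_map_without`, `true_map_with`, `config`), `shape`, `probes`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    shape <- make_shape(config)
    margin <- default_margin(config, shape)
    truth_wo <- sample_truth(shape, config$n_probes, config$condition_shift, margin)
    truth_wi <- truth_wo + config$condition_shift
    pid <- sprintf("p%02d", seq_len(config$n_probes))
    rownames(truth_wo) <- rownames(truth_wi) <- pid
    # base-stimulus probe locations: the without-intermediates truth, i.e. the
    # synthetic base->test correspondence is the identity map
    probes <- probe_set(pid, truth_wo[, 1L], truth_wo[, 2L],
                        stimulus_pair = config$stimulus_pair)

    gen_cohort <- function(observers, cohort, condition, truth, sigma,
                           n_rep, rt_par = NULL) {
      grid <- expand.grid(repetition = seq_len(n_rep), probe = seq_len(config$n_probes),
                          obs = seq_along(observers), KEEP.OUT.ATTRS = FALSE)
      centres <- truth[grid$probe, , drop = FALSE]
      pts <- clipped_gaussian(shape, centres, sigma)
      rt <- if (is.null(rt_par)) NA_real_ else {
        stats::rlnorm(nrow(grid), meanlog = rt_par[["meanlog"]],
                      sdlog = rt_par[["sdlog"]])
      }
      data.frame(observer_id = observers[grid$obs], cohort = cohort,
                 condition = condition, stimulus_pair = config$stimulus_pair,
                 probe_id = pid[grid$probe], repetition = grid$repetition,
                 x = pts[, 1L], y = pts[, 2L], rt_s = rt,
                 stringsAsFactors = FALSE)
    }

    naive_ids <- sprintf("obs%02d", seq_len(config$n_observers))
    expert_ids <- if (config$n_experts > 0L) sprintf("expert%d", seq_len(config$n_experts))
    rec_wo <- gen_cohort(naive_ids, "naive", "without_intermediates", truth_wo,
                         config$sigma_without, config$n_repetitions,
                         config$rt_lognormal$without_intermediates)
    rec_wi <- gen_cohort(naive_ids, "naive", "with_intermediates", truth_wi,
                         config$sigma_with, config$n_repetitions,
                         config$rt_lognormal$with_intermediates)
    rec_ex <- if (config$n_experts > 0L) {
      # experts judge with full information: one careful placement per probe,
      # centred on the with-intermediates truth, untimed
      gen_cohort(expert_ids, "expert", "with_intermediates", truth_wi,
                 config$sigma_expert, 1L, rt_par = NULL)
    }

    q_rows <- list()
    for (cond in dm_conditions) {
      q_rows[[cond]] <- data.frame(
        observer_id = naive_ids, condition = cond,
        stimulus_pair = config$stimulus_pair,
        identity_choices = vapply(naive_ids, function(o)
          identity_draw(config$identity_probs[[cond]]), character(1L)),
        confidence = likert_draw(config$n_observers,
                                 config$likert_means$confidence[[cond]],
                                 config$likert_sd),
        similarity = likert_draw(config$n_observers,
                                 config$likert_means$similarity[[cond]],
                                 config$likert_sd),
        stringsAsFactors = FALSE)
    }
    questionnaire <- questionnaire_table(do.call(rbind, c(q_rows, make.row.names = FALSE)))

    all_rec <- rbind(rec_wo, rec_wi, if (!is.null(rec_ex)) rec_ex)
    as_table <- function(rec) {
      suppressWarnings(response_table(rec, probes, shape))
    }
    structure(
      list(
        responses_without = as_table(rec_wo),
        responses_with = as_table(rec_wi),
        responses_expert = if (!is.null(rec_ex)) as_table(rec_ex),
        responses = as_table(all_rec),
        questionnaire = questionnaire,
        truth = list(true_map_without = truth_wo, true_map_with = truth_wi,
                     config = config),
        shape = shape,
        probes = probes
      ),
      class = "synthetic_experiment"
    )
  })
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(
    "<synthetic_experiment> %s (scale %g): %d probes, %d observers x %d reps, %d experts, seed %d\n",
    cfg$shape_kind, cfg$shape_scale, cfg$n_probes, cfg$n_observers,
    cfg$n_repetitions, cfg$n_experts, cfg$seed))
  invisible(x)
}

truth_as_map <- function(truth_matrix) {
  out <- data.frame(probe_id = rownames(truth_matrix),
                    x = truth_matrix[, 1L], y = truth_matrix[, 2L],
                    n_observers = NA_integer_, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("median_map", "data.frame")
  out
}

config_as_list <- function(config) {
  out <- unclass(config)
  out$condition_shift <- apply(out$condition_shift, 1L, function(r) as.numeric(r),
                               simplify = FALSE)
  out
}

#' Write a simulated experiment as a fixture directory
#'
#' Writes `responses.csv` (all cohorts and conditions, distinguished by the
#' `cohort` and `condition` columns), `probes.csv`, `shape.geojson`,
#' `questionnaire.csv`, `ground_truth.json`, and `config.json`.
#'
#' @param sim A `synthetic_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_responses(sim$responses, file.path(dir, "responses.csv"))
  write_probes(sim$probes, file.path(dir, "probes.csv"))
  write_shape_geojson(sim$shape, file.path(dir, "shape.geojson"))
  write_questionnaire(sim$questionnaire, file.path(dir, "questionnaire.csv"))
  mat_to_map <- function(m) {
    stats::setNames(lapply(rownames(m), function(p) as.numeric(m[p, ])), rownames(m))
  }
  gt <- list(true_map_without = mat_to_map(sim$truth$true_map_without),
             true_map_with = mat_to_map(sim$truth$true_map_with),
             config = config_as_list(sim$truth$config))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(config_as_list(sim$truth$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
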