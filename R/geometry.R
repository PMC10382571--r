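# Planar primitives underlying every statistic in the pipeline.
#
# Coordinates are continuous pixels in image convention: origin top-left,
# x rightward, y downward, 0-based. All distances are Euclidean and reported
# in the same pixel units.

as_points <- function(p) {
  if (is.data.frame(p)) {
    if (!all(c("x", "y") %in% names(p))) {
      dm_stop("validation", "point data frame needs `x` and `y` columns")
    }
    p <- cbind(p$x, p$y)
  } else if (is.numeric(p) && is.null(dim(p)) && length(p) == 2L) {
    p <- matrix(p, ncol = 2L)
  }
  p <- as.matrix(p)
  if (ncol(p) != 2L) {
    dm_stop("validation", "points must be an n x 2 matrix of (x, y) coordinates")
  }
  storage.mode(p) <- "double"
  if (nrow(p) > 0L && !all(is.finite(p))) {
    dm_stop("validation", "point coordinates must be finite")
  }
  colnames(p) <- c("x", "y")
  p
}

# signed shoelace area of an open vertex ring
shoelace_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# orientation of the triplet (a, b, c): >0 counter-clockwise in mathematical
# axes (sign is consistent, which is all the intersection test needs)
orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

on_segment <- function(ax, ay, bx, by, px, py, eps) {
  abs(orient(ax, ay, bx, by, px, py)) <= eps &
    px >= pmin(ax, bx) - eps & px <= pmax(ax, bx) + eps &
    py >= pmin(ay, by) - eps & py <= pmax(ay, by) + eps
}

segments_intersect <- function(p1, p2, q1, q2, eps) {
  d1 <- orient(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  d2 <- orient(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  d3 <- orient(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  d4 <- orient(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  if (((d1 > eps && d2 < -eps) || (d1 < -eps && d2 > eps)) &&
      ((d3 > eps && d4 < -eps) || (d3 < -eps && d4 > eps))) {
    return(TRUE)
  }
  any(
    on_segment(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2], eps),
    on_segment(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2], eps),
    on_segment(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2], eps),
    on_segment(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2], eps)
  )
}

#' Construct a test-shape outline
#'
#' A `shape_outline` is the simple closed polygon bounding the test stimulus,
#' in pixel coordinates. It is the support of the uniform resampling null used
#' as the random baseline for inter-observer consistency. The vertex ring is
#' stored open (the closing edge back to the first vertex is implicit).
#'
#' @param vertices An n x 2 matrix or data frame of vertex coordinates
#'   (columns `x`, `y`), n >= 3. A repeated closing vertex is dropped.
#' @param label Text label for the shape.
#' @return An object of class `shape_outline` with elements `vertices`,
#'   `label`, and `area` (pixels squared).
#' @export
shape_outline <- function(vertices, label = "shape") {
  v <- as_points(vertices)
  if (nrow(v) >= 2L && all(v[1L, ] == v[nrow(v), ])) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  if (nrow(v) < 3L) {
    dm_stop("validation", "a polygon needs at least 3 distinct vertices")
  }
  area <- abs(shoelace_area(v))
  scale <- max(apply(v, 2L, function(z) diff(range(z))))
  if (!is.finite(area) || area <= 0 || scale <= 0) {
    dm_stop("validation", "polygon area must be strictly positive")
  }
  eps <- 1e-12 * scale^2
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # skip edges sharing a vertex (adjacent in the ring)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ], eps)) {
        dm_stop("validation", sprintf(
          "polygon is not simple: edges %d and %d intersect", i, j))
      }
    }
  }
  structure(list(vertices = v, label = as.character(label)[1L], area = area),
            class = "shape_outline")
}

is_shape_outline <- function(x) inherits(x, "shape_outline")

assert_shape <- function(shape) {
  if (!is_shape_outline(shape)) {
    dm_stop("validation", "`shape` must be a shape_outline object")
  }
  shape
}

#' @export
print.shape_outline <- function(x, ...) {
  cat(sprintf("<shape_outline> %s: %d vertices, area %.4g px^2\n",
              x$label, nrow(x$vertices), x$area))
  invisible(x)
}

#' Point-in-polygon containment
#'
#' Tests whether points lie inside or on the boundary of a shape outline.
#' Containment is closed: boundary points count as inside, so responses
#' digitized exactly on the contour are never discarded.
#'
#' @param shape A [shape_outline()].
#' @param points An n x 2 matrix/data frame of points, or a length-2 vector.
#' @return Logical vector, one entry per point.
#' @export
polygon_contains <- function(shape, points) {
  assert_shape(shape)
  p <- as_points(points)
  n <- nrow(p)
  if (n == 0L) return(logical(0L))
  v <- shape$vertices
  scale <- max(apply(v, 2L, function(z) diff(range(z))))
  eps <- 1e-9 * scale
  px <- p[, 1L]; py <- p[, 2L]
  inside <- rep(FALSE, n)
  boundary <- rep(FALSE, n)
  nv <- nrow(v)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    boundary <- boundary | on_segment(xi, yi, xj, yj, px, py, eps)
    crosses <- ((yi > py) != (yj > py))
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside | boundary
}

#' Uniform random points inside a polygon
#'
#' Draws points uniformly over the area of a simple polygon by rejection
#' sampling from the bounding box. This is the sampler behind the
#' random-response baseline ("randomly sampled locations anywhere within the
#' contour of the test shape").
#'
#' @param shape A [shape_outline()].
#' @param n Number of points (>= 0).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return An n x 2 matrix of points, all satisfying [polygon_contains()].
#' @export
sample_uniform <- function(shape, n, seed = NULL) {
  assert_shape(shape)
  if (!is_count(n)) dm_stop("validation", "`n` must be a non-negative integer")
  n <- as.integer(n)
  with_seed(seed, {
    out <- matrix(numeric(0L), ncol = 2L, dimnames = list(NULL, c("x", "y")))
    if (n > 0L) {
      v <- shape$vertices
      xr <- range(v[, 1L]); yr <- range(v[, 2L])
      bbox_area <- diff(xr) * diff(yr)
      accept <- max(shape$area / bbox_area, 1e-3)
      while (nrow(out) < n) {
        need <- n - nrow(out)
        m <- ceiling(need / accept * 1.15) + 16L
        cand <- cbind(x = stats::runif(m, xr[1L], xr[2L]),
                      y = stats::runif(m, yr[1L], yr[2L]))
        keep <- polygon_contains(shape, cand)
        out <- rbind(out, cand[keep, , drop = FALSE])
      }
      out <- out[seq_len(n), , drop = FALSE]
    }
    out
  })
}

#' Mean pairwise distance of a point set
#'
#' The consistency statistic: the arithmetic mean of Euclidean distances over
#' all unordered pairs of points ("the average distance between the responses
#' of different participants"). Invariant under translation and rotation;
#' scales linearly under uniform scaling.
#'
#' @param points An n x 2 matrix/data frame, n >= 2.
#' @return Mean pairwise distance in pixels.
#' @export
mean_pairwise_distance <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 2L) {
    dm_stop("insufficient_data", "mean pairwise distance needs at least 2 points")
  }
  mean(stats::dist(p))
}

#' Componentwise (per-axis) median of a point set
#'
#' The default 2-D median convention for aggregating repetitions and building
#' median response maps: the median of the x coordinates paired with the
#' median of the y coordinates. Even counts use the midpoint of the two
#' central values. See [geometric_median()] for the spatial alternative.
#'
#' @param points An n x 2 matrix/data frame, n >= 1.
#' @return Named numeric vector `c(x =, y =)`.
#' @export
componentwise_median <- function(points) {
  p <- as_points(points)
  if (nrow(p) < 1L) {
    dm_stop("insufficient_data", "median of an empty point set is undefined")
  }
  c(x = stats::median(p[, 1L]), y = stats::median(p[, 2L]))
}

#' Geometric (spatial) median of a point set
#'
#' Weiszfeld iteration for the point minimising the sum of Euclidean distances
#' to the input points. Offered as a configuration alternative to the default
#' componentwise convention.
#'
#' @param points An n x 2 matrix/data frame, n >= 1.
#' @param tol Convergence tolerance on the step size, relative to spread.
#' @param max_iter Iteration cap.
#' @return Named numeric vector `c(x =, y =)`.
#' @export
geometric_median <- function(points, tol = 1e-10, max_iter = 1000L) {
  p <- as_points(points)
  if (nrow(p) < 1L) {
    dm_stop("insufficient_data", "median of an empty point set is undefined")
  }
  if (nrow(p) == 1L) return(c(x = p[1L, 1L], y = p[1L, 2L]))
  m <- colMeans(p)
  spread <- max(stats::sd(p[, 1L]), stats::sd(p[, 2L]), .Machine$double.eps)
  for (it in seq_len(max_iter)) {
    d <- sqrt((p[, 1L] - m[1L])^2 + (p[, 2L] - m[2L])^2)
    if (any(d < 1e-14 * spread)) {
      # sitting on a data point: it is the minimiser unless the pull of the
      # remaining points exceeds 1 (Vardi-Zhang); good enough to stop here
      break
    }
    w <- 1 / d
    new <- c(sum(w * p[, 1L]), sum(w * p[, 2L])) / sum(w)
    if (sqrt(sum((new - m)^2)) < tol * spread) {
      m <- new
      break
    }
    m <- new
  }
  c(x = m[1L], y = m[2L])
}

point_median <- function(points, method = c("componentwise", "geometric")) {
  method <- match.arg(method)
  if (method == "componentwise") componentwise_median(points) else geometric_median(points)
}

# Euclidean distances from each row of `points` to a single point `q`
dist_to_point <- function(points, q) {
  p <- as_points(points)
  sqrt((p[, 1L] - q[[1L]])^2 + (p[, 2L] - q[[2L]])^2)
}

# minimum distance from point q to the polygon boundary
boundary_distance <- function(shape, q) {
  v <- shape$vertices
  n <- nrow(v)
  j <- c(seq_len(n)[-1L], 1L)
  ax <- v[, 1L]; ay <- v[, 2L]
  bx <- v[j, 1L]; by <- v[j, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  t <- pmin(1, pmax(0, ((q[[1L]] - ax) * dx + (q[[2L]] - ay) * dy) / pmax(len2, 1e-300)))
  px <- ax + t * dx; py <- ay + t * dy
  min(sqrt((q[[1L]] - px)^2 + (q[[2L]] - py)^2))
}
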