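# ---- points -----------------------------------------------------------------

#' Construct a 2D point
#'
#' Points live in the calibrated millimetre frame with y increasing toward
#' the patient's head (proximal). Raster (y-down pixel) input is converted at
#' calibration time, so everything downstream can reason in anatomical
#' directions.
#'
#' @param x,y Finite coordinates (mm).
#' @return A named numeric vector of length 2.
#' @export
pt2 <- function(x, y) {
  p <- c(x = as.numeric(x), y = as.numeric(y))
  if (!all(is.finite(p))) stop("point coordinates must be finite", call. = FALSE)
  p
}

# Coerce a point, list of points, or n x 2 matrix to an n x 2 matrix.
as_point_matrix <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2)
    m <- p
  } else if (is.list(p)) {
    if (length(p) == 0L) return(matrix(numeric(0), ncol = 2))
    m <- do.call(rbind, lapply(p, function(q) as.numeric(q)[1:2]))
  } else {
    m <- matrix(as.numeric(p), ncol = 2, byrow = TRUE)
  }
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y")
  m
}

vnorm <- function(v) sqrt(sum(v^2))

normalize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

# z-component of the 2D cross product a x b
cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

# ---- directed lines ---------------------------------------------------------

#' Construct a directed line
#'
#' A directed line is an origin plus a unit direction. Mechanical axes
#' (femoral: hip centre to trochlear groove; tibial: plateau midpoint to talar
#' dome) are represented this way with the direction oriented distally, as are
#' resection lines and the anterior cortical line.
#'
#' @param origin A point on the line.
#' @param direction Direction vector (normalised internally; must be nonzero).
#' @return An object of class `directed_line`.
#' @export
directed_line <- function(origin, direction) {
  origin <- as.numeric(origin)[1:2]
  direction <- as.numeric(direction)[1:2]
  if (!all(is.finite(origin), is.finite(direction)))
    stop("line origin/direction must be finite", call. = FALSE)
  structure(list(origin = pt2(origin[1], origin[2]),
                 direction = normalize(direction)),
            class = "directed_line")
}

#' @export
print.directed_line <- function(x, ...) {
  cat(sprintf("<directed_line> origin (%.3f, %.3f), direction (%.6f, %.6f)\n",
              x$origin[1], x$origin[2], x$direction[1], x$direction[2]))
  invisible(x)
}

#' Line through two points
#'
#' @param a,b Distinct points; the direction runs from `a` to `b`.
#' @return A `directed_line`.
#' @export
line_through <- function(a, b) {
  a <- as.numeric(a)[1:2]; b <- as.numeric(b)[1:2]
  d <- b - a
  if (vnorm(d) < 1e-9) stop("degenerate axis: the two defining points coincide",
                            call. = FALSE)
  directed_line(a, d)
}

# ---- contour polygons -------------------------------------------------------

#' Construct a closed contour polygon
#'
#' Bone silhouettes are closed simple polygons. Vertices are stored
#' counter-clockwise (orientation is normalised on construction); a repeated
#' closing vertex is dropped.
#'
#' @param vertices An n x 2 matrix or list of points, n >= 3.
#' @param check_simple If `TRUE` (default) verify the polygon does not
#'   self-intersect.
#' @return An object of class `contour_polygon` with element `vertices`.
#' @export
contour_polygon <- function(vertices, check_simple = TRUE) {
  V <- as_point_matrix(vertices)
  n <- nrow(V)
  if (n >= 2 && vnorm(V[n, ] - V[1, ]) < 1e-12) {
    V <- V[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3) stop("a contour polygon needs at least 3 vertices", call. = FALSE)
  if (!all(is.finite(V))) stop("contour vertices must be finite", call. = FALSE)
  a <- polygon_signed_area(V)
  if (abs(a) < 1e-12) stop("degenerate contour: zero area", call. = FALSE)
  if (a < 0) V <- V[n:1, , drop = FALSE]  # normalise to counter-clockwise
  if (check_simple && !polygon_is_simple(V))
    stop("contour polygon is self-intersecting", call. = FALSE)
  structure(list(vertices = V), class = "contour_polygon")
}

#' @export
print.contour_polygon <- function(x, ...) {
  V <- x$vertices
  cat(sprintf("<contour_polygon> %d vertices, area %.2f, bbox x [%.2f, %.2f] y [%.2f, %.2f]\n",
              nrow(V), polygon_signed_area(V),
              min(V[, 1]), max(V[, 1]), min(V[, 2]), max(V[, 2])))
  invisible(x)
}

polygon_signed_area <- function(V) {
  n <- nrow(V)
  j <- c(2:n, 1L)
  sum(V[, 1] * V[j, 2] - V[j, 1] * V[, 2]) / 2
}

# Simplicity test: no two non-adjacent edges intersect or touch.
# Vectorised over all edge pairs with a bounding-box prefilter.
polygon_is_simple <- function(V) {
  n <- nrow(V)
  j <- c(2:n, 1L)
  A <- V
  B <- V[j, , drop = FALSE]
  idx <- utils::combn(n, 2L)
  i1 <- idx[1, ]; i2 <- idx[2, ]
  adjacent <- (i2 - i1 == 1L) | (i1 == 1L & i2 == n)
  i1 <- i1[!adjacent]; i2 <- i2[!adjacent]
  if (length(i1) == 0L) return(TRUE)
  # bbox prefilter
  keep <- pmin(A[i1, 1], B[i1, 1]) <= pmax(A[i2, 1], B[i2, 1]) &
          pmin(A[i2, 1], B[i2, 1]) <= pmax(A[i1, 1], B[i1, 1]) &
          pmin(A[i1, 2], B[i1, 2]) <= pmax(A[i2, 2], B[i2, 2]) &
          pmin(A[i2, 2], B[i2, 2]) <= pmax(A[i1, 2], B[i1, 2])
  i1 <- i1[keep]; i2 <- i2[keep]
  if (length(i1) == 0L) return(TRUE)
  p <- A[i1, , drop = FALSE]; r <- B[i1, , drop = FALSE] - p
  q <- A[i2, , drop = FALSE]; s <- B[i2, , drop = FALSE] - q
  d1 <- r[, 1] * (q[, 2] - p[, 2]) - r[, 2] * (q[, 1] - p[, 1])
  d2 <- r[, 1] * (B[i2, , drop = FALSE][, 2] - p[, 2]) -
        r[, 2] * (B[i2, , drop = FALSE][, 1] - p[, 1])
  d3 <- s[, 1] * (p[, 2] - q[, 2]) - s[, 2] * (p[, 1] - q[, 1])
  d4 <- s[, 1] * (B[i1, , drop = FALSE][, 2] - q[, 2]) -
        s[, 2] * (B[i1, , drop = FALSE][, 1] - q[, 1])
  eps <- 1e-12
  proper <- (d1 * d2 < -eps) & (d3 * d4 < -eps)
  # any endpoint exactly on the other (non-adjacent) segment = self-touch;
  # bbox overlap already established by the prefilter
  graze <- (abs(d1) <= eps & d3 * d4 <= eps) | (abs(d2) <= eps & d3 * d4 <= eps) |
           (abs(d3) <= eps & d1 * d2 <= eps) | (abs(d4) <= eps & d1 * d2 <= eps)
  !any(proper | graze)
}

# ---- operations -------------------------------------------------------------

#' Signed offsets of points along a directed line
#'
#' Each offset is the scalar projection of (point - origin) onto the line
#' direction; order is preserved. This is the primitive behind "furthest point
#' when projected to the mechanical axis".
#'
#' @param points Points (matrix, list, or single point); may be empty.
#' @param axis A `directed_line`.
#' @return Numeric vector of signed offsets (mm).
#' @export
project_offsets <- function(points, axis) {
  stopifnot(inherits(axis, "directed_line"))
  P <- as_point_matrix(points)
  if (nrow(P) == 0L) return(numeric(0))
  unname((P[, 1] - axis$origin[1]) * axis$direction[1] +
           (P[, 2] - axis$origin[2]) * axis$direction[2])
}

#' Extreme contour vertex along an axis
#'
#' Returns the polygon vertex with the largest (`sense = "+"`) or smallest
#' (`sense = "-"`) signed offset along the axis. Extremes of a linear
#' functional over a polygon occur at vertices, so only vertices are
#' searched. Ties are broken by the smallest vertex index.
#'
#' @param contour A `contour_polygon`.
#' @param axis A `directed_line`.
#' @param sense `"+"` for the most positive offset, `"-"` for the most negative.
#' @return A point (named numeric of length 2).
#' @export
furthest_point_along <- function(contour, axis, sense = c("+", "-")) {
  sense <- match.arg(sense)
  stopifnot(inherits(contour, "contour_polygon"))
  offs <- project_offsets(contour$vertices, axis)
  i <- if (sense == "+") which.max(offs) else which.min(offs)
  pt2(contour$vertices[i, 1], contour$vertices[i, 2])
}

#' Perpendicular line at an offset along an axis
#'
#' The returned line passes through `axis$origin + offset * axis$direction`
#' and is perpendicular to the axis (direction rotated +90 degrees).
#'
#' @param axis A `directed_line`.
#' @param offset Signed distance (mm) along the axis from its origin.
#' @return A `directed_line`.
#' @export
perpendicular_line_at <- function(axis, offset) {
  stopifnot(inherits(axis, "directed_line"))
  o <- axis$origin + offset * axis$direction
  d <- c(-axis$direction[2], axis$direction[1])
  structure(list(origin = pt2(o[1], o[2]),
                 direction = d),  # exact perpendicular, already unit
            class = "directed_line")
}

#' Intersections of an infinite line with a closed contour
#'
#' All crossing points of the infinite line with the polygon boundary,
#' deduplicated within `tol` mm (vertex-grazing crossings produce a single
#' point), sorted by signed position along the line direction.
#'
#' @param line A `directed_line`.
#' @param contour A `contour_polygon`.
#' @param tol Deduplication tolerance along the line (mm).
#' @return An n x 2 matrix of points (possibly 0 rows).
#' @export
line_polygon_intersections <- function(line, contour, tol = 1e-6) {
  stopifnot(inherits(line, "directed_line"), inherits(contour, "contour_polygon"))
  V <- contour$vertices
  n <- nrow(V)
  o <- line$origin; d <- line$direction
  # signed side of each vertex relative to the line
  s <- d[1] * (V[, 2] - o[2]) - d[2] * (V[, 1] - o[1])
  eps <- 1e-12
  s[abs(s) < eps] <- 0
  j <- c(2:n, 1L)
  s2 <- s[j]
  pts <- matrix(numeric(0), ncol = 2)
  # proper crossings
  crossing <- s * s2 < 0
  if (any(crossing)) {
    t <- s[crossing] / (s[crossing] - s2[crossing])
    P <- V[crossing, , drop = FALSE] +
      t * (V[j, , drop = FALSE][crossing, , drop = FALSE] - V[crossing, , drop = FALSE])
    pts <- rbind(pts, P)
  }
  # vertices lying exactly on the line
  onl <- s == 0
  if (any(onl)) pts <- rbind(pts, V[onl, , drop = FALSE])
  if (nrow(pts) == 0L) return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  tpos <- (pts[, 1] - o[1]) * d[1] + (pts[, 2] - o[2]) * d[2]
  ord <- order(tpos)
  pts <- pts[ord, , drop = FALSE]
  tpos <- tpos[ord]
  keep <- c(TRUE, diff(tpos) > tol)
  out <- pts[keep, , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

#' Undirected acute angle between two lines, in degrees
#'
#' @param a,b Objects of class `directed_line`.
#' @return Angle in \[0, 90\] degrees.
#' @export
angle_between_deg <- function(a, b) {
  stopifnot(inherits(a, "directed_line"), inherits(b, "directed_line"))
  cd <- abs(sum(a$direction * b$direction))
  cd <- min(max(cd, 0), 1)
  acos(cd) * 180 / pi
}

#' Rotate a line about a pivot point
#'
#' The returned line passes through `pivot` with the direction rotated by
#' `angle_deg` (counter-clockwise positive). Used to realise the 2 degree
#' tibial realignment and the 3 degree posterior slope.
#'
#' @param line A `directed_line`.
#' @param pivot Pivot point.
#' @param angle_deg Rotation angle in degrees.
#' @return A `directed_line`.
#' @export
rotate_line_about <- function(line, pivot, angle_deg) {
  stopifnot(inherits(line, "directed_line"))
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  d <- line$direction
  nd <- c(co * d[1] - si * d[2], si * d[1] + co * d[2])
  directed_line(pivot, nd)
}

# Perpendicular (signed) distance of points to a line; positive on the side
# the +90-degree normal points to.
signed_distance_to_line <- function(points, line) {
  P <- as_point_matrix(points)
  nrm <- c(-line$direction[2], line$direction[1])
  (P[, 1] - line$origin[1]) * nrm[1] + (P[, 2] - line$origin[2]) * nrm[2]
}

# Distance, measured parallel to `axis`, from point p to `line` (positive in
# the +axis direction). Solves p + t * axis_dir on line.
axis_parallel_distance <- function(p, axis, line) {
  p <- as.numeric(p)[1:2]
  a <- axis$direction; w <- line$direction
  den <- cross2(a, w)
  if (abs(den) < 1e-12) stop("axis is parallel to the line", call. = FALSE)
  as.numeric(cross2(line$origin - p, w) / den)
}

# Intersection point of two non-parallel lines.
line_line_intersection <- function(l1, l2) {
  d1 <- l1$direction; d2 <- l2$direction
  den <- cross2(d1, d2)
  if (abs(den) < 1e-12) stop("lines are parallel", call. = FALSE)
  t <- cross2(l2$origin - l1$origin, d2) / den
  p <- l1$origin + t * d1
  pt2(p[1], p[2])
}

# Insert extra vertices so no edge is longer than max_len (used before
# scanline extraction where straight stretches carry few vertices).
resample_contour <- function(contour, max_len = 2) {
  V <- contour$vertices
  n <- nrow(V)
  j <- c(2:n, 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- V[i, ]; b <- V[j[i], ]
    len <- vnorm(b - a)
    k <- max(1L, ceiling(len / max_len))
    t <- (seq_len(k) - 1L) / k
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}
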