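test_that("project_offsets matches per-point dot products", {
  axis <- directed_line(c(0, 0), c(0, 1))
  expect_equal(project_offsets(pt2(3, 5), axis), 5)
  expect_equal(project_offsets(axis$origin, axis), 0)
  set.seed(41)
  P <- matrix(stats::rnorm(40, sd = 10), ncol = 2)
  ax <- random_line()
  expected <- apply(P, 1, function(p) sum((p - ax$origin) * ax$direction))
  expect_equal(project_offsets(P, ax), expected, tolerance = 1e-12)
  expect_identical(project_offsets(matrix(numeric(0), ncol = 2), ax), numeric(0))
})

test_that("furthest_point_along finds the extreme vertex with index tie-break", {
  sq <- contour_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  up <- directed_line(c(0.5, 0.5), c(0, 1))
  expect_equal(unname(furthest_point_along(sq, up, "+")[2]), 1)
  # two co-extreme vertices: the lower-index vertex of the stored
  # (counter-clockwise) polygon wins
  flat <- contour_polygon(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)))
  expect_equal(unname(furthest_point_along(flat, up, "+")), c(2, 1))
  # regular 17-gon against the exhaustive scan, random axes
  th <- 2 * pi * (0:16) / 17
  gon <- contour_polygon(cbind(cos(th), sin(th)))
  set.seed(7)
  for (i in 1:25) {
    ax <- random_line()
    for (s in c("+", "-"))
      expect_equal(unname(furthest_point_along(gon, ax, s)),
                   unname(bf_furthest(gon, ax, s)), tolerance = 1e-12)
  }
})

test_that("perpendicular_line_at passes through the station and is orthogonal", {
  ax <- directed_line(c(0, 0), c(0, 1))
  l <- perpendicular_line_at(ax, 9)
  expect_equal(unname(l$origin), c(0, 9))
  expect_equal(sum(l$direction * ax$direction), 0)
  l0 <- perpendicular_line_at(ax, 0)
  expect_equal(unname(l0$origin), unname(ax$origin))
  set.seed(13)
  for (i in 1:100) {
    a <- random_line()
    p <- perpendicular_line_at(a, stats::runif(1, -50, 50))
    expect_lt(abs(sum(p$direction * a$direction)), 1e-9)
    expect_equal(sqrt(sum(p$direction^2)), 1, tolerance = 1e-12)
  }
})

test_that("line_polygon_intersections agrees with the per-edge oracle", {
  sq <- contour_polygon(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
  h <- directed_line(c(-5, 0.5), c(1, 0))
  ips <- line_polygon_intersections(h, sq)
  expect_equal(nrow(ips), 2)
  expect_equal(sort(ips[, 1]), c(0, 1))
  expect_equal(unname(ips[, 2]), c(0.5, 0.5))
  miss <- directed_line(c(0, 5), c(1, 0))
  expect_equal(nrow(line_polygon_intersections(miss, sq)), 0)
  set.seed(23)
  for (i in 1:50) {
    poly <- random_star_polygon(12)
    ln <- random_line()
    got <- line_polygon_intersections(ln, poly)
    want <- bf_line_poly_intersections(ln, poly)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) expect_equal(unname(got), unname(want), tolerance = 1e-9)
  }
})

test_that("angle_between_deg gives the undirected acute angle", {
  a <- directed_line(c(0, 0), c(1, 0))
  expect_equal(angle_between_deg(a, a), 0)
  expect_equal(angle_between_deg(a, directed_line(c(3, 3), c(0, -1))), 90)
  expect_equal(angle_between_deg(a, directed_line(c(0, 0), c(1, 1))), 45)
  expect_equal(angle_between_deg(a, directed_line(c(0, 0), c(-1, 0))), 0)
})

test_that("rotate_line_about pivots and composes correctly", {
  l <- directed_line(c(0, 0), c(1, 0))
  same <- rotate_line_about(l, c(2, 3), 0)
  expect_equal(unname(same$direction), c(1, 0))
  expect_equal(unname(same$origin), c(2, 3))
  vert <- rotate_line_about(l, c(1, 1), 90)
  expect_equal(angle_between_deg(vert, directed_line(c(0, 0), c(0, 1))), 0,
               tolerance = 1e-12)
  r <- rotate_line_about(rotate_line_about(l, c(0, 0), 2), c(0, 0), -2)
  expect_equal(unname(r$direction), c(1, 0), tolerance = 1e-9)
})

test_that("operations are translation-equivariant and rotation-invariant", {
  set.seed(91)
  for (i in 1:20) {
    poly <- random_star_polygon(10)
    ln <- random_line()
    tr <- stats::runif(2, -40, 40)
    poly_t <- contour_polygon(sweep(poly$vertices, 2, tr, `+`))
    ln_t <- directed_line(ln$origin + tr, ln$direction)
    # scalar outputs unchanged
    expect_equal(project_offsets(poly_t$vertices, ln_t),
                 project_offsets(poly$vertices, ln), tolerance = 1e-9)
    # point outputs shifted by t
    expect_equal(unname(furthest_point_along(poly_t, ln_t, "+")),
                 unname(furthest_point_along(poly, ln, "+") + tr),
                 tolerance = 1e-9)
    ips <- line_polygon_intersections(ln, poly)
    ips_t <- line_polygon_intersections(ln_t, poly_t)
    if (nrow(ips))
      expect_equal(unname(ips_t), unname(sweep(ips, 2, tr, `+`)), tolerance = 1e-9)
    # furthest point equivariant under joint rotation
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    poly_r <- contour_polygon(poly$vertices %*% t(R))
    ln_r <- directed_line(as.numeric(R %*% ln$origin), as.numeric(R %*% ln$direction))
    expect_equal(unname(furthest_point_along(poly_r, ln_r, "+")),
                 as.numeric(R %*% furthest_point_along(poly, ln, "+")),
                 tolerance = 1e-9)
  }
})

test_that("degenerate geometric inputs are rejected", {
  expect_error(directed_line(c(0, 0), c(0, 0)), "zero-length")
  expect_error(line_through(c(1, 1), c(1, 1)), "degenerate")
  expect_error(contour_polygon(rbind(c(0, 0), c(1, 1))), "3 vertices")
  expect_error(contour_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))), "zero area")
  # crossing edges with nonzero net area
  expect_error(contour_polygon(rbind(c(0, 0), c(4, 0), c(4, 3), c(2, -1),
                                     c(0, 3))),
               "self-intersecting")
})
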