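# Shared fixtures and independent brute-force oracles.

# star-shaped polygon around a centre: random radii at sorted angles
# (simple by construction)
random_star_polygon <- function(n_vertices = 12, r_range = c(5, 30),
                                center = c(0, 0)) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, r_range[1], r_range[2])
  contour_polygon(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
                  check_simple = FALSE)
}

random_line <- function(origin_range = 20) {
  th <- stats::runif(1, 0, 2 * pi)
  directed_line(stats::runif(2, -origin_range, origin_range),
                c(cos(th), sin(th)))
}

# brute-force infinite-line vs polygon intersection: solve the 2x2 system
# per edge independently of the implementation's side-sign approach
bf_line_poly_intersections <- function(line, contour, tol = 1e-6) {
  V <- contour$vertices
  n <- nrow(V)
  o <- line$origin; d <- line$direction
  out <- list()
  for (i in seq_len(n)) {
    a <- V[i, ]; b <- V[if (i == n) 1 else i + 1, ]
    e <- b - a
    den <- d[1] * (-e[2]) - d[2] * (-e[1])
    if (abs(den) < 1e-14) next
    rhs <- a - o
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    u <- (d[1] * rhs[2] - d[2] * rhs[1]) / den
    if (u >= 0 && u <= 1) out[[length(out) + 1]] <- a + u * e
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  P <- do.call(rbind, out)
  tp <- (P[, 1] - o[1]) * d[1] + (P[, 2] - o[2]) * d[2]
  P <- P[order(tp), , drop = FALSE]
  tp <- sort(tp)
  P[c(TRUE, diff(tp) > tol), , drop = FALSE]
}

# exhaustive furthest-vertex scan
bf_furthest <- function(contour, axis, sense) {
  V <- contour$vertices
  best <- NULL; bestv <- if (sense == "+") -Inf else Inf
  for (i in seq_len(nrow(V))) {
    v <- sum((V[i, ] - axis$origin) * axis$direction)
    better <- if (sense == "+") v > bestv + 1e-15 else v < bestv - 1e-15
    if (better) { bestv <- v; best <- V[i, ] }
  }
  best
}

# apply a rigid motion (rotation about the origin then translation) to a
# whole scene
rigid_scene <- function(scene, angle_deg = 0, translation = c(0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  mv <- function(P) sweep(P %*% t(R), 2, translation, `+`)
  knee_scene(scene$view, scene$side,
             contours = lapply(scene$contours, function(ct)
               contour_polygon(mv(ct$vertices), check_simple = FALSE)),
             landmarks = lapply(scene$landmarks, function(p) {
               q <- mv(matrix(p, 1)); pt2(q[1], q[2])
             }),
             calibration = scene$calibration)
}

# mirror a scene left<->right about x = 0
mirror_scene <- function(scene) {
  flip <- function(P) { P[, 1] <- -P[, 1]; P }
  knee_scene(scene$view, if (scene$side == "right") "left" else "right",
             contours = lapply(scene$contours, function(ct)
               contour_polygon(flip(ct$vertices), check_simple = FALSE)),
             landmarks = lapply(scene$landmarks, function(p) pt2(-p[1], p[2])),
             calibration = scene$calibration)
}

# rectangular-phantom AP scene: femur and tibia are axis-aligned rectangles
# with vertical mechanical axes, for closed-form width checks
rect_ap_scene <- function(femur_w = 60, tibia_w = 70) {
  femur <- contour_polygon(rbind(c(-femur_w / 2, 10), c(-femur_w / 2, 80),
                                 c(femur_w / 2, 80), c(femur_w / 2, 10)))
  tibia <- contour_polygon(rbind(c(-tibia_w / 2, 0), c(tibia_w / 2, 0),
                                 c(tibia_w / 2, -120), c(-tibia_w / 2, -120)))
  knee_scene("AP", "right",
             contours = list(femur = femur, tibia = tibia),
             landmarks = list(
               femoral_head_center = pt2(0, 400),
               trochlear_groove = pt2(0, 12),
               tibial_plateau_medial = pt2(-tibia_w / 2, 0),
               tibial_plateau_lateral = pt2(tibia_w / 2, 0),
               talar_dome_center = pt2(0, -350)))
}

# rectangular-phantom lateral scene: femur with straight anterior cortex and
# rectangular body of AP depth femur_ap; rectangular tibia of AP depth
# tibia_ap with a vertical anatomical axis
rect_lat_scene <- function(femur_ap = 62, tibia_ap = 48) {
  femur <- contour_polygon(rbind(c(0, 0), c(femur_ap, 0),
                                 c(femur_ap, 95), c(0, 95)))
  tibia <- contour_polygon(rbind(c(0, -6), c(tibia_ap, -6),
                                 c(tibia_ap, -140), c(0, -140)))
  patella <- contour_polygon(rbind(c(-12, 15), c(-4, 15), c(-4, 40), c(-12, 40)))
  fibula <- contour_polygon(rbind(c(tibia_ap + 2, -20), c(tibia_ap + 8, -20),
                                  c(tibia_ap + 8, -90), c(tibia_ap + 2, -90)))
  knee_scene("LAT", "right",
             contours = list(femur = femur, tibia = tibia,
                             patella = patella, fibula = fibula),
             landmarks = list(
               plateau_anterior = pt2(0, -6),
               plateau_posterior = pt2(tibia_ap, -6),
               tibial_shaft_proximal = pt2(tibia_ap / 2, -30),
               tibial_shaft_distal = pt2(tibia_ap / 2, -140)))
}

# run the bundled CLI in a fresh R process
run_cli <- function(args) {
  script <- system.file("exec", "tkatemplate", package = "kneetemplate")
  if (!nzchar(script))
    script <- file.path(dirname(system.file(package = "kneetemplate")),
                        "kneetemplate", "exec", "tkatemplate")
  stopifnot(nzchar(script), file.exists(script))
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(script, args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}
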