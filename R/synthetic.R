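# ---- synthetic knee generator -----------------------------------------------
#
# Seeded parametric generator of paired AP/lateral knee scenes with analytic
# ground truth. Silhouettes are piecewise line/arc polygons chosen so that
# every measurement station has a closed-form cross-section: the coronal
# femoral condyles are circular arcs (chord width at the 9 mm station is
# analytic), the tibial metaphysis walls are straight with a fixed flare
# slope (width at the 10 mm station is linear in the parameters), the
# lateral femur has a straight anterior cortex and a circular posterior
# condyle, and the lateral tibial plateau is flat with vertical walls
# (the 3-degree sloped chord is depth / cos(slope)).

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# geometry constants shared between generator and its analytic oracles
GEN <- list(
  condyle_radius = 24,      # AP femoral condyle arc radius (mm)
  femur_station = 9,        # distal femoral resection (mm)
  tibia_station = 10,       # tibial resection offset (mm)
  tibia_flare = 0.2,        # inward slope of tibial metaphysis walls (mm/mm)
  shaft_half_femur = 16,    # AP femoral shaft half-width (mm)
  lat_condyle_radius = 22,  # lateral posterior condyle radius (mm)
  joint_gap = 8,            # AP femorotibial gap (mm)
  lat_joint_gap = 6,
  arc_step_deg = 2.5        # arc discretisation
)

#' Ground-truth parameters for one synthetic knee
#'
#' Defines a synthetic knee: true implant sizes (widths are derived from the
#' chart entry plus a fixed in-bin margin so the floor size rule recovers the
#' size exactly in the absence of noise), hip-knee-ankle deformity (varus
#' positive), medial plateau attrition, pixel scale, contour noise and
#' landmark jitter. All stochastic elements downstream are driven by `seed`.
#'
#' @param seed Integer seed (< 2^31) driving contour noise and jitter.
#' @param side `"left"` or `"right"`.
#' @param hka_deg Hip-knee-ankle angle (degrees, varus positive).
#' @param medial_attrition_mm Medial plateau bone loss (mm, >= 0).
#' @param femoral_size,tibial_size True catalogue sizes (labels in the chart).
#' @param chart An [implant_size_chart()].
#' @param size_margin_mm Margin added to the chart dimension when deriving
#'   bone widths (mm); keeps widths inside the size bin.
#' @param noise_mm Contour noise amplitude (uniform, along the outward
#'   normal; mm).
#' @param landmark_jitter_mm Landmark jitter amplitude (uniform per
#'   coordinate; mm).
#' @param mm_per_pixel Pixel scale used when the scene is rasterised.
#' @param widths Optional named list overriding the derived widths
#'   (`femoral_ml`, `tibial_ml`, `femoral_ap`, `tibial_ap`, mm).
#' @return Object of class `synthetic_knee_truth`.
#' @export
synthetic_knee_truth <- function(seed = 1L, side = "right", hka_deg = 0,
                                 medial_attrition_mm = 0,
                                 femoral_size = 4, tibial_size = 4,
                                 chart = default_size_chart(),
                                 size_margin_mm = 1,
                                 noise_mm = 0, landmark_jitter_mm = 0,
                                 mm_per_pixel = 0.15, widths = NULL) {
  side <- match.arg(side, c("left", "right"))
  stopifnot(medial_attrition_mm >= 0, noise_mm >= 0, landmark_jitter_mm >= 0)
  dim_of <- function(component, size, d) {
    e <- chart[chart$component == component & chart$size == size, ]
    if (nrow(e) != 1) stop("size ", size, " not in chart for ", component,
                           call. = FALSE)
    e[[paste0(d, "_mm")]]
  }
  w <- list(
    femoral_ml = dim_of("femoral", femoral_size, "ml") + size_margin_mm,
    tibial_ml  = dim_of("tibial",  tibial_size,  "ml") + size_margin_mm,
    femoral_ap = dim_of("femoral", femoral_size, "ap") + size_margin_mm,
    tibial_ap  = dim_of("tibial",  tibial_size,  "ap") + size_margin_mm)
  if (!is.null(widths)) w[names(widths)] <- widths
  structure(list(seed = as.integer(seed), side = side, hka_deg = hka_deg,
                 medial_attrition_mm = medial_attrition_mm,
                 femoral_size = femoral_size, tibial_size = tibial_size,
                 femoral_ml_mm = w$femoral_ml, tibial_ml_mm = w$tibial_ml,
                 femoral_ap_mm = w$femoral_ap, tibial_ap_mm = w$tibial_ap,
                 chart = chart,
                 noise_mm = noise_mm, landmark_jitter_mm = landmark_jitter_mm,
                 mm_per_pixel = mm_per_pixel),
            class = "synthetic_knee_truth")
}

#' @export
print.synthetic_knee_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_knee_truth> seed %d, %s knee, HKA %+.1f deg, ",
                     "attrition %.1f mm\n  sizes F%d/T%d; ML %.1f/%.1f mm, ",
                     "AP %.1f/%.1f mm; noise %.2f mm, jitter %.2f mm\n"),
              x$seed, x$side, x$hka_deg, x$medial_attrition_mm,
              x$femoral_size, x$tibial_size, x$femoral_ml_mm, x$tibial_ml_mm,
              x$femoral_ap_mm, x$tibial_ap_mm, x$noise_mm, x$landmark_jitter_mm))
  invisible(x)
}

# arc points on a circle, angles in degrees, exact endpoints included
arc_points <- function(cx, cy, r, from_deg, to_deg, step = GEN$arc_step_deg) {
  k <- max(2L, ceiling(abs(to_deg - from_deg) / step) + 1L)
  th <- seq(from_deg, to_deg, length.out = k) * pi / 180
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# uniform noise along outward vertex normals; retried (continuing the RNG
# stream) if a draw produces a self-intersecting contour
perturb_polygon <- function(V, noise_mm, retries = 5L) {
  if (noise_mm <= 0) return(V)
  n <- nrow(V)
  jm <- c(2:n, 1L); jp <- c(n, 1:(n - 1L))
  for (k in seq_len(retries)) {
    e <- V[jm, , drop = FALSE] - V[jp, , drop = FALSE]  # central tangent
    nr <- cbind(e[, 2], -e[, 1])
    len <- sqrt(rowSums(nr^2)); len[len < 1e-9] <- 1
    nr <- nr / len
    u <- stats::runif(n, -noise_mm, noise_mm)
    W <- V + u * nr
    if (polygon_is_simple(W)) return(W)
  }
  stop("contour noise produced a self-intersecting polygon after ",
       retries, " attempts", call. = FALSE)
}

jitter_point <- function(p, amp) {
  if (amp <= 0) return(p)
  pt2(p[1] + stats::runif(1, -amp, amp), p[2] + stats::runif(1, -amp, amp))
}

# AP femur in its local frame: distal-most condyle point at y = 0, mechanical
# axis along +y (proximal). Width at the 9 mm station is
# 2 * d + 2 * sqrt(r^2 - (r - 9)^2) with condyle circles of radius r centred
# at (+-d, r).
ap_femur_local <- function(ml_width) {
  r <- GEN$condyle_radius
  h <- GEN$femur_station
  half_chord <- sqrt(r^2 - (r - h)^2)
  d <- ml_width / 2 - half_chord
  if (d <= 1) stop("femoral ML width too small for the condyle geometry",
                   call. = FALSE)
  th_station <- 180 + asin((r - h) / r) * 180 / pi    # outer-left station angle
  sw <- GEN$shaft_half_femur
  left_arc <- rbind(
    arc_points(-d, r, r, 145, th_station),
    arc_points(-d, r, r, th_station, 270))
  right_arc <- rbind(
    arc_points(d, r, r, 270, 540 - th_station),
    arc_points(d, r, r, 540 - th_station, 395))
  V <- rbind(
    c(-sw, 120), c(-sw, 70),
    left_arc,
    c(0, 4),                      # intercondylar notch apex
    right_arc,
    c(sw, 70), c(sw, 120))
  V[!duplicated(round(V, 9)), , drop = FALSE]
}

# AP tibia in its local frame: plateau lateral corner at (X, 0), medial corner
# at (-X, -attrition); mechanical axis along -y (distal); walls flare inward
# with slope GEN$tibia_flare so the width at the 10 mm station is
# 2 X - flare * (2 * station - attrition).
ap_tibia_local <- function(ml_width, attrition) {
  s <- GEN$tibia_flare
  st <- GEN$tibia_station
  X <- (ml_width + s * (2 * st - attrition)) / 2
  ws <- max(10, X - s * 40)
  V <- rbind(
    c(-X, -attrition),                      # medial plateau corner
    c(X, 0),                                # lateral plateau corner
    c(X - s * st, -st),                     # exact station vertex, lateral
    c(X - s * 40, -40),
    c(ws, -60), c(ws, -325),
    c(20, -328), c(20, -340), c(-20, -340), c(-20, -328),
    c(-ws, -325), c(-ws, -60),
    c(-(X - s * (40 - attrition)), -40),
    c(-(X - s * (st - attrition)), -st))    # exact station vertex, medial
  # station vertex on the medial wall only exists below the medial corner
  if (st <= attrition) V <- V[-nrow(V), , drop = FALSE]
  V
}

#' Generate the AP (coronal) scene of a synthetic knee
#'
#' Builds the femoral and tibial silhouettes, places the full-leg landmarks
#' consistently with the requested hip-knee-ankle angle (the femur is rotated
#' about the knee centre, head deviating medially for varus), lowers the
#' medial plateau by the attrition, perturbs contour vertices along their
#' outward normals by uniform noise and jitters landmarks. Deterministic
#' given the truth's seed.
#'
#' @param truth A [synthetic_knee_truth()].
#' @return List with `scene` (a [knee_scene()] in the mm frame) and `oracle`
#'   (analytic station widths and angles: `femoral_ml_mm`, `tibial_ml_mm`,
#'   `hka_deg`, `adjustment_expected`, `lesser_depth_mm`).
#' @export
generate_ap_scene <- function(truth) {
  stopifnot(inherits(truth, "synthetic_knee_truth"))
  with_seed(truth$seed + 1L, {
    a <- truth$medial_attrition_mm
    tibiaV <- ap_tibia_local(truth$tibial_ml_mm, a)
    femV <- ap_femur_local(truth$femoral_ml_mm)
    # femur rotated by the deformity about the knee centre; medial is -x in
    # the build frame, head deviates medially for varus
    psi <- truth$hka_deg * pi / 180
    R <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2)
    G <- c(0, GEN$joint_gap)
    femV <- sweep(femV %*% t(R), 2, G, `+`)
    lm <- list(
      femoral_head_center = pt2(G[1] - sin(psi) * 400, G[2] + cos(psi) * 400),
      trochlear_groove = pt2(G[1] - sin(psi) * 6, G[2] + cos(psi) * 6),
      tibial_plateau_medial = pt2(-max(tibiaV[, 1]), -a),
      tibial_plateau_lateral = pt2(max(tibiaV[, 1]), 0),
      talar_dome_center = pt2(0, -337))
    if (truth$side == "left") {   # mirror: medial becomes +x
      femV[, 1] <- -femV[, 1]
      tibiaV[, 1] <- -tibiaV[, 1]
      lm <- lapply(lm, function(p) pt2(-p[1], p[2]))
    }
    femV <- perturb_polygon(femV, truth$noise_mm)
    tibiaV <- perturb_polygon(tibiaV, truth$noise_mm)
    lm <- lapply(lm, jitter_point, amp = truth$landmark_jitter_mm)
    scene <- knee_scene("AP", truth$side,
                        contours = list(femur = contour_polygon(femV),
                                        tibia = contour_polygon(tibiaV)),
                        landmarks = lm,
                        calibration = calibration(truth$mm_per_pixel))
    st <- GEN$tibia_station
    list(scene = scene,
         oracle = list(femoral_ml_mm = truth$femoral_ml_mm,
                       tibial_ml_mm = truth$tibial_ml_mm,
                       hka_deg = truth$hka_deg,
                       lesser_depth_mm = st - a,
                       adjustment_expected = (st - a) < 2))
  })
}

# lateral femur local frame: anterior cortex is the segment x = 0,
# y in [15, 95]; posterior condyle is a circle of radius R centred at
# (ap_length - R, R), so the most posterior point is at distance ap_length
# from the cortical line and the distal-most point at y = 0.
lat_femur_local <- function(ap_length) {
  R <- GEN$lat_condyle_radius
  cc <- ap_length - R
  if (cc <= 5) stop("femoral AP length too small for the condyle geometry",
                    call. = FALSE)
  V <- rbind(
    c(0, 95), c(0, 15),
    arc_points(cc, R, R, 180, 270),
    arc_points(cc, R, R, 270, 360),
    arc_points(cc, R, R, 0, 60),
    c(30, 60), c(30, 95))
  V[!duplicated(round(V, 9)), , drop = FALSE]
}

#' Generate the lateral (sagittal) scene of a synthetic knee
#'
#' The femur has a straight anterior cortex and a circular posterior condyle
#' (closed-form AP length); the tibia has a flat plateau with vertical walls
#' (closed-form sloped chord, depth / cos(slope)). Patella and fibula are
#' simple filler silhouettes. Deterministic given the truth's seed.
#'
#' @param truth A [synthetic_knee_truth()].
#' @param slope_deg Slope assumed by the analytic tibial oracle (degrees);
#'   default 3.
#' @return List with `scene` and `oracle` (`femoral_ap_mm`,
#'   `tibial_ap_mm` at `slope_deg`, `plateau_depth_mm`).
#' @export
generate_lat_scene <- function(truth, slope_deg = 3) {
  stopifnot(inherits(truth, "synthetic_knee_truth"))
  with_seed(truth$seed + 2L, {
    d <- truth$tibial_ap_mm * cos(slope_deg * pi / 180)  # plateau AP depth
    femV <- lat_femur_local(truth$femoral_ap_mm)
    g <- GEN$lat_joint_gap
    x0 <- 2
    tibV <- rbind(
      c(x0, -g), c(x0 + d, -g),
      c(x0 + d, -150), c(x0 + d - 6, -160), c(x0 + 6, -160), c(x0, -150))
    patV <- rbind(c(-14, 12), c(-5, 10), c(-4, 26), c(-9, 40), c(-14, 34))
    fibV <- rbind(c(x0 + d + 2, -24), c(x0 + d + 8, -26),
                  c(x0 + d + 7, -90), c(x0 + d + 3, -90))
    lm <- list(
      plateau_anterior = pt2(x0, -g),
      plateau_posterior = pt2(x0 + d, -g),
      tibial_shaft_proximal = pt2(x0 + d / 2, -26),
      tibial_shaft_distal = pt2(x0 + d / 2, -150))
    polys <- list(femur = femV, tibia = tibV, patella = patV, fibula = fibV)
    if (truth$side == "left") {  # mirror anterior/posterior chirality
      polys <- lapply(polys, function(V) { V[, 1] <- -V[, 1]; V })
      lm <- lapply(lm, function(p) pt2(-p[1], p[2]))
    }
    polys <- lapply(polys, perturb_polygon, noise_mm = truth$noise_mm)
    lm <- lapply(lm, jitter_point, amp = truth$landmark_jitter_mm)
    scene <- knee_scene("LAT", truth$side,
                        contours = lapply(polys, contour_polygon),
                        landmarks = lm,
                        calibration = calibration(truth$mm_per_pixel))
    list(scene = scene,
         oracle = list(femoral_ap_mm = truth$femoral_ap_mm,
                       tibial_ap_mm = truth$tibial_ap_mm,
                       plateau_depth_mm = d,
                       slope_deg = slope_deg))
  })
}

#' Generate a seeded cohort of paired synthetic knees
#'
#' Draws independent knees whose parameter distributions mimic an
#' osteoarthritic total-knee-arthroplasty cohort: mostly varus alignment
#' (78% varus beyond 3 degrees, 14% valgus, 8% neutral), medial attrition
#' increasing with varus severity, mid-catalogue implant sizes, and a small
#' right-side majority. The defaults emulate the statistical structure such
#' a validation cohort exhibits without claiming anthropometric realism.
#'
#' @param n Number of knees (>= 1).
#' @param seed Cohort seed (integer < 2^31).
#' @param noise_mm Contour noise amplitude (mm) for every knee.
#' @param landmark_jitter_mm Landmark jitter amplitude (mm).
#' @param chart An [implant_size_chart()].
#' @param size_margin_mm In-bin width margin (mm); see
#'   [synthetic_knee_truth()].
#' @return List of length `n`; each element has `truth`, `ap`, `lat`
#'   (the latter two as returned by the scene generators).
#' @export
generate_cohort <- function(n, seed = 1L, noise_mm = 0,
                            landmark_jitter_mm = 0,
                            chart = default_size_chart(),
                            size_margin_mm = 1) {
  stopifnot(n >= 1)
  truths <- with_seed(seed, {
    seeds <- sample.int(2147483600L, n)
    lapply(seq_len(n), function(i) {
      cls <- sample(c("neutral", "varus", "valgus"), 1,
                    prob = c(0.086, 0.777, 0.137))
      hka <- switch(cls,
                    neutral = stats::runif(1, -3, 3),
                    varus   = stats::runif(1, 3, 12),
                    valgus  = -stats::runif(1, 3, 10))
      attr_mm <- if (hka > 3) stats::runif(1, 0, min(9.5, hka)) else
        stats::runif(1, 0, 1.5)
      side <- sample(c("right", "left"), 1, prob = c(0.543, 0.457))
      # mid-catalogue sizes dominate; tibial size tracks femoral within one
      fsize <- sample(1:8, 1, prob = c(2, 6, 10, 10, 7, 4, 2, 1))
      tsize <- min(8L, max(1L, fsize + sample(-1:1, 1, prob = c(1, 3, 1))))
      synthetic_knee_truth(
        seed = seeds[i], side = side, hka_deg = hka,
        medial_attrition_mm = attr_mm,
        femoral_size = fsize, tibial_size = tsize, chart = chart,
        size_margin_mm = size_margin_mm,
        noise_mm = noise_mm, landmark_jitter_mm = landmark_jitter_mm,
        mm_per_pixel = stats::runif(1, 0.12, 0.18))
    })
  })
  lapply(truths, function(tr)
    list(truth = tr, ap = generate_ap_scene(tr), lat = generate_lat_scene(tr)))
}
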