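# ---- coronal (AP) templating -----------------------------------------------
#
# Mechanical-alignment planning on the AP view: femoral and tibial mechanical
# axes from landmarks, a distal femoral resection 9 mm proximal to the most
# distal condyle, a tibial resection 10 mm distal to the most proximal
# plateau point, mediolateral widths from the outermost contour crossings,
# and a 2 degree tibial realignment (medial proximal tibial angle 90 -> 88)
# whenever the lesser-side resection depth falls below 2 mm.

#' Femoral mechanical axis from AP landmarks
#'
#' Line through the femoral head centre and the trochlear groove, oriented
#' distally (head toward groove).
#'
#' @param scene An AP [knee_scene()].
#' @return A `directed_line`.
#' @export
femoral_mechanical_axis <- function(scene) {
  stopifnot(inherits(scene, "knee_scene"))
  line_through(scene$landmarks$femoral_head_center,
               scene$landmarks$trochlear_groove)
}

#' Tibial mechanical axis from AP landmarks
#'
#' Line from the midpoint of the medial and lateral tibial plateau edges to
#' the talar dome centre, oriented distally.
#'
#' @param scene An AP [knee_scene()].
#' @return A `directed_line`.
#' @export
tibial_mechanical_axis <- function(scene) {
  stopifnot(inherits(scene, "knee_scene"))
  mid <- (scene$landmarks$tibial_plateau_medial +
            scene$landmarks$tibial_plateau_lateral) / 2
  line_through(mid, scene$landmarks$talar_dome_center)
}

# Outermost pair of line/contour crossings, labelled by the side unit vector.
# When more than two crossings occur (concave contour, osteophyte lobes) the
# outermost pair is used: the insert points are the cortical borders.
outermost_insert_points <- function(cut, contour, side_unit, what = "resection") {
  ips <- line_polygon_intersections(cut, contour)
  if (nrow(ips) < 2)
    stop(what, " line misses the bone contour (", nrow(ips),
         " intersection(s))", call. = FALSE)
  a <- ips[1, ]; b <- ips[nrow(ips), ]
  sa <- sum((a - b) * side_unit)
  if (sa >= 0) list(pos = pt2(a[1], a[2]), neg = pt2(b[1], b[2]))
  else         list(pos = pt2(b[1], b[2]), neg = pt2(a[1], a[2]))
}

#' Distal femoral resection and mediolateral width on the AP view
#'
#' Finds the most distal femoral contour point by projection on the femoral
#' mechanical axis, translates `resection_mm` proximally along the axis,
#' draws the perpendicular resection line there, and takes the outermost
#' intersections with the femoral contour as the medial and lateral insert
#' points; the mediolateral width is their distance.
#'
#' @param scene An AP [knee_scene()].
#' @param fma Femoral mechanical axis (distally oriented `directed_line`).
#' @param resection_mm Distal resection thickness (mm); default 9, the
#'   implant-thickness resection prescribed in at least one compartment.
#' @return List with `resection` (line), `insert_medial`, `insert_lateral`,
#'   `ml_width_mm`, `station_offset` (signed offset of the cut along the axis).
#' @export
femoral_coronal_sizing <- function(scene, fma, resection_mm = 9) {
  femur <- scene$contours$femur
  fp <- furthest_point_along(femur, fma, "+")        # most distal condyle
  o_star <- project_offsets(fp, fma)
  cut <- perpendicular_line_at(fma, o_star - resection_mm)  # proximal shift
  m <- medial_unit(scene)
  ip <- outermost_insert_points(cut, femur, m, "femoral resection")
  list(resection = cut,
       insert_medial = ip$pos, insert_lateral = ip$neg,
       ml_width_mm = vnorm(ip$pos - ip$neg),
       station_offset = o_star - resection_mm)
}

#' Proximal tibial resection with the minimum lesser-side depth rule
#'
#' Places the tibial resection perpendicular to the tibial mechanical axis,
#' `offset_mm` distal to the most proximal plateau contour point (medial
#' proximal tibial angle 90 degrees). The resection depth on each side is the
#' distance, measured parallel to the axis, from the plateau landmark to the
#' resection line. If the lesser (shallower) side receives less than
#' `min_lesser_depth_mm`, the cut is rotated about its intersection with the
#' axis so that the angle becomes `adjusted_mpta_deg` (default 88 degrees,
#' i.e. a 2 degree tilt), deepening the lesser side; insert points and width
#' are then recomputed. The adjustment is applied once; if the lesser-side
#' depth still falls short, the residual depth is reported, not treated as an
#' error.
#'
#' @param scene An AP [knee_scene()].
#' @param tma Tibial mechanical axis (distally oriented).
#' @param offset_mm Resection offset distal to the most proximal plateau
#'   point (mm); default 10.
#' @param min_lesser_depth_mm Minimum acceptable lesser-side resection depth
#'   (mm); default 2.
#' @param adjusted_mpta_deg Medial proximal tibial angle after adjustment
#'   (degrees); default 88.
#' @return List with `resection`, `insert_medial`, `insert_lateral`,
#'   `ml_width_mm`, `depth_medial_mm`, `depth_lateral_mm`,
#'   `lesser_side` ("medial"/"lateral"), `lesser_depth_pre_mm`,
#'   `lesser_depth_mm` (post-adjustment), `mpta_deg`, `adjusted` (flag).
#' @export
tibial_coronal_sizing <- function(scene, tma, offset_mm = 10,
                                  min_lesser_depth_mm = 2,
                                  adjusted_mpta_deg = 88) {
  tibia <- scene$contours$tibia
  m <- medial_unit(scene)
  tp <- furthest_point_along(tibia, tma, "-")        # most proximal point
  o_star <- project_offsets(tp, tma)
  cut0 <- perpendicular_line_at(tma, o_star + offset_mm)  # distal shift
  dep <- function(cut) c(
    medial  = axis_parallel_distance(scene$landmarks$tibial_plateau_medial,  tma, cut),
    lateral = axis_parallel_distance(scene$landmarks$tibial_plateau_lateral, tma, cut))
  d0 <- dep(cut0)
  lesser <- if (d0["medial"] <= d0["lateral"]) "medial" else "lateral"
  lesser_pre <- unname(min(d0))
  adjusted <- lesser_pre < min_lesser_depth_mm
  cut <- cut0
  if (adjusted) {
    pivot <- cut0$origin   # intersection of the unrotated cut with the axis
    tilt <- 90 - adjusted_mpta_deg
    cand <- list(rotate_line_about(cut0, pivot, tilt),
                 rotate_line_about(cut0, pivot, -tilt))
    depths <- vapply(cand, function(cc) unname(min(dep(cc))), numeric(1))
    cut <- cand[[which.max(depths)]]  # tilt toward deeper lesser-side resection
  }
  d <- dep(cut)
  ip <- outermost_insert_points(cut, tibia, m, "tibial resection")
  # medial-side angle between axis and cut: 90 minus the distal inclination of
  # the medially oriented cut direction
  r <- cut$direction
  if (sum(r * m) < 0) r <- -r
  tilt_med <- asin(min(max(sum(r * tma$direction), -1), 1)) * 180 / pi
  list(resection = cut,
       insert_medial = ip$pos, insert_lateral = ip$neg,
       ml_width_mm = vnorm(ip$pos - ip$neg),
       depth_medial_mm = unname(d["medial"]),
       depth_lateral_mm = unname(d["lateral"]),
       lesser_side = lesser,
       lesser_depth_pre_mm = lesser_pre,
       lesser_depth_mm = unname(min(d)),
       mpta_deg = 90 - tilt_med,
       adjusted = adjusted,
       station_offset = o_star + offset_mm)
}

# Signed hip-knee-ankle angle, varus positive: positive when the proximally
# oriented femoral axis deviates medially from the proximally oriented tibial
# axis (bow-legged alignment).
signed_hka_deg <- function(fma, tma, medial) {
  ang <- angle_between_deg(fma, tma)
  u <- -tma$direction; v <- -fma$direction   # proximal senses
  if (sum(u * v) < 0) v <- -v
  dev <- v - sum(v * u) * u
  s <- sign(sum(dev * medial))
  if (s == 0) s <- 1
  s * ang
}

#' Full coronal-plane templating of one AP scene
#'
#' Assembles the femoral and tibial mechanical axes, both resections, insert
#' points, mediolateral widths, the signed hip-knee-ankle angle (varus
#' positive), the medial proximal tibial angle and the lesser-side depth rule.
#'
#' @inheritParams tibial_coronal_sizing
#' @param femur_resection_mm Distal femoral resection (mm), default 9.
#' @return Object of class `coronal_plan`.
#' @export
coronal_template <- function(scene, femur_resection_mm = 9, offset_mm = 10,
                             min_lesser_depth_mm = 2, adjusted_mpta_deg = 88) {
  stopifnot(inherits(scene, "knee_scene"))
  if (scene$view != "AP")
    stop("coronal templating requires an AP scene", call. = FALSE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("coronal templating failed at stage '", what, "': ",
           conditionMessage(e), call. = FALSE))
  }
  fma <- stage("femoral mechanical axis", femoral_mechanical_axis(scene))
  tma <- stage("tibial mechanical axis", tibial_mechanical_axis(scene))
  fem <- stage("femoral sizing",
               femoral_coronal_sizing(scene, fma, femur_resection_mm))
  tib <- stage("tibial sizing",
               tibial_coronal_sizing(scene, tma, offset_mm,
                                     min_lesser_depth_mm, adjusted_mpta_deg))
  structure(list(
    fma = fma, tma = tma,
    femoral_resection = fem$resection,
    tibial_resection = tib$resection,
    femoral_insert_points = list(medial = fem$insert_medial,
                                 lateral = fem$insert_lateral),
    tibial_insert_points = list(medial = tib$insert_medial,
                                lateral = tib$insert_lateral),
    femoral_ml_width_mm = fem$ml_width_mm,
    tibial_ml_width_mm = tib$ml_width_mm,
    hka_deg = signed_hka_deg(fma, tma, medial_unit(scene)),
    mpta_deg = tib$mpta_deg,
    lesser_side = tib$lesser_side,
    lesser_side_depth_mm = tib$lesser_depth_mm,
    lesser_side_depth_pre_mm = tib$lesser_depth_pre_mm,
    depth_medial_mm = tib$depth_medial_mm,
    depth_lateral_mm = tib$depth_lateral_mm,
    mpta_adjusted = tib$adjusted,
    params = list(femur_resection_mm = femur_resection_mm,
                  tibia_offset_mm = offset_mm,
                  min_lesser_depth_mm = min_lesser_depth_mm,
                  adjusted_mpta_deg = adjusted_mpta_deg)),
    class = "coronal_plan")
}

#' @export
print.coronal_plan <- function(x, ...) {
  cat("Coronal (AP) templating plan\n")
  cat(sprintf("  HKA: %+.2f deg (%s)\n", x$hka_deg,
              if (x$hka_deg > 0) "varus" else if (x$hka_deg < 0) "valgus" else "neutral"))
  cat(sprintf("  Femoral ML width: %.2f mm (resection %g mm distal)\n",
              x$femoral_ml_width_mm, x$params$femur_resection_mm))
  cat(sprintf("  Tibial  ML width: %.2f mm (offset %g mm)\n",
              x$tibial_ml_width_mm, x$params$tibia_offset_mm))
  cat(sprintf("  MPTA: %.2f deg%s; lesser (%s) depth %.2f mm\n",
              x$mpta_deg, if (x$mpta_adjusted) " [adjusted]" else "",
              x$lesser_side, x$lesser_side_depth_mm))
  invisible(x)
}
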