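# ---- sagittal (lateral) templating -----------------------------------------
#
# Lateral-view planning: the femoral component is aligned flush to the
# anterior cortical line of the distal femur (notch avoidance) and sized by
# the longest perpendicular distance from that line to the distal femoral
# condyle; the tibial component is cut 10 mm below the plateau with a
# 3 degree posterior slope relative to the tibial anatomical axis and sized
# by the anteroposterior chord of that cut.

#' Anterior cortical line of the distal femur
#'
#' Total-least-squares line through the anterior-most contour points of the
#' femoral shaft, oriented distally. The fit region consists of contour
#' points whose offset along the tibial anatomical axis lies
#' `fit_window_mm` proximal to the most distal femoral point; within the
#' region the contour is resampled and the anterior-most point of each
#' 2 mm scanline bin is kept, so the fit follows the cortex rather than the
#' posterior shaft.
#'
#' @param scene A lateral [knee_scene()].
#' @param fit_window_mm Two-vector (mm proximal to the most distal femoral
#'   point) delimiting the shaft window; default `c(20, 80)`.
#' @return A `directed_line` (distally oriented).
#' @export
anterior_cortical_line <- function(scene, fit_window_mm = c(20, 80)) {
  stopifnot(inherits(scene, "knee_scene"))
  axis <- tibial_anatomical_axis_sagittal(scene)
  femur <- scene$contours$femur
  post <- posterior_unit(scene, axis)
  V <- resample_contour(femur, max_len = 2)
  distal_most <- max(project_offsets(V, axis))
  prox <- distal_most - project_offsets(V, axis)   # mm proximal to distal tip
  sel <- prox >= fit_window_mm[1] & prox <= fit_window_mm[2]
  if (sum(sel) < 2)
    stop("degenerate cortical-line fit: fewer than 2 contour points in the shaft window",
         call. = FALSE)
  Vs <- V[sel, , drop = FALSE]
  ant <- -(Vs[, 1] * post[1] + Vs[, 2] * post[2])   # anterior coordinate
  bin <- floor((prox[sel] - fit_window_mm[1]) / 2)
  keep <- unlist(lapply(split(seq_along(bin), bin), function(i) i[which.max(ant[i])]),
                 use.names = FALSE)
  P <- Vs[keep, , drop = FALSE]
  if (nrow(P) < 2)
    stop("degenerate cortical-line fit: fewer than 2 scanline points", call. = FALSE)
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  ev <- eigen(crossprod(Pc), symmetric = TRUE)
  d <- ev$vectors[, 1]
  if (sum(d * axis$direction) < 0) d <- -d   # orient distally
  directed_line(ctr, d)
}

#' Femoral anteroposterior length on the lateral view
#'
#' The longest perpendicular distance from the anterior cortical line to a
#' point of the distal femoral contour, restricted to points posterior to
#' the line.
#'
#' @param scene A lateral [knee_scene()].
#' @param cortical_line Anterior cortical line (`directed_line`).
#' @return List with `ap_length_mm` and `posterior_point` (the contour point
#'   realising the maximum).
#' @export
femoral_sagittal_sizing <- function(scene, cortical_line) {
  axis <- tibial_anatomical_axis_sagittal(scene)
  post <- posterior_unit(scene, axis)
  V <- scene$contours$femur$vertices
  nrm <- c(-cortical_line$direction[2], cortical_line$direction[1])
  if (sum(nrm * post) < 0) nrm <- -nrm            # posterior-pointing normal
  d <- (V[, 1] - cortical_line$origin[1]) * nrm[1] +
       (V[, 2] - cortical_line$origin[2]) * nrm[2]
  d[d < 0] <- NA                                   # ignore points anterior to the line
  i <- which.max(d)
  list(ap_length_mm = d[i], posterior_point = pt2(V[i, 1], V[i, 2]))
}

#' Tibial anatomical axis on the lateral view
#'
#' Line through the proximal and distal tibial shaft landmarks, oriented
#' distally.
#'
#' @param scene A lateral [knee_scene()].
#' @return A `directed_line`.
#' @export
tibial_anatomical_axis_sagittal <- function(scene) {
  stopifnot(inherits(scene, "knee_scene"))
  line_through(scene$landmarks$tibial_shaft_proximal,
               scene$landmarks$tibial_shaft_distal)
}

#' Sloped proximal tibial resection and anteroposterior width
#'
#' Starts from the perpendicular to the tibial anatomical axis translated
#' `offset_mm` distally from the most proximal plateau contour point, then
#' rotates it by `slope_deg` about its intersection with the axis so that the
#' posterior end drops (posterior slope). The outermost intersections with
#' the tibial contour are the anterior and posterior insert points; the
#' anteroposterior width is their distance.
#'
#' @param scene A lateral [knee_scene()].
#' @param axis Tibial anatomical axis (distally oriented).
#' @param slope_deg Posterior tibial slope (degrees); default 3.
#' @param offset_mm Resection offset below the plateau (mm); default 10.
#' @return List with `resection`, `insert_anterior`, `insert_posterior`,
#'   `ap_width_mm`, `pts_deg`.
#' @export
tibial_sagittal_sizing <- function(scene, axis, slope_deg = 3, offset_mm = 10) {
  tibia <- scene$contours$tibia
  post <- posterior_unit(scene, axis)
  tp <- furthest_point_along(tibia, axis, "-")      # most proximal point
  o_star <- project_offsets(tp, axis)
  cut <- perpendicular_line_at(axis, o_star + offset_mm)
  if (slope_deg != 0) {
    pivot <- cut$origin
    cand <- list(rotate_line_about(cut, pivot, slope_deg),
                 rotate_line_about(cut, pivot, -slope_deg))
    # posterior end must drop: posteriorly oriented direction gains a distal
    # component
    drops <- vapply(cand, function(cc) {
      r <- cc$direction
      if (sum(r * post) < 0) r <- -r
      sum(r * axis$direction)
    }, numeric(1))
    cut <- cand[[which.max(drops)]]
  }
  ip <- outermost_insert_points(cut, tibia, post, "tibial sagittal resection")
  list(resection = cut,
       insert_anterior = ip$neg, insert_posterior = ip$pos,
       ap_width_mm = vnorm(ip$pos - ip$neg),
       pts_deg = slope_deg)
}

#' Full sagittal-plane templating of one lateral scene
#'
#' @inheritParams tibial_sagittal_sizing
#' @param fit_window_mm Shaft window for the cortical-line fit; see
#'   [anterior_cortical_line()].
#' @return Object of class `sagittal_plan`.
#' @export
sagittal_template <- function(scene, slope_deg = 3, offset_mm = 10,
                              fit_window_mm = c(20, 80)) {
  stopifnot(inherits(scene, "knee_scene"))
  if (scene$view != "LAT")
    stop("sagittal templating requires a LAT scene", call. = FALSE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("sagittal templating failed at stage '", what, "': ",
           conditionMessage(e), call. = FALSE))
  }
  axis <- stage("tibial anatomical axis", tibial_anatomical_axis_sagittal(scene))
  cort <- stage("anterior cortical line",
                anterior_cortical_line(scene, fit_window_mm))
  fem <- stage("femoral sizing", femoral_sagittal_sizing(scene, cort))
  tib <- stage("tibial sizing",
               tibial_sagittal_sizing(scene, axis, slope_deg, offset_mm))
  structure(list(
    anterior_cortical_line = cort,
    femoral_ap_length_mm = fem$ap_length_mm,
    femoral_posterior_point = fem$posterior_point,
    tibial_anatomical_axis = axis,
    tibial_resection = tib$resection,
    tibial_ap_width_mm = tib$ap_width_mm,
    tibial_insert_points = list(anterior = tib$insert_anterior,
                                posterior = tib$insert_posterior),
    pts_deg = tib$pts_deg,
    params = list(slope_deg = slope_deg, tibia_offset_mm = offset_mm,
                  fit_window_mm = fit_window_mm)),
    class = "sagittal_plan")
}

#' @export
print.sagittal_plan <- function(x, ...) {
  cat("Sagittal (lateral) templating plan\n")
  cat(sprintf("  Femoral AP length: %.2f mm (from anterior cortical line)\n",
              x$femoral_ap_length_mm))
  cat(sprintf("  Tibial AP width: %.2f mm at %g deg posterior slope\n",
              x$tibial_ap_width_mm, x$pts_deg))
  invisible(x)
}
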