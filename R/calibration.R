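# ---- calibration ------------------------------------------------------------

#' Calibration marker
#'
#' Two pixel points of known physical separation (a ruler segment or the
#' diameter endpoints of a calibration sphere), used to counteract
#' radiographic magnification.
#'
#' @param p1,p2 Pixel coordinates of the marker endpoints.
#' @param known_separation_mm Physical distance between them (mm, > 0).
#' @return Object of class `calibration_marker`.
#' @export
calibration_marker <- function(p1, p2, known_separation_mm) {
  p1 <- as.numeric(p1)[1:2]; p2 <- as.numeric(p2)[1:2]
  if (!all(is.finite(c(p1, p2, known_separation_mm))) || known_separation_mm <= 0)
    stop("invalid calibration marker", call. = FALSE)
  structure(list(p1 = pt2(p1[1], p1[2]), p2 = pt2(p2[1], p2[2]),
                 known_separation_mm = as.numeric(known_separation_mm)),
            class = "calibration_marker")
}

#' Compute the image scale from a calibration marker
#'
#' @param marker A `calibration_marker`.
#' @return Object of class `calibration` with element `mm_per_pixel`.
#' @export
compute_scale <- function(marker) {
  stopifnot(inherits(marker, "calibration_marker"))
  d <- vnorm(marker$p2 - marker$p1)
  if (d < 1e-9) stop("degenerate calibration marker: coincident points", call. = FALSE)
  calibration(marker$known_separation_mm / d)
}

#' @rdname compute_scale
#' @param mm_per_pixel Isotropic scale (mm per pixel, > 0).
#' @export
calibration <- function(mm_per_pixel) {
  mm_per_pixel <- as.numeric(mm_per_pixel)
  if (!is.finite(mm_per_pixel) || mm_per_pixel <= 0)
    stop("mm_per_pixel must be positive and finite", call. = FALSE)
  structure(list(mm_per_pixel = mm_per_pixel), class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.6f mm/pixel\n", x$mm_per_pixel))
  invisible(x)
}

px_to_mm <- function(P, cal, image_height_px) {
  P <- as_point_matrix(P)
  cbind(x = P[, 1] * cal$mm_per_pixel,
        y = (image_height_px - P[, 2]) * cal$mm_per_pixel)
}

mm_to_px <- function(P, cal, image_height_px) {
  P <- as_point_matrix(P)
  cbind(x = P[, 1] / cal$mm_per_pixel,
        y = image_height_px - P[, 2] / cal$mm_per_pixel)
}

#' Convert a pixel-frame scene to the calibrated millimetre frame
#'
#' Pixel input uses the raster convention (y increasing downward); the
#' calibrated frame uses y increasing proximally (toward the head):
#' `x_mm = x_px * s`, `y_mm = (image_height - y_px) * s`.
#'
#' @param contours_px Named list of pixel `contour_polygon`s (or raw vertex
#'   matrices).
#' @param landmarks_px Named list of pixel points (may be empty).
#' @param cal A `calibration`.
#' @param image_height_px Raster height in pixels.
#' @param view `"AP"` or `"LAT"`; passed through to [knee_scene()].
#' @param side `"left"` or `"right"`.
#' @return A [knee_scene()] in the millimetre frame.
#' @export
calibrate_scene <- function(contours_px, landmarks_px, cal, image_height_px,
                            view, side = "right") {
  stopifnot(inherits(cal, "calibration"))
  conv_poly <- function(p) {
    V <- if (inherits(p, "contour_polygon")) p$vertices else as_point_matrix(p)
    contour_polygon(px_to_mm(V, cal, image_height_px))
  }
  contours <- lapply(contours_px, conv_poly)
  landmarks <- lapply(landmarks_px, function(q) {
    m <- px_to_mm(q, cal, image_height_px)
    pt2(m[1, 1], m[1, 2])
  })
  knee_scene(view = view, side = side, contours = contours,
             landmarks = landmarks, calibration = cal)
}

# ---- knee scene -------------------------------------------------------------

required_landmarks <- function(view) {
  switch(view,
         AP  = c("femoral_head_center", "trochlear_groove",
                 "tibial_plateau_medial", "tibial_plateau_lateral",
                 "talar_dome_center"),
         LAT = c("plateau_anterior", "plateau_posterior",
                 "tibial_shaft_proximal", "tibial_shaft_distal"),
         stop("unknown view: ", view, call. = FALSE))
}

required_contours <- function(view) {
  switch(view,
         AP  = c("femur", "tibia"),
         LAT = c("femur", "tibia", "patella", "fibula"),
         stop("unknown view: ", view, call. = FALSE))
}

#' One calibrated view of a knee
#'
#' Bundles the bone contours and named anatomical landmarks of a single view
#' (AP coronal or lateral sagittal) in the calibrated millimetre frame.
#' Required landmarks: AP needs femoral_head_center, trochlear_groove,
#' tibial_plateau_medial, tibial_plateau_lateral, talar_dome_center;
#' LAT needs plateau_anterior, plateau_posterior, tibial_shaft_proximal,
#' tibial_shaft_distal. Required contours: AP femur + tibia; LAT femur,
#' tibia, patella, fibula.
#'
#' @param view `"AP"` or `"LAT"`.
#' @param side `"left"` or `"right"`.
#' @param contours Named list of `contour_polygon`s.
#' @param landmarks Named list of points.
#' @param calibration Optional `calibration` the scene was converted with.
#' @return Object of class `knee_scene`.
#' @export
knee_scene <- function(view, side, contours, landmarks, calibration = NULL) {
  view <- match.arg(view, c("AP", "LAT"))
  side <- match.arg(side, c("left", "right"))
  miss_lm <- setdiff(required_landmarks(view), names(landmarks))
  if (length(miss_lm))
    stop("missing required landmark(s) for ", view, " view: ",
         paste(miss_lm, collapse = ", "), call. = FALSE)
  miss_ct <- setdiff(required_contours(view), names(contours))
  if (length(miss_ct))
    stop("missing required contour(s) for ", view, " view: ",
         paste(miss_ct, collapse = ", "), call. = FALSE)
  ok <- vapply(contours, inherits, logical(1), what = "contour_polygon")
  if (!all(ok)) stop("all contours must be contour_polygon objects", call. = FALSE)
  structure(list(view = view, side = side, contours = contours,
                 landmarks = lapply(landmarks, function(p) pt2(p[1], p[2])),
                 calibration = calibration),
            class = "knee_scene")
}

#' @export
print.knee_scene <- function(x, ...) {
  cat(sprintf("<knee_scene> %s view, %s knee; contours: %s; %d landmarks\n",
              x$view, x$side, paste(names(x$contours), collapse = ", "),
              length(x$landmarks)))
  invisible(x)
}

# Unit vector pointing medially, derived from the plateau landmarks (AP view).
medial_unit <- function(scene) {
  normalize(scene$landmarks$tibial_plateau_medial -
              scene$landmarks$tibial_plateau_lateral)
}

# Unit vector pointing posteriorly, perpendicular to the tibial anatomical
# axis (LAT view).
posterior_unit <- function(scene, axis) {
  v <- scene$landmarks$plateau_posterior - scene$landmarks$plateau_anterior
  w <- v - sum(v * axis$direction) * axis$direction
  normalize(w)
}
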