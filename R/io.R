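# ---- file formats -----------------------------------------------------------
#
# Masks: 8-bit single-channel PNG, nonzero = bone, raster convention
# (row 1 = top, y increasing downward; pixel (x, y) = matrix [y + 1, x + 1]).
# Landmarks: JSON {"view": ..., "side": ..., "landmarks": {name: [x, y]},
# "calibration": {"p1": [x, y], "p2": [x, y], "mm": value}} in pixel
# coordinates. Size chart: CSV component,size,ml_mm,ap_mm. Reports: JSON.

read_mask_png <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  if (all(m == 0)) stop("empty mask (no bone pixels): ", path, call. = FALSE)
  m
}

# Douglas-Peucker polyline simplification (closed contour: anchored at the
# two most distant vertices).
dp_simplify <- function(V, tol) {
  n <- nrow(V)
  if (n <= 4 || tol <= 0) return(V)
  simplify_open <- function(idx) {
    keep <- rep(FALSE, length(idx))
    keep[c(1, length(idx))] <- TRUE
    stack <- list(c(1L, length(idx)))
    while (length(stack)) {
      seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- seg[1]; j <- seg[2]
      if (j - i < 2) next
      a <- V[idx[i], ]; b <- V[idx[j], ]
      ab <- b - a; L <- vnorm(ab)
      mid <- idx[(i + 1):(j - 1)]
      d <- if (L < 1e-12) sqrt(rowSums(sweep(V[mid, , drop = FALSE], 2, a)^2))
           else abs((V[mid, 1] - a[1]) * ab[2] - (V[mid, 2] - a[2]) * ab[1]) / L
      k <- which.max(d)
      if (d[k] > tol) {
        keep[i + k] <- TRUE
        stack <- c(stack, list(c(i, i + k)), list(c(i + k, j)))
      }
    }
    idx[keep]
  }
  ext <- c(which.max(V[, 1]), which.min(V[, 1]))
  if (ext[1] == ext[2]) return(V)
  i1 <- min(ext); i2 <- max(ext)
  idx1 <- simplify_open(i1:i2)
  idx2 <- simplify_open(c(i2:n, 1:i1))
  keep <- sort(unique(c(idx1, idx2[-length(idx2)])))
  V[keep, , drop = FALSE]
}

#' Extract the bone contour polygon from a binary mask
#'
#' Marching-squares boundary of the largest region at level 0.5, simplified
#' with a Douglas-Peucker tolerance (default 0.5 px). If the mask contains
#' more than one region the largest is used and a warning is issued.
#'
#' @param mask Numeric matrix (nonzero = bone) or a PNG path.
#' @param simplify_tol_px Simplification tolerance in pixels.
#' @return A `contour_polygon` in pixel coordinates (y down).
#' @export
mask_to_contour <- function(mask, simplify_tol_px = 0.5) {
  if (is.character(mask)) mask <- read_mask_png(mask)
  # pad so boundary-touching regions still close
  m <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.numeric(mask > 0)
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  if (length(cl) == 0) stop("empty mask: no contour found", call. = FALSE)
  polys <- lapply(cl, function(co) cbind(x = co$y - 2, y = co$x - 2))
  areas <- vapply(polys, function(P) abs(polygon_signed_area(P)), numeric(1))
  if (length(polys) > 1)
    warning("mask contains ", length(polys),
            " regions; using the largest", call. = FALSE)
  V <- polys[[which.max(areas)]]
  V <- dp_simplify(V, simplify_tol_px)
  contour_polygon(V, check_simple = FALSE)
}

#' Read one view's pixel-frame scene from mask and landmark files
#'
#' @param mask_paths Named character vector/list of PNG paths (names are the
#'   bone names, e.g. `c(femur = ..., tibia = ...)`).
#' @param landmarks_path Path to the landmarks JSON (must contain the view's
#'   required landmark names and a `calibration` block).
#' @param view `"AP"` or `"LAT"`; defaults to the JSON's `view` field.
#' @param simplify_tol_px Contour simplification tolerance (pixels).
#' @return List (pixel frame, pre-calibration): `contours`, `landmarks`,
#'   `marker`, `view`, `side`, `image_height`.
#' @export
read_scene <- function(mask_paths, landmarks_path, view = NULL,
                       simplify_tol_px = 0.5) {
  if (!file.exists(landmarks_path))
    stop("landmarks file not found: ", landmarks_path, call. = FALSE)
  js <- jsonlite::fromJSON(landmarks_path, simplifyVector = TRUE)
  if (is.null(view)) view <- js$view
  if (is.null(view)) stop("view not given and absent from landmarks JSON",
                          call. = FALSE)
  side <- if (!is.null(js$side)) js$side else "right"
  lms <- lapply(js$landmarks, function(v) pt2(v[1], v[2]))
  miss <- setdiff(required_landmarks(view), names(lms))
  if (length(miss))
    stop("missing required landmark(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(js$calibration))
    stop("landmarks JSON lacks the calibration block", call. = FALSE)
  marker <- calibration_marker(js$calibration$p1, js$calibration$p2,
                               js$calibration$mm)
  masks <- lapply(mask_paths, read_mask_png)
  contours <- lapply(masks, mask_to_contour, simplify_tol_px = simplify_tol_px)
  heights <- vapply(masks, nrow, integer(1))
  list(contours = contours, landmarks = lms, marker = marker,
       view = view, side = side, image_height = max(heights))
}

#' Read and calibrate one view into a millimetre-frame scene
#'
#' Convenience wrapper: [read_scene()] then [compute_scale()] and
#' [calibrate_scene()].
#'
#' @inheritParams read_scene
#' @return A [knee_scene()] in the calibrated millimetre frame.
#' @export
load_scene <- function(mask_paths, landmarks_path, view = NULL,
                       simplify_tol_px = 0.5) {
  sc <- read_scene(mask_paths, landmarks_path, view, simplify_tol_px)
  cal <- compute_scale(sc$marker)
  calibrate_scene(sc$contours, sc$landmarks, cal, sc$image_height,
                  view = sc$view, side = sc$side)
}

# ---- writing scenes (used by the generator / CLI simulate) ------------------

# Fill a polygon (pixel coords, y down) into a 0/1 matrix by scanline parity.
rasterize_polygon <- function(V, width, height) {
  m <- matrix(0, nrow = height, ncol = width)
  ys <- V[, 2]
  for (r in seq_len(height)) {
    y <- r - 1
    j <- c(2:nrow(V), 1L)
    y1 <- ys; y2 <- ys[j]
    cr <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)   # half-open rule
    if (!any(cr)) next
    t <- (y - y1[cr]) / (y2[cr] - y1[cr])
    xs <- sort(V[cr, 1] + t * (V[j, 1][cr] - V[cr, 1]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c1 <- max(1L, ceiling(xs[k] + 1))
      c2 <- min(width, floor(xs[k + 1] + 1))
      if (c1 <= c2) m[r, c1:c2] <- 1
    }
  }
  m
}

#' Write a synthetic knee scene as a mask + landmarks case bundle
#'
#' Serialises a millimetre-frame scene into the same dialect [read_scene()]
#' ingests: one 8-bit PNG mask per bone plus a landmarks JSON with a
#' calibration block (two marker points 100 px apart whose physical
#' separation encodes the scene's pixel scale). The scene is shifted into
#' the positive pixel quadrant with a margin.
#'
#' @param scene A [knee_scene()] (mm frame) carrying its `calibration`.
#' @param dir Output directory (created if needed).
#' @param margin_px Margin around the anatomy (pixels).
#' @return Invisibly, a list with the mask paths and landmarks path.
#' @export
write_scene_bundle <- function(scene, dir, margin_px = 12) {
  stopifnot(inherits(scene, "knee_scene"))
  if (is.null(scene$calibration))
    stop("scene carries no calibration; cannot rasterise", call. = FALSE)
  s <- scene$calibration$mm_per_pixel
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  allpts <- rbind(do.call(rbind, lapply(scene$contours, function(p) p$vertices)),
                  do.call(rbind, lapply(scene$landmarks, rbind)))
  xmin <- min(allpts[, 1]); ymax <- max(allpts[, 2]); ymin <- min(allpts[, 2])
  width <- ceiling((max(allpts[, 1]) - xmin) / s) + 2 * margin_px
  height <- ceiling((ymax - ymin) / s) + 2 * margin_px
  to_px <- function(P) {
    P <- as_point_matrix(P)
    cbind(x = (P[, 1] - xmin) / s + margin_px,
          y = height - ((P[, 2] - ymin) / s + margin_px))
  }
  mask_paths <- character(0)
  for (bone in names(scene$contours)) {
    m <- rasterize_polygon(to_px(scene$contours[[bone]]$vertices), width, height)
    p <- file.path(dir, paste0(bone, ".png"))
    png::writePNG(m, p)
    mask_paths[bone] <- p
  }
  lm_px <- lapply(scene$landmarks, function(p) as.numeric(to_px(p)))
  js <- list(view = scene$view, side = scene$side,
             landmarks = lm_px,
             calibration = list(p1 = c(10, 10), p2 = c(110, 10),
                                mm = 100 * s))
  lm_path <- file.path(dir, "landmarks.json")
  jsonlite::write_json(js, lm_path, auto_unbox = TRUE, digits = NA)
  invisible(list(mask_paths = mask_paths, landmarks_path = lm_path,
                 image_height = height))
}

# ---- report -----------------------------------------------------------------

#' Serialise a templating result to a report JSON
#'
#' Writes sizes, widths, angles, insert-point coordinates, flags, the tool
#' version and (when input paths are supplied) their MD5 hashes, with stable
#' key order. The output is byte-identical across runs on the same inputs.
#'
#' @param result A `tka_template`.
#' @param path Output path.
#' @param inputs Optional character vector of input file paths to hash.
#' @return Invisibly, the report list.
#' @export
write_report <- function(result, path, inputs = NULL) {
  stopifnot(inherits(result, "tka_template"))
  s <- result$sizes
  cor <- result$coronal; sag <- result$sagittal
  as_xy <- function(p) c(round(p[[1]], 6), round(p[[2]], 6))
  rep <- list(
    tool = "kneetemplate",
    version = as.character(utils::packageVersion("kneetemplate")),
    sizes = lapply(seq_len(nrow(s)), function(i) list(
      component = s$component[i],
      coronal_size = s$coronal_size[i],
      sagittal_size = s$sagittal_size[i],
      merged_size = s$merged_size[i],
      coronal_width_mm = round(s$coronal_width_mm[i], 6),
      sagittal_width_mm = round(s$sagittal_width_mm[i], 6),
      coronal_flag = s$coronal_flag[i],
      sagittal_flag = s$sagittal_flag[i])),
    angles = list(hka_deg = round(cor$hka_deg, 6),
                  mpta_deg = round(cor$mpta_deg, 6),
                  pts_deg = round(sag$pts_deg, 6)),
    mpta_adjusted = cor$mpta_adjusted,
    lesser_side = cor$lesser_side,
    lesser_side_depth_mm = round(cor$lesser_side_depth_mm, 6),
    insert_points = list(
      ap_femoral = list(medial = as_xy(cor$femoral_insert_points$medial),
                        lateral = as_xy(cor$femoral_insert_points$lateral)),
      ap_tibial = list(medial = as_xy(cor$tibial_insert_points$medial),
                       lateral = as_xy(cor$tibial_insert_points$lateral)),
      lat_tibial = list(anterior = as_xy(sag$tibial_insert_points$anterior),
                        posterior = as_xy(sag$tibial_insert_points$posterior)),
      lat_femoral_posterior = as_xy(sag$femoral_posterior_point)))
  if (!is.null(inputs))
    rep$input_md5 <- as.list(tools::md5sum(inputs))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rep)
}

# ---- overlay rendering ------------------------------------------------------

draw_line_seg <- function(line, span, ...) {
  a <- line$origin - span * line$direction
  b <- line$origin + span * line$direction
  graphics::segments(a[1], a[2], b[1], b[2], ...)
}

plot_scene_layer <- function(scene) {
  for (ct in scene$contours)
    graphics::polygon(ct$vertices[, 1], ct$vertices[, 2],
                      border = "grey35", col = "grey88", lwd = 1)
  lm <- do.call(rbind, scene$landmarks)
  graphics::points(lm[, 1], lm[, 2], pch = 3, col = "red3", cex = 0.7)
}

# rectangle proxy for the chosen implant at the planned position/alignment
implant_rect <- function(center, along, across, half_len, thickness) {
  a <- center - half_len * along
  b <- center + half_len * along
  rbind(a, b, b - thickness * across, a - thickness * across)
}

#' Render a plan overlay image
#'
#' Draws the bone contours, mechanical axes, resection lines, insert points
#' and a rectangle proxy of the merged-size implant (exact catalogue width,
#' drawn in pure red) over the scene, and writes a PNG whose pixel grid
#' matches the scene extent at the requested resolution.
#'
#' @param scene The [knee_scene()] that was templated (AP or LAT).
#' @param result A `tka_template`.
#' @param path Output PNG path.
#' @param px_per_mm Rendering resolution (default 4).
#' @return Invisibly, c(width, height) of the written image in pixels.
#' @export
render_overlay <- function(scene, result, path, px_per_mm = 4) {
  stopifnot(inherits(result, "tka_template"))
  allpts <- do.call(rbind, lapply(scene$contours, function(p) p$vertices))
  pad <- 5
  xl <- c(min(allpts[, 1]) - pad, max(allpts[, 1]) + pad)
  yl <- c(min(allpts[, 2]) - pad, max(allpts[, 2]) + pad)
  W <- ceiling(diff(xl) * px_per_mm); H <- ceiling(diff(yl) * px_per_mm)
  if (capabilities("cairo")) {
    grDevices::png(path, width = W, height = H, type = "cairo",
                   antialias = "none")
  } else {
    grDevices::png(path, width = W, height = H)
  }
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot(NA, xlim = xl, ylim = yl, axes = FALSE,
                 xlab = "", ylab = "")
  for (ct in scene$contours)
    graphics::polygon(ct$vertices[, 1], ct$vertices[, 2],
                      border = "grey35", col = "grey88", lwd = 1)
  span <- max(diff(xl), diff(yl))
  chart <- result$chart
  dim_mm <- function(component, size, d)
    chart[[paste0(d, "_mm")]][chart$component == component & chart$size == size]
  s <- result$sizes
  if (scene$view == "AP") {
    cor <- result$coronal
    draw_line_seg(cor$fma, span, col = "dodgerblue3", lwd = 1)
    draw_line_seg(cor$tma, span, col = "dodgerblue3", lwd = 1)
    draw_line_seg(cor$femoral_resection, span / 2, col = "darkorange2", lwd = 1)
    draw_line_seg(cor$tibial_resection, span / 2, col = "darkorange2", lwd = 1)
    ip <- rbind(cor$femoral_insert_points$medial, cor$femoral_insert_points$lateral,
                cor$tibial_insert_points$medial, cor$tibial_insert_points$lateral)
    graphics::points(ip[, 1], ip[, 2], pch = 16, col = "blue", cex = 0.6)
    for (i in 1:2) {
      comp <- s$component[i]
      plan_ip <- if (comp == "femoral") cor$femoral_insert_points else cor$tibial_insert_points
      ln <- if (comp == "femoral") cor$femoral_resection else cor$tibial_resection
      ml <- dim_mm(comp, s$merged_size[i], "ml")
      ctr <- midpoint(plan_ip$medial, plan_ip$lateral)
      ax <- if (comp == "femoral") cor$fma else cor$tma
      rect_dir <- if (comp == "femoral") -1 else 1   # femur body proximal, tibia distal
      Rct <- implant_rect(ctr, ln$direction, rect_dir * ax$direction, ml / 2, 8)
      graphics::polygon(Rct[, 1], Rct[, 2], border = NA, col = "#FF0000")
    }
  } else {
    sag <- result$sagittal
    draw_line_seg(sag$anterior_cortical_line, span, col = "dodgerblue3", lwd = 1)
    draw_line_seg(sag$tibial_anatomical_axis, span, col = "dodgerblue3", lwd = 1)
    draw_line_seg(sag$tibial_resection, span / 2, col = "darkorange2", lwd = 1)
    ip <- rbind(sag$tibial_insert_points$anterior, sag$tibial_insert_points$posterior,
                sag$femoral_posterior_point)
    graphics::points(ip[, 1], ip[, 2], pch = 16, col = "blue", cex = 0.6)
    i <- which(s$component == "tibial")
    ap <- dim_mm("tibial", s$merged_size[i], "ap")
    ctr <- midpoint(sag$tibial_insert_points$anterior,
                    sag$tibial_insert_points$posterior)
    Rct <- implant_rect(ctr, sag$tibial_resection$direction,
                        -sag$tibial_anatomical_axis$direction, ap / 2, 8)
    graphics::polygon(Rct[, 1], Rct[, 2], border = NA, col = "#FF0000")
  }
  invisible(c(width = W, height = H))
}

#' Plot a templating result
#'
#' Base-graphics rendering of the AP and lateral plans side by side.
#'
#' @param x A `tka_template`.
#' @param ... Unused.
#' @export
plot.tka_template <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  draw_view <- function(scene, title, lines, pts) {
    allpts <- do.call(rbind, lapply(scene$contours, function(p) p$vertices))
    graphics::plot(NA, xlim = range(allpts[, 1]) + c(-5, 5),
                   ylim = range(allpts[, 2]) + c(-5, 5), asp = 1,
                   axes = FALSE, xlab = "", ylab = "", main = title)
    plot_scene_layer(scene)
    span <- diff(range(allpts[, 2]))
    for (ln in lines) draw_line_seg(ln$line, span * ln$f, col = ln$col, lwd = 1.2)
    P <- do.call(rbind, pts)
    graphics::points(P[, 1], P[, 2], pch = 16, col = "blue", cex = 0.8)
  }
  cor <- x$coronal; sag <- x$sagittal
  draw_view(x$ap_scene, "Coronal plan",
            list(list(line = cor$fma, f = 1, col = "dodgerblue3"),
                 list(line = cor$tma, f = 1, col = "dodgerblue3"),
                 list(line = cor$femoral_resection, f = 0.2, col = "darkorange2"),
                 list(line = cor$tibial_resection, f = 0.2, col = "darkorange2")),
            c(cor$femoral_insert_points, cor$tibial_insert_points))
  draw_view(x$lat_scene, "Sagittal plan",
            list(list(line = sag$anterior_cortical_line, f = 0.6, col = "dodgerblue3"),
                 list(line = sag$tibial_anatomical_axis, f = 0.6, col = "dodgerblue3"),
                 list(line = sag$tibial_resection, f = 0.3, col = "darkorange2")),
            c(sag$tibial_insert_points, list(sag$femoral_posterior_point)))
  invisible(x)
}
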