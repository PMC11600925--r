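# ---- implant size chart and size selection ----------------------------------

#' Implant size chart
#'
#' Catalogue of femoral and tibial component dimensions per size. Sizes and
#' both dimensions must be strictly increasing within each component.
#'
#' @param df Data frame with columns `component` ("femoral"/"tibial"),
#'   `size` (integer label), `ml_mm`, `ap_mm`.
#' @return Object of class `implant_size_chart` (a validated data frame).
#' @export
implant_size_chart <- function(df) {
  need <- c("component", "size", "ml_mm", "ap_mm")
  if (!all(need %in% names(df)))
    stop("size chart needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  df <- df[order(df$component, df$size), need]
  df$component <- as.character(df$component)
  if (!all(df$component %in% c("femoral", "tibial")))
    stop("size chart component must be 'femoral' or 'tibial'", call. = FALSE)
  for (cmp in unique(df$component)) {
    e <- df[df$component == cmp, ]
    if (nrow(e) == 0) next
    if (any(diff(e$size) <= 0) || any(diff(e$ml_mm) <= 0) || any(diff(e$ap_mm) <= 0))
      stop("size chart for ", cmp,
           " component must have strictly increasing size, ml_mm and ap_mm",
           call. = FALSE)
  }
  structure(df, class = c("implant_size_chart", "data.frame"))
}

#' Read an implant size chart from CSV or JSON
#'
#' CSV columns (or JSON array-of-objects fields): component, size, ml_mm, ap_mm.
#'
#' @param path File path (.csv or .json).
#' @return An [implant_size_chart()].
#' @export
read_size_chart <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  implant_size_chart(df)
}

#' Built-in synthetic size chart
#'
#' A synthetic eight-size chart with plausibly spaced dimensions (3 mm steps),
#' mirroring the structure of a commercial knee system catalogue without
#' reproducing any vendor's dimensions. Used as the default chart and by the
#' synthetic knee generator.
#'
#' @return An [implant_size_chart()].
#' @export
default_size_chart <- function() {
  sizes <- 1:8
  implant_size_chart(data.frame(
    component = rep(c("femoral", "tibial"), each = 8),
    size = c(sizes, sizes),
    ml_mm = c(54 + 3 * sizes,   # femoral ML 57..78
              56 + 3 * sizes),  # tibial  ML 59..80
    ap_mm = c(46 + 3 * sizes,   # femoral AP 49..70
              38 + 3 * sizes))) # tibial  AP 41..62
}

#' Map a measured width to a catalogue size (no-overhang rule)
#'
#' Chooses the largest size whose chart dimension does not exceed the
#' measured bone width, so the implant never overhangs the cortex. Widths
#' below the smallest entry clamp to the smallest size with an
#' `undersized_bone` flag; widths above the largest entry clamp to the
#' largest size with an `oversized_bone` flag.
#'
#' @param width_mm Measured bone width (mm, > 0).
#' @param chart An [implant_size_chart()].
#' @param component `"femoral"` or `"tibial"`.
#' @param dimension `"ml"` or `"ap"`.
#' @return List with `size` and `flag` (`"ok"`, `"undersized_bone"` or
#'   `"oversized_bone"`).
#' @export
select_size <- function(width_mm, chart, component = c("femoral", "tibial"),
                        dimension = c("ml", "ap")) {
  component <- match.arg(component)
  dimension <- match.arg(dimension)
  stopifnot(inherits(chart, "implant_size_chart"))
  if (!is.finite(width_mm) || width_mm <= 0)
    stop("width must be positive and finite", call. = FALSE)
  e <- chart[chart$component == component, ]
  if (nrow(e) == 0) stop("size chart has no entries for component ", component,
                         call. = FALSE)
  dims <- e[[paste0(dimension, "_mm")]]
  if (width_mm < dims[1])
    return(list(size = e$size[1], flag = "undersized_bone"))
  i <- max(which(dims <= width_mm))
  flag <- if (i == nrow(e) && width_mm > dims[i]) "oversized_bone" else "ok"
  list(size = e$size[i], flag = flag)
}

#' Merge per-view size predictions (min rule)
#'
#' The merged prediction is the smaller of the coronal and sagittal sizes,
#' preventing implant overhang. If one view failed, the other is returned
#' with a single-view flag.
#'
#' @param coronal,sagittal Size labels (either may be `NA`).
#' @return List with `size` and `single_view` flag.
#' @export
merge_sizes <- function(coronal, sagittal) {
  if (is.na(coronal) && is.na(sagittal))
    stop("no size prediction available from either view", call. = FALSE)
  if (is.na(coronal))  return(list(size = sagittal, single_view = TRUE))
  if (is.na(sagittal)) return(list(size = coronal,  single_view = TRUE))
  list(size = min(coronal, sagittal), single_view = FALSE)
}

#' Template a knee from paired AP and lateral scenes
#'
#' Runs coronal and sagittal templating, maps the measured mediolateral
#' (coronal) and anteroposterior (sagittal) widths of each component to
#' catalogue sizes, and merges the per-view predictions by taking the
#' smaller size.
#'
#' @param ap_scene Calibrated AP [knee_scene()].
#' @param lat_scene Calibrated lateral [knee_scene()].
#' @param chart An [implant_size_chart()]; defaults to [default_size_chart()].
#' @param femur_resection_mm Distal femoral resection (mm), default 9.
#' @param tibia_offset_mm Tibial resection offset (mm), default 10.
#' @param min_depth_mm Minimum lesser-side tibial depth (mm), default 2.
#' @param adjusted_mpta_deg Adjusted medial proximal tibial angle, default 88.
#' @param slope_deg Posterior tibial slope (degrees), default 3.
#' @return Object of class `tka_template` with elements `coronal`
#'   (`coronal_plan`), `sagittal` (`sagittal_plan`), `sizes` (data frame with
#'   one row per component: coronal, sagittal and merged size labels plus
#'   flags) and `chart`.
#' @export
template_knee <- function(ap_scene, lat_scene, chart = default_size_chart(),
                          femur_resection_mm = 9, tibia_offset_mm = 10,
                          min_depth_mm = 2, adjusted_mpta_deg = 88,
                          slope_deg = 3) {
  cor <- coronal_template(ap_scene, femur_resection_mm, tibia_offset_mm,
                          min_depth_mm, adjusted_mpta_deg)
  sag <- sagittal_template(lat_scene, slope_deg, tibia_offset_mm)
  pick <- function(width, component, dimension)
    select_size(width, chart, component, dimension)
  fc <- pick(cor$femoral_ml_width_mm, "femoral", "ml")
  fs <- pick(sag$femoral_ap_length_mm, "femoral", "ap")
  tc <- pick(cor$tibial_ml_width_mm, "tibial", "ml")
  ts <- pick(sag$tibial_ap_width_mm, "tibial", "ap")
  fm <- merge_sizes(fc$size, fs$size)
  tm <- merge_sizes(tc$size, ts$size)
  sizes <- data.frame(
    component = c("femoral", "tibial"),
    coronal_size = c(fc$size, tc$size),
    sagittal_size = c(fs$size, ts$size),
    merged_size = c(fm$size, tm$size),
    coronal_width_mm = c(cor$femoral_ml_width_mm, cor$tibial_ml_width_mm),
    sagittal_width_mm = c(sag$femoral_ap_length_mm, sag$tibial_ap_width_mm),
    coronal_flag = c(fc$flag, tc$flag),
    sagittal_flag = c(fs$flag, ts$flag),
    stringsAsFactors = FALSE)
  structure(list(coronal = cor, sagittal = sag, sizes = sizes, chart = chart,
                 ap_scene = ap_scene, lat_scene = lat_scene),
            class = "tka_template")
}

#' @export
print.tka_template <- function(x, ...) {
  cat("Total knee arthroplasty templating result\n")
  s <- x$sizes
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-7s component: merged size %d (coronal %d / sagittal %d)\n",
                s$component[i], s$merged_size[i], s$coronal_size[i],
                s$sagittal_size[i]))
  }
  cat(sprintf("  HKA %+.2f deg, MPTA %.2f deg%s, PTS %g deg\n",
              x$coronal$hka_deg, x$coronal$mpta_deg,
              if (x$coronal$mpta_adjusted) " (adjusted)" else "",
              x$sagittal$pts_deg))
  invisible(x)
}

#' @export
summary.tka_template <- function(object, ...) {
  x <- object
  print(x)
  cat("\nCoronal measurements\n")
  cat(sprintf("  femoral ML %.2f mm, tibial ML %.2f mm\n",
              x$coronal$femoral_ml_width_mm, x$coronal$tibial_ml_width_mm))
  cat(sprintf("  resection depths: medial %.2f mm, lateral %.2f mm (lesser: %s)\n",
              x$coronal$depth_medial_mm, x$coronal$depth_lateral_mm,
              x$coronal$lesser_side))
  cat("Sagittal measurements\n")
  cat(sprintf("  femoral AP %.2f mm, tibial AP %.2f mm\n",
              x$sagittal$femoral_ap_length_mm, x$sagittal$tibial_ap_width_mm))
  flags <- unique(c(x$sizes$coronal_flag, x$sizes$sagittal_flag))
  flags <- setdiff(flags, "ok")
  if (length(flags)) cat("Flags:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}
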