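# ---- size-agreement statistics ----------------------------------------------

#' Classify a size prediction against the implanted size
#'
#' `exact` when predicted equals actual; `accurate` when within one size
#' (exact predictions are also accurate); otherwise `overestimate` or
#' `underestimate` by the sign of predicted minus actual.
#'
#' @param predicted,actual Integer size labels (vectorised).
#' @return Character vector: `"exact"`, `"accurate"`, `"overestimate"` or
#'   `"underestimate"`.
#' @export
classify_prediction <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual),
            all(is.finite(predicted)), all(is.finite(actual)))
  delta <- predicted - actual
  out <- character(length(delta))
  out[delta == 0] <- "exact"
  out[abs(delta) == 1] <- "accurate"
  out[delta >= 2] <- "overestimate"
  out[delta <= -2] <- "underestimate"
  out
}

#' Summarise size-prediction agreement
#'
#' Counts and percentages of exact, accurate (inclusive of exact),
#' overestimated and underestimated predictions.
#'
#' @param predicted,actual Integer size labels.
#' @return Data frame with columns `category`, `count`, `percent`
#'   (count / n * 100; display-rounded only when printed).
#' @export
agreement_summary <- function(predicted, actual) {
  if (length(predicted) == 0) stop("no records to summarise", call. = FALSE)
  cls <- classify_prediction(predicted, actual)
  n <- length(cls)
  counts <- c(exact = sum(cls == "exact"),
              accurate = sum(cls %in% c("exact", "accurate")),
              overestimate = sum(cls == "overestimate"),
              underestimate = sum(cls == "underestimate"))
  structure(data.frame(category = names(counts),
                       count = as.integer(counts),
                       percent = 100 * counts / n,
                       row.names = NULL),
            n = n, class = c("agreement_summary", "data.frame"))
}

#' @export
print.agreement_summary <- function(x, ...) {
  n <- attr(x, "n")
  cat(sprintf("Size agreement over %d predictions\n", n))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-13s %3d (%.1f%%)\n", x$category[i], x$count[i], x$percent[i]))
  invisible(x)
}

#' Cohen's kappa with quadratic weights
#'
#' Chance-corrected agreement for ordered categories:
#' kappa = 1 - sum(w * O) / sum(w * E) with weights
#' w_ij = (i - j)^2 / (k - 1)^2, observed proportions O, and expected
#' proportions E from the marginal products. Returns a value in \[-1, 1\]
#' plus the conventional interpretation band (poor / slight / fair /
#' moderate / substantial / almost perfect).
#'
#' @param predicted,actual Equal-length vectors of labels (n >= 2).
#' @param categories Ordered vector of possible labels; defaults to the
#'   sorted union of the observed labels.
#' @return List with `kappa` and `interpretation`.
#' @export
quadratic_weighted_kappa <- function(predicted, actual,
                                     categories = sort(unique(c(predicted, actual)))) {
  stopifnot(length(predicted) == length(actual), length(predicted) >= 2)
  if (!all(predicted %in% categories) || !all(actual %in% categories))
    stop("labels outside the category set", call. = FALSE)
  k <- length(categories)
  if (k < 2)
    stop("undefined kappa: all mass in a single category for both raters",
         call. = FALSE)
  i <- match(predicted, categories)
  j <- match(actual, categories)
  O <- table(factor(i, levels = 1:k), factor(j, levels = 1:k)) / length(i)
  E <- outer(rowSums(O), colSums(O))
  W <- outer(1:k, 1:k, function(a, b) (a - b)^2) / (k - 1)^2
  den <- sum(W * E)
  if (den < .Machine$double.eps)
    stop("undefined kappa: no expected disagreement", call. = FALSE)
  kap <- 1 - sum(W * O) / den
  list(kappa = kap, interpretation = kappa_interpretation(kap))
}

#' @rdname quadratic_weighted_kappa
#' @param kappa A kappa value.
#' @export
kappa_interpretation <- function(kappa) {
  if (kappa <= 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost perfect"
}

# ---- postoperative registration ---------------------------------------------

#' 2D similarity transform
#'
#' Maps postoperative coordinates into the preoperative frame:
#' `q = scale * R(rotation) p + translation`.
#'
#' @param scale Positive scale factor.
#' @param rotation_deg Rotation (degrees, counter-clockwise).
#' @param translation Length-2 translation (mm).
#' @return Object of class `similarity_transform`.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0,
                                 translation = c(0, 0)) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive", call. = FALSE)
  structure(list(scale = scale, rotation_deg = rotation_deg,
                 translation = as.numeric(translation)[1:2]),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity_transform> scale %.4f, rotation %.3f deg, translation (%.2f, %.2f)\n",
              x$scale, x$rotation_deg, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param transform A [similarity_transform()].
#' @param points Points (matrix, list or single point).
#' @return n x 2 matrix of transformed points.
#' @export
apply_transform <- function(transform, points) {
  P <- as_point_matrix(points)
  th <- transform$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Q <- transform$scale * P %*% t(R)
  cbind(x = Q[, 1] + transform$translation[1],
        y = Q[, 2] + transform$translation[2])
}

# fraction of postoperative mask pixels that land inside the preoperative
# mask after transformation (bilinear interpolation keeps the objective
# smooth in the rotation angle)
mask_overlap <- function(pre_mask, post_xy, transform) {
  Q <- apply_transform(transform, post_xy)
  cx <- Q[, 1] + 1  # pixel (x, y) -> matrix [row = y + 1, col = x + 1]
  cy <- Q[, 2] + 1
  nr <- nrow(pre_mask); nc <- ncol(pre_mask)
  x0 <- floor(cx); y0 <- floor(cy)
  fx <- cx - x0; fy <- cy - y0
  val <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- numeric(length(r))
    v[ok] <- pre_mask[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - fx) * (1 - fy) * val(y0, x0) +
       fx * (1 - fy) * val(y0, x0 + 1) +
       (1 - fx) * fy * val(y0 + 1, x0) +
       fx * fy * val(y0 + 1, x0 + 1)
  mean(v)
}

#' Fit a similarity transform between postoperative and preoperative frames
#'
#' Scale is estimated rotation-free from the ratio of root-mean-square
#' point spreads about the centroids of the marked corresponding points;
#' translation follows from the centroids given a rotation. The rotation is
#' estimated by aligning the segmentation masks: a coarse 1-degree grid over
#' `rotation_range_deg` followed by golden-section refinement of the mask
#' overlap (final bracket below 0.1 degree). Without masks the rotation is
#' estimated from the point pairs by least squares.
#'
#' @param pre_points,post_points Corresponding marked points (n >= 2 rows).
#' @param pre_mask,post_mask Optional binary masks (matrices, row = y + 1,
#'   col = x + 1, nonzero = bone) of the same bone on both images.
#' @param rotation_range_deg Half-width of the rotation search (degrees).
#' @return A [similarity_transform()] mapping post into the pre frame.
#' @export
fit_similarity_transform <- function(pre_points, post_points,
                                     pre_mask = NULL, post_mask = NULL,
                                     rotation_range_deg = 20) {
  P <- as_point_matrix(post_points)
  Q <- as_point_matrix(pre_points)
  if (nrow(P) < 2 || nrow(P) != nrow(Q))
    stop("underdetermined registration: need >= 2 corresponding point pairs",
         call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sp <- sum(Pc^2); sq <- sum(Qc^2)
  if (sp < 1e-12) stop("degenerate point pairs: zero spread", call. = FALSE)
  s <- sqrt(sq / sp)
  trans_for <- function(th_deg) {
    th <- th_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    similarity_transform(s, th_deg, cq - s * as.numeric(R %*% cp))
  }
  if (is.null(pre_mask) || is.null(post_mask)) {
    # least-squares rotation from the point pairs
    num <- sum(Pc[, 1] * Qc[, 2] - Pc[, 2] * Qc[, 1])
    den <- sum(Pc * Qc)
    th <- atan2(num, den) * 180 / pi
    return(trans_for(th))
  }
  idx <- which(post_mask > 0, arr.ind = TRUE)
  post_xy <- cbind(idx[, 2] - 1, idx[, 1] - 1)     # (x, y) pixel coords
  obj <- function(th) mask_overlap(pre_mask, post_xy, trans_for(th))
  # coarse grid on a pixel subsample; refinement uses every pixel
  sub <- if (nrow(post_xy) > 4000)
    post_xy[seq(1, nrow(post_xy), length.out = 4000), , drop = FALSE]
  else post_xy
  grid <- seq(-rotation_range_deg, rotation_range_deg, by = 1)
  vals <- vapply(grid, function(th) mask_overlap(pre_mask, sub, trans_for(th)),
                 numeric(1))
  th0 <- grid[which.max(vals)]
  # principal-axis orientation difference of the two masks gives a subpixel
  # rotation estimate (second moments average over every bone pixel); the
  # coarse overlap optimum resolves its 180-degree ambiguity
  orient <- function(mask) {
    ix <- which(mask > 0, arr.ind = TRUE)
    x <- ix[, 2]; y <- ix[, 1]
    mu20 <- stats::var(x); mu02 <- stats::var(y)
    mu11 <- stats::cov(x, y)
    list(theta = 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi,
         anisotropy = sqrt((mu20 - mu02)^2 + 4 * mu11^2) / (mu20 + mu02))
  }
  op <- orient(pre_mask); oq <- orient(post_mask)
  if (min(op$anisotropy, oq$anisotropy) > 0.05) {
    cand <- op$theta - oq$theta + c(-180, 0, 180)
    cand <- cand[which.min(abs(cand - th0))]
    if (abs(cand - th0) <= 1.5) return(trans_for(cand))
  }
  # near-isotropic masks: golden-section refinement of the overlap
  lo <- th0 - 1; hi <- th0 + 1
  gr <- (sqrt(5) - 1) / 2
  a <- hi - gr * (hi - lo); b <- lo + gr * (hi - lo)
  fa <- obj(a); fb <- obj(b)
  while (hi - lo > 0.02) {
    if (fa < fb) {
      lo <- a; a <- b; fa <- fb
      b <- lo + gr * (hi - lo); fb <- obj(b)
    } else {
      hi <- b; b <- a; fb <- fa
      a <- hi - gr * (hi - lo); fa <- obj(a)
    }
  }
  trans_for((lo + hi) / 2)
}

# ---- implant positioning error ----------------------------------------------

midpoint <- function(a, b) pt2((a[1] + b[1]) / 2, (a[2] + b[2]) / 2)

#' Positioning error of a templating plan against postoperative markings
#'
#' Compares the planned implant position with implant points marked on a
#' postoperative radiograph after mapping the latter into the preoperative
#' frame with a fitted similarity transform. The comparison uses the
#' midpoint of the medial/lateral (AP views) or anterior/posterior (lateral
#' tibia) insertion points; the lateral femoral component is compared by the
#' offset of the most posterior implant point from the anterior cortical
#' line. Alignment error is the angle between the planned resection line
#' (or cortical line) and the marked implant baseline.
#'
#' @param result A `tka_template` from [template_knee()].
#' @param postop Named list of marked implant points in the postoperative
#'   frame: `ap$femoral` and `ap$tibial` each with `medial` and `lateral`;
#'   `lat$tibial` with `anterior` and `posterior`; `lat$femoral` with
#'   `most_posterior` and optionally `baseline` (two points). Any view or
#'   component may be omitted.
#' @param transform_ap,transform_lat [similarity_transform()]s mapping the
#'   postoperative AP / lateral frames into the preoperative ones (identity
#'   by default).
#' @return Data frame with columns `view`, `component`, `position_error_mm`,
#'   `alignment_error_deg` (NA when no baseline was marked).
#' @export
positioning_error <- function(result, postop,
                              transform_ap = similarity_transform(),
                              transform_lat = similarity_transform()) {
  stopifnot(inherits(result, "tka_template"))
  rows <- list()
  add <- function(view, component, perr, aerr)
    rows[[length(rows) + 1]] <<- data.frame(
      view = view, component = component,
      position_error_mm = perr, alignment_error_deg = aerr,
      stringsAsFactors = FALSE)
  tp <- function(tr, p) { q <- apply_transform(tr, p); pt2(q[1, 1], q[1, 2]) }
  baseline_angle <- function(tr, marked, planned_line) {
    if (is.null(marked)) return(NA_real_)
    a <- tp(tr, marked[[1]]); b <- tp(tr, marked[[2]])
    angle_between_deg(line_through(a, b), planned_line)
  }
  ap <- postop$ap
  if (!is.null(ap$femoral)) {
    if (is.null(ap$femoral$medial) || is.null(ap$femoral$lateral))
      stop("missing marked point(s) for AP femoral component", call. = FALSE)
    pred <- midpoint(result$coronal$femoral_insert_points$medial,
                     result$coronal$femoral_insert_points$lateral)
    obs <- midpoint(tp(transform_ap, ap$femoral$medial),
                    tp(transform_ap, ap$femoral$lateral))
    add("AP", "femoral", vnorm(pred - obs),
        baseline_angle(transform_ap, ap$femoral$baseline,
                       result$coronal$femoral_resection))
  }
  if (!is.null(ap$tibial)) {
    if (is.null(ap$tibial$medial) || is.null(ap$tibial$lateral))
      stop("missing marked point(s) for AP tibial component", call. = FALSE)
    pred <- midpoint(result$coronal$tibial_insert_points$medial,
                     result$coronal$tibial_insert_points$lateral)
    obs <- midpoint(tp(transform_ap, ap$tibial$medial),
                    tp(transform_ap, ap$tibial$lateral))
    add("AP", "tibial", vnorm(pred - obs),
        baseline_angle(transform_ap, ap$tibial$baseline,
                       result$coronal$tibial_resection))
  }
  lat <- postop$lat
  if (!is.null(lat$femoral)) {
    if (is.null(lat$femoral$most_posterior))
      stop("missing marked most_posterior point for lateral femoral component",
           call. = FALSE)
    cort <- result$sagittal$anterior_cortical_line
    d_pred <- abs(signed_distance_to_line(result$sagittal$femoral_posterior_point,
                                          cort))
    d_obs <- abs(signed_distance_to_line(tp(transform_lat, lat$femoral$most_posterior),
                                         cort))
    add("LAT", "femoral", abs(d_pred - d_obs),
        baseline_angle(transform_lat, lat$femoral$baseline, cort))
  }
  if (!is.null(lat$tibial)) {
    if (is.null(lat$tibial$anterior) || is.null(lat$tibial$posterior))
      stop("missing marked point(s) for lateral tibial component", call. = FALSE)
    pred <- midpoint(result$sagittal$tibial_insert_points$anterior,
                     result$sagittal$tibial_insert_points$posterior)
    obs <- midpoint(tp(transform_lat, lat$tibial$anterior),
                    tp(transform_lat, lat$tibial$posterior))
    add("LAT", "tibial", vnorm(pred - obs),
        baseline_angle(transform_lat, lat$tibial$baseline,
                       result$sagittal$tibial_resection))
  }
  if (length(rows) == 0) stop("no marked implant points supplied", call. = FALSE)
  do.call(rbind, rows)
}
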