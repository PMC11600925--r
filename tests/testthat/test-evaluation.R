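test_that("predictions are classified by the exact/accurate taxonomy", {
  expect_equal(classify_prediction(4, 4), "exact")
  expect_equal(classify_prediction(5, 4), "accurate")
  expect_equal(classify_prediction(6, 4), "overestimate")
  expect_equal(classify_prediction(2, 4), "underestimate")
  # every integer difference lands in exactly one category
  deltas <- -6:6
  cls <- classify_prediction(4 + deltas, rep(4, length(deltas)))
  expect_true(all(nzchar(cls)))
  expect_equal(cls[deltas == 0], "exact")
  expect_true(all(cls[abs(deltas) == 1] == "accurate"))
  expect_true(all(cls[deltas >= 2] == "overestimate"))
  expect_true(all(cls[deltas <= -2] == "underestimate"))
})

test_that("agreement summary computes inclusive accurate percentages", {
  # 81 predictions: 32 exact, 40 within one size, 2 over, 7 under
  actual <- rep(4, 81)
  predicted <- c(rep(4, 32), rep(5, 20), rep(3, 20), rep(6, 2), rep(2, 7))
  s <- agreement_summary(predicted, actual)
  expect_equal(s$count[s$category == "exact"], 32L)
  expect_equal(s$count[s$category == "accurate"], 72L)   # inclusive of exact
  expect_equal(round(s$percent[s$category == "exact"], 1), 39.5)
  expect_equal(round(s$percent[s$category == "accurate"], 1), 88.9)
  # categories partition: accurate + over + under = n
  expect_equal(s$count[s$category == "accurate"] +
                 s$count[s$category == "overestimate"] +
                 s$count[s$category == "underestimate"], 81L)
  all_exact <- agreement_summary(rep(3, 10), rep(3, 10))
  expect_equal(all_exact$percent, c(100, 100, 0, 0))
  expect_error(agreement_summary(integer(0), integer(0)), "no records")
})

test_that("quadratic weighted kappa matches the double-sum oracle", {
  # independent brute-force evaluation over an explicit confusion table
  bf_qwk <- function(pred, act, cats) {
    k <- length(cats)
    n <- length(pred)
    num <- 0; den <- 0
    for (i in seq_len(k)) for (j in seq_len(k)) {
      w <- (i - j)^2 / (k - 1)^2
      o <- sum(pred == cats[i] & act == cats[j]) / n
      e <- (sum(pred == cats[i]) / n) * (sum(act == cats[j]) / n)
      num <- num + w * o
      den <- den + w * e
    }
    1 - num / den
  }
  expect_equal(quadratic_weighted_kappa(1:8, 1:8)$kappa, 1.0)
  set.seed(83)
  for (rep in 1:20) {
    cats <- 1:sample(3:8, 1)
    n <- sample(20:60, 1)
    pred <- sample(cats, n, replace = TRUE)
    act <- pmin(max(cats), pmax(1, pred + sample(-2:2, n, replace = TRUE)))
    got <- quadratic_weighted_kappa(pred, act, cats)$kappa
    expect_equal(got, bf_qwk(pred, act, cats), tolerance = 1e-12)
    # exchangeable in record order
    o <- sample(n)
    expect_equal(quadratic_weighted_kappa(pred[o], act[o], cats)$kappa, got,
                 tolerance = 1e-12)
  }
  expect_error(quadratic_weighted_kappa(rep(2, 5), rep(2, 5)), "undefined")
  expect_error(quadratic_weighted_kappa(c(1, 9), c(1, 2), categories = 1:8),
               "outside")
})

test_that("kappa interpretation bands follow the conventional cut points", {
  expect_equal(kappa_interpretation(-0.1), "poor")
  expect_equal(kappa_interpretation(0.1), "slight")
  expect_equal(kappa_interpretation(0.3), "fair")
  expect_equal(kappa_interpretation(0.5), "moderate")
  expect_equal(kappa_interpretation(0.7), "substantial")
  expect_equal(kappa_interpretation(0.9), "almost perfect")
})

test_that("similarity transforms are recovered from points and masks", {
  set.seed(85)
  P <- cbind(stats::runif(6, 20, 80), stats::runif(6, 20, 80))
  # identity
  tid <- fit_similarity_transform(P, P)
  expect_equal(tid$scale, 1, tolerance = 1e-9)
  expect_equal(tid$rotation_deg, 0, tolerance = 1e-9)
  expect_equal(tid$translation, c(0, 0), tolerance = 1e-9)
  # scale + shift, no rotation
  post <- P / 1.2
  post[, 1] <- post[, 1] - 5 / 1.2
  post[, 2] <- post[, 2] + 3 / 1.2
  tr <- fit_similarity_transform(P, post)
  expect_equal(tr$scale, 1.2, tolerance = 0.01)
  expect_equal(tr$rotation_deg, 0, tolerance = 0.1)
  expect_equal(tr$translation, c(5, -3), tolerance = 0.1)
  # rotation via mask alignment: an asymmetric L-shaped bone proxy
  shape <- rbind(c(30, 20), c(90, 20), c(90, 40), c(55, 40), c(55, 110),
                 c(30, 110))
  rasterize <- function(V, w = 140, h = 140)
    kneetemplate:::rasterize_polygon(V, w, h)
  pre_mask <- rasterize(shape)
  th <- 7 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  ctr <- c(60, 60)
  # post frame: the pre shape rotated by -7 deg (so mapping post->pre is +7)
  post_shape <- sweep((sweep(shape, 2, ctr) %*% R), 2, ctr, `+`)
  post_mask <- rasterize(post_shape)
  pre_pts <- shape[c(1, 3, 5), ]
  post_pts <- post_shape[c(1, 3, 5), ]
  tr7 <- fit_similarity_transform(pre_pts, post_pts, pre_mask, post_mask)
  expect_equal(tr7$rotation_deg, 7, tolerance = 0.2)
  expect_equal(tr7$scale, 1, tolerance = 0.01)
  expect_error(fit_similarity_transform(P[1, , drop = FALSE],
                                        P[1, , drop = FALSE]),
               "underdetermined")
})

test_that("positioning error measures midpoint and baseline deviations", {
  tr <- synthetic_knee_truth(seed = 87)
  res <- template_knee(generate_ap_scene(tr)$scene, generate_lat_scene(tr)$scene)
  cor <- res$coronal; sag <- res$sagittal
  postop <- list(
    ap = list(femoral = list(medial = cor$femoral_insert_points$medial,
                             lateral = cor$femoral_insert_points$lateral,
                             baseline = list(cor$femoral_insert_points$medial,
                                             cor$femoral_insert_points$lateral)),
              tibial = list(medial = cor$tibial_insert_points$medial,
                            lateral = cor$tibial_insert_points$lateral)),
    lat = list(femoral = list(most_posterior = sag$femoral_posterior_point),
               tibial = list(anterior = sag$tibial_insert_points$anterior,
                             posterior = sag$tibial_insert_points$posterior)))
  pe <- positioning_error(res, postop)
  expect_equal(nrow(pe), 4)
  expect_equal(pe$position_error_mm, rep(0, 4), tolerance = 1e-9)
  expect_equal(pe$alignment_error_deg[pe$view == "AP" & pe$component == "femoral"],
               0, tolerance = 1e-9)
  # displace the tibial midpoint by 4 mm along the resection line
  d <- cor$tibial_resection$direction
  postop$ap$tibial$medial <- cor$tibial_insert_points$medial + 4 * d
  postop$ap$tibial$lateral <- cor$tibial_insert_points$lateral + 4 * d
  pe2 <- positioning_error(res, postop)
  expect_equal(pe2$position_error_mm[pe2$view == "AP" & pe2$component == "tibial"],
               4, tolerance = 1e-9)
  # rotate the femoral baseline by 2 degrees
  m <- cor$femoral_insert_points$medial; l <- cor$femoral_insert_points$lateral
  ctr <- (m + l) / 2
  th <- 2 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  postop$ap$femoral$baseline <- list(
    pt2((R %*% (m - ctr))[1] + ctr[1], (R %*% (m - ctr))[2] + ctr[2]),
    pt2((R %*% (l - ctr))[1] + ctr[1], (R %*% (l - ctr))[2] + ctr[2]))
  pe3 <- positioning_error(res, postop)
  expect_equal(pe3$alignment_error_deg[pe3$view == "AP" & pe3$component == "femoral"],
               2, tolerance = 1e-6)
  expect_error(positioning_error(res, list(ap = list(femoral = list(medial = pt2(0, 0))))),
               "missing marked")
})
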