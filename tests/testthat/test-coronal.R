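test_that("mechanical axes follow their defining landmarks", {
  sc <- rect_ap_scene()
  fma <- femoral_mechanical_axis(sc)
  expect_equal(unname(fma$direction), c(0, -1))              # distally oriented
  # two-point line through both landmarks
  sc$landmarks$femoral_head_center <- pt2(10, 400)
  sc$landmarks$trochlear_groove <- pt2(0, 0)
  fma2 <- femoral_mechanical_axis(sc)
  expect_lt(abs(kneetemplate:::signed_distance_to_line(pt2(10, 400), fma2)), 1e-9)
  expect_lt(abs(kneetemplate:::signed_distance_to_line(pt2(0, 0), fma2)), 1e-9)
  # swapping the landmarks flips the direction, not the angle
  sc$landmarks$femoral_head_center <- pt2(0, 0)
  sc$landmarks$trochlear_groove <- pt2(10, 400)
  fma3 <- femoral_mechanical_axis(sc)
  expect_equal(unname(fma3$direction), -unname(fma2$direction), tolerance = 1e-12)
  expect_lt(angle_between_deg(fma2, fma3), 1e-5)
})

test_that("tibial mechanical axis uses the plateau midpoint", {
  sc <- rect_ap_scene()
  sc$landmarks$tibial_plateau_medial <- pt2(-35, 0)
  sc$landmarks$tibial_plateau_lateral <- pt2(35, 0)
  sc$landmarks$talar_dome_center <- pt2(0, -350)
  tma <- tibial_mechanical_axis(sc)
  expect_equal(unname(tma$direction), c(0, -1))
  sc$landmarks$tibial_plateau_medial <- pt2(-30, 2)
  sc$landmarks$tibial_plateau_lateral <- pt2(40, -2)
  sc$landmarks$talar_dome_center <- pt2(5, -350)
  tma2 <- tibial_mechanical_axis(sc)
  expect_lt(abs(kneetemplate:::signed_distance_to_line(pt2(5, 0), tma2)), 1e-9)
  expect_lt(abs(kneetemplate:::signed_distance_to_line(pt2(5, -350), tma2)), 1e-9)
  # invariant to swapping the medial/lateral labels
  tmp <- sc$landmarks$tibial_plateau_medial
  sc$landmarks$tibial_plateau_medial <- sc$landmarks$tibial_plateau_lateral
  sc$landmarks$tibial_plateau_lateral <- tmp
  tma3 <- tibial_mechanical_axis(sc)
  expect_equal(unname(tma3$origin), unname(tma2$origin), tolerance = 1e-12)
  expect_equal(unname(tma3$direction), unname(tma2$direction), tolerance = 1e-12)
})

test_that("femoral coronal sizing measures the rectangle width at 9 mm", {
  sc <- rect_ap_scene(femur_w = 60)
  fma <- femoral_mechanical_axis(sc)
  out <- femoral_coronal_sizing(sc, fma, resection_mm = 9)
  expect_equal(out$ml_width_mm, 60, tolerance = 1e-9)
  expect_equal(unname(out$insert_medial[2]), 19, tolerance = 1e-9)  # 10 + 9
  expect_equal(unname(out$insert_lateral[2]), 19, tolerance = 1e-9)
  # resection perpendicular to the axis
  expect_equal(angle_between_deg(out$resection, fma), 90, tolerance = 1e-9)
  # joint rigid rotation leaves the width unchanged
  sc10 <- rigid_scene(sc, angle_deg = 10, translation = c(7, -3))
  out10 <- femoral_coronal_sizing(sc10, femoral_mechanical_axis(sc10), 9)
  expect_equal(out10$ml_width_mm, 60, tolerance = 1e-6)
})

test_that("condylar contour width matches the generator's analytic chord", {
  tr <- synthetic_knee_truth(seed = 31, femoral_size = 6)
  ap <- generate_ap_scene(tr)
  plan <- coronal_template(ap$scene)
  expect_equal(plan$femoral_ml_width_mm, ap$oracle$femoral_ml_mm,
               tolerance = 1e-6)
  expect_equal(plan$tibial_ml_width_mm, ap$oracle$tibial_ml_mm,
               tolerance = 1e-6)
})

test_that("symmetric plateau needs no adjustment and keeps MPTA at 90", {
  sc <- rect_ap_scene()
  tma <- tibial_mechanical_axis(sc)
  out <- tibial_coronal_sizing(sc, tma)
  expect_equal(out$depth_medial_mm, out$depth_lateral_mm, tolerance = 1e-9)
  expect_false(out$adjusted)
  expect_identical(out$mpta_deg, 90)   # exact when untriggered
})

test_that("9 mm medial attrition triggers the 2 degree MPTA adjustment", {
  tr <- synthetic_knee_truth(seed = 33, medial_attrition_mm = 9)
  ap <- generate_ap_scene(tr)
  plan <- coronal_template(ap$scene)
  expect_true(plan$mpta_adjusted)
  expect_equal(plan$lesser_side_depth_pre_mm, 1, tolerance = 1e-6)
  expect_equal(plan$mpta_deg, 88, tolerance = 1e-6)
  # tilt of the cut relative to the perpendicular of the mechanical axis
  perp <- perpendicular_line_at(plan$tma, 0)
  expect_equal(angle_between_deg(plan$tibial_resection, perp), 2,
               tolerance = 1e-6)
  # adjustment deepened the lesser (medial) side
  expect_gt(plan$lesser_side_depth_mm, plan$lesser_side_depth_pre_mm)
  expect_identical(plan$lesser_side, "medial")
})

test_that("coronal_template recovers the deformity and is self-consistent", {
  tr0 <- synthetic_knee_truth(seed = 35, hka_deg = 0)
  plan0 <- coronal_template(generate_ap_scene(tr0)$scene)
  expect_lt(abs(plan0$hka_deg), 0.1)
  expect_false(plan0$mpta_adjusted)
  tr8 <- synthetic_knee_truth(seed = 36, hka_deg = 8)
  plan8 <- coronal_template(generate_ap_scene(tr8)$scene)
  expect_equal(plan8$hka_deg, 8, tolerance = 0.2)
  # valgus: negative sign
  trv <- synthetic_knee_truth(seed = 37, hka_deg = -6)
  expect_equal(coronal_template(generate_ap_scene(trv)$scene)$hka_deg, -6,
               tolerance = 0.2)
  # left knees report the same signed deformity
  trl <- synthetic_knee_truth(seed = 38, side = "left", hka_deg = 8)
  expect_equal(coronal_template(generate_ap_scene(trl)$scene)$hka_deg, 8,
               tolerance = 0.2)
  # insert points lie on their resection lines
  for (plan in list(plan0, plan8)) {
    expect_lt(abs(kneetemplate:::signed_distance_to_line(
      plan$femoral_insert_points$medial, plan$femoral_resection)), 1e-6)
    expect_lt(abs(kneetemplate:::signed_distance_to_line(
      plan$femoral_insert_points$lateral, plan$femoral_resection)), 1e-6)
    expect_lt(abs(kneetemplate:::signed_distance_to_line(
      plan$tibial_insert_points$medial, plan$tibial_resection)), 1e-6)
    expect_lt(abs(kneetemplate:::signed_distance_to_line(
      plan$tibial_insert_points$lateral, plan$tibial_resection)), 1e-6)
  }
})

test_that("coronal measurements are invariant under global rigid motion", {
  tr <- synthetic_knee_truth(seed = 39, hka_deg = 7, medial_attrition_mm = 5)
  sc <- generate_ap_scene(tr)$scene
  p0 <- coronal_template(sc)
  p1 <- coronal_template(rigid_scene(sc, angle_deg = 23, translation = c(-40, 65)))
  expect_equal(p1$femoral_ml_width_mm, p0$femoral_ml_width_mm, tolerance = 1e-6)
  expect_equal(p1$tibial_ml_width_mm, p0$tibial_ml_width_mm, tolerance = 1e-6)
  expect_equal(p1$hka_deg, p0$hka_deg, tolerance = 1e-9)
  expect_equal(p1$mpta_deg, p0$mpta_deg, tolerance = 1e-9)
})

test_that("coronal errors carry stage context", {
  sc <- rect_ap_scene()
  sc$landmarks$trochlear_groove <- sc$landmarks$femoral_head_center
  expect_error(coronal_template(sc), "femoral mechanical axis")
  sc2 <- rect_ap_scene()
  sc2$view <- "LAT"
  expect_error(coronal_template(sc2), "AP")
})
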