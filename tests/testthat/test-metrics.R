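test_that("landmark distances convert mm offsets to cm per landmark", {
  lm <- landmark_set(c(0, 0, 80), c(0, 0, 0), c(30, 0, 10))
  expect_equal(unname(landmark_distances(lm, lm)), c(0, 0, 0))

  shifted <- transform_landmarks(rigid_transform(diag(3), c(10, 0, 0)), lm)
  expect_equal(unname(landmark_distances(lm, shifted)), c(1, 1, 1))

  apex_off <- landmark_set(c(3, 4, 80), c(0, 0, 0), c(30, 0, 10))
  d <- landmark_distances(lm, apex_off)
  expect_equal(unname(d), c(0.5, 0, 0))   # 3-4-5 triangle
})

test_that("long-axis angle reproduces constructed tilts and the arccos formula", {
  lm <- landmark_set(c(0, 0, 80), c(0, 0, 0), c(30, 0, 10))
  expect_equal(long_axis_angle(lm, lm), 0)
  tilt <- rotation_about_axis(c(1, 0, 0), 10)
  tilted <- landmark_set(drop(tilt %*% lm$apex), lm$mitral_center, lm$outflow_tract)
  expect_equal(long_axis_angle(lm, tilted), 10, tolerance = 1e-9)
  set.seed(111)
  for (i in 1:5) {
    a <- random_landmarks(3); b <- random_landmarks(3)
    u <- a$apex - a$mitral_center; v <- b$apex - b$mitral_center
    expected <- acos(sum(u * v) / (vnorm_test(u) * vnorm_test(v))) * 180 / pi
    expect_equal(long_axis_angle(a, b), expected, tolerance = 1e-9)
  }
})

test_that("transverse-plane angle measures rotation about the shared long axis", {
  lm <- landmark_set(c(0, 0, -80), c(0, 0, 0), c(25, 0, 0))
  expect_equal(transverse_plane_angle(lm, lm), 0)
  spin <- rigid_transform(rotation_about_axis(c(0, 0, 1), 90))
  spun <- transform_landmarks(spin, lm)
  expect_equal(transverse_plane_angle(lm, spun), 90, tolerance = 1e-9)
  # independent evaluation of the stated construction on a generic pair
  set.seed(121)
  for (i in 1:5) {
    a <- random_landmarks(3); b <- random_landmarks(3)
    u1 <- (a$apex - a$mitral_center); u1 <- u1 / vnorm_test(u1)
    u2 <- (b$apex - b$mitral_center); u2 <- u2 / vnorm_test(u2)
    d <- (u1 + u2) / vnorm_test(u1 + u2)
    anchor <- (a$mitral_center + b$mitral_center) / 2
    pu <- a$outflow_tract - anchor; pu <- pu - sum(pu * d) * d
    pv <- b$outflow_tract - anchor; pv <- pv - sum(pv * d) * d
    expected <- acos(max(-1, min(1, sum(pu * pv) / (vnorm_test(pu) * vnorm_test(pv))))) * 180 / pi
    expect_equal(transverse_plane_angle(a, b), expected, tolerance = 1e-9)
  }
  on_axis <- landmark_set(c(0, 0, -80), c(0, 0, 0), c(0, 0, 40))
  expect_error(transverse_plane_angle(lm, on_axis), class = "lvfuse_degenerate_error")
})

test_that("mean point-to-surface distance handles identical, offset-plate and phantom cases", {
  lv <- generate_lv_surface()
  expect_lt(mean_point_to_surface_distance(lv$surface, lv$surface), 1e-12)

  plate <- make_plate(half = 50, n = 11L)
  inner <- plate$vertices[abs(plate$vertices[, 1]) <= 30 &
                            abs(plate$vertices[, 2]) <= 30, , drop = FALSE]
  lifted <- inner + matrix(c(0, 0, 2), nrow(inner), 3, byrow = TRUE)
  expect_equal(mean_point_to_surface_distance(lifted, plate), 0.2, tolerance = 1e-12)

  pair <- make_phantom_pair(phantom_params(seed = 23, noise_sd = 1))
  moved <- transform_surface(pair$ground_truth, pair$echo$surface)
  got <- mean_point_to_surface_distance(moved, pair$ccta$surface)
  ora <- exhaustive_closest(moved$vertices, pair$ccta$surface, "triangle")
  expect_equal(got, mean(ora[, 2]) / 10, tolerance = 1e-9)
})

test_that("evaluate_registration is exact for perfect registrations", {
  pair <- make_phantom_pair(phantom_params(seed = 29))
  same <- evaluate_registration(pair$ccta, pair$ccta, identity_transform())
  expect_equal(unname(unlist(unclass(same))), c(0, 0, 0, 0, 0, 0, 1),
               tolerance = 1e-9)
  rep <- evaluate_registration(pair$ccta, pair$echo, pair$ground_truth)
  expect_lt(rep$apex_distance, 1e-6)
  expect_lt(rep$mitral_center_distance, 1e-6)
  expect_lt(rep$aortic_center_distance, 1e-6)
  expect_lt(rep$long_axis_angle, 1e-6)
  expect_lt(rep$transverse_plane_angle, 1e-6)
  expect_lt(rep$mean_point_to_point_distance, 1e-6)
  expect_gt(rep$three_chamber_dice, 0.999)
})

test_that("quality metrics are invariant under a common rigid motion", {
  pair <- make_phantom_pair(phantom_params(seed = 31, subdivision_level = 2,
                                           noise_sd = 1, landmark_jitter_sd = 2,
                                           shape_mismatch = c(0.9, 1.05, 1)))
  tr <- three_chamber_align(pair$echo$landmarks, pair$ccta$landmarks)
  rep1 <- evaluate_registration(pair$ccta, pair$echo, tr)
  set.seed(131)
  g <- random_rigid_transform(90, 50)
  ccta_g <- transform_dataset(g, pair$ccta)
  echo_g <- transform_dataset(g, pair$echo)
  tr_g <- compose_transforms(g, compose_transforms(tr, invert_transform(g)))
  rep2 <- evaluate_registration(ccta_g, echo_g, tr_g)
  expect_equal(unlist(unclass(rep1)), unlist(unclass(rep2)), tolerance = 1e-6)
})

test_that("observer variability reports distances and angles of repeated segmentations", {
  lm <- landmark_set(c(0, 0, -80), c(0, 0, 0), c(25, 0, 0))
  tr <- random_rigid_transform(30, 20)
  same <- observer_variability(tr, tr, lm, lm, c(0, 0, 0), c(0, 0, -80))
  expect_equal(unname(unlist(unclass(same))), rep(0, 5))

  lm2 <- landmark_set(lm$apex + c(8, 0, 0), lm$mitral_center, lm$outflow_tract)
  rep <- observer_variability(identity_transform(), identity_transform(),
                              lm, lm2, c(0, 0, 0), c(0, 0, -80))
  expect_equal(rep$apex_distance, 0.8)
  expect_equal(rep$mitral_center_distance, 0)
  expect_equal(rep$outflow_center_distance, 0)
  expect_equal(rep$transverse_plane_angle, 0)

  # random repeated-segmentation pair vs direct evaluation of the formulas
  set.seed(141)
  for (i in 1:5) {
    t1 <- random_rigid_transform(40, 25); t2 <- random_rigid_transform(40, 25)
    l1 <- random_landmarks(2); l2 <- random_landmarks(2)
    ref_m <- c(1, -2, 0); ref_a <- c(3, 1, -78)
    got <- observer_variability(t1, t2, l1, l2, ref_m, ref_a)
    a1 <- transform_landmarks(t1, l1); a2 <- transform_landmarks(t2, l2)
    expect_equal(got$apex_distance, vnorm_test(a1$apex - a2$apex) / 10)
    expect_equal(got$outflow_center_distance,
                 vnorm_test(a1$outflow_tract - a2$outflow_tract) / 10)
    expect_equal(got$long_axis_angle,
                 angle_between(a1$apex - a1$mitral_center, a2$apex - a2$mitral_center))
    d <- (ref_a - ref_m) / vnorm_test(ref_a - ref_m)
    pu <- a1$outflow_tract - ref_m; pu <- pu - sum(pu * d) * d
    pv <- a2$outflow_tract - ref_m; pv <- pv - sum(pv * d) * d
    expect_equal(got$transverse_plane_angle, angle_between(pu, pv), tolerance = 1e-9)
  }
})
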