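test_that("procrustes_align recovers exact rigid correspondences", {
  lm <- landmark_set(c(0, 0, 80), c(0, 0, 0), c(30, 0, 10))
  idt <- procrustes_align(lm, lm)
  expect_lt(max(abs(idt$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(idt$translation)), 1e-12)

  shifted <- transform_landmarks(rigid_transform(diag(3), c(10, 0, 0)), lm)
  tr <- procrustes_align(lm, shifted)
  expect_lt(max(abs(tr$rotation - diag(3))), 1e-12)
  expect_equal(tr$translation, c(10, 0, 0), tolerance = 1e-12)

  g <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(4, -7, 2))
  tr2 <- procrustes_align(lm, transform_landmarks(g, lm))
  d <- transform_difference(tr2, g)
  expect_lt(d$rotation_deg, 1e-9)
  expect_lt(d$translation_mm, 1e-9)
  moved <- transform_landmarks(tr2, lm)
  expect_lt(max(abs(landmark_matrix(moved) - landmark_matrix(transform_landmarks(g, lm)))),
            1e-9)
})

test_that("procrustes_align matches Horn's quaternion solution on noisy pairs", {
  set.seed(61)
  for (i in 1:10) {
    src <- random_landmarks(jitter = 2)
    dst <- transform_landmarks(random_rigid_transform(90, 40),
                               random_landmarks(jitter = 2))
    tr <- procrustes_align(src, dst)
    horn <- horn_quaternion_fit(landmark_matrix(src), landmark_matrix(dst))
    expect_lt(max(abs(tr$rotation - horn$rotation)), 1e-8)
    expect_lt(max(abs(tr$translation - horn$translation)), 1e-7)
  }
})

test_that("procrustes_align beats reflections properly and matches the grid oracle", {
  lm <- landmark_set(c(5, 3, 78), c(1, -2, 0), c(28, 4, 9))
  mirrored <- landmark_matrix(lm) %*% diag(c(-1, 1, 1))
  dst <- landmark_set(mirrored[1, ], mirrored[2, ], mirrored[3, ])
  tr <- procrustes_align(lm, dst)
  expect_gt(det(tr$rotation), 0)
  ours <- centered_objective(tr$rotation, landmark_matrix(lm), landmark_matrix(dst))
  set.seed(71)
  oracle <- grid_procrustes_objective(landmark_matrix(lm), landmark_matrix(dst))
  expect_lte(ours, oracle + 1e-9)
  # three landmarks are coplanar, so their mirror image is exactly reachable
  # by a proper rotation: both objectives must be (near) zero
  expect_lt(abs(ours - oracle), 0.01 * oracle + 1e-3)
  expect_lt(ours, 1e-9)

  set.seed(72)
  for (i in 1:5) {
    src <- random_landmarks(jitter = 4)
    dst <- transform_landmarks(random_rigid_transform(90, 40),
                               random_landmarks(jitter = 4))
    tr <- procrustes_align(src, dst)
    ours <- centered_objective(tr$rotation, landmark_matrix(src), landmark_matrix(dst))
    oracle <- grid_procrustes_objective(landmark_matrix(src), landmark_matrix(dst))
    expect_lte(ours, oracle + 1e-9)
    expect_lt(abs(ours - oracle), 0.01 * oracle)
  }
})

test_that("collinear landmark sets are rejected by procrustes_align", {
  collinear <- landmark_set(c(0, 0, 80), c(0, 0, 0), c(0, 0, 40.5))
  ok <- landmark_set(c(0, 0, 80), c(0, 0, 0), c(30, 0, 10))
  expect_error(procrustes_align(collinear, ok), class = "lvfuse_degenerate_error")
})

test_that("closest_point_pairs equals exhaustive search in both modes", {
  lv <- generate_lv_surface()
  set.seed(81)
  q <- matrix(rnorm(150, sd = 35), 50, 3)
  q[1, ] <- lv$surface$vertices[100, ]   # exactly on a vertex
  for (mode in c("vertex", "triangle")) {
    res <- closest_point_pairs(q, lv$surface, mode = mode)
    ora <- exhaustive_closest(q, lv$surface, mode)
    expect_equal(res$distance, ora[, 2], tolerance = 1e-9)
    if (mode == "vertex") expect_equal(res$index, as.integer(ora[, 1]))
  }
  resv <- closest_point_pairs(q[1, , drop = FALSE], lv$surface, "vertex")
  expect_equal(resv$index, 100L)
  expect_equal(resv$distance, 0)
})

test_that("closest point above a flat plate lands at its foot point", {
  plate <- make_plate(half = 50, n = 11L)
  res <- closest_point_pairs(matrix(c(3.2, -7.7, 6), 1, 3), plate, "triangle")
  expect_equal(res$distance, 6, tolerance = 1e-12)
  expect_equal(drop(res$closest), c(3.2, -7.7, 0), tolerance = 1e-12)
})

test_that("icp_align is exact on identical surfaces and recovers a known transform", {
  pair <- make_phantom_pair(phantom_params(seed = 5))
  same <- icp_align(pair$ccta$surface, pair$ccta$surface,
                    pair$ccta$landmarks, pair$ccta$landmarks)
  expect_equal(same$trace$iterations_run, 1L)
  expect_true(same$trace$converged)
  expect_lt(same$trace$objective[1], 1e-9)
  expect_lt(transform_difference(same$transform, identity_transform())$rotation_deg, 1e-9)

  res <- icp_align(pair$echo$surface, pair$ccta$surface,
                   pair$echo$landmarks, pair$ccta$landmarks)
  d <- transform_difference(res$transform, pair$ground_truth)
  expect_lt(d$rotation_deg, 0.01)
  expect_lt(d$translation_mm, 1e-3)
  expect_lt(tail(res$trace$objective, 1), 1e-6)
  expect_true(res$trace$converged)
  # the ground-truth transform cannot beat the returned fit on the final pairs
  moved <- apply_transform(res$transform, pair$echo$surface$vertices)
  obj_fit <- mean(closest_point_pairs(moved, pair$ccta$surface, "vertex")$distance^2)
  moved_gt <- apply_transform(pair$ground_truth, pair$echo$surface$vertices)
  obj_gt <- mean(closest_point_pairs(moved_gt, pair$ccta$surface, "vertex")$distance^2)
  expect_lte(obj_fit, obj_gt + 1e-9)
})

test_that("icp trace is non-increasing and non-convergence is flagged, not an error", {
  pair <- make_phantom_pair(phantom_params(seed = 9, subdivision_level = 2,
                                           noise_sd = 2, shape_mismatch = c(0.9, 1.1, 1)))
  res <- icp_align(pair$echo$surface, pair$ccta$surface,
                   pair$echo$landmarks, pair$ccta$landmarks)
  trace <- c(res$trace$initial_objective, res$trace$objective)
  expect_true(all(diff(trace) <= 1e-9))

  hard <- icp_align(pair$echo$surface, pair$ccta$surface,
                    pair$echo$landmarks, pair$ccta$landmarks,
                    icp_params(max_iterations = 1, convergence_tol = 1e-12))
  expect_false(hard$trace$converged)
  expect_equal(hard$trace$iterations_run, 1L)
})

test_that("icp triangle correspondence mode also recovers exact copies", {
  pair <- make_phantom_pair(phantom_params(seed = 13, subdivision_level = 2))
  res <- icp_align(pair$echo$surface, pair$ccta$surface,
                   pair$echo$landmarks, pair$ccta$landmarks,
                   icp_params(correspondence_mode = "triangle"))
  d <- transform_difference(res$transform, pair$ground_truth)
  expect_lt(d$rotation_deg, 0.01)
  expect_lt(d$translation_mm, 1e-3)
})

test_that("three_chamber_align is exact for rigid copies and satisfies its constraints", {
  lm <- landmark_set(c(0, 0, 80), c(0, 0, 0), c(30, 0, 10))
  idt <- three_chamber_align(lm, lm)
  expect_lt(max(abs(idt$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(idt$translation)), 1e-12)

  g <- random_rigid_transform(45, 30)
  moved <- transform_landmarks(g, lm)
  back <- three_chamber_align(moved, lm)
  d <- transform_difference(back, invert_transform(g))
  expect_lt(d$rotation_deg, 1e-9)
  expect_lt(d$translation_mm, 1e-9)
})

test_that("three_chamber_align under shape mismatch keeps its three constraints", {
  dst <- landmark_set(c(0, 0, 80), c(0, 0, 0), c(30, 0, 10))
  # apex 5 mm farther from the mitral center along the shared axis
  src0 <- landmark_set(c(0, 0, 85), c(0, 0, 0), c(30, 0, 10))
  g <- random_rigid_transform(60, 40)
  src <- transform_landmarks(g, src0)
  tr <- three_chamber_align(src, dst)
  reg <- transform_landmarks(tr, src)
  expect_lt(vnorm_test(reg$mitral_center - dst$mitral_center), 1e-9)
  expect_lt(long_axis_angle(dst, reg), 1e-9)
  expect_equal(landmark_distances(dst, reg)[["apex_distance"]], 0.5,
               tolerance = 1e-9)
  # coplanarity: all six landmarks in the destination three-chamber plane
  fr <- build_frame(dst)
  offs <- abs((landmark_matrix(reg) - matrix(fr$origin, 3, 3, byrow = TRUE)) %*%
                fr$plane_normal)
  expect_lt(max(offs), 1e-9)
  expect_gt(sum((reg$outflow_tract - fr$origin) * fr$in_plane), 0)
})

test_that("all three methods are rigid-motion equivariant", {
  pair <- make_phantom_pair(phantom_params(seed = 17, subdivision_level = 2,
                                           noise_sd = 1, landmark_jitter_sd = 2))
  set.seed(91)
  g <- random_rigid_transform(90, 50)
  ginv <- invert_transform(g)
  pre_lm <- transform_landmarks(g, pair$echo$landmarks)
  pre_surf <- transform_surface(g, pair$echo$surface)

  base_p <- procrustes_align(pair$echo$landmarks, pair$ccta$landmarks)
  pre_p <- procrustes_align(pre_lm, pair$ccta$landmarks)
  d <- transform_difference(pre_p, compose_transforms(base_p, ginv))
  expect_lt(d$rotation_deg, 1e-6); expect_lt(d$translation_mm, 1e-6)

  base_3 <- three_chamber_align(pair$echo$landmarks, pair$ccta$landmarks)
  pre_3 <- three_chamber_align(pre_lm, pair$ccta$landmarks)
  d <- transform_difference(pre_3, compose_transforms(base_3, ginv))
  expect_lt(d$rotation_deg, 1e-6); expect_lt(d$translation_mm, 1e-6)

  base_i <- icp_align(pair$echo$surface, pair$ccta$surface,
                      pair$echo$landmarks, pair$ccta$landmarks)
  pre_i <- icp_align(pre_surf, pair$ccta$surface, pre_lm, pair$ccta$landmarks)
  d <- transform_difference(pre_i$transform, compose_transforms(base_i$transform, ginv))
  expect_lt(d$rotation_deg, 1e-6); expect_lt(d$translation_mm, 1e-6)
})

test_that("procrustes and three-chamber agree on identical landmark geometry", {
  set.seed(101)
  for (i in 1:5) {
    lm <- random_landmarks(jitter = 3)
    g <- random_rigid_transform(90, 40)
    moved <- transform_landmarks(g, lm)
    tp <- procrustes_align(lm, moved)
    t3 <- three_chamber_align(lm, moved)
    expect_lt(max(abs(tp$rotation - t3$rotation)), 1e-9)
    expect_lt(max(abs(tp$translation - t3$translation)), 1e-9)
  }
})
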