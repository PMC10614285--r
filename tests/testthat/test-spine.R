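test_that("segment angles match the independent endplate-vector oracle", {
  tp <- template_spine()
  for (seg in c("lumbar_lordosis", "thoracic_kyphosis", "cervical_lordosis"))
    expect_equal(segment_angle(tp, seg), oracle_segment_angle(tp, seg),
                 tolerance = 1e-12)
  # an arbitrarily deformed fixture
  sp <- rotate_about_joint(tp, "T8-T9", -7.3)
  sp <- rotate_about_joint(sp, "L2-L3", 4.1)
  sp <- rigid_rotate_to_distance(sp, -80)
  for (seg in c("lumbar_lordosis", "thoracic_kyphosis", "cervical_lordosis"))
    expect_equal(segment_angle(sp, seg), oracle_segment_angle(sp, seg),
                 tolerance = 1e-9)
})

test_that("parallel endplates give zero angle and a rigid 10 deg offset reads as 10 deg", {
  tp <- align_segment(template_spine(), "lumbar_lordosis", 0, tol = 1e-9)
  expect_lt(abs(segment_angle(tp, "lumbar_lordosis")), 1e-9)
  vu <- kinesens:::endplate_vector(tp, "L1", "superior")
  vl <- kinesens:::endplate_vector(tp, "L5", "inferior")
  expect_lt(abs(vu[1] * vl[2] - vu[2] * vl[1]) /
              sqrt(sum(vu^2) * sum(vl^2)), 1e-10)  # parallel
  # rotating the topmost lumbar joint rigidly carries L1 with it
  sp <- rotate_about_joint(tp, "L1-L2", 10)
  expect_equal(segment_angle(sp, "lumbar_lordosis"), 10, tolerance = 1e-9)
})

test_that("joint rotations are rigid, invertible and leave the lower spine untouched", {
  tp <- template_spine()
  expect_identical(rotate_about_joint(tp, "L1-L2", 0)$landmarks, tp$landmarks)
  back <- rotate_about_joint(rotate_about_joint(tp, "L1-L2", 2), "L1-L2", -2)
  expect_lt(max(abs(landmark_matrix(back) - landmark_matrix(tp))), 1e-9)
  rot <- rotate_about_joint(tp, "C7-T1", 5)
  below <- tp$landmarks$level %in% c("S1", paste0("L", 5:1), paste0("T", 12:1))
  expect_identical(rot$landmarks[below, ], tp$landmarks[below, ])
  # radius from the pivot and all pairwise distances among moved landmarks
  pv <- kinesens:::spine_point(tp, "C7", "pivot")
  r0 <- sqrt(sum((kinesens:::spine_point(tp, "C2", "meas") - pv)^2))
  r1 <- sqrt(sum((kinesens:::spine_point(rot, "C2", "meas") - pv)^2))
  expect_lt(abs(r1 - r0), 1e-9)
  d0 <- dist(landmark_matrix(tp)[!below, ])
  d1 <- dist(landmark_matrix(rot)[!below, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
  expect_error(rotate_about_joint(tp, "L9-L10", 1), "unknown joint")
})

test_that("alignment sweeps divide the residual equally over the segment's joints", {
  tp <- template_spine()
  cur <- segment_angle(tp, "lumbar_lordosis")
  al <- align_segment(tp, "lumbar_lordosis", cur + 8)
  sweeps <- attr(al, "sweeps")
  expect_equal(sweeps$per_joint_rotation_deg[1], 2)  # 8 deg over 4 joints
  expect_lt(abs(segment_angle(al, "lumbar_lordosis") - (cur + 8)), 0.01)

  cur_c <- segment_angle(tp, "cervical_lordosis")
  al_c <- align_segment(tp, "cervical_lordosis", cur_c + 12)
  expect_equal(attr(al_c, "sweeps")$per_joint_rotation_deg[1], 2.4)  # 5 joints
  expect_lt(abs(segment_angle(al_c, "cervical_lordosis") - (cur_c + 12)), 0.01)
  expect_equal(oracle_segment_angle(al_c, "cervical_lordosis"), cur_c + 12,
               tolerance = 1e-6)

  same <- align_segment(tp, "thoracic_kyphosis",
                        segment_angle(tp, "thoracic_kyphosis"))
  expect_identical(same$landmarks, tp$landmarks)
  expect_equal(nrow(attr(same, "sweeps")), 0L)
})

test_that("rigid sacrum rotation hits the target offset with minimal rotation", {
  tp <- template_spine()
  m0 <- measure_spine(tp)
  same <- rigid_rotate_to_distance(tp, m0$c7_sacrum_dx_mm)
  expect_lt(max(abs(landmark_matrix(same) - landmark_matrix(tp))), 1e-9)
  # closed-form check: ask for the offset a -10 deg whole-spine rotation gives
  s1 <- kinesens:::spine_point(tp, "S1", "meas")
  c7 <- kinesens:::spine_point(tp, "C7", "meas") - s1
  g <- -10 * pi / 180
  target <- c7[1] * cos(g) - c7[2] * sin(g)
  rot <- rigid_rotate_to_distance(tp, target)
  m1 <- measure_spine(rot)
  expect_equal(m1$c7_sacrum_dx_mm, target, tolerance = 1e-6)
  # sacrum node fixed, rigid everywhere
  expect_equal(kinesens:::spine_point(rot, "S1", "meas"), s1)
  expect_lt(max(abs(dist(landmark_matrix(rot)) - dist(landmark_matrix(tp)))),
            1e-8)
  r <- sqrt(sum(c7^2))
  expect_error(rigid_rotate_to_distance(tp, r + 1), "exceeds")
})

test_that("full alignment meets all four targets and the stages do not disturb each other", {
  tp <- template_spine()
  m0 <- measure_spine(tp)
  self <- align_spine(tp, m0)
  expect_lt(max(abs(landmark_matrix(self) - landmark_matrix(tp))), 1e-6)

  pop <- fx_population()
  for (i in c(1, 9, 23, 36)) {
    m <- measure_spine(fx_spines()[[i]])
    expect_lt(abs(m$lumbar_lordosis_deg - pop$lumbar_lordosis_deg[i]), 0.01)
    expect_lt(abs(m$thoracic_kyphosis_deg - pop$thoracic_kyphosis_deg[i]), 0.01)
    expect_lt(abs(m$cervical_lordosis_deg - pop$cervical_lordosis_deg[i]), 0.01)
    expect_lt(abs(m$c7_sacrum_dx_mm - pop$c7_sacrum_dx_mm[i]), 1e-6)
  }

  # changing only the lumbar target leaves the other segment angles intact
  m1 <- m0; m1$lumbar_lordosis_deg <- m0$lumbar_lordosis_deg + 5
  al <- align_spine(tp, m1)
  expect_lt(abs(segment_angle(al, "thoracic_kyphosis") -
                m0$thoracic_kyphosis_deg), 0.02)
  expect_lt(abs(segment_angle(al, "cervical_lordosis") -
                m0$cervical_lordosis_deg), 0.02)
})

test_that("spine CSV round-trips and measurement validation rejects bad input", {
  tp <- template_spine()
  f <- withr::local_tempfile(fileext = ".csv")
  write_spine_csv(tp, f)
  rt <- read_spine_csv(f)
  expect_lt(max(abs(landmark_matrix(rt) - landmark_matrix(tp))), 1e-6)
  expect_error(spine_measurements(95, 20, 1, 0), "degrees")
  expect_error(spine_measurements(1, 20, 1, Inf), "finite")
})
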