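test_that("the canonical five-segment hierarchy validates with correct ranks", {
  m <- sloth_marionette()
  expect_s3_class(m, "marionette")
  expect_equal(m$root, "global")
  expect_equal(unname(m$rank["thoracic_vertebra_1"]), 1L)
  expect_equal(unname(m$rank["scapula"]), 2L)
  expect_equal(unname(m$rank["clavicle"]), 2L)
  expect_equal(unname(m$rank["humerus"]), 3L)
})

test_that("malformed hierarchies are rejected with the offending name", {
  expect_s3_class(build_marionette(list(segment_spec("global"))), "marionette")
  expect_error(build_marionette(list(
    segment_spec("global"),
    segment_spec("scapula", "humerus"),
    segment_spec("humerus", "scapula"))), "cycle")
  expect_error(build_marionette(list(
    segment_spec("global"), segment_spec("scapula", "thorax"))), "thorax")
  expect_error(build_marionette(list(
    segment_spec("global"), segment_spec("a", "global"),
    segment_spec("a", "global"))), "duplicate")
  expect_error(build_marionette(list(segment_spec("a", "b"),
                                     segment_spec("b", "a"))), "root")
})

test_that("zero poses reproduce the axis-aligned zero configuration", {
  m <- sloth_marionette()
  poses <- lapply(setdiff(names(m$segments), "global"), function(x) pose6dof())
  names(poses) <- setdiff(names(m$segments), "global")
  w <- forward_kinematics(m, poses)
  for (nm in names(w)) expect_equal(w[[nm]]$R, diag(3))
  # origins accumulate down the chain
  expect_equal(w$humerus$t, m$segments$scapula$origin +
                 m$segments$humerus$origin)
})

test_that("a translation of the vertebra shifts every descendant rigidly", {
  m <- sloth_marionette()
  nms <- setdiff(names(m$segments), "global")
  zero <- stats::setNames(lapply(nms, function(x) pose6dof()), nms)
  shifted <- zero
  shifted$thoracic_vertebra_1 <- pose6dof(tx = 1)
  w0 <- forward_kinematics(m, zero)
  w1 <- forward_kinematics(m, shifted)
  for (nm in nms)
    expect_equal(w1[[nm]]$t - w0[[nm]]$t, c(1, 0, 0))
})

test_that("forward kinematics matches the homogeneous-matrix oracle", {
  m <- sloth_marionette()
  nms <- setdiff(names(m$segments), "global")
  set.seed(201)
  for (i in 1:50) {
    poses <- stats::setNames(lapply(nms, function(x) {
      a <- rand_angles(1)
      pose6dof(stats::runif(1, -5, 5), stats::runif(1, -5, 5),
               stats::runif(1, -5, 5), a[1], a[2], a[3])
    }), nms)
    w <- forward_kinematics(m, poses)
    for (nm in nms) {
      H <- fk_oracle(m, poses, nm)
      expect_lt(max(abs(as_h4(w[[nm]]) - H)), 1e-9)
    }
  }
  expect_error(forward_kinematics(m, list(scapula = pose6dof())), "missing pose")
})

test_that("landmark trajectories behave under trivial references", {
  m <- sloth_marionette()
  set.seed(202)
  vals <- cbind(matrix(stats::runif(30, -2, 2), 10),
                matrix(stats::runif(30, -40, 40), 10))
  ser <- one_segment_series(vals, "humerus")
  # reference = carrying segment: constant local coordinates
  traj <- landmark_trajectory(m, ser, "elbow", reference = "humerus")
  expect_equal(traj, matrix(rep(m$segments$humerus$landmarks$elbow, each = 10),
                            10, dimnames = list(NULL, c("x", "y", "z"))))
  # frozen chain: constant trajectory
  frozen <- one_segment_series(vals[rep(1, 10), ], "humerus")
  tf <- landmark_trajectory(m, frozen, "elbow", reference = "thoracic_vertebra_1")
  expect_equal(max(apply(tf, 2, function(v) diff(range(v)))), 0)
  expect_error(landmark_trajectory(m, ser, "nose", "global"), "unknown landmark")
  expect_error(landmark_trajectory(m, ser, "elbow", "pelvis"), "unknown reference")
})

test_that("trajectories relative to a reference ignore motion above it", {
  m <- sloth_marionette()
  st <- template_stride()
  base <- landmark_trajectory(m, st, "elbow", "thoracic_vertebra_1")
  # perturb the vertebra wildly: the elbow-relative-to-T1 path is unchanged
  d <- st$data
  sel <- d$segment == "thoracic_vertebra_1"
  set.seed(203)
  d[sel, c("tx_cm", "ty_cm", "tz_cm")] <-
    d[sel, c("tx_cm", "ty_cm", "tz_cm")] + matrix(stats::rnorm(3 * sum(sel), 0, 5), ncol = 3)
  d[sel, c("rx_deg", "ry_deg", "rz_deg")] <-
    d[sel, c("rx_deg", "ry_deg", "rz_deg")] + matrix(stats::rnorm(3 * sum(sel), 0, 30), ncol = 3)
  moved <- pose_series(d, fps = st$fps)
  expect_equal(landmark_trajectory(m, moved, "elbow", "thoracic_vertebra_1"),
               base, tolerance = 1e-10)
})

test_that("model JSON and pose CSV round-trip through files", {
  m <- sloth_marionette(scale = 1)
  fj <- tempfile(fileext = ".json")
  write_marionette(m, fj)
  m2 <- read_marionette(fj)
  expect_equal(m2$segments$humerus$landmarks$elbow,
               m$segments$humerus$landmarks$elbow)
  expect_equal(m2$rank, m$rank[names(m2$rank)])

  st <- template_stride()
  fc <- tempfile(fileext = ".csv")
  write_pose_series(st, fc)
  expect_match(readLines(fc, n = 1), "euler_convention")
  st2 <- read_pose_series(fc)
  expect_equal(st2$fps, 300)
  expect_equal(st2$data, st$data, tolerance = 1e-12)
  unlink(c(fj, fc))
})

test_that("isotropic scaling rescales lengths, origins and landmarks", {
  m <- sloth_marionette(scale = 2)
  m1 <- sloth_marionette()
  expect_equal(m$segments$humerus$length, 2 * m1$segments$humerus$length)
  expect_equal(m$segments$scapula$origin, 2 * m1$segments$scapula$origin)
  expect_equal(m$segments$humerus$landmarks$elbow,
               2 * m1$segments$humerus$landmarks$elbow)
})
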