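test_that("reference extrapolation matches the layout-ratio identity", {
  # equal spacing extrapolates symmetrically
  expect_equal(extrapolate_reference(300, 200, 1, 1), 100)
  # alpha = 2, beta = 1: C sits half the A-B spacing beyond B
  expect_equal(extrapolate_reference(300, 200, 2, 1), 150)
  expect_error(extrapolate_reference(1, 0, -1, 1), class = "gr_argument_error")
})

test_that("extrapolated reference satisfies the dividing-ratio identity", {
  set.seed(5)
  for (i in 1:200) {
    alpha <- runif(1, 0.1, 5)
    beta <- runif(1, 0.1, 5)
    bx <- runif(1, -200, 500)
    ax <- bx + runif(1, 1, 300)   # Ax > Bx
    cx <- extrapolate_reference(ax, bx, alpha, beta)
    expect_equal((beta * ax + alpha * cx) / (alpha + beta), bx, tolerance = 1e-9)
    expect_true(cx < bx && bx < ax)
  }
})

test_that("calibration recovers the forward-pose marker anchors", {
  sc <- shared_scene()
  ref <- sc$calib$ref
  truth <- marker_positions(c(0, 0, 0), sc$spec)
  for (id in 1:3) {
    expect_lte(abs(ref$x[ref$marker_id == id] - truth$x[truth$marker_id == id]), 1)
    expect_lte(abs(ref$y[ref$marker_id == id] - truth$y[truth$marker_id == id]), 1)
  }
  # the star marker's reference equals its true (off-screen) anchor
  expect_lte(abs(ref$x[ref$marker_id == 4] - truth$x[truth$marker_id == 4]), 1)
  expect_equal(ref$y[ref$marker_id == 4], ref$y[ref$marker_id == 3])
  expect_equal(sc$calib$extrapolated, 4L)
})

test_that("calibration failure names the missing marker", {
  sc <- shared_scene()
  blank <- list(matrix(0.5, 240, 320))
  err <- tryCatch(calibrate(blank, sc$templates, sc$config),
                  error = function(e) e)
  expect_s3_class(err, "gr_calibration_error")
  expect_match(conditionMessage(err), "Marker1")
})

test_that("roll from a detection pair follows the arctangent geometry", {
  d <- function(x, y) gazerange:::marker_detection(1, x, y, 1)
  expect_equal(estimate_roll(d(100, 50), d(200, 50)), 0)
  expect_equal(estimate_roll(d(0, 0), d(100, 100)), 45)
  expect_equal(estimate_roll(d(50, 10), d(150, 60)), atan(0.5) * 180 / pi,
               tolerance = 1e-9)
  # argument order must not matter (the pair is sorted by x internally)
  expect_equal(estimate_roll(d(200, 50), d(100, 20)),
               estimate_roll(d(100, 20), d(200, 50)))
  expect_error(estimate_roll(d(100, 0), d(100, 50)), class = "gr_degenerate_error")
})

test_that("coordinate rotation is exact and invertible", {
  p <- rotate_coords(3, 4, 0)
  expect_equal(c(p$x, p$y), c(3, 4))
  p <- rotate_coords(1, 0, 90)
  expect_equal(c(p$x, p$y), c(0, 1), tolerance = 1e-12)

  set.seed(9)
  for (i in 1:100) {
    x <- runif(1, -500, 500); y <- runif(1, -500, 500)
    th <- runif(1, -180, 180)
    f <- rotate_coords(x, y, th)
    b <- rotate_coords(f$x, f$y, -th)
    expect_equal(c(b$x, b$y), c(x, y), tolerance = 1e-9)
  }
})

test_that("pixel-to-angle conversion is linear in the displacement", {
  expect_equal(pixels_to_angle(0, 640, 60), 0)
  expect_equal(pixels_to_angle(64, 640, 60), 6)
  set.seed(13)
  a <- runif(50, -300, 300); b <- runif(50, -300, 300)
  expect_equal(pixels_to_angle(a + b, 640, 60),
               pixels_to_angle(a, 640, 60) + pixels_to_angle(b, 640, 60),
               tolerance = 1e-12)
  expect_error(pixels_to_angle(1, 0, 60), class = "gr_argument_error")
  expect_error(pixels_to_angle(1, 640, 200), class = "gr_argument_error")
})

test_that("markers at their reference positions give the zero pose", {
  sc <- shared_scene()
  ref <- sc$calib$ref
  dets <- do.call(rbind, lapply(1:3, function(id)
    gazerange:::marker_detection(id, ref$x[ref$marker_id == id],
                                 ref$y[ref$marker_id == id], 1)))
  pose <- estimate_head_pose(dets, sc$calib, sc$config$camera)
  expect_true(pose$valid)
  expect_equal(c(pose$yaw, pose$pitch, pose$roll), c(0, 0, 0), tolerance = 1e-9)
})

test_that("a frame without detections yields an invalid pose, not an error", {
  sc <- shared_scene()
  pose <- estimate_head_pose(gazerange:::empty_detections(), sc$calib,
                             sc$config$camera, frame_index = 7)
  expect_false(pose$valid)
  expect_true(is.na(pose$yaw))
  expect_equal(pose$frame, 7L)
})

test_that("rendered poses are recovered within a degree", {
  for (pose in list(c(15, -5, 0), c(-10, 4, 0), c(22, 0, 0), c(0, -8, 0))) {
    est <- estimate_pose_of(pose)
    expect_lt(abs(est$yaw - pose[1]), 1)
    expect_lt(abs(est$pitch - pose[2]), 1)
  }
})

test_that("a pure roll pose leaves yaw and pitch at zero", {
  for (roll in c(-20, 10, 25)) {
    est <- estimate_pose_of(c(0, 0, roll))
    expect_lt(abs(est$yaw), 1)
    expect_lt(abs(est$pitch), 1)
    expect_lt(abs(est$roll - roll), 1.5)
  }
})

test_that("tracking a simulated drive recovers the head trajectory", {
  set.seed(77)
  sc <- shared_scene()
  n <- 30
  traj <- make_trajectory(n, yaw_max = 18, pitch_max = 6, roll_max = 6)
  res <- track_session(function(i)
    render_frame(c(traj$yaw[i], traj$pitch[i], traj$roll[i]), sc$spec),
    templates = sc$templates, calib = sc$calib, config = sc$config,
    n_frames = n)
  expect_equal(nrow(res$poses), n)
  expect_true(all(res$poses$valid))
  expect_lt(max(abs(res$poses$yaw - traj$yaw)), 1)
  expect_lt(max(abs(res$poses$pitch - traj$pitch)), 1)

  # the star marker is never co-framed with markers 1 or 2
  by_frame <- split(res$detections$marker_id, res$detections$frame)
  for (ids in by_frame) {
    expect_false(4 %in% ids && any(c(1, 2) %in% ids))
  }
})
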