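# Even-odd point-in-polygon test on a closed polygon (px, py vertices).
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

glyph_polygon <- function(shape) {
  switch(shape,
    triangle_up = list(x = c(0.50, 0.06, 0.94), y = c(0.06, 0.94, 0.94)),
    triangle_down = list(x = c(0.50, 0.06, 0.94), y = c(0.94, 0.06, 0.06)),
    star = {
      k <- 0:9
      r <- ifelse(k %% 2 == 0, 0.48, 0.19)
      a <- -pi / 2 + k * pi / 5
      list(x = 0.5 + r * cos(a), y = 0.5 + r * sin(a))
    },
    NULL
  )
}

#' Marker glyphs (upward triangle, circle, downward triangle, star)
#'
#' Draws one of the four printed marker shapes as a filled, anti-aliased
#' coverage mask (values in \[0, 1\], 1 = fully inside the shape),
#' rendered by 3x3 supersampling on a square grid.
#'
#' @param shape One of `"triangle_up"`, `"circle"`, `"triangle_down"`,
#'   `"star"`.
#' @param size Side length in pixels.
#' @return `size x size` numeric matrix.
#' @export
marker_glyph <- function(shape = c("triangle_up", "circle", "triangle_down", "star"),
                         size = 17) {
  shape <- match.arg(shape)
  ss <- 3L
  g <- seq(0.5 / (size * ss), 1 - 0.5 / (size * ss), length.out = size * ss)
  xx <- matrix(g, size * ss, size * ss, byrow = TRUE)
  yy <- matrix(g, size * ss, size * ss)
  inside <- if (shape == "circle") {
    (xx - 0.5)^2 + (yy - 0.5)^2 <= 0.44^2
  } else {
    p <- glyph_polygon(shape)
    matrix(point_in_polygon(as.vector(xx), as.vector(yy), p$x, p$y),
           size * ss, size * ss)
  }
  # average the supersamples back down to size x size
  m <- matrix(0, size, size)
  for (i in seq_len(ss)) {
    for (j in seq_len(ss)) {
      m <- m + inside[seq(i, by = ss, length.out = size),
                      seq(j, by = ss, length.out = size)]
    }
  }
  m / ss^2
}

marker_shapes <- function() c("triangle_up", "circle", "triangle_down", "star")

#' Render the four marker template patches
#'
#' @param size Template side length in px.
#' @param bg_value,fg_value Background and glyph intensities in \[0, 1\].
#' @return Named list `"1"`..`"4"` of `size x size` grayscale matrices.
#' @export
make_templates <- function(size = 17, bg_value = 0.5, fg_value = 1) {
  shapes <- marker_shapes()
  out <- lapply(seq_along(shapes), function(i) {
    g <- marker_glyph(shapes[i], size)
    bg_value * (1 - g) + fg_value * g
  })
  names(out) <- as.character(1:4)
  out
}

#' Specification of a synthetic marker scene
#'
#' Describes the forward model used to render ground-truthed view-camera
#' frames: camera geometry, the pixel anchor (template top-left) of each
#' marker at pose (0, 0, 0), glyph size and background model. The
#' inter-marker layout ratio `alpha:beta` (Marker2-Marker3 spacing to
#' Marker3-Marker4 spacing) is derived from the anchors.
#'
#' @param camera [camera_model()].
#' @param anchors data.frame `marker_id`, `x`, `y`: template top-left
#'   anchors at the forward-facing pose, ordered monotonically in x.
#' @param template_size Glyph/template side length in px.
#' @param background `"uniform"` or `"noise"` (seeded Gaussian pixel
#'   noise around `bg_value`).
#' @param bg_value,fg_value,noise_sd Background intensity, glyph
#'   intensity, noise standard deviation.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(camera, anchors, template_size = 17,
                       background = c("uniform", "noise"),
                       bg_value = 0.5, fg_value = 1, noise_sd = 0.08) {
  background <- match.arg(background)
  stopifnot(all(c("marker_id", "x", "y") %in% names(anchors)),
            identical(sort(anchors$marker_id), 1:4))
  anchors <- anchors[order(anchors$marker_id), , drop = FALSE]
  dx <- diff(anchors$x)
  if (!(all(dx > 0) || all(dx < 0)))
    gr_stop("marker anchors must be ordered monotonically in x", "gr_config_error")
  alpha <- abs(anchors$x[3] - anchors$x[2])
  beta <- abs(anchors$x[4] - anchors$x[3])
  structure(list(camera = camera, anchors = anchors,
                 template_size = template_size, background = background,
                 bg_value = bg_value, fg_value = fg_value,
                 noise_sd = noise_sd, alpha = alpha, beta = beta),
            class = "scene_spec")
}

#' Default synthetic scene
#'
#' A 320 x 240 px view camera with an 80 x 60 degree field of view
#' (4 px/deg), markers 1-3 on a horizontal rail inside the forward view
#' and the star marker beyond the right frame edge (off-screen while
#' facing forward, entering the view during right head turns, and far
#' enough out that it can never be co-framed with Marker1), with an
#' unequal 1:2 spacing ratio.
#'
#' @param background,template_size Passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
default_scene <- function(background = "uniform", template_size = 17) {
  cam <- camera_model(320, 240, 80, 60)
  anchors <- data.frame(marker_id = 1:4,
                        x = c(40, 120, 200, 360),
                        y = rep(112, 4))
  scene_spec(cam, anchors, template_size = template_size,
             background = background)
}

#' Ground-truth marker anchor positions under a pose
#'
#' Forward model mirroring the estimator's geometry exactly (linear
#' degrees-to-pixels, no perspective): every anchor is displaced by
#' `(-yaw * width / fov_x, +pitch * height / fov_y)` pixels and then
#' rotated by `roll` about the image centre.
#'
#' @param pose Numeric `c(yaw, pitch, roll)` in degrees.
#' @param spec [scene_spec()].
#' @return data.frame `marker_id`, `x`, `y` (exact), `xpx`, `ypx`
#'   (rounded draw positions), `visible` (glyph fully inside the frame).
#' @export
marker_positions <- function(pose, spec) {
  cam <- spec$camera
  yaw <- pose[1]; pitch <- pose[2]; roll <- pose[3]
  dx <- -yaw * cam$width / cam$fov_x
  dy <- pitch * cam$height / cam$fov_y
  cx <- cam$width / 2; cy <- cam$height / 2
  rel <- rotate_coords(spec$anchors$x + dx - cx, spec$anchors$y + dy - cy, roll)
  x <- rel$x + cx
  y <- rel$y + cy
  xpx <- round(x); ypx <- round(y)
  s <- spec$template_size
  visible <- xpx >= 0 & ypx >= 0 & (xpx + s) <= cam$width & (ypx + s) <= cam$height
  data.frame(marker_id = spec$anchors$marker_id, x = x, y = y,
             xpx = xpx, ypx = ypx, visible = visible)
}

render_background <- function(spec) {
  cam <- spec$camera
  if (spec$background == "noise") {
    m <- matrix(spec$bg_value + stats::rnorm(cam$height * cam$width, 0, spec$noise_sd),
                cam$height, cam$width)
    pmin(pmax(m, 0), 1)
  } else {
    matrix(spec$bg_value, cam$height, cam$width)
  }
}

#' Render one synthetic view-camera frame
#'
#' Draws each marker glyph at its [marker_positions()] draw position
#' (alpha-blended onto the background; markers crossing the frame edge
#' are clipped). With `background = "noise"` the pixel noise is drawn
#' from the current RNG stream, so seed the session for reproducibility.
#'
#' @param pose Numeric `c(yaw, pitch, roll)` in degrees.
#' @param spec [scene_spec()].
#' @return Grayscale matrix `height x width`.
#' @export
render_frame <- function(pose, spec) {
  frame <- render_background(spec)
  pos <- marker_positions(pose, spec)
  s <- spec$template_size
  shapes <- marker_shapes()
  for (k in seq_len(nrow(pos))) {
    g <- marker_glyph(shapes[pos$marker_id[k]], s)
    x0 <- pos$xpx[k]; y0 <- pos$ypx[k]   # 0-based anchor
    rows <- (y0 + 1):(y0 + s)
    cols <- (x0 + 1):(x0 + s)
    rok <- rows >= 1 & rows <= nrow(frame)
    cok <- cols >= 1 & cols <= ncol(frame)
    if (!any(rok) || !any(cok)) next
    gr <- g[rok, cok, drop = FALSE]
    sub <- frame[rows[rok], cols[cok], drop = FALSE]
    frame[rows[rok], cols[cok]] <- sub * (1 - gr) + spec$fg_value * gr
  }
  frame
}

#' Smooth head-angle trajectory
#'
#' Generates a smooth, band-limited head trajectory (sum of two seeded
#' sinusoids per axis with random frequency and phase) emulating the slow
#' sweep of a driver's head, with yaw dominating and small pitch and
#' roll. Roll stays well below 45 degrees by construction.
#'
#' @param n Number of frames.
#' @param yaw_max,pitch_max,roll_max Amplitude caps in degrees.
#' @param frame_rate Frames per second.
#' @param seed Optional integer seed.
#' @return data.frame `frame` (0-based), `t` (s), `yaw`, `pitch`, `roll`.
#' @export
make_trajectory <- function(n, yaw_max = 25, pitch_max = 8, roll_max = 8,
                            frame_rate = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n) - 1) / frame_rate
  axis <- function(amp) {
    f1 <- stats::runif(1, 0.02, 0.05)
    f2 <- stats::runif(1, 0.06, 0.12)
    p1 <- stats::runif(1, 0, 2 * pi)
    p2 <- stats::runif(1, 0, 2 * pi)
    w <- 0.75 * sin(2 * pi * f1 * t + p1) + 0.25 * sin(2 * pi * f2 * t + p2)
    amp * w
  }
  data.frame(frame = seq_len(n) - 1L, t = t,
             yaw = axis(yaw_max), pitch = axis(pitch_max), roll = axis(roll_max))
}

#' Simulate a complete ground-truthed recording session
#'
#' Produces everything a real recording would: view-camera frames under a
#' known head trajectory, forward-facing calibration frames, the four
#' marker templates, a simulated eye-angle stream, and the matching
#' session config -- plus the ground truth for every stage.
#'
#' The gaze model is a saccade-and-hold process: at each frame a new gaze
#' target is drawn from an independent 2-D Gaussian
#' (`gaze_mu`, `gaze_sigma`) with probability `saccade_rate`, otherwise
#' the previous target is held (fixation). Eye angles are defined as the
#' sampled gaze minus the trajectory's head angles, so fusing the
#' simulated eye stream with the ground-truth head angles reproduces the
#' sampled gaze distribution exactly.
#'
#' @param n_frames Number of driving frames.
#' @param spec [scene_spec()] (default [default_scene()]).
#' @param trajectory Optional [make_trajectory()] data.frame; generated
#'   from the session RNG stream when `NULL`.
#' @param gaze_mu,gaze_sigma Length-2 mean and spread (deg) of the gaze
#'   target distribution (x, y).
#' @param saccade_rate Per-frame probability of a new gaze target.
#' @param n_calib Number of forward-facing calibration frames.
#' @param frame_rate Frames per second.
#' @param seed Optional integer seed; identical seeds give identical
#'   sessions.
#' @param render If `FALSE`, skip frame rendering (statistical tests that
#'   only need the eye/truth streams).
#' @return A list of class `gaze_session`: `frames`, `calib_frames`,
#'   `templates`, `eye` (t, x_eye, y_eye), `truth` (frame, t, yaw, pitch,
#'   roll, x_gaze, y_gaze), `config`, `spec`.
#' @export
simulate_session <- function(n_frames, spec = default_scene(),
                             trajectory = NULL,
                             gaze_mu = c(0, 0), gaze_sigma = c(15, 8),
                             saccade_rate = 0.3, n_calib = 10,
                             frame_rate = 10, seed = NULL, render = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  if (any(gaze_sigma < 0)) gr_stop("gaze_sigma must be >= 0", "gr_argument_error")
  if (is.null(trajectory))
    trajectory <- make_trajectory(n_frames, frame_rate = frame_rate)
  stopifnot(nrow(trajectory) == n_frames)

  new_target <- c(TRUE, stats::runif(n_frames - 1) < saccade_rate)
  gx <- gy <- numeric(n_frames)
  for (i in seq_len(n_frames)) {
    if (new_target[i]) {
      gx[i] <- stats::rnorm(1, gaze_mu[1], gaze_sigma[1])
      gy[i] <- stats::rnorm(1, gaze_mu[2], gaze_sigma[2])
    } else {
      gx[i] <- gx[i - 1]; gy[i] <- gy[i - 1]
    }
  }
  x_eye <- pmin(pmax(gx - trajectory$yaw, -180), 180)
  y_eye <- pmin(pmax(gy - trajectory$pitch, -180), 180)

  eye <- data.frame(t = trajectory$t, x_eye = x_eye, y_eye = y_eye)
  truth <- data.frame(frame = trajectory$frame, t = trajectory$t,
                      yaw = trajectory$yaw, pitch = trajectory$pitch,
                      roll = trajectory$roll, x_gaze = gx, y_gaze = gy)

  frames <- NULL
  calib_frames <- NULL
  if (render) {
    frames <- lapply(seq_len(n_frames), function(i)
      render_frame(c(trajectory$yaw[i], trajectory$pitch[i], trajectory$roll[i]), spec))
    calib_frames <- lapply(seq_len(n_calib), function(i)
      render_frame(c(0, 0, 0), spec))
  }

  cam <- spec$camera
  config <- list(
    camera = list(width = cam$width, height = cam$height,
                  fov_x = cam$fov_x, fov_y = cam$fov_y),
    markers = lapply(1:4, function(id)
      list(id = id, shape = marker_shapes()[id],
           template = file.path("templates", paste0("marker", id, ".png")))),
    layout = list(alpha = spec$alpha, beta = spec$beta),
    frame_rate = frame_rate,
    calibration = list(n_frames = n_calib)
  )
  config <- validate_session_config(config)

  structure(list(frames = frames, calib_frames = calib_frames,
                 templates = make_templates(spec$template_size,
                                            spec$bg_value, spec$fg_value),
                 eye = eye, truth = truth, config = config, spec = spec),
            class = "gaze_session")
}

#' Write a simulated session to disk in the session on-disk layout
#'
#' Creates `frames/frame_%05d.png`, `calib/calib_%05d.png`,
#' `templates/marker[1-4].png`, `eye.csv`, `truth.csv` and `config.yaml`
#' under `out_dir`.
#'
#' @param session A `gaze_session` from [simulate_session()] (rendered).
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_session <- function(session, out_dir) {
  if (is.null(session$frames))
    gr_stop("session was simulated with render = FALSE; nothing to write",
            "gr_argument_error")
  for (d in c("", "frames", "calib", "templates")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(session$frames))
    write_image(session$frames[[i]],
                file.path(out_dir, "frames", sprintf("frame_%05d.png", i - 1)))
  for (i in seq_along(session$calib_frames))
    write_image(session$calib_frames[[i]],
                file.path(out_dir, "calib", sprintf("calib_%05d.png", i - 1)))
  for (id in 1:4)
    write_image(session$templates[[as.character(id)]],
                file.path(out_dir, "templates", paste0("marker", id, ".png")))
  write_eye_csv(session$eye, file.path(out_dir, "eye.csv"))
  utils::write.csv(session$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  write_session_config(session$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
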