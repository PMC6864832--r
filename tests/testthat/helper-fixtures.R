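# Shared fixtures, built in code at test time.

# Brute-force zero-normalised cross-correlation oracle: plain R, scans
# every anchor with an explicit window extraction. Independent of the
# compiled scanner it is used to check.
ncc_oracle <- function(frame, templ) {
  th <- nrow(templ); tw <- ncol(templ)
  ny <- nrow(frame) - th + 1
  nx <- ncol(frame) - tw + 1
  tc <- templ - mean(templ)
  tss <- sum(tc^2)
  out <- matrix(0, ny, nx)
  for (ax in seq_len(nx)) {
    for (ay in seq_len(ny)) {
      w <- frame[ay:(ay + th - 1), ax:(ax + tw - 1)]
      wc <- w - mean(w)
      denom <- sqrt(sum(wc^2) * tss)
      s <- if (denom > 1e-12) sum(wc * tc) / denom else 0
      out[ay, ax] <- min(max(s, 0), 1)
    }
  }
  out
}

# Config matching a scene_spec (template paths are placeholders; tests
# pass template matrices directly).
scene_config <- function(spec) {
  validate_session_config(list(
    camera = list(width = spec$camera$width, height = spec$camera$height,
                  fov_x = spec$camera$fov_x, fov_y = spec$camera$fov_y),
    markers = lapply(1:4, function(i)
      list(id = i, template = paste0("marker", i, ".png"))),
    layout = list(alpha = spec$alpha, beta = spec$beta)
  ))
}

# One shared default scene + calibration, computed once per test run.
.fixture_env <- new.env(parent = emptyenv())

shared_scene <- function() {
  if (is.null(.fixture_env$spec)) {
    spec <- default_scene()
    templates <- make_templates(spec$template_size, spec$bg_value, spec$fg_value)
    config <- scene_config(spec)
    calib_frames <- lapply(1:3, function(i) render_frame(c(0, 0, 0), spec))
    calib <- calibrate(calib_frames, templates, config)
    .fixture_env$spec <- list(spec = spec, templates = templates,
                              config = config, calib = calib)
  }
  .fixture_env$spec
}

# Head pose of a single independently rendered frame (no tracking prior).
estimate_pose_of <- function(pose, scene = shared_scene(),
                             spec = scene$spec) {
  frame <- render_frame(pose, spec)
  res <- track_session(list(frame), scene$templates, scene$calib, scene$config)
  res$poses[1, ]
}

# Noise frame with a template pasted at a known 0-based anchor.
paste_template <- function(frame, templ, x, y) {
  frame[(y + 1):(y + nrow(templ)), (x + 1):(x + ncol(templ))] <- templ
  frame
}

expect_region_equal <- function(r, x0, y0, x1, y1) {
  expect_equal(c(r$x0, r$y0, r$x1, r$y1), c(x0, y0, x1, y1))
}
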