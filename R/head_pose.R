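#' Extrapolate the reference x of the off-screen fourth marker
#'
#' The fourth (star) marker extends the measurable head-angle range but is
#' outside the view frame while the driver faces forward, so its reference
#' position cannot be recorded during calibration. It is instead
#' extrapolated collinearly from the reference x positions of the two
#' markers nearest to it, using the known physical spacing ratio
#' `alpha : beta` (`alpha` = spacing between the two calibrated markers,
#' `beta` = spacing from the inner calibrated marker to the star marker):
#'
#'   `Cx = -(1/alpha) * (beta * (Ax - Bx) - alpha * Bx)`
#'
#' which is the unique solution of `Bx = (beta * Ax + alpha * Cx) /
#' (alpha + beta)`, i.e. the inner marker divides the segment A-C in ratio
#' `alpha : beta`. The formula is orientation-free: when `Ax > Bx` the
#' result satisfies `Cx < Bx < Ax`, and mirrored layouts extrapolate to the
#' other side.
#'
#' @param ax Reference x of the far calibrated marker (A, Marker2).
#' @param bx Reference x of the near calibrated marker (B, Marker3).
#' @param alpha,beta Positive spacing ratio (A-B : B-C).
#' @return Extrapolated reference x (Cx) of the star marker.
#' @examples
#' extrapolate_reference(300, 200, 1, 1) # equal spacing -> 100
#' @export
extrapolate_reference <- function(ax, bx, alpha, beta) {
  if (!(alpha > 0 && beta > 0))
    gr_stop("alpha and beta must be > 0", "gr_argument_error")
  -(1 / alpha) * (beta * (ax - bx) - alpha * bx)
}

#' Record per-marker reference positions from forward-facing frames
#'
#' The driver faces straight ahead for a few seconds; markers 1-3 are
#' detected in every calibration frame and the per-marker median position
#' over the frames is stored as that marker's reference (the median is
#' robust to isolated mismatches). Marker4 is off-screen in this posture,
#' so its reference x is extrapolated with [extrapolate_reference()] from
#' the Marker2/Marker3 references and the configured `alpha:beta` layout
#' ratio; its reference y is taken from Marker3 (the markers sit on one
#' horizontal rail).
#'
#' @param forward_frames List of grayscale frames recorded while facing
#'   forward.
#' @param templates Named list of template matrices (`"1"`..`"4"`).
#' @param config Validated session config (similarity threshold, layout
#'   ratio).
#' @return A `calibration_result`: list with `ref` (data.frame `marker_id`,
#'   `x`, `y`), `n_frames`, and `extrapolated` (marker ids whose reference
#'   was computed, not observed).
#' @export
calibrate <- function(forward_frames, templates, config) {
  if (length(forward_frames) < 1)
    gr_stop("calibration requires at least one forward-facing frame", "gr_calibration_error")
  thr <- config$similarity_threshold
  pos <- list(`1` = NULL, `2` = NULL, `3` = NULL)
  for (frame in forward_frames) {
    found <- empty_detections()
    for (id in 1:3) {
      tmpl <- templates[[as.character(id)]]
      # sequential ordering constraint: each marker right of the previous
      x0 <- 0
      if (nrow(found) > 0) x0 <- max(found$x) + 1
      r <- tryCatch(clip_region(search_region(x0, 0, ncol(frame), nrow(frame)),
                                dim(frame)), error = function(e) NULL)
      if (is.null(r) || !region_fits(r, tmpl)) next
      det <- match_template(frame, tmpl, r, thr, marker_id = id)
      if (!is.null(det)) {
        found <- rbind(found, det)
        pos[[as.character(id)]] <- rbind(pos[[as.character(id)]], c(det$x, det$y))
      }
    }
  }
  for (id in 1:3) {
    if (is.null(pos[[as.character(id)]]))
      gr_stop(paste0("calibration failed: Marker", id,
                     " was never detected in the forward-facing frames"),
              "gr_calibration_error")
  }
  ref <- do.call(rbind, lapply(1:3, function(id) {
    p <- pos[[as.character(id)]]
    data.frame(marker_id = id, x = stats::median(p[, 1]), y = stats::median(p[, 2]))
  }))
  ax <- ref$x[ref$marker_id == 2]
  bx <- ref$x[ref$marker_id == 3]
  cx <- extrapolate_reference(ax, bx, config$layout$alpha, config$layout$beta)
  ref <- rbind(ref, data.frame(marker_id = 4L, x = cx, y = ref$y[ref$marker_id == 3]))
  structure(list(ref = ref, n_frames = length(forward_frames), extrapolated = 4L),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration over %d frame(s); Marker%s reference extrapolated>\n",
              x$n_frames, paste(x$extrapolated, collapse = ",")))
  print(x$ref)
  invisible(x)
}

#' Roll angle from a pair of marker detections
#'
#' With two markers visible, the head's roll (image-plane tilt) is the
#' angle of the line joining them: `theta = atan((y2 - y1) / (x2 - x1))`
#' in degrees, with the detections ordered so that `x2 > x1`. Positive
#' theta means the right-hand marker sits lower in the image (image y
#' grows downward).
#'
#' @param d1,d2 One-row detection data.frames (fields `x`, `y`).
#' @return Roll angle in degrees, in (-90, 90).
#' @export
estimate_roll <- function(d1, d2) {
  if (d2$x < d1$x) { tmp <- d1; d1 <- d2; d2 <- tmp }
  dx <- d2$x - d1$x
  if (dx == 0)
    gr_stop("degenerate geometry: the two detections share the same x", "gr_degenerate_error")
  atan((d2$y - d1$y) / dx) * 180 / pi
}

#' Rotate image coordinates by an angle
#'
#' The rotation conversion `x' = x cos(theta) - y sin(theta)`,
#' `y' = x sin(theta) + y cos(theta)` (theta in degrees). Applying the
#' inverse angle undoes the transform; the tracker uses this with
#' `-roll` to map marker coordinates back to the zero-roll frame before
#' reading off yaw and pitch.
#'
#' @param x,y Coordinates (vectorised).
#' @param theta Angle in degrees.
#' @return List with components `x`, `y`.
#' @export
rotate_coords <- function(x, y, theta) {
  th <- theta * pi / 180
  list(x = x * cos(th) - y * sin(th),
       y = x * sin(th) + y * cos(th))
}

#' Convert a pixel displacement to a head angle
#'
#' The linear camera model: a displacement of the full axis resolution
#' corresponds to the full viewing angle, so
#' `angle = displacement * fov / resolution` (degrees).
#'
#' @param displacement Pixels (vectorised).
#' @param axis_resolution Axis resolution in px (> 0).
#' @param axis_fov Axis viewing angle in degrees, in (0, 180).
#' @return Angle in degrees.
#' @export
pixels_to_angle <- function(displacement, axis_resolution, axis_fov) {
  if (!(axis_resolution > 0))
    gr_stop("axis_resolution must be > 0", "gr_argument_error")
  if (!(axis_fov > 0 && axis_fov < 180))
    gr_stop("axis_fov must lie in (0, 180)", "gr_argument_error")
  displacement * axis_fov / axis_resolution
}

invalid_pose <- function(frame_index) {
  data.frame(frame = as.integer(frame_index), yaw = NA_real_, pitch = NA_real_,
             roll = NA_real_, valid = FALSE,
             yaw_marker = NA_integer_, pitch_marker = NA_integer_,
             n_markers = 0L)
}

#' Estimate the head pose of one frame from its marker detections
#'
#' Pipeline per frame:
#'
#' 1. *Roll*: with two or more detections, the two highest-scoring ones
#'    (ties broken by lower marker id) give the roll via [estimate_roll()],
#'    minus the same pair's reference baseline angle (zero when the markers
#'    were calibrated on one horizontal rail). With fewer than two
#'    detections the last valid roll is carried (0 if none yet).
#' 2. *Roll correction*: every detection is rotated by `-roll` about the
#'    image centre, mapping marker coordinates back to the zero-roll frame.
#'    References were recorded facing forward (zero roll) and stay fixed.
#' 3. *Yaw/pitch*: displacement-to-angle conversion is most accurate for
#'    the marker nearest the image centre on that axis, so yaw is read from
#'    the corrected marker whose x is nearest the x-centre and pitch from
#'    the one nearest the y-centre (ties: lower marker id). Signs: the
#'    scene shifts left when the head turns right and down when it tilts
#'    up, so `yaw = (ref_x - x') * fov_x / width` and
#'    `pitch = (y' - ref_y) * fov_y / height`.
#'
#' A frame with no accepted detection yields an invalid pose (NA angles).
#'
#' @param detections Detection data.frame for one frame (0-4 rows).
#' @param calib [calibrate()] result.
#' @param camera [camera_model()].
#' @param frame_index Frame index stored in the output.
#' @param prev_roll Roll carried from the last valid frame (deg).
#' @return One-row data.frame: `frame`, `yaw`, `pitch`, `roll`, `valid`,
#'   `yaw_marker`, `pitch_marker`, `n_markers`.
#' @export
estimate_head_pose <- function(detections, calib, camera,
                               frame_index = NA_integer_, prev_roll = 0) {
  if (is.null(detections) || nrow(detections) == 0)
    return(invalid_pose(frame_index))
  ref <- calib$ref

  theta <- prev_roll
  if (nrow(detections) >= 2) {
    ord <- order(-detections$score, detections$marker_id)
    pair <- detections[ord[1:2], , drop = FALSE]
    r1 <- ref[ref$marker_id == pair$marker_id[1], , drop = FALSE]
    r2 <- ref[ref$marker_id == pair$marker_id[2], , drop = FALSE]
    theta <- tryCatch(
      estimate_roll(pair[1, ], pair[2, ]) - estimate_roll(r1, r2),
      error = function(e) prev_roll
    )
  }

  cx <- camera$width / 2
  cy <- camera$height / 2
  rot <- rotate_coords(detections$x - cx, detections$y - cy, -theta)
  xr <- rot$x + cx
  yr <- rot$y + cy

  pick <- function(dist) {
    ord <- order(dist, detections$marker_id)
    ord[1]
  }
  iy <- pick(abs(xr - cx))   # marker nearest the x-centre -> yaw
  ip <- pick(abs(yr - cy))   # marker nearest the y-centre -> pitch
  ref_yaw <- ref[ref$marker_id == detections$marker_id[iy], , drop = FALSE]
  ref_pit <- ref[ref$marker_id == detections$marker_id[ip], , drop = FALSE]

  yaw <- pixels_to_angle(ref_yaw$x - xr[iy], camera$width, camera$fov_x)
  pitch <- pixels_to_angle(yr[ip] - ref_pit$y, camera$height, camera$fov_y)

  data.frame(frame = as.integer(frame_index), yaw = yaw, pitch = pitch,
             roll = theta, valid = TRUE,
             yaw_marker = detections$marker_id[iy],
             pitch_marker = detections$marker_id[ip],
             n_markers = nrow(detections))
}

#' Track markers and head pose over a frame sequence
#'
#' Runs the full per-frame loop: search regions are planned from the two
#' previous frames ([plan_search_regions()]), markers are searched in the
#' fixed order 1 (up triangle), 2 (circle), 3 (down triangle), 4 (star) --
#' Marker4 being skipped whenever Marker1 or Marker2 has already been found
#' in the current frame -- each within its centre/upper/bottom sections,
#' and the accepted detections are converted to a head pose
#' ([estimate_head_pose()]). Frames may be supplied as a list of matrices
#' or as a zero-argument-per-index function `function(i)` returning frame
#' `i` (so long sessions need not be held in memory).
#'
#' @param frames List of grayscale matrices, or `function(i)`.
#' @param n_frames Number of frames (required when `frames` is a function).
#' @param templates Named template list.
#' @param calib [calibrate()] result.
#' @param config Validated session config.
#' @return List with `poses` (one row per frame) and `detections` (one row
#'   per accepted match).
#' @export
track_session <- function(frames, templates, calib, config, n_frames = NULL) {
  get_frame <- if (is.function(frames)) frames else function(i) frames[[i]]
  n <- n_frames %||% length(frames)
  camera <- config$camera
  thr <- config$similarity_threshold
  margin <- config$search$margin
  gain <- config$search$extension_gain

  poses <- vector("list", n)
  dets <- vector("list", n)
  prev <- NULL; prev2 <- NULL
  last_roll <- 0

  for (i in seq_len(n)) {
    frame <- get_frame(i)
    found <- empty_detections()
    for (id in 1:4) {
      if (id == 4L && any(found$marker_id %in% c(1L, 2L))) next
      plan <- plan_search_regions(prev, prev2, dim(frame), templates,
                                  margin = margin, extension_gain = gain,
                                  found = found)
      det <- search_marker(frame, templates[[as.character(id)]],
                           plan[[as.character(id)]], thr,
                           marker_id = id, frame_index = i - 1L)
      if (!is.null(det)) found <- rbind(found, det)
    }
    pose <- estimate_head_pose(found, calib, camera, frame_index = i - 1L,
                               prev_roll = last_roll)
    if (pose$valid) last_roll <- pose$roll
    poses[[i]] <- pose
    dets[[i]] <- found
    prev2 <- prev
    prev <- if (nrow(found) > 0) found else NULL
  }
  list(poses = do.call(rbind, poses),
       detections = do.call(rbind, dets))
}
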