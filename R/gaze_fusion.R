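#' Fuse eye-in-head angles with head angles into gaze angles
#'
#' Eye and head movements combine additively when a person redirects their
#' gaze (eye-head coordinated movement), so the gaze direction in
#' vehicle/world coordinates is the componentwise sum of the eye-in-head
#' angle and the head angle: `x_gaze = x_eye + yaw`,
#' `y_gaze = y_eye + pitch`. A sample whose head pose is invalid yields an
#' invalid gaze sample (NA angles); no interpolation is performed.
#'
#' Inputs are matched row-by-row and must have equal length. Use
#' [align_eye_to_frames()] first when the eye stream and the video frames
#' are sampled on different clocks.
#'
#' @param eye data.frame with columns `x_eye`, `y_eye` and optionally `t`.
#' @param head data.frame with columns `yaw`, `pitch` and optionally
#'   `valid` (default all valid) and `frame`.
#' @param zone_map Zone map used to label each sample; `NULL` skips
#'   labelling (zone set to NA).
#' @return data.frame with columns `t`, `x_gaze`, `y_gaze`, `zone`,
#'   `valid`.
#' @examples
#' fuse(data.frame(x_eye = -30.8, y_eye = 0.6),
#'      data.frame(yaw = -25.3, pitch = -20.2))
#' @export
fuse <- function(eye, head, zone_map = default_zone_map()) {
  if (nrow(eye) != nrow(head))
    gr_stop(sprintf("eye (%d rows) and head (%d rows) streams are not aligned",
                    nrow(eye), nrow(head)), "gr_alignment_error")
  valid <- if ("valid" %in% names(head)) head$valid else rep(TRUE, nrow(head))
  valid <- valid & !is.na(head$yaw) & !is.na(head$pitch)
  x <- ifelse(valid, eye$x_eye + head$yaw, NA_real_)
  y <- ifelse(valid, eye$y_eye + head$pitch, NA_real_)
  t <- if ("t" %in% names(eye)) eye$t else seq_len(nrow(eye)) - 1
  zone <- if (is.null(zone_map)) rep(NA_character_, length(x)) else
    classify_zone(x, y, valid = valid, zone_map = zone_map)
  data.frame(t = t, x_gaze = x, y_gaze = y, zone = zone, valid = valid)
}

#' Align an eye-angle stream to video frame times
#'
#' For each frame time the nearest eye sample is taken, provided it lies
#' within half a frame interval; frames with no eye sample that close are
#' an alignment error (the streams do not overlap).
#'
#' @param eye data.frame from [read_eye_csv()].
#' @param frame_times Numeric vector of frame timestamps (s).
#' @param frame_rate Frames per second, used for the matching tolerance
#'   (half a frame interval).
#' @return data.frame with one eye row per frame time (`t` replaced by the
#'   frame time).
#' @export
align_eye_to_frames <- function(eye, frame_times, frame_rate) {
  if (nrow(eye) == 0)
    gr_stop("eye stream is empty: no overlap with the video", "gr_alignment_error")
  tol <- 0.5 / frame_rate
  idx <- vapply(frame_times, function(ft) {
    j <- which.min(abs(eye$t - ft))
    if (abs(eye$t[j] - ft) > tol) NA_integer_ else j
  }, integer(1))
  if (anyNA(idx))
    gr_stop(sprintf("no eye sample within %.3f s of frame time %.3f s",
                    tol, frame_times[which(is.na(idx))[1]]), "gr_alignment_error")
  out <- eye[idx, , drop = FALSE]
  out$t <- frame_times
  rownames(out) <- NULL
  out
}

#' Default nine-zone gaze map
#'
#' The gaze plane (x right, y up, degrees) is partitioned into the nine
#' cabin areas a driving evaluator distinguishes: front, rearview mirror,
#' meter, right mirror, right, right back, left mirror, left and left
#' back. Zones are matched in order, first match wins:
#' four specific open rectangles (rearview mirror above centre, meter
#' below centre, side mirrors low-left / low-right), then the closed
#' central/left/right bands with the "back" variants beyond +/-90 deg.
#' Boundary points therefore fall through to the band rows and get the
#' more central label. All angular limits are conventions of this map (the
#' evaluation vocabulary itself carries no geometry) and can be replaced
#' wholesale via the `zones` config block.
#'
#' @return data.frame with columns `label`, `xmin`, `xmax`, `ymin`,
#'   `ymax`, `closed` (closed = bounds inclusive).
#' @export
default_zone_map <- function() {
  z <- rbind(
    data.frame(label = "rearview mirror", xmin = -20, xmax = 20, ymin = 30,  ymax = 60,  closed = FALSE),
    data.frame(label = "meter",           xmin = -20, xmax = 20, ymin = -60, ymax = -30, closed = FALSE),
    data.frame(label = "right mirror",    xmin = 20,  xmax = 70, ymin = -60, ymax = -35, closed = FALSE),
    data.frame(label = "left mirror",     xmin = -70, xmax = -20, ymin = -60, ymax = -35, closed = FALSE),
    data.frame(label = "front",           xmin = -20, xmax = 20, ymin = -Inf, ymax = Inf, closed = TRUE),
    data.frame(label = "left",            xmin = -90, xmax = -20, ymin = -Inf, ymax = Inf, closed = TRUE),
    data.frame(label = "right",           xmin = 20,  xmax = 90, ymin = -Inf, ymax = Inf, closed = TRUE),
    data.frame(label = "left back",       xmin = -Inf, xmax = -90, ymin = -Inf, ymax = Inf, closed = TRUE),
    data.frame(label = "right back",      xmin = 90,  xmax = Inf, ymin = -Inf, ymax = Inf, closed = TRUE)
  )
  z
}

zone_map_from_config <- function(config) {
  if (is.null(config$zones)) return(default_zone_map())
  do.call(rbind, lapply(config$zones, function(z) {
    data.frame(label = z$label,
               xmin = z$x[[1]], xmax = z$x[[2]],
               ymin = z$y[[1]], ymax = z$y[[2]],
               closed = isTRUE(z$closed %||% TRUE))
  }))
}

#' Classify gaze angles into the nine cabin zones
#'
#' Deterministic first-match lookup in the ordered `zone_map`. Invalid
#' samples (NA angles or `valid = FALSE`) get the label `"unknown"`. The
#' default map is a total partition: every finite point receives exactly
#' one label.
#'
#' @param x,y Gaze angles in degrees (vectorised).
#' @param valid Logical vector (default all TRUE).
#' @param zone_map data.frame as from [default_zone_map()].
#' @return Character vector of zone labels.
#' @examples
#' classify_zone(0, 0)       # "front"
#' classify_zone(-56.1, -19.6) # "left"
#' @export
classify_zone <- function(x, y, valid = TRUE, zone_map = default_zone_map()) {
  n <- length(x)
  valid <- rep_len(valid, n)
  out <- rep("unknown", n)
  ok <- valid & !is.na(x) & !is.na(y)
  if (!any(ok)) return(out)
  lab <- rep(NA_character_, n)
  for (i in seq_len(nrow(zone_map))) {
    zm <- zone_map[i, ]
    inside <- if (zm$closed) {
      x >= zm$xmin & x <= zm$xmax & y >= zm$ymin & y <= zm$ymax
    } else {
      x > zm$xmin & x < zm$xmax & y > zm$ymin & y < zm$ymax
    }
    take <- ok & is.na(lab) & inside
    lab[take] <- zm$label
  }
  out[ok & !is.na(lab)] <- lab[ok & !is.na(lab)]
  out
}

#' Collapse a zone label to its left/right/front judgment family
#'
#' On-road judgment logs record only which side the driver was looking at:
#' left-family zones (left, left back, left mirror) map to `"Left"`,
#' right-family to `"Right"`, and the central zones (front, rearview
#' mirror, meter) to `"Front"`. `"unknown"` maps to `NA`.
#'
#' @param zone Character vector of zone labels.
#' @return Character vector of `"Left"`, `"Right"`, `"Front"` or `NA`.
#' @export
judgment_flag <- function(zone) {
  fam <- rep(NA_character_, length(zone))
  fam[zone %in% c("left", "left back", "left mirror")] <- "Left"
  fam[zone %in% c("right", "right back", "right mirror")] <- "Right"
  fam[zone %in% c("front", "rearview mirror", "meter")] <- "Front"
  fam
}

#' Agreement between annotated situations and system judgment flags
#'
#' Compares a human annotation of the driving situation (`Left`, `Right`,
#' `Front`, or `Straight`, the latter equivalent to `Front`) with the
#' system's judgment flag, case-insensitively.
#'
#' @param situation Character vector of annotated situations.
#' @param flag Character vector of system flags.
#' @return List with `n_match`, `n`, and `rate` (percent, matched / total
#'   * 100).
#' @export
flag_agreement <- function(situation, flag) {
  if (length(situation) != length(flag))
    gr_stop("situation and flag vectors differ in length", "gr_argument_error")
  s <- tolower(situation)
  s[s == "straight"] <- "front"
  f <- tolower(flag)
  n_match <- sum(s == f, na.rm = TRUE)
  list(n_match = n_match, n = length(s), rate = 100 * n_match / length(s))
}
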