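#' Rectangular search region
#'
#' Half-open pixel rectangle `[x0, x1) x [y0, y1)` in 0-based image
#' coordinates (x rightward along columns, y downward along rows).
#'
#' @param x0,y0 Inclusive top-left corner.
#' @param x1,y1 Exclusive bottom-right corner.
#' @return A list of class `search_region`.
#' @export
search_region <- function(x0, y0, x1, y1) {
  x0 <- as.numeric(x0); y0 <- as.numeric(y0)
  x1 <- as.numeric(x1); y1 <- as.numeric(y1)
  if (!(x0 < x1 && y0 < y1))
    gr_stop("search region must satisfy x0 < x1 and y0 < y1", "gr_argument_error")
  structure(list(x0 = floor(x0), y0 = floor(y0), x1 = ceiling(x1), y1 = ceiling(y1)),
            class = "search_region")
}

#' @export
print.search_region <- function(x, ...) {
  cat(sprintf("<search_region [%d,%d) x [%d,%d)>\n", x$x0, x$x1, x$y0, x$y1))
  invisible(x)
}

full_frame_region <- function(frame_dim) {
  search_region(0, 0, frame_dim[2], frame_dim[1])
}

clip_region <- function(r, frame_dim) {
  x0 <- max(r$x0, 0); y0 <- max(r$y0, 0)
  x1 <- min(r$x1, frame_dim[2]); y1 <- min(r$y1, frame_dim[1])
  if (!(x0 < x1 && y0 < y1)) return(NULL)
  search_region(x0, y0, x1, y1)
}

region_fits <- function(r, template) {
  (r$x1 - r$x0) >= ncol(template) && (r$y1 - r$y0) >= nrow(template)
}

marker_detection <- function(marker_id, x, y, score, frame = NA_integer_) {
  data.frame(marker_id = as.integer(marker_id), x = as.numeric(x),
             y = as.numeric(y), score = as.numeric(score),
             frame = as.integer(frame))
}

empty_detections <- function() {
  marker_detection(integer(0), numeric(0), numeric(0), numeric(0), integer(0))
}

#' Locate a marker template inside a frame
#'
#' Scans the template over every anchor position inside `region` and scores
#' each placement with zero-normalised cross-correlation on grayscale
#' intensities (score clamped to \[0, 1\]; a flat window scores 0). The
#' maximum-score position is returned as a detection iff its score reaches
#' `threshold`; otherwise `NULL`. The reported `(x, y)` is the template's
#' top-left anchor in 0-based pixels. Ties on the maximum score resolve to
#' the smallest y, then smallest x.
#'
#' @param frame Grayscale matrix (rows = y).
#' @param template Grayscale matrix strictly smaller than the region.
#' @param region [search_region()]; defaults to the full frame.
#' @param threshold Similarity threshold in \[0, 1\] (default 0.70).
#' @param marker_id,frame_index Carried into the returned detection.
#' @return One-row detection data.frame (`marker_id`, `x`, `y`, `score`,
#'   `frame`) or `NULL` when no placement reaches the threshold.
#' @export
match_template <- function(frame, template, region = NULL, threshold = 0.70,
                           marker_id = NA_integer_, frame_index = NA_integer_) {
  if (is.null(region)) region <- full_frame_region(dim(frame))
  region <- clip_region(region, dim(frame))
  if (is.null(region) || !region_fits(region, template))
    gr_stop("template is larger than the search region", "gr_argument_error")
  sc <- ncc_scan_cpp(frame, template, region$x0, region$y0, region$x1, region$y1)
  best <- arrayInd(which.max(sc), dim(sc))
  s <- sc[best[1], best[2]]
  if (s < threshold) return(NULL)
  marker_detection(marker_id,
                   x = region$x0 + best[2] - 1L,
                   y = region$y0 + best[1] - 1L,
                   score = s, frame = frame_index)
}

# Exhaustive score map over a region (used by the search planner tests and
# as the raw interface for diagnostic tooling).
ncc_score_map <- function(frame, template, region = NULL) {
  if (is.null(region)) region <- full_frame_region(dim(frame))
  ncc_scan_cpp(frame, template, region$x0, region$y0, region$x1, region$y1)
}

lookup_pos <- function(detections, id) {
  if (is.null(detections) || nrow(detections) == 0) return(NULL)
  row <- detections[detections$marker_id == id, , drop = FALSE]
  if (nrow(row) == 0) return(NULL)
  row[1, , drop = FALSE]
}

#' Plan per-marker search regions for the next frame
#'
#' Implements the three search-space reductions used by the tracker:
#'
#' 1. *Ordering constraints* from the left-to-right marker layout:
#'    Marker2 lies right of Marker1; Marker3 right of Marker1 and Marker2;
#'    Marker4 right of Marker3; and Marker4 is never searched in a frame
#'    where Marker1 or Marker2 is present (they cannot be co-framed --
#'    applied in both directions, so Marker1/2 are likewise skipped right
#'    after Marker4 was seen). The same left-to-right order also bounds
#'    each marker's window on the right by the last known positions of its
#'    right-hand neighbours.
#' 2. *Tracking windows*: a marker seen in the previous frame is searched in
#'    a window of half-width `margin` around its last position.
#' 3. *Motion extension*: when the marker was also seen two frames back, the
#'    window is grown along the inter-frame displacement vector by
#'    `extension_gain` times the displacement magnitude (per axis), so a
#'    marker sweeping across the scene during a head turn stays inside the
#'    search range.
#'
#' Ordering positions are taken from markers already found in the current
#' frame (`found`) when available, else from the previous frame. With no
#' information at all the plan degenerates to a full-frame search.
#'
#' @param prev,prev2 Detections from frames t-1 and t-2 (possibly empty).
#' @param frame_dim `dim(frame)`, i.e. `c(height, width)`.
#' @param templates Named list of template matrices (for window sizing).
#' @param margin Window half-width in px.
#' @param extension_gain Motion extension multiplier.
#' @param found Detections already made in the current frame.
#' @return Named list `"1"`..`"4"`; each element is a list of
#'   [search_region()]s (empty when the marker must be skipped).
#' @export
plan_search_regions <- function(prev = NULL, prev2 = NULL, frame_dim,
                                templates, margin = 48, extension_gain = 1.5,
                                found = NULL) {
  out <- list(`1` = list(), `2` = list(), `3` = list(), `4` = list())
  ord_pos <- function(id) lookup_pos(found, id) %||% lookup_pos(prev, id)

  for (id in 1:4) {
    tmpl <- templates[[as.character(id)]]
    tw <- ncol(tmpl); th <- nrow(tmpl)

    # Marker4 sits beyond the frame edge when markers 1/2 are in view,
    # and vice versa: the pairs {1,2} and {4} are never co-framed.
    if (id == 4L) {
      if (!is.null(ord_pos(1L)) || !is.null(ord_pos(2L))) next
    } else if (id %in% c(1L, 2L)) {
      if (!is.null(ord_pos(4L))) next
    }

    pm <- lookup_pos(prev, id)
    if (!is.null(pm)) {
      x0 <- pm$x - margin; x1 <- pm$x + tw + margin
      y0 <- pm$y - margin; y1 <- pm$y + th + margin
      p2 <- lookup_pos(prev2, id)
      if (!is.null(p2)) {
        dx <- pm$x - p2$x; dy <- pm$y - p2$y
        if (dx > 0) x1 <- x1 + extension_gain * dx else x0 <- x0 + extension_gain * dx
        if (dy > 0) y1 <- y1 + extension_gain * dy else y0 <- y0 + extension_gain * dy
      }
    } else {
      x0 <- 0; y0 <- 0; x1 <- frame_dim[2]; y1 <- frame_dim[1]
    }

    # ordering: each marker lies strictly right of its left-hand
    # neighbours and strictly left of its right-hand ones
    left_ids <- switch(as.character(id), `1` = integer(0), `2` = 1L,
                       `3` = c(1L, 2L), `4` = 3L)
    right_ids <- switch(as.character(id), `1` = 2:3, `2` = 3L,
                        `3` = 4L, `4` = integer(0))
    for (lid in left_ids) {
      lp <- ord_pos(lid)
      if (!is.null(lp)) x0 <- max(x0, lp$x + 1)
    }
    for (rid in right_ids) {
      rp <- ord_pos(rid)
      if (!is.null(rp)) x1 <- min(x1, rp$x - 1 + tw)
    }

    r <- tryCatch(clip_region(search_region(x0, y0, x1, y1), frame_dim),
                  error = function(e) NULL)
    if (is.null(r) || !region_fits(r, tmpl)) {
      # degenerate window: fall back to the constrained frame portion
      x0f <- 0
      for (lid in left_ids) {
        lp <- ord_pos(lid)
        if (!is.null(lp)) x0f <- max(x0f, lp$x + 1)
      }
      r <- tryCatch(clip_region(search_region(x0f, 0, frame_dim[2], frame_dim[1]),
                                frame_dim), error = function(e) NULL)
      if (is.null(r) || !region_fits(r, tmpl)) next
    }
    out[[as.character(id)]] <- list(r)
  }
  out
}

#' Split a search region into three vertically expanded bands
#'
#' A driver's head rarely pitches far, so a marker is most likely near the
#' vertical centre of its search range. The region is cut into three
#' horizontal bands, each then grown vertically by `template_height - 1`
#' pixels on both sides (clipped to the region) so that a marker straddling
#' a band boundary is still fully contained in at least one band. Bands are
#' returned in the search order: centre, upper, bottom.
#'
#' @param region [search_region()] with height >= 3 px.
#' @param template_height Template height in px.
#' @return List of three [search_region()]s, ordered centre, upper, bottom.
#' @export
split_into_sections <- function(region, template_height) {
  h <- region$y1 - region$y0
  if (h < 3) gr_stop("region height must be at least 3 px", "gr_argument_error")
  e <- template_height - 1
  b1 <- region$y0 + floor(h / 3)
  b2 <- region$y0 + floor(2 * h / 3)
  band <- function(lo, hi) {
    search_region(region$x0, max(region$y0, lo - e),
                  region$x1, min(region$y1, hi + e))
  }
  list(center = band(b1, b2),
       upper = band(region$y0, b1),
       bottom = band(b2, region$y1))
}

# Search one marker inside its planned regions, section by section, and
# return the first detection whose score reaches the threshold.
search_marker <- function(frame, template, regions, threshold,
                          marker_id, frame_index) {
  for (r in regions) {
    sections <- if ((r$y1 - r$y0) >= 3 && (r$y1 - r$y0) > 3 * nrow(template)) {
      split_into_sections(r, nrow(template))
    } else {
      list(r)
    }
    for (s in sections) {
      if (!region_fits(s, template)) next
      det <- match_template(frame, template, s, threshold,
                            marker_id = marker_id, frame_index = frame_index)
      if (!is.null(det)) return(det)
    }
  }
  NULL
}
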