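#' Camera model for the wearable view camera
#'
#' The view camera is described by its pixel resolution and its horizontal
#' and vertical viewing angles. The degrees-per-pixel ratios
#' `fov_x / width` and `fov_y / height` convert marker displacements in
#' pixels to head angles in degrees, so both must be supplied explicitly:
#' they are properties of the recording hardware, not constants of the
#' method.
#'
#' @param width,height Frame size in pixels.
#' @param fov_x,fov_y Horizontal and vertical viewing angle in degrees,
#'   each in (0, 180).
#' @return A list of class `camera_model`.
#' @examples
#' camera_model(640, 480, 80, 60)
#' @export
camera_model <- function(width, height, fov_x, fov_y) {
  if (!is_count(width) || !is_count(height))
    gr_stop("camera width/height must be positive integers", "gr_config_error")
  for (fov in c(fov_x, fov_y)) {
    if (!is.numeric(fov) || length(fov) != 1L || !is.finite(fov) || fov <= 0 || fov >= 180)
      gr_stop("camera viewing angles must lie in (0, 180) degrees", "gr_config_error")
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         fov_x = as.numeric(fov_x), fov_y = as.numeric(fov_y)),
    class = "camera_model"
  )
}

zone_vocabulary <- function() {
  c("front", "rearview mirror", "meter", "right mirror", "right",
    "right back", "left mirror", "left", "left back")
}

#' Default session configuration
#'
#' Returns the fully spelled-out defaults for every tunable of the pipeline.
#' The camera block and the marker template paths are deliberately absent:
#' they describe the recording hardware and must come from the session's own
#' config file.
#'
#' @return A named list of defaults (similarity threshold, search-window
#'   margin and motion extension gain, histogram bin width, range threshold,
#'   frame rate, marker layout ratio).
#' @export
default_session_config <- function() {
  list(
    similarity_threshold = 0.70,   # accept a match only above this NCC score
    search = list(margin = 48,     # px half-width of the tracking window
                  extension_gain = 1.5),
    bin_width = 5,                 # deg, gaze histogram
    range_threshold = 0.05,        # fraction of the peak marginal count
    frame_rate = 10,               # frames / s of the view camera
    calibration = list(n_frames = 50)
  )
}

#' Validate an in-memory session configuration
#'
#' Applies the same schema checks as [read_session_config()] to a config
#' assembled in code: required camera block, exactly four markers with
#' template paths, positive layout ratio; tunables are filled from
#' [default_session_config()].
#'
#' @param cfg Config list.
#' @return The validated config (camera coerced to [camera_model()]).
#' @export
validate_session_config <- function(cfg) {
  req <- function(ok, what) if (!ok) gr_stop(paste0("config: ", what), "gr_config_error")
  req(is.list(cfg), "must be a list")
  req(!is.null(cfg$camera), "missing required field 'camera'")
  cam <- cfg$camera
  for (f in c("width", "height", "fov_x", "fov_y"))
    req(!is.null(cam[[f]]), paste0("camera is missing required field '", f, "'"))
  cfg$camera <- camera_model(cam$width, cam$height, cam$fov_x, cam$fov_y)

  req(!is.null(cfg$markers), "missing required field 'markers'")
  req(length(cfg$markers) == 4L, "exactly 4 markers are required")
  ids <- vapply(cfg$markers, function(m) as.integer(m$id %||% NA_integer_), integer(1))
  req(identical(sort(ids), 1:4), "marker ids must be exactly 1..4")
  for (m in cfg$markers)
    req(!is.null(m$template), paste0("marker ", m$id, " is missing its 'template' path"))

  req(!is.null(cfg$layout), "missing required field 'layout'")
  a <- cfg$layout$alpha; b <- cfg$layout$beta
  req(!is.null(a) && !is.null(b), "layout must give the inter-marker ratio 'alpha' and 'beta'")
  req(is.numeric(a) && is.numeric(b) && a > 0 && b > 0, "layout alpha and beta must be > 0")

  dft <- default_session_config()
  for (f in names(dft)) cfg[[f]] <- cfg[[f]] %||% dft[[f]]
  st <- cfg$similarity_threshold
  req(is.numeric(st) && st >= 0 && st <= 1, "similarity_threshold must lie in [0, 1]")
  req(is.numeric(cfg$bin_width) && cfg$bin_width > 0, "bin_width must be > 0")
  rt <- cfg$range_threshold
  req(is.numeric(rt) && rt > 0 && rt < 1, "range_threshold must lie in (0, 1)")
  cfg$search$margin <- cfg$search$margin %||% dft$search$margin
  cfg$search$extension_gain <- cfg$search$extension_gain %||% dft$search$extension_gain

  if (!is.null(cfg$zones)) {
    labs <- vapply(cfg$zones, function(z) as.character(z$label %||% NA_character_), character(1))
    req(all(labs %in% zone_vocabulary()),
        paste0("zone labels must be drawn from: ", paste(zone_vocabulary(), collapse = ", ")))
  }
  cfg
}

#' Read a session configuration (YAML or JSON)
#'
#' Required fields are the camera block (`width`, `height`, `fov_x`,
#' `fov_y`), exactly four `markers` entries (id + template path) and the
#' `layout` ratio `alpha`/`beta` used to extrapolate the off-screen marker
#' reference. Any missing required field raises a config error; tunables
#' absent from the file take the [default_session_config()] values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated config list (camera coerced to [camera_model()]).
#' @export
read_session_config <- function(path) {
  if (!file.exists(path))
    gr_stop(paste0("config file not found: ", path), "gr_config_error")
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    gr_stop("config must be a .yaml/.yml or .json file", "gr_config_error")
  }
  cfg <- validate_session_config(cfg)
  attr(cfg, "config_dir") <- dirname(normalizePath(path))
  cfg
}

#' Write a session configuration to YAML
#' @param config Config list as returned by [read_session_config()].
#' @param path Output path (`.yaml`).
#' @export
write_session_config <- function(config, path) {
  config$camera <- unclass(config$camera)
  attr(config, "config_dir") <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}

read_strict_csv <- function(path, required, what) {
  if (!file.exists(path))
    gr_stop(paste0(what, " file not found: ", path), "gr_schema_error")
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    gr_stop(paste0(what, " CSV is missing required column(s): ",
                   paste(missing, collapse = ", ")), "gr_schema_error")
  raw
}

numeric_column <- function(raw, col, what) {
  x <- suppressWarnings(as.numeric(raw[[col]]))
  bad <- which(is.na(x) & !is.na(raw[[col]]) & nzchar(trimws(raw[[col]])))
  if (length(bad) > 0)
    gr_stop(paste0(what, " CSV: non-numeric value '", raw[[col]][bad[1]],
                   "' in column '", col, "', data row ", bad[1]), "gr_parse_error")
  if (anyNA(x))
    gr_stop(paste0(what, " CSV: empty/NA value in column '", col, "', data row ",
                   which(is.na(x))[1]), "gr_parse_error")
  x
}

#' Read an eye-angle time series
#'
#' Expects the columns `t` (seconds), `x_eye` (deg, subject's right
#' positive) and `y_eye` (deg, up positive) as exported from a
#' pupil-tracking eye tracker. Rows are returned sorted by time (stable);
#' the row count is preserved. Angles must be finite and within the
#' device range of +/-180 degrees.
#'
#' @param path CSV path.
#' @return data.frame with columns `t`, `x_eye`, `y_eye`.
#' @export
read_eye_csv <- function(path) {
  raw <- read_strict_csv(path, c("t", "x_eye", "y_eye"), "eye")
  out <- data.frame(
    t = numeric_column(raw, "t", "eye"),
    x_eye = numeric_column(raw, "x_eye", "eye"),
    y_eye = numeric_column(raw, "y_eye", "eye")
  )
  if (nrow(out) > 0) {
    if (any(!is.finite(out$x_eye)) || any(!is.finite(out$y_eye)))
      gr_stop("eye CSV: angles must be finite", "gr_schema_error")
    if (any(abs(out$x_eye) > 180) || any(abs(out$y_eye) > 180))
      gr_stop("eye CSV: angles exceed the +/-180 degree device range", "gr_schema_error")
    out <- out[order(out$t), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' @rdname read_eye_csv
#' @param eye data.frame with columns `t`, `x_eye`, `y_eye`.
#' @export
write_eye_csv <- function(eye, path) {
  stopifnot(all(c("t", "x_eye", "y_eye") %in% names(eye)))
  utils::write.csv(eye[, c("t", "x_eye", "y_eye")], path, row.names = FALSE)
  invisible(path)
}

#' Read / write a head-pose time series
#'
#' Columns: `frame` (0-based index), `yaw`, `pitch`, `roll` (deg) and
#' `valid` (0/1; frames where no marker was accepted carry NA angles).
#'
#' @param path CSV path.
#' @return data.frame with columns `frame`, `yaw`, `pitch`, `roll`, `valid`.
#' @export
read_head_csv <- function(path) {
  raw <- read_strict_csv(path, c("frame", "yaw", "pitch", "roll", "valid"), "head")
  n <- nrow(raw)
  num_or_na <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    x
  }
  out <- data.frame(
    frame = numeric_column(raw, "frame", "head"),
    yaw = num_or_na("yaw"), pitch = num_or_na("pitch"), roll = num_or_na("roll"),
    valid = numeric_column(raw, "valid", "head") != 0
  )
  if (n > 0 && any(out$valid & (is.na(out$yaw) | is.na(out$pitch) | is.na(out$roll))))
    gr_stop("head CSV: valid rows must carry finite angles", "gr_schema_error")
  out
}

#' @rdname read_head_csv
#' @param head data.frame as returned by [track_session()].
#' @export
write_head_csv <- function(head, path) {
  stopifnot(all(c("frame", "yaw", "pitch", "roll", "valid") %in% names(head)))
  out <- head
  out$valid <- as.integer(out$valid)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a fused gaze time series
#'
#' Columns: `t` (s), `x_gaze`, `y_gaze` (deg), `zone` (one of the nine
#' area labels, or "unknown") and `valid` (0/1).
#'
#' @param path CSV path.
#' @return data.frame with columns `t`, `x_gaze`, `y_gaze`, `zone`, `valid`.
#' @export
read_gaze_csv <- function(path) {
  raw <- read_strict_csv(path, c("t", "x_gaze", "y_gaze", "zone", "valid"), "gaze")
  data.frame(
    t = numeric_column(raw, "t", "gaze"),
    x_gaze = suppressWarnings(as.numeric(raw$x_gaze)),
    y_gaze = suppressWarnings(as.numeric(raw$y_gaze)),
    zone = as.character(raw$zone),
    valid = numeric_column(raw, "valid", "gaze") != 0
  )
}

#' @rdname read_gaze_csv
#' @param gaze data.frame as returned by [fuse()].
#' @export
write_gaze_csv <- function(gaze, path) {
  stopifnot(all(c("t", "x_gaze", "y_gaze", "zone", "valid") %in% names(gaze)))
  out <- gaze[, c("t", "x_gaze", "y_gaze", "zone", "valid")]
  out$valid <- as.integer(out$valid)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

# Read one image file (PNG) as a grayscale matrix in [0, 1], rows = y.
read_image <- function(path) {
  if (!file.exists(path))
    gr_stop(paste0("image file not found: ", path), "gr_config_error")
  img <- png::readPNG(path)
  as_gray(img)
}

as_gray <- function(img) {
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    if (nch >= 3) {
      img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      img <- img[, , 1]
    }
  }
  img
}

write_image <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  png::writePNG(img, path)
  invisible(path)
}

#' Load the four marker template images
#'
#' Resolves the template paths in the config (relative to the config file's
#' directory when the config was read from disk, else to `base_dir`), reads
#' each PNG as a grayscale matrix in \[0, 1\], and checks that every patch is
#' strictly smaller than the camera frame.
#'
#' @param config Validated session config.
#' @param base_dir Directory against which relative template paths are
#'   resolved. Defaults to the config file's own directory.
#' @return Named list `"1"`..`"4"` of grayscale matrices.
#' @export
load_templates <- function(config, base_dir = NULL) {
  base_dir <- base_dir %||% attr(config, "config_dir") %||% "."
  cam <- config$camera
  out <- vector("list", 4L)
  names(out) <- as.character(1:4)
  for (m in config$markers) {
    p <- m$template
    if (!file.exists(p)) p <- file.path(base_dir, m$template)
    if (!file.exists(p))
      gr_stop(paste0("template for marker ", m$id, " not found: ", m$template),
              "gr_config_error")
    img <- read_image(p)
    if (length(img) == 0)
      gr_stop(paste0("template for marker ", m$id, " is empty"), "gr_config_error")
    if (nrow(img) >= cam$height || ncol(img) >= cam$width)
      gr_stop(paste0("template for marker ", m$id,
                     " is not smaller than the camera frame"), "gr_config_error")
    out[[as.character(m$id)]] <- img
  }
  out
}
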