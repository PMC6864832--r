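#' Build the 2-D gaze histogram
#'
#' Valid gaze samples are binned on a square grid of `bin_width` degrees.
#' Bin edges are aligned to multiples of the bin width and each bin is
#' half-open `[edge, edge + bin_width)`, so a sample sitting exactly on an
#' edge falls into the upper bin. Counts conserve the number of valid
#' samples.
#'
#' @param gaze data.frame with `x_gaze`, `y_gaze` and optionally `valid`.
#' @param bin_width Bin width in degrees (> 0).
#' @return A `gaze_histogram`: list with `bin_width`, `x_edges`, `y_edges`,
#'   `counts` (matrix, rows = x bins, cols = y bins) and `n`.
#' @export
build_histogram <- function(gaze, bin_width = 5) {
  if (!(is.numeric(bin_width) && bin_width > 0))
    gr_stop("bin_width must be > 0", "gr_argument_error")
  valid <- if ("valid" %in% names(gaze)) gaze$valid else rep(TRUE, nrow(gaze))
  x <- gaze$x_gaze[valid & !is.na(gaze$x_gaze) & !is.na(gaze$y_gaze)]
  y <- gaze$y_gaze[valid & !is.na(gaze$x_gaze) & !is.na(gaze$y_gaze)]
  if (length(x) == 0)
    gr_stop("no valid gaze samples: cannot build a histogram", "gr_empty_session_error")

  edges_for <- function(v) {
    lo <- floor(min(v) / bin_width) * bin_width
    nb <- floor((max(v) - lo) / bin_width) + 1
    lo + bin_width * (0:nb)
  }
  xe <- edges_for(x)
  ye <- edges_for(y)
  ix <- floor((x - xe[1]) / bin_width) + 1
  iy <- floor((y - ye[1]) / bin_width) + 1
  nx <- length(xe) - 1
  ny <- length(ye) - 1
  counts <- matrix(0L, nrow = nx, ncol = ny)
  tab <- table(factor(ix, levels = 1:nx), factor(iy, levels = 1:ny))
  counts[] <- as.integer(tab)
  structure(list(bin_width = bin_width, x_edges = xe, y_edges = ye,
                 counts = counts, n = length(x)),
            class = "gaze_histogram")
}

#' @export
print.gaze_histogram <- function(x, ...) {
  cat(sprintf("<gaze_histogram: %d samples, %d x %d bins of %g deg>\n",
              x$n, nrow(x$counts), ncol(x$counts), x$bin_width))
  invisible(x)
}

#' Per-axis Gaussian fit of the gaze distribution
#'
#' Fits an independent normal distribution to each gaze axis (maximum
#' likelihood mean, sample standard deviation) and reports the 95%
#' interval `mu +/- 1.96 sigma` per axis. This is the smooth companion of
#' the histogram-threshold range rule: wide intervals mean a wide gaze
#' range.
#'
#' @param gaze data.frame with `x_gaze`, `y_gaze` and optionally `valid`.
#' @return List with `mu_x`, `mu_y`, `sigma_x`, `sigma_y`, `ci_x`, `ci_y`
#'   (each `c(lo, hi)`), and `n`.
#' @export
fit_gaussian <- function(gaze) {
  valid <- if ("valid" %in% names(gaze)) gaze$valid else rep(TRUE, nrow(gaze))
  x <- gaze$x_gaze[valid & !is.na(gaze$x_gaze)]
  y <- gaze$y_gaze[valid & !is.na(gaze$y_gaze)]
  if (length(x) < 3)
    gr_stop("Gaussian fit needs at least 3 valid samples", "gr_degenerate_error")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    gr_stop("degenerate fit: zero variance on one axis", "gr_degenerate_error")
  z <- stats::qnorm(0.975)
  mx <- mean(x); my <- mean(y)
  list(mu_x = mx, mu_y = my, sigma_x = sx, sigma_y = sy,
       ci_x = c(mx - z * sx, mx + z * sx),
       ci_y = c(my - z * sy, my + z * sy),
       n = length(x))
}

#' Gaze range from the peak-relative histogram threshold
#'
#' The headline gaze-range statistic. The 2-D histogram is marginalised
#' per axis; on each axis the bins whose marginal count reaches
#' `threshold` times the peak marginal count are kept, and the range is
#' the span of the outer edges of the kept bins: `X = Xmax - Xmin` on the
#' horizontal axis, `Y = Ymax - Ymin` on the vertical, and the gaze range
#' area is `X * Y` (deg^2). The threshold is peak-relative, so scaling
#' every count leaves the result unchanged; the peak bin always
#' qualifies, so the result is never empty.
#'
#' For gaze drawn from a Gaussian with axis spread sigma and fine bins,
#' the marginal falls to 5% of its peak at `sigma * sqrt(2 * ln 20) =
#' 2.448 sigma`, so X approaches `2 * 2.448 sigma`.
#'
#' @param hist A [build_histogram()] result.
#' @param threshold Fraction of the peak marginal count in (0, 1), default
#'   0.05.
#' @param gauss Optional [fit_gaussian()] result carried into the output.
#' @return A `gaze_range_result`: list with `Xmax`, `Xmin`, `Ymax`,
#'   `Ymin`, `X`, `Y`, `area`, `gauss`, `n_samples`.
#' @export
range_from_threshold <- function(hist, threshold = 0.05, gauss = NULL) {
  if (!(is.numeric(threshold) && threshold > 0 && threshold < 1))
    gr_stop("threshold must lie in (0, 1)", "gr_argument_error")
  mx <- rowSums(hist$counts)
  my <- colSums(hist$counts)
  keep_x <- which(mx >= threshold * max(mx))
  keep_y <- which(my >= threshold * max(my))
  xmin <- hist$x_edges[min(keep_x)]
  xmax <- hist$x_edges[max(keep_x) + 1]
  ymin <- hist$y_edges[min(keep_y)]
  ymax <- hist$y_edges[max(keep_y) + 1]
  X <- xmax - xmin
  Y <- ymax - ymin
  structure(list(Xmax = xmax, Xmin = xmin, Ymax = ymax, Ymin = ymin,
                 X = X, Y = Y, area = X * Y, gauss = gauss,
                 n_samples = hist$n, threshold = threshold,
                 bin_width = hist$bin_width),
            class = "gaze_range_result")
}

#' @export
print.gaze_range_result <- function(x, ...) {
  cat(sprintf(paste0("<gaze_range: X = %.1f deg [%.1f, %.1f], ",
                     "Y = %.1f deg [%.1f, %.1f], area = %.0f deg^2, n = %d>\n"),
              x$X, x$Xmin, x$Xmax, x$Y, x$Ymin, x$Ymax, x$area, x$n_samples))
  invisible(x)
}

#' One-call gaze range of a session
#'
#' Convenience wrapper: histogram + threshold rule + per-axis Gaussian
#' fit.
#'
#' @param gaze data.frame with `x_gaze`, `y_gaze`, optionally `valid`.
#' @param bin_width Histogram bin width (deg).
#' @param threshold Peak-relative threshold fraction.
#' @return A `gaze_range_result` (see [range_from_threshold()]).
#' @export
gaze_range <- function(gaze, bin_width = 5, threshold = 0.05) {
  h <- build_histogram(gaze, bin_width)
  g <- tryCatch(fit_gaussian(gaze), gazerange_error = function(e) NULL)
  range_from_threshold(h, threshold, gauss = g)
}

#' Compare gaze ranges across subjects
#'
#' Tabulates X, Y and area per subject and the area ratio to a designated
#' reference subject (for a driving evaluation, typically the
#' instructor). Subjects whose area falls below `narrow_fraction` of the
#' reference area are flagged as narrow.
#'
#' @param results Named list of `gaze_range_result`s (>= 2, unique names).
#' @param reference Name of the reference subject (default: first name).
#' @param narrow_fraction Flagging threshold on the area ratio (default
#'   0.5).
#' @return data.frame: `subject`, `X`, `Y`, `area`, `area_ratio`,
#'   `narrow`; the reference row first, remaining subjects in name order.
#' @export
compare_subjects <- function(results, reference = NULL, narrow_fraction = 0.5) {
  if (length(results) < 2)
    gr_stop("compare_subjects needs at least two subjects", "gr_argument_error")
  nm <- names(results)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    gr_stop("subject names must be present and unique", "gr_argument_error")
  reference <- reference %||% nm[1]
  if (!reference %in% nm)
    gr_stop(paste0("reference subject not found: ", reference), "gr_argument_error")
  ord <- c(reference, sort(setdiff(nm, reference)))
  ref_area <- results[[reference]]$area
  out <- do.call(rbind, lapply(ord, function(s) {
    r <- results[[s]]
    data.frame(subject = s, X = r$X, Y = r$Y, area = r$area,
               area_ratio = r$area / ref_area)
  }))
  out$narrow <- out$area_ratio < narrow_fraction
  rownames(out) <- NULL
  out
}

#' Write a per-subject gaze-range report
#'
#' @param comparison data.frame from [compare_subjects()].
#' @param path Output path; `.json` writes JSON, anything else CSV.
#' @export
write_range_report <- function(comparison, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(comparison, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE)
  } else {
    utils::write.csv(comparison, path, row.names = FALSE)
  }
  invisible(path)
}
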