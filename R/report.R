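gr_extdata <- function(name) {
  p <- system.file("extdata", name, package = "gazerange")
  if (p == "")
    gr_stop(paste0("bundled data file not found: ", name), "gr_config_error")
  p
}

#' Bundled validation records of the reference marker-based gaze system
#'
#' Three small datasets recorded with the reference implementation of this
#' measurement method, bundled for report-generator validation and as
#' worked-example inputs:
#'
#' * `indoor_error_table()` -- indoor accuracy check: a seated subject
#'   fixated wall targets at known head angles (10-60 deg in 10 deg
#'   steps); columns `true_deg`, `error_deg` (absolute head-angle error).
#' * `recognition_rate_table()` -- per-marker template-matching
#'   recognition rates from the same campaign; columns `marker_id`,
#'   `marker`, `rate_pct`.
#' * `judgment_log()` -- 30 on-road gaze judgments sampled around turns
#'   and straight driving: annotated situation, eye / head / gaze angles
#'   (deg) and the system's judgment flag. `judgment_error = 1` marks the
#'   two samples whose flag was wrong (one template-matching failure, one
#'   eye-measurement failure); for those rows the printed gaze values are
#'   not trustworthy.
#'
#' @return A data.frame.
#' @export
indoor_error_table <- function() {
  utils::read.csv(gr_extdata("indoor_head_angle_errors.csv"))
}

#' @rdname indoor_error_table
#' @export
recognition_rate_table <- function() {
  utils::read.csv(gr_extdata("marker_recognition_rates.csv"))
}

#' @rdname indoor_error_table
#' @export
judgment_log <- function() {
  utils::read.csv(gr_extdata("onroad_judgment_log.csv"))
}

#' Aggregate summaries for accuracy reports
#'
#' `mean_head_angle_error()` averages per-target absolute head-angle
#' errors; `mean_recognition_rate()` averages per-marker recognition
#' rates; `judgment_agreement()` scores a judgment log's situation
#' annotations against the system flags via [flag_agreement()]
#' (Straight is equivalent to Front).
#'
#' @param errors data.frame with column `error_deg`.
#' @return Mean error in degrees.
#' @export
mean_head_angle_error <- function(errors = indoor_error_table()) {
  mean(errors$error_deg)
}

#' @rdname mean_head_angle_error
#' @param rates data.frame with column `rate_pct`.
#' @export
mean_recognition_rate <- function(rates = recognition_rate_table()) {
  mean(rates$rate_pct)
}

#' @rdname mean_head_angle_error
#' @param log data.frame with columns `situation` and `flag`.
#' @export
judgment_agreement <- function(log = judgment_log()) {
  flag_agreement(log$situation, log$flag)
}
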