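# Shared helpers used across modules.

#' Weighted weekly average of weekday and weekend minutes per day
#'
#' Combines weekday and weekend-day values into a whole-week average using
#' the 5/2 weighting: `(5 * weekday + 2 * weekend) / 7`. The same formula is
#' applied to questionnaire scores and to accelerometer-derived sedentary
#' time so the two instruments are compared on an identical scale.
#'
#' @param weekday_min Weekday value in minutes per day.
#' @param weekend_min Weekend-day value in minutes per day.
#' @return Weekly average in minutes per day.
#' @export
#' @examples
#' weekly_total(100, 170) # 120
weekly_total <- function(weekday_min, weekend_min) {
  (5 * weekday_min + 2 * weekend_min) / 7
}

#' Classify total sedentary time against the 120 min/day guideline
#'
#' Flags whether a weekly-average sedentary time meets the recommended
#' limit of less than 120 min/day (2 h/day) of screen/sitting time. The
#' default rule is strict (`total < limit`); an inclusive rule
#' (`total <= limit`) is available because published tabulations sometimes
#' state the limit as "<= 120".
#'
#' @param total_min Total sedentary time, minutes per day. Must be >= 0.
#' @param limit Guideline limit in minutes per day (default 120).
#' @param inclusive If `TRUE`, use `<=` instead of the default strict `<`.
#' @return Logical vector: `TRUE` when the guideline is met.
#' @export
#' @examples
#' classify_guideline(c(119.9, 120, 0))
classify_guideline <- function(total_min, limit = 120, inclusive = FALSE) {
  if (!is.numeric(total_min)) {
    stop("`total_min` must be numeric", call. = FALSE)
  }
  if (any(total_min < 0, na.rm = TRUE)) {
    stop("sedentary time cannot be negative", call. = FALSE)
  }
  if (inclusive) total_min <= limit else total_min < limit
}

# Round half away from zero (base round() rounds half to even). Report
# percentages use this so printed rates match conventional rounding.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Error constructors: condition classes let callers distinguish bad input
# from legitimately insufficient data.
stop_insufficient_data <- function(msg) {
  stop(errorCondition(msg, class = c("sedvalid_insufficient_data", "error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("sedvalid_config_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
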