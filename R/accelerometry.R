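# Reduction of epoch-level accelerometer counts to daily and weekly
# sedentary time. Thresholds follow the standard uniaxial waist-worn
# protocol for youth: counts are aggregated to counts per minute (cpm),
# minutes above 20,000 cpm are excluded as device malfunction, runs of
# zero cpm longer than 20 min are excluded as non-wear, and sedentary
# time is the worn time accumulated below 100 cpm. All cut-points are
# applied with strict inequalities ("more than", "lower than").

#' Construct an epoch-level count series
#'
#' Container for one participant's raw accelerometer export: activity
#' counts at a fixed epoch length with a start timestamp, plus the device
#' delivery and return dates (those calendar days are excluded from
#' analysis because they hold partial protocols).
#'
#' @param participant_id Participant identifier.
#' @param start `POSIXct` timestamp of the first epoch.
#' @param counts Integer vector of non-negative epoch counts.
#' @param epoch_length Epoch length in seconds; must divide 60. Default 5.
#' @param delivery_date,return_date `Date` the monitor was handed out /
#'   collected, or `NULL` when unknown.
#' @return An object of class `count_epoch_series`.
#' @export
count_epoch_series <- function(participant_id, start, counts, epoch_length = 5L,
                               delivery_date = NULL, return_date = NULL) {
  if (!inherits(start, "POSIXct")) {
    stop("`start` must be POSIXct", call. = FALSE)
  }
  counts <- as.numeric(counts)
  if (any(counts < 0) || anyNA(counts)) {
    stop("epoch counts must be non-negative and non-missing", call. = FALSE)
  }
  structure(
    list(
      participant_id = participant_id,
      start = start,
      epoch_length = as.integer(epoch_length),
      counts = counts,
      delivery_date = delivery_date,
      return_date = return_date
    ),
    class = "count_epoch_series"
  )
}

#' @export
print.count_epoch_series <- function(x, ...) {
  cat(
    sprintf(
      "<count_epoch_series> participant %s: %d epochs of %d s from %s\n",
      x$participant_id, length(x$counts), x$epoch_length, format(x$start)
    )
  )
  invisible(x)
}

#' Aggregate epoch counts to counts per minute
#'
#' Sums each block of `60 / epoch_length` consecutive epochs into one
#' minute. A trailing incomplete minute is dropped. All intensity
#' thresholds downstream are defined on the cpm scale.
#'
#' @param series A [count_epoch_series()].
#' @return A tibble with one row per complete minute: `participant_id`,
#'   `time` (minute start), `date`, `cpm`, and flag columns `malfunction`
#'   (initialised `FALSE`) and `wear` (initialised `TRUE`).
#' @export
aggregate_to_minutes <- function(series) {
  stopifnot(inherits(series, "count_epoch_series"))
  k <- 60L %/% series$epoch_length
  if (series$epoch_length * k != 60L) {
    stop("epoch length must divide 60 seconds", call. = FALSE)
  }
  n_min <- length(series$counts) %/% k
  if (n_min == 0L) {
    return(tibble::tibble(
      participant_id = character(), time = as.POSIXct(character()),
      date = as.Date(character()), cpm = numeric(),
      malfunction = logical(), wear = logical()
    ))
  }
  used <- series$counts[seq_len(n_min * k)]
  cpm <- as.numeric(rowsum(used, rep(seq_len(n_min), each = k)))
  time <- series$start + (seq_len(n_min) - 1L) * 60
  tibble::tibble(
    participant_id = series$participant_id,
    time = time,
    date = as.Date(time, tz = attr(series$start, "tzone") %||% "UTC"),
    cpm = cpm,
    malfunction = FALSE,
    wear = TRUE
  )
}

#' Flag minutes with implausibly high counts as malfunction
#'
#' Minutes with strictly more than `threshold` cpm (default 20,000) are
#' marked as potential device malfunction and excluded from wear and
#' sedentary tallies. The exclusion is per minute, not per day.
#'
#' @param minutes Minute-level tibble from [aggregate_to_minutes()].
#' @param threshold Malfunction cut-point in cpm; a minute exactly at the
#'   threshold is retained.
#' @return `minutes` with the `malfunction` column set.
#' @export
flag_malfunction <- function(minutes, threshold = 20000) {
  minutes$malfunction <- minutes$cpm > threshold
  minutes
}

#' Detect non-wear time from long zero-count runs
#'
#' Maximal runs of consecutive zero-cpm minutes strictly longer than
#' `max_zero_run` minutes (default 20) are flagged as non-wear. Shorter
#' zero runs remain wear time, and any non-zero minute breaks a run (no
#' interruption tolerance). Runs are assessed on the continuous minute
#' stream, so a zero run spanning midnight counts as one run.
#'
#' @param minutes Minute-level tibble with malfunction flags already set.
#' @param max_zero_run Longest zero run (minutes) still considered wear.
#' @return `minutes` with the `wear` column set (`FALSE` during non-wear).
#' @export
detect_nonwear <- function(minutes, max_zero_run = 20) {
  if (nrow(minutes) == 0L) {
    return(minutes)
  }
  r <- rle(minutes$cpm == 0)
  nonwear_run <- r$values & r$lengths > max_zero_run
  minutes$wear <- !rep(nonwear_run, r$lengths)
  minutes
}

day_type_of <- function(date) {
  # ISO weekday: Mon-Fri = weekday, Sat-Sun = weekend
  wd <- as.POSIXlt(date)$wday # 0 = Sunday
  ifelse(wd %in% 1:5, "weekday", "weekend")
}

#' Summarise flagged minutes into per-day wear and sedentary time
#'
#' Wear minutes are worn, non-malfunction minutes; sedentary minutes are
#' the worn minutes with cpm strictly below 100 (a minute at exactly
#' 100 cpm is non-sedentary). Day type is taken from the calendar
#' (Monday-Friday weekday, Saturday-Sunday weekend), with day boundaries
#' at local midnight.
#'
#' @param minutes Minute-level tibble with `malfunction` and `wear` set.
#' @param sedentary_cpm Sedentary cut-point in cpm (default 100).
#' @return A tibble with one row per calendar day present in `minutes`:
#'   `date`, `day_type`, `wear_min`, `sedentary_min`, `valid` (`NA` until
#'   [filter_valid_days()] is applied).
#' @export
summarize_days <- function(minutes, sedentary_cpm = 100) {
  if (nrow(minutes) == 0L) {
    return(tibble::tibble(
      date = as.Date(character()), day_type = character(),
      wear_min = integer(), sedentary_min = integer(), valid = logical()
    ))
  }
  worn <- minutes$wear & !minutes$malfunction
  sed <- worn & minutes$cpm < sedentary_cpm
  out <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(date = minutes$date, worn = worn, sed = sed),
      date
    ),
    wear_min = sum(worn),
    sedentary_min = sum(sed),
    .groups = "drop"
  )
  out$day_type <- day_type_of(out$date)
  out$valid <- NA
  out[, c("date", "day_type", "wear_min", "sedentary_min", "valid")]
}

#' Summarise a single calendar day
#'
#' Convenience wrapper around [summarize_days()] restricted to one date.
#'
#' @inheritParams summarize_days
#' @param date The calendar day to summarise.
#' @return A one-row day summary (zero wear if the date is absent).
#' @export
summarize_day <- function(minutes, date, sedentary_cpm = 100) {
  date <- as.Date(date)
  out <- summarize_days(minutes[minutes$date == date, , drop = FALSE], sedentary_cpm)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      date = date, day_type = day_type_of(date),
      wear_min = 0L, sedentary_min = 0L, valid = NA
    )
  }
  out
}

#' Apply day-level validity rules
#'
#' Removes the device delivery and return days (partial protocols) and
#' marks the remaining days valid when they accumulate at least
#' `min_wear_min` minutes of wear (default 480 min = 8 h, the protocol
#' minimum). Set `min_wear_min = 0` to treat the 8-h rule as a protocol
#' instruction rather than a validity criterion.
#'
#' @param days Day summaries from [summarize_days()].
#' @param series Optional [count_epoch_series()] carrying the delivery and
#'   return dates; alternatively pass them explicitly.
#' @param min_wear_min Minimum wear minutes for a valid day (inclusive).
#' @param delivery_date,return_date Dates to exclude (override `series`).
#' @return `days` with delivery/return days removed and `valid` filled in.
#' @export
filter_valid_days <- function(days, series = NULL, min_wear_min = 480,
                              delivery_date = NULL, return_date = NULL) {
  delivery_date <- delivery_date %||% series$delivery_date
  return_date <- return_date %||% series$return_date
  drop <- as.Date(c(delivery_date, return_date))
  if (length(drop)) {
    days <- days[!(days$date %in% drop), , drop = FALSE]
  }
  days$valid <- days$wear_min >= min_wear_min
  days
}

#' Standardise daily sedentary time by wear time
#'
#' Rescales a day's sedentary minutes by the proportion of monitor-wearing
#' time to a common reference wear period:
#' `sedentary_min / wear_min * reference_wear_min`. This removes
#' between-day differences in how long the monitor was worn. The usual
#' reference is the participant's mean wear over their valid days (the
#' pipeline default); any fixed reference (e.g. 960 min) may be supplied.
#'
#' @param sedentary_min,wear_min Daily sedentary and wear minutes.
#' @param reference_wear_min Reference wear period in minutes.
#' @return Standardised sedentary time, minutes per day.
#' @export
#' @examples
#' standardize_sedentary(300, 600, 960) # 480
standardize_sedentary <- function(sedentary_min, wear_min, reference_wear_min) {
  if (any(wear_min == 0)) {
    stop("cannot standardize a day with zero wear time", call. = FALSE)
  }
  sedentary_min / wear_min * reference_wear_min
}

#' Weekly accelerometer summary for one participant
#'
#' Requires at least three valid days including two weekdays and one
#' weekend day; otherwise an insufficient-data error naming the missing
#' stratum is raised. Weekday and weekend sedentary time are the means of
#' the standardised daily values over valid days of each type, combined
#' into the weekly total with the 5/2 weighting, and classified against
#' the 120 min/day guideline.
#'
#' @param days Day summaries that have been filtered with
#'   [filter_valid_days()] and carry a `sedentary_std` column of
#'   standardised daily sedentary minutes.
#' @param participant_id Identifier copied into the output.
#' @param min_days,min_weekdays,min_weekend_days Composition rule for a
#'   valid measurement (defaults 3 / 2 / 1).
#' @return A one-row tibble: `participant_id`, `weekday_sed`,
#'   `weekend_sed`, `total_sed` (min/day), `meets_guideline`,
#'   `n_valid_days`, `n_valid_weekdays`, `n_valid_weekend_days`.
#' @export
compute_accel_summary <- function(days, participant_id = NA_character_,
                                  min_days = 3, min_weekdays = 2,
                                  min_weekend_days = 1) {
  if (!"sedentary_std" %in% names(days)) {
    stop("`days` must carry standardized sedentary time (`sedentary_std`)",
      call. = FALSE
    )
  }
  v <- days[which(days$valid), , drop = FALSE]
  n_wd <- sum(v$day_type == "weekday")
  n_we <- sum(v$day_type == "weekend")
  if (nrow(v) < min_days || n_wd < min_weekdays || n_we < min_weekend_days) {
    missing_bits <- c(
      if (nrow(v) < min_days) sprintf("%d valid days (need %d)", nrow(v), min_days),
      if (n_wd < min_weekdays) sprintf("%d weekdays (need %d)", n_wd, min_weekdays),
      if (n_we < min_weekend_days) sprintf("%d weekend days (need %d)", n_we, min_weekend_days)
    )
    stop_insufficient_data(
      paste0(
        "insufficient valid days for participant ", participant_id, ": ",
        paste(missing_bits, collapse = ", ")
      )
    )
  }
  weekday_sed <- mean(v$sedentary_std[v$day_type == "weekday"])
  weekend_sed <- mean(v$sedentary_std[v$day_type == "weekend"])
  total_sed <- weekly_total(weekday_sed, weekend_sed)
  tibble::tibble(
    participant_id = participant_id,
    weekday_sed = weekday_sed,
    weekend_sed = weekend_sed,
    total_sed = total_sed,
    meets_guideline = classify_guideline(total_sed),
    n_valid_days = nrow(v),
    n_valid_weekdays = n_wd,
    n_valid_weekend_days = n_we
  )
}

#' Full reduction of a count series to a weekly summary
#'
#' Runs the whole chain: minute aggregation, malfunction flagging,
#' non-wear detection, day summaries, day-validity filtering, wear-time
#' standardisation and the weekly summary.
#'
#' @param series A [count_epoch_series()].
#' @param min_wear_min Minimum wear minutes for a valid day.
#' @param reference_wear_min Fixed standardisation reference in minutes,
#'   or `NULL` (default) to use the participant's mean wear over valid
#'   days.
#' @param sedentary_cpm,malfunction_cpm,max_zero_run Reduction cut-points.
#' @return The one-row summary from [compute_accel_summary()].
#' @export
reduce_accel <- function(series, min_wear_min = 480, reference_wear_min = NULL,
                         sedentary_cpm = 100, malfunction_cpm = 20000,
                         max_zero_run = 20) {
  minutes <- aggregate_to_minutes(series)
  minutes <- flag_malfunction(minutes, malfunction_cpm)
  minutes <- detect_nonwear(minutes, max_zero_run)
  days <- summarize_days(minutes, sedentary_cpm)
  days <- filter_valid_days(days, series, min_wear_min)
  v <- days$valid & days$wear_min > 0
  ref <- reference_wear_min %||% mean(days$wear_min[v])
  days$sedentary_std <- NA_real_
  days$sedentary_std[v] <- standardize_sedentary(
    days$sedentary_min[v], days$wear_min[v], ref
  )
  compute_accel_summary(days, participant_id = series$participant_id)
}
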