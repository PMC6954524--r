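# Orchestration of the two method-comparison studies: test-retest
# reliability (Q1 vs Q2 of the questionnaire) and concurrent validity
# (Q1 vs accelerometer), plus study-accounting and sample-planning
# arithmetic. Children and adolescents are always analysed separately.

#' Assemble a study dataset from its component tables
#'
#' @param q1,q2 Long-format questionnaire response tables
#'   (administrations Q1 and Q2; `q2` may be `NULL`).
#' @param accel Accelerometer summary tibble as produced by
#'   [reduce_accel()] / [simulate_study()], or `NULL`.
#' @param config Optional provenance (e.g. a [sim_config()]).
#' @return A list of class `study_dataset`.
#' @export
study_dataset <- function(q1, q2 = NULL, accel = NULL, config = NULL) {
  validate_responses(q1)
  if (!is.null(q2)) validate_responses(q2)
  structure(
    list(config = config, cohort = NULL, q1 = q1, q2 = q2, accel = accel),
    class = "study_dataset"
  )
}

quantile_cells <- function(x) {
  # linear-interpolation quantiles (type 7), the common default
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE)
  list(median = q[1], p25 = q[2], p75 = q[3])
}

group_scores <- function(responses, group, guideline_limit) {
  if (is.null(responses)) {
    return(NULL)
  }
  score_responses(
    responses[responses$group == group, , drop = FALSE],
    guideline_limit = guideline_limit
  )
}

#' Test-retest reliability report (Q1 vs Q2)
#'
#' For each week segment (weekdays, weekend days, total days) of one age
#' group: the median (25th-75th percentile) of the Q1 and Q2 scores, the
#' Spearman correlation, the quadratic-weighted kappa on quartiles, and
#' the percentage meeting the 120 min/day guideline under each
#' administration with the unweighted (binary) kappa. Only participants
#' with complete pairs in a segment contribute to that segment.
#'
#' @param data A `study_dataset` with both administrations.
#' @param group `"children"` or `"adolescents"`.
#' @param guideline_limit Guideline cut-off in min/day.
#' @return A tibble of class `reliability_report`, one row per segment:
#'   `group`, `segment`, `n`, Q1/Q2 median and quartiles, `rho`, `rho_p`,
#'   `kappa_quartile`, `pct_meet_q1`, `pct_meet_q2`, `kappa_binary`.
#' @export
run_reliability_study <- function(data, group = c("children", "adolescents"),
                                  guideline_limit = 120) {
  group <- match.arg(group)
  if (is.null(data$q2)) {
    stop("reliability analysis needs a second administration (`q2`)", call. = FALSE)
  }
  s1 <- group_scores(data$q1, group, guideline_limit)
  s2 <- group_scores(data$q2, group, guideline_limit)
  merged <- dplyr::inner_join(
    s1, s2,
    by = "participant_id", suffix = c("_q1", "_q2")
  )
  seg_col <- c(weekday = "weekday_min", weekend = "weekend_min", total = "total_min")
  rows <- lapply(c("weekday", "weekend", "total"), function(seg) {
    x <- merged[[paste0(seg_col[[seg]], "_q1")]]
    y <- merged[[paste0(seg_col[[seg]], "_q2")]]
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < 4) {
      stop_insufficient_data(sprintf(
        "reliability analysis (%s, %s segment) needs at least 4 complete pairs, got %d",
        group, seg, length(x)
      ))
    }
    sp <- spearman_rho(x, y)
    kq <- weighted_kappa_quadratic(quartile_bins(x), quartile_bins(y), K = 4)
    meet_x <- classify_guideline(x, guideline_limit)
    meet_y <- classify_guideline(y, guideline_limit)
    kb <- tryCatch(
      cohen_kappa(meet_x, meet_y, levels = c(FALSE, TRUE))$kappa,
      error = function(e) NA_real_
    )
    qx <- quantile_cells(x)
    qy <- quantile_cells(y)
    tibble::tibble(
      group = group, segment = seg, n = length(x),
      q1_median = qx$median, q1_p25 = qx$p25, q1_p75 = qx$p75,
      q2_median = qy$median, q2_p25 = qy$p25, q2_p75 = qy$p75,
      rho = sp$rho, rho_p = sp$p,
      kappa_quartile = kq$kappa,
      pct_meet_q1 = 100 * mean(meet_x),
      pct_meet_q2 = 100 * mean(meet_y),
      kappa_binary = kb
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("reliability_report", class(out))
  out
}

#' Concurrent validity report (Q1 vs accelerometer)
#'
#' For each week segment of one age group: medians (25th-75th
#' percentile) of the questionnaire and accelerometer values,
#' Bland-Altman bias with SD of differences and 95% limits of agreement,
#' the Pitman trend correlation (absolute-difference variant by
#' default), the Spearman correlation and the quadratic-weighted kappa
#' on quartiles. Differences are oriented questionnaire minus
#' accelerometer by default, so systematic under-reporting appears as a
#' negative bias.
#'
#' @inheritParams run_reliability_study
#' @param orientation `"q1_minus_reference"` (default) or
#'   `"reference_minus_q1"`.
#' @param trend_variant Passed to [pitman_trend()].
#' @return A tibble of class `validity_report`, one row per segment.
#' @export
run_validity_study <- function(data, group = c("children", "adolescents"),
                               guideline_limit = 120,
                               orientation = c("q1_minus_reference", "reference_minus_q1"),
                               trend_variant = "absolute") {
  group <- match.arg(group)
  orientation <- match.arg(orientation)
  if (is.null(data$accel) || nrow(data$accel) == 0) {
    stop("validity analysis needs accelerometer summaries", call. = FALSE)
  }
  s1 <- group_scores(data$q1, group, guideline_limit)
  merged <- dplyr::inner_join(s1, data$accel, by = "participant_id")
  seg_cols <- list(
    weekday = c("weekday_min", "weekday_sed"),
    weekend = c("weekend_min", "weekend_sed"),
    total = c("total_min", "total_sed")
  )
  rows <- lapply(names(seg_cols), function(seg) {
    x <- merged[[seg_cols[[seg]][1]]] # questionnaire
    y <- merged[[seg_cols[[seg]][2]]] # accelerometer
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < 4) {
      stop_insufficient_data(sprintf(
        "validity analysis (%s, %s segment) needs at least 4 complete pairs, got %d",
        group, seg, length(x)
      ))
    }
    sgn <- if (orientation == "q1_minus_reference") 1 else -1
    ba <- bland_altman(x, y)
    sp <- spearman_rho(x, y)
    kq <- weighted_kappa_quadratic(quartile_bins(x), quartile_bins(y), K = 4)
    tr <- tryCatch(pitman_trend(x, y, trend_variant), error = function(e) NULL)
    qx <- quantile_cells(x)
    qy <- quantile_cells(y)
    tibble::tibble(
      group = group, segment = seg, n = length(x),
      q1_median = qx$median, q1_p25 = qx$p25, q1_p75 = qx$p75,
      accel_median = qy$median, accel_p25 = qy$p25, accel_p75 = qy$p75,
      bias = sgn * ba$bias, sd_diff = ba$sd_diff,
      loa_low = if (sgn == 1) ba$loa_low else -ba$loa_high,
      loa_high = if (sgn == 1) ba$loa_high else -ba$loa_low,
      trend_r = if (is.null(tr)) NA_real_ else tr$r,
      trend_p = if (is.null(tr)) NA_real_ else tr$p,
      rho = sp$rho, rho_p = sp$p,
      kappa_quartile = kq$kappa,
      orientation = orientation
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("validity_report", class(out))
  out
}

#' Response-rate accounting
#'
#' Computes the response rates a multi-stage measurement study reports:
#' the first-administration rate against all eligible participants, and
#' the second-administration and accelerometer rates against the
#' first-administration completers. Rates are percentages rounded half
#' up to one decimal.
#'
#' @param eligible Participants meeting the inclusion criteria.
#' @param q1_complete Completers of the first questionnaire
#'   administration.
#' @param q2_complete Completers of the second administration.
#' @param accel_valid Participants with valid accelerometer data.
#' @return A list: `q1_rate`, `q2_rate`, `accel_rate` (percent).
#' @export
#' @examples
#' study_accounting(495, 415, 161, 187)
study_accounting <- function(eligible, q1_complete, q2_complete, accel_valid) {
  counts <- c(eligible, q1_complete, q2_complete, accel_valid)
  if (any(counts < 0) || any(counts[-1] > eligible)) {
    stop("counts must satisfy 0 <= count <= eligible", call. = FALSE)
  }
  if (eligible == 0) {
    stop("undefined rate: no eligible participants", call. = FALSE)
  }
  if (q1_complete == 0) {
    stop("undefined rate: no first-administration completers", call. = FALSE)
  }
  list(
    q1_rate = round_half_up(100 * q1_complete / eligible, 1),
    q2_rate = round_half_up(100 * q2_complete / q1_complete, 1),
    accel_rate = round_half_up(100 * accel_valid / q1_complete, 1)
  )
}

#' Inflate a planned sample size for anticipated losses
#'
#' `floor(base_n * (1 + loss_inflation))`: the conventional arithmetic
#' for padding a power-derived sample size against attrition.
#'
#' @param base_n Power-derived base sample size (> 0).
#' @param loss_inflation Anticipated loss fraction (default 0.25).
#' @return Integer planned sample size.
#' @export
#' @examples
#' plan_sample(136) # 170
#' plan_sample(65) # 81
plan_sample <- function(base_n, loss_inflation = 0.25) {
  if (base_n <= 0) {
    stop("`base_n` must be positive", call. = FALSE)
  }
  if (loss_inflation < 0) {
    stop("`loss_inflation` cannot be negative", call. = FALSE)
  }
  as.integer(floor(base_n * (1 + loss_inflation)))
}

fmt_cell <- function(median, p25, p75) {
  sprintf("%.1f (%.1f to %.1f)", median, p25, p75)
}

#' Format a reliability report for display
#'
#' Rounds minute quantities to one decimal and coefficients to two,
#' mirroring the layout of published test-retest tables. The raw report
#' keeps full precision for machine use.
#'
#' @param report A `reliability_report` from [run_reliability_study()].
#' @return A character data frame.
#' @export
format_reliability_report <- function(report) {
  data.frame(
    segment = report$segment,
    n = report$n,
    q1 = fmt_cell(report$q1_median, report$q1_p25, report$q1_p75),
    q2 = fmt_cell(report$q2_median, report$q2_p25, report$q2_p75),
    rho = sprintf("%.2f", report$rho),
    kappa_quartile = sprintf("%.2f", report$kappa_quartile),
    pct_meet_q1 = sprintf("%.1f", report$pct_meet_q1),
    pct_meet_q2 = sprintf("%.1f", report$pct_meet_q2),
    kappa_binary = sprintf("%.2f", report$kappa_binary)
  )
}

#' Format a validity report for display
#'
#' @param report A `validity_report` from [run_validity_study()].
#' @return A character data frame mirroring published validity tables.
#' @export
format_validity_report <- function(report) {
  data.frame(
    segment = report$segment,
    n = report$n,
    q1 = fmt_cell(report$q1_median, report$q1_p25, report$q1_p75),
    accelerometer = fmt_cell(report$accel_median, report$accel_p25, report$accel_p75),
    bias = sprintf("%.1f ± %.1f", report$bias, report$sd_diff),
    loa = sprintf("%.1f to %.1f", report$loa_low, report$loa_high),
    trend = sprintf("%.2f", report$trend_r),
    rho = sprintf("%.2f", report$rho),
    kappa_quartile = sprintf("%.2f", report$kappa_quartile)
  )
}
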