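# Synthetic cohorts with known ground truth. The generator emulates the
# statistical structure a questionnaire-vs-accelerometer measurement
# study assumes: per-participant true sedentary minutes with
# weekday/weekend structure, an accelerometer count stream whose
# reduction recovers the truth, questionnaire reports that cover only a
# fraction of total sedentary time (systematic under-reporting), and a
# second administration coupled to the first through a shared Gaussian
# latent so the realised test-retest correlation can be dialled.

#' Simulation configuration
#'
#' Study conditions for one synthetic cohort. Defaults anchor the true
#' sedentary-time distributions to the objectively measured levels
#' typical of South American school-age cohorts (medians near 520-550
#' min/day for children and 570-600 for adolescents), a wear protocol of
#' 12 h/day, a questionnaire covering about a quarter of total sedentary
#' time (the four items deliberately measure a narrower construct than
#' "all time below 100 cpm"), and test-retest correlations of 0.70 for
#' parent-reported children and 0.50 for self-reported adolescents.
#'
#' @param n_participants Cohort size (>= 0).
#' @param group `"children"` (parent-proxy report) or `"adolescents"`
#'   (self report).
#' @param days Number of consecutive monitored days (default 7, starting
#'   on a Monday).
#' @param true_sed_weekday_mean,true_sed_weekday_sd Per-day true
#'   sedentary minutes on weekdays: normal mean/sd, truncated to
#'   `[0, wear minutes]`.
#' @param true_sed_weekend_mean,true_sed_weekend_sd Same for weekend days.
#' @param wear_start,wear_end Clock hours the monitor is worn (default
#'   08:00-20:00, i.e. 720 min/day of scheduled wear).
#' @param nonwear_gap_rate Expected number of injected non-wear gaps per
#'   day (Poisson).
#' @param nonwear_gap_len_mean Mean gap length in minutes (exponential,
#'   truncated below at 21 min so every injected gap is detectable).
#' @param underreport_fraction Share of true sedentary time NOT captured
#'   by the four questionnaire items, in `[0, 1]`.
#' @param retest_rho Target Spearman correlation between Q1 and Q2 weekly
#'   totals, in `[-1, 1]`.
#' @param report_noise_sd SD of the reporting noise added to each
#'   segment total, in minutes.
#' @param start_date First monitored day (default 2019-04-01, a Monday).
#' @param seed Integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants,
                       group = c("children", "adolescents"),
                       days = 7,
                       true_sed_weekday_mean = NULL,
                       true_sed_weekday_sd = 60,
                       true_sed_weekend_mean = NULL,
                       true_sed_weekend_sd = 80,
                       wear_start = 8, wear_end = 20,
                       nonwear_gap_rate = 1,
                       nonwear_gap_len_mean = 45,
                       underreport_fraction = 0.75,
                       retest_rho = NULL,
                       report_noise_sd = 30,
                       start_date = as.Date("2019-04-01"),
                       seed) {
  group <- match.arg(group)
  true_sed_weekday_mean <- true_sed_weekday_mean %||%
    if (group == "children") 522 else 570
  true_sed_weekend_mean <- true_sed_weekend_mean %||%
    if (group == "children") 547 else 599
  retest_rho <- retest_rho %||% if (group == "children") 0.70 else 0.50
  if (missing(seed)) {
    stop_config("`seed` is required: synthetic cohorts must be reproducible")
  }
  cfg <- list(
    n_participants = n_participants, group = group, days = days,
    true_sed_weekday_mean = true_sed_weekday_mean,
    true_sed_weekday_sd = true_sed_weekday_sd,
    true_sed_weekend_mean = true_sed_weekend_mean,
    true_sed_weekend_sd = true_sed_weekend_sd,
    wear_start = wear_start, wear_end = wear_end,
    nonwear_gap_rate = nonwear_gap_rate,
    nonwear_gap_len_mean = nonwear_gap_len_mean,
    underreport_fraction = underreport_fraction,
    retest_rho = retest_rho,
    report_noise_sd = report_noise_sd,
    start_date = as.Date(start_date),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ok <- function(cond, msg) if (!cond) stop_config(msg)
  ok(
    is.numeric(cfg$n_participants) && cfg$n_participants >= 0 &&
      cfg$n_participants == round(cfg$n_participants),
    "`n_participants` must be a non-negative integer"
  )
  ok(cfg$days >= 1, "`days` must be at least 1")
  ok(
    cfg$true_sed_weekday_sd >= 0 && cfg$true_sed_weekend_sd >= 0 &&
      cfg$report_noise_sd >= 0,
    "standard deviations must be non-negative"
  )
  ok(
    cfg$true_sed_weekday_mean >= 0 && cfg$true_sed_weekend_mean >= 0,
    "mean sedentary minutes must be non-negative"
  )
  ok(
    cfg$underreport_fraction >= 0 && cfg$underreport_fraction <= 1,
    "`underreport_fraction` must lie in [0, 1]"
  )
  ok(
    cfg$retest_rho >= -1 && cfg$retest_rho <= 1,
    "`retest_rho` must lie in [-1, 1]"
  )
  ok(
    cfg$wear_start < cfg$wear_end && cfg$wear_start >= 0 && cfg$wear_end <= 24,
    "wear window must satisfy 0 <= wear_start < wear_end <= 24"
  )
  ok(cfg$nonwear_gap_rate >= 0, "`nonwear_gap_rate` must be non-negative")
  ok(cfg$nonwear_gap_len_mean >= 0, "`nonwear_gap_len_mean` must be non-negative")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d %s, %d days, true sed %g/%g (wd/we) min/day, underreport %.2f, retest rho %.2f, seed %d\n",
    x$n_participants, x$group, x$days,
    x$true_sed_weekday_mean, x$true_sed_weekend_mean,
    x$underreport_fraction, x$retest_rho, x$seed
  ))
  invisible(x)
}

sim_dates <- function(config) {
  dates <- config$start_date + seq_len(config$days) - 1L
  tibble::tibble(date = dates, day_type = day_type_of(dates))
}

scheduled_wear_min <- function(config) {
  (config$wear_end - config$wear_start) * 60
}

#' Simulate a cohort's true behaviour
#'
#' Draws, for each participant, per-day true sedentary minutes (normal
#' by day type, clamped to `[0, wear minutes]`) and the split of the
#' questionnaire-visible share `(1 - underreport_fraction)` across the
#' four activity items via a symmetric Dirichlet (concentration 1). The
#' activity-specific minutes therefore always sum to the visible share
#' of true sedentary time, and never exceed it.
#'
#' @param config A [sim_config()].
#' @return A list of `true_behavior` records, one per participant. Each
#'   holds the daily truth table (`date`, `day_type`, `wear_min`,
#'   `true_sed_min`), the weekday/weekend/weekly true averages, the item
#'   table of activity-specific minutes, and per-participant seeds for
#'   the accelerometer and questionnaire generators.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  cal <- sim_dates(config)
  wear <- scheduled_wear_min(config)
  is_wd <- cal$day_type == "weekday"
  mu <- ifelse(is_wd, config$true_sed_weekday_mean, config$true_sed_weekend_mean)
  sdv <- ifelse(is_wd, config$true_sed_weekday_sd, config$true_sed_weekend_sd)
  items <- sb_items(config$group)
  lapply(seq_len(config$n_participants), function(i) {
    sed <- pmin(pmax(stats::rnorm(config$days, mu, sdv), 0), wear)
    g <- stats::rgamma(4, shape = 1)
    shares <- g / sum(g)
    seeds <- sample.int(2147483646L, 2L)
    avg_wd <- if (any(is_wd)) mean(sed[is_wd]) else 0
    avg_we <- if (any(!is_wd)) mean(sed[!is_wd]) else 0
    visible <- 1 - config$underreport_fraction
    structure(
      list(
        participant_id = sprintf("P%04d", i),
        group = config$group,
        days = tibble::tibble(
          date = cal$date, day_type = cal$day_type,
          wear_min = wear, true_sed_min = sed
        ),
        item_shares = shares,
        items = tibble::tibble(
          item = items,
          weekday_min = visible * avg_wd * shares,
          weekend_min = visible * avg_we * shares
        ),
        true_weekday_sed = avg_wd,
        true_weekend_sed = avg_we,
        true_total_sed = weekly_total(avg_wd, avg_we),
        accel_seed = seeds[1],
        quest_seed = seeds[2]
      ),
      class = "true_behavior"
    )
  })
}

#' Simulate an accelerometer count stream for one participant
#'
#' Emits a full-day 5-s epoch stream (midnight to midnight) for each
#' monitored day. Within the wear window, minutes are drawn sedentary
#' (1-99 cpm) or active (100-6000 cpm) so that the day's sedentary
#' minute count equals the rounded truth; outside the wear window and
#' during injected non-wear gaps all counts are zero. Gap counts per day
#' are Poisson with the configured rate; gap lengths are exponential
#' with the configured mean, truncated below at 21 min so that every gap
#' is detectable by the 20-min non-wear rule. Minute cpm totals are
#' spread across the 12 epochs of each minute.
#'
#' @param truth A `true_behavior` record from [simulate_cohort()].
#' @param config The [sim_config()] used to generate `truth`.
#' @param seed Integer seed (defaults to the per-participant seed stored
#'   in `truth`); an explicit `NULL` is an error, reproducibility is
#'   mandatory.
#' @return A [count_epoch_series()] whose delivery and return dates
#'   bracket the monitored days.
#' @export
simulate_accel_stream <- function(truth, config, seed = truth$accel_seed) {
  if (is.null(seed)) {
    stop_config("`seed` is required for accelerometer simulation")
  }
  set.seed(seed)
  wear_idx_day <- (config$wear_start * 60 + 1):(config$wear_end * 60)
  n_min_day <- 1440L
  cpm <- integer(config$days * n_min_day)
  for (d in seq_len(config$days)) {
    offset <- (d - 1L) * n_min_day
    s <- round(truth$days$true_sed_min[d])
    day_cpm <- integer(n_min_day)
    sed_idx <- sample(wear_idx_day, s)
    act_idx <- setdiff(wear_idx_day, sed_idx)
    day_cpm[sed_idx] <- sample(1:99, s, replace = TRUE)
    day_cpm[act_idx] <- sample(100:6000, length(act_idx), replace = TRUE)
    n_gaps <- stats::rpois(1, config$nonwear_gap_rate)
    occupied <- integer(0)
    for (g in seq_len(n_gaps)) {
      len <- max(21L, round(stats::rexp(1, 1 / max(config$nonwear_gap_len_mean, 1e-9))))
      len <- min(len, length(wear_idx_day))
      for (try in 1:20) {
        start <- sample(wear_idx_day[seq_len(length(wear_idx_day) - len + 1L)], 1)
        span <- start:(start + len - 1L)
        if (!any(span %in% occupied)) {
          day_cpm[span] <- 0L
          occupied <- c(occupied, span)
          break
        }
      }
    }
    cpm[offset + seq_len(n_min_day)] <- day_cpm
  }
  # spread each minute's cpm over its 12 five-second epochs
  k <- 12L
  epochs <- rep(cpm %/% k, each = k)
  rem <- cpm %% k
  if (any(rem > 0)) {
    idx <- rep((seq_along(cpm) - 1L) * k, times = rem) + sequence(rem)
    epochs[idx] <- epochs[idx] + 1L
  }
  count_epoch_series(
    participant_id = truth$participant_id,
    start = as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC"),
    counts = epochs,
    epoch_length = 5L,
    delivery_date = config$start_date - 1L,
    return_date = config$start_date + config$days
  )
}

# Mixing weight of the shared Gaussian latent coupling Q1 and Q2.
#
# Reported segment totals are R + sd * W_a with R the truth-derived part
# and W_a a standard normal latent per administration. Writing the
# target Spearman correlation of the weekly totals as a Pearson
# correlation via the bivariate-normal relation r = 2 sin(pi * rho / 6),
# the required correlation c between the two administrations' noise
# terms solves r = (var(R) + c * var(E)) / (var(R) + var(E)). The shared
# latent W_a = lambda * U + sqrt(1 - lambda^2) * V_a (with a sign flip on
# U for negative c) realises c = sign * lambda^2.
retest_mixing <- function(config) {
  cal <- sim_dates(config)
  n_wd <- sum(cal$day_type == "weekday")
  n_we <- sum(cal$day_type == "weekend")
  visible <- 1 - config$underreport_fraction
  var_r <- visible^2 * (
    (if (n_wd > 0) (25 / 49) * config$true_sed_weekday_sd^2 / n_wd else 0) +
      (if (n_we > 0) (4 / 49) * config$true_sed_weekend_sd^2 / n_we else 0)
  )
  # independent latents per segment: the weekly-total noise variance is
  # sd^2 * (25 + 4) / 49
  var_e <- config$report_noise_sd^2 * 29 / 49
  if (var_e == 0) {
    if (config$retest_rho < 1) {
      stop_config(
        "a retest correlation below 1 is unreachable with report_noise_sd = 0"
      )
    }
    return(list(lambda = 0, sign = 1))
  }
  r_target <- 2 * sin(pi * config$retest_rho / 6)
  c_needed <- (r_target * (var_r + var_e) - var_r) / var_e
  if (c_needed < -1) {
    stop_config(paste0(
      "target retest correlation ", config$retest_rho,
      " is unreachable: increase report_noise_sd or lower the truth variance"
    ))
  }
  c_needed <- min(c_needed, 1)
  list(lambda = sqrt(abs(c_needed)), sign = if (c_needed >= 0) 1 else -1)
}

#' Simulate one questionnaire administration for one participant
#'
#' Reported weekday and weekend segment totals are the truth-visible
#' share plus Gaussian reporting noise, clamped at zero, and split across
#' the four items by the participant's activity shares. The two
#' administrations share a latent noise component whose mixing weight is
#' solved so the realised Spearman correlation of Q1 and Q2 weekly
#' totals approaches `retest_rho` at large n. Call with the same `seed`
#' for both administrations of a participant (the default, stored in
#' `truth`, does this) so the shared latent is common to Q1 and Q2.
#'
#' @inheritParams simulate_accel_stream
#' @param administration `"Q1"` or `"Q2"`.
#' @param seed Integer seed; defaults to the per-participant
#'   questionnaire seed in `truth`.
#' @return A long-format response tibble (four rows) matching the
#'   questionnaire schema of [validate_responses()].
#' @export
simulate_questionnaire <- function(truth, config,
                                   administration = c("Q1", "Q2"),
                                   seed = truth$quest_seed) {
  administration <- match.arg(administration)
  if (is.null(seed)) {
    stop_config("`seed` is required for questionnaire simulation")
  }
  mix <- retest_mixing(config)
  set.seed(seed)
  u_seg <- stats::rnorm(2) # shared latent per segment (weekday, weekend)
  v <- matrix(stats::rnorm(4), nrow = 2) # own noise: [segment, administration]
  a <- if (administration == "Q1") 1L else 2L
  u_sign <- if (a == 1L) 1 else mix$sign
  w <- u_sign * mix$lambda * u_seg + sqrt(1 - mix$lambda^2) * v[, a]
  visible <- 1 - config$underreport_fraction
  rep_wd <- max(0, visible * truth$true_weekday_sed + config$report_noise_sd * w[1])
  rep_we <- max(0, visible * truth$true_weekend_sed + config$report_noise_sd * w[2])
  tibble::tibble(
    participant_id = truth$participant_id,
    group = truth$group,
    respondent = expected_respondent(truth$group),
    administration = administration,
    item = truth$items$item,
    weekday_min = truth$item_shares * rep_wd,
    weekend_min = truth$item_shares * rep_we
  )
}

#' Simulate a complete measurement study
#'
#' Generates a cohort, both questionnaire administrations and the
#' accelerometer arm, linked by participant id.
#'
#' @param config A [sim_config()].
#' @param accel How to produce the accelerometer summaries: `"stream"`
#'   (default) synthesises epoch streams and runs the full reduction in
#'   [reduce_accel()]; `"summary"` derives idealised summaries directly
#'   from the truth (fast, for large reliability-only cohorts);
#'   `"none"` skips the accelerometer arm.
#' @return A list of class `study_dataset`: `config`, `cohort` (truth),
#'   `q1`, `q2` (long response tables) and `accel` (summary tibble;
#'   participants failing the valid-day composition rule are dropped).
#' @export
simulate_study <- function(config, accel = c("stream", "summary", "none")) {
  accel <- match.arg(accel)
  cohort <- simulate_cohort(config)
  q1 <- dplyr::bind_rows(
    lapply(cohort, simulate_questionnaire, config = config, administration = "Q1")
  )
  q2 <- dplyr::bind_rows(
    lapply(cohort, simulate_questionnaire, config = config, administration = "Q2")
  )
  accel_tab <- NULL
  if (accel == "stream") {
    # standardize to the scheduled wear window: the protocol wear time is
    # known here, and it keeps the accelerometer arm an unbiased estimate
    # of the configured truth when non-wear gaps are injected
    ref <- scheduled_wear_min(config)
    accel_tab <- dplyr::bind_rows(lapply(cohort, function(tb) {
      s <- simulate_accel_stream(tb, config)
      tryCatch(
        reduce_accel(s, reference_wear_min = ref),
        sedvalid_insufficient_data = function(e) NULL
      )
    }))
  } else if (accel == "summary") {
    accel_tab <- dplyr::bind_rows(lapply(cohort, function(tb) {
      n_wd <- sum(tb$days$day_type == "weekday")
      n_we <- sum(tb$days$day_type == "weekend")
      if (nrow(tb$days) < 3 || n_wd < 2 || n_we < 1) {
        return(NULL)
      }
      total <- weekly_total(tb$true_weekday_sed, tb$true_weekend_sed)
      tibble::tibble(
        participant_id = tb$participant_id,
        weekday_sed = tb$true_weekday_sed,
        weekend_sed = tb$true_weekend_sed,
        total_sed = total,
        meets_guideline = classify_guideline(total),
        n_valid_days = nrow(tb$days),
        n_valid_weekdays = n_wd,
        n_valid_weekend_days = n_we
      )
    }))
  }
  structure(
    list(config = config, cohort = cohort, q1 = q1, q2 = q2, accel = accel_tab),
    class = "study_dataset"
  )
}
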