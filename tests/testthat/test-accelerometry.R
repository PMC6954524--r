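# Count-stream reduction: aggregation, exclusion rules, day summaries,
# standardisation and the weekly summary.

series_of <- function(counts, epoch_length = 5L,
                      start = as.POSIXct("2019-04-01 00:00:00", tz = "UTC"),
                      ...) {
  count_epoch_series("T", start, counts, epoch_length = epoch_length, ...)
}

test_that("epoch counts aggregate to counts per minute, dropping a trailing partial minute", {
  m <- aggregate_to_minutes(series_of(rep(10, 24)))
  expect_equal(nrow(m), 2L)
  expect_equal(m$cpm, c(120, 120))

  m13 <- aggregate_to_minutes(series_of(rep(1, 13)))
  expect_equal(nrow(m13), 1L)
  expect_equal(m13$cpm, 12)

  expect_error(
    aggregate_to_minutes(series_of(rep(1, 10), epoch_length = 7L)),
    "divide 60"
  )
  expect_equal(nrow(aggregate_to_minutes(series_of(numeric(0)))), 0L)
})

test_that("minute aggregation matches a brute-force window sum on random streams", {
  for (seed in 1:5) {
    set.seed(seed)
    counts <- rpois(600, 30)
    m <- aggregate_to_minutes(series_of(counts))
    expect_equal(m$cpm, oracle_minute_agg(counts, 5))
  }
  set.seed(99)
  counts <- rpois(240, 10)
  m <- aggregate_to_minutes(series_of(counts, epoch_length = 15L))
  expect_equal(m$cpm, oracle_minute_agg(counts, 15))
})

test_that("malfunction flagging is strictly above 20,000 cpm, per minute", {
  m <- flag_malfunction(make_minutes(c(19999, 20000, 20001, 0)))
  expect_equal(m$malfunction, c(FALSE, FALSE, TRUE, FALSE))
  expect_false(any(flag_malfunction(make_minutes(rep(0, 60)))$malfunction))
})

test_that("non-wear needs a zero run strictly longer than 20 minutes", {
  z21 <- detect_nonwear(make_minutes(c(50, rep(0, 21), 50)))
  expect_equal(sum(!z21$wear), 21L)
  z20 <- detect_nonwear(make_minutes(c(50, rep(0, 20), 50)))
  expect_true(all(z20$wear))
  # any non-zero minute breaks a run: two 15-min zero runs split by one count
  split <- detect_nonwear(make_minutes(c(rep(0, 15), 1, rep(0, 15))))
  expect_true(all(split$wear))
})

test_that("non-wear flags equal an exhaustive run-length scan on random sequences", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(50:500, 1)
    cpm <- ifelse(runif(n) < 0.6, 0, sample(1:200, n, replace = TRUE))
    got <- detect_nonwear(make_minutes(cpm))$wear
    expect_equal(got, oracle_nonwear_wear(cpm))
  }
})

test_that("day summaries count worn minutes and apply the strict 100 cpm cut", {
  d <- summarize_days(make_minutes(rep(50, 600)))
  expect_equal(d$wear_min, 600L)
  expect_equal(d$sedentary_min, 600L)

  d100 <- summarize_days(make_minutes(c(100)))
  expect_equal(d100$wear_min, 1L)
  expect_equal(d100$sedentary_min, 0L)

  d99 <- summarize_days(make_minutes(c(99)))
  expect_equal(d99$sedentary_min, 1L)

  # malfunction minutes drop out of both tallies
  m <- flag_malfunction(make_minutes(c(50, 25000, 150)))
  dm <- summarize_days(m)
  expect_equal(dm$wear_min, 2L)
  expect_equal(dm$sedentary_min, 1L)

  set.seed(7)
  cpm <- sample(0:300, 500, replace = TRUE)
  mm <- detect_nonwear(flag_malfunction(make_minutes(cpm)))
  dd <- summarize_days(mm)
  worn <- mm$wear & !mm$malfunction
  expect_equal(sum(dd$sedentary_min), sum(worn & cpm < 100))
})

test_that("day types come from the calendar and days split at midnight", {
  # 2019-04-01 is a Monday; 48 h of sedentary minutes span Mon + Tue
  m <- make_minutes(rep(50, 2880))
  d <- summarize_days(m)
  expect_equal(nrow(d), 2L)
  expect_equal(d$day_type, c("weekday", "weekday"))
  sat <- summarize_days(make_minutes(rep(50, 60), start = as.POSIXct("2019-04-06 10:00:00", tz = "UTC")))
  expect_equal(sat$day_type, "weekend")
})

test_that("minute classifications are conserved: wear + non-wear + malfunction = recorded", {
  set.seed(3)
  cpm <- c(rep(0, 400), sample(c(0, 40, 150, 30000), 1040, replace = TRUE))
  m <- detect_nonwear(flag_malfunction(make_minutes(cpm)))
  worn <- sum(m$wear & !m$malfunction)
  nonwear <- sum(!m$wear)
  malf_worn <- sum(m$wear & m$malfunction)
  expect_equal(worn + nonwear + malf_worn, 1440L)
})

test_that("delivery/return days are excluded and 480 wear minutes is the inclusive validity bound", {
  days <- tibble::tibble(
    date = as.Date("2019-04-01") + 0:6,
    day_type = c(rep("weekday", 5), "weekend", "weekend"),
    wear_min = c(100, 479, 480, 600, 700, 800, 90),
    sedentary_min = rep(50, 7),
    valid = NA
  )
  out <- filter_valid_days(days,
    delivery_date = as.Date("2019-04-01"),
    return_date = as.Date("2019-04-07")
  )
  expect_equal(nrow(out), 5L) # at most 5 candidate days remain
  expect_equal(out$valid, c(FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("wear-time standardisation is proportional and guards zero wear", {
  expect_equal(standardize_sedentary(300, 600, 960), 480)
  # sedentary == wear gives the reference back whatever the wear
  expect_equal(standardize_sedentary(123, 123, 960), 960)
  expect_equal(standardize_sedentary(700, 700, 960), 960)
  expect_error(standardize_sedentary(0, 0, 960), "zero wear")

  set.seed(11)
  sed <- runif(50, 0, 400)
  wear <- sed + runif(50, 1, 600)
  expect_equal(
    standardize_sedentary(sed, wear, 720),
    sed / wear * 720
  )
})

test_that("weekly summary applies the 5/2 formula and the day-composition rule", {
  mk_days <- function(types, std) {
    tibble::tibble(
      date = as.Date("2019-04-01") + seq_along(types) - 1,
      day_type = types,
      wear_min = 600, sedentary_min = 300,
      valid = TRUE, sedentary_std = std
    )
  }
  d <- mk_days(c("weekday", "weekday", "weekend"), c(100, 100, 170))
  s <- compute_accel_summary(d, "P1")
  expect_equal(s$total_sed, 120)
  expect_false(s$meets_guideline)

  eq <- compute_accel_summary(mk_days(c("weekday", "weekday", "weekend"), c(80, 80, 80)), "P1")
  expect_equal(eq$total_sed, 80)

  expect_error(
    compute_accel_summary(mk_days(c("weekday", "weekday"), c(1, 2)), "P1"),
    class = "sedvalid_insufficient_data"
  )
  err <- tryCatch(
    compute_accel_summary(
      mk_days(c("weekday", "weekday", "weekday"), c(1, 2, 3)), "P1"
    ),
    error = identity
  )
  expect_match(conditionMessage(err), "weekend")
})

test_that("guideline classification is strict by default with an inclusive option", {
  expect_true(classify_guideline(119.9))
  expect_false(classify_guideline(120))
  expect_true(classify_guideline(0))
  expect_true(classify_guideline(120, inclusive = TRUE))
  expect_error(classify_guideline(-1), "negative")
})

test_that("full reduction equals a straight-line single-pass oracle on random streams", {
  for (seed in 1:8) {
    set.seed(seed)
    n_min <- 300
    cpm <- sample(c(0, 0, 0, 30, 500, 25000), n_min,
      replace = TRUE,
      prob = c(0.3, 0.2, 0.1, 0.2, 0.15, 0.05)
    )
    counts <- as.integer(rep(cpm / 12, each = 12)) # divisible by 12 below
    cpm <- oracle_minute_agg(counts, 5)
    m <- detect_nonwear(flag_malfunction(aggregate_to_minutes(series_of(counts))))
    ref <- oracle_reduce_minutes(cpm)
    expect_equal(m$malfunction, ref$malfunction)
    expect_equal(m$wear, ref$wear)
    d <- summarize_days(m)
    expect_equal(sum(d$wear_min), ref$wear_min)
    expect_equal(sum(d$sedentary_min), ref$sedentary_min)
  }
})

test_that("adding a non-wear gap never increases wear and leaves other minutes' class unchanged", {
  cfg <- sim_config(
    n_participants = 1, group = "children", nonwear_gap_rate = 0, seed = 21
  )
  truth <- simulate_cohort(cfg)[[1]]
  s <- simulate_accel_stream(truth, cfg)
  m0 <- detect_nonwear(flag_malfunction(aggregate_to_minutes(s)))
  # zero a 30-min window inside the wear period of day 1 (minutes 541-570)
  gap_min <- 541:570
  gap_epochs <- ((min(gap_min) - 1) * 12 + 1):(max(gap_min) * 12)
  s2 <- s
  s2$counts[gap_epochs] <- 0
  m1 <- detect_nonwear(flag_malfunction(aggregate_to_minutes(s2)))
  d0 <- summarize_days(m0)
  d1 <- summarize_days(m1)
  expect_equal(d1$wear_min[1], d0$wear_min[1] - 30L)
  expect_true(all(d1$wear_min <= d0$wear_min))
  untouched <- setdiff(seq_len(nrow(m0)), gap_min)
  expect_equal(
    (m1$cpm < 100)[untouched] & m1$wear[untouched],
    (m0$cpm < 100)[untouched] & m0$wear[untouched]
  )
})
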