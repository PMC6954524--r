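# Brute-force reference implementations and fixture builders. The
# oracles are deliberately naive (single pass, explicit loops) and stay
# independent of the code paths they check.

# Minute-level fixture matching the aggregate_to_minutes() layout.
make_minutes <- function(cpm, start = as.POSIXct("2019-04-01 00:00:00", tz = "UTC"),
                         id = "T") {
  time <- start + (seq_along(cpm) - 1) * 60
  tibble::tibble(
    participant_id = id, time = time, date = as.Date(time, tz = "UTC"),
    cpm = as.numeric(cpm), malfunction = FALSE, wear = TRUE
  )
}

# Straight-line window sum for epoch -> minute aggregation.
oracle_minute_agg <- function(counts, epoch_length) {
  k <- 60 / epoch_length
  n <- floor(length(counts) / k)
  vapply(seq_len(n), function(m) sum(counts[((m - 1) * k + 1):(m * k)]), numeric(1))
}

# Exhaustive zero-run scan for non-wear flags.
oracle_nonwear_wear <- function(cpm, max_zero_run = 20) {
  n <- length(cpm)
  wear <- rep(TRUE, n)
  i <- 1
  while (i <= n) {
    if (cpm[i] == 0) {
      j <- i
      while (j < n && cpm[j + 1] == 0) j <- j + 1
      if (j - i + 1 > max_zero_run) wear[i:j] <- FALSE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  wear
}

# Full single-pass reduction of one minute stream: malfunction, non-wear,
# wear and sedentary tallies.
oracle_reduce_minutes <- function(cpm) {
  malf <- cpm > 20000
  wear <- oracle_nonwear_wear(cpm)
  worn <- wear & !malf
  list(
    malfunction = malf, wear = wear,
    wear_min = sum(worn),
    sedentary_min = sum(worn & cpm < 100)
  )
}

# Rank-then-Pearson Spearman via base R.
oracle_spearman <- function(x, y) {
  stats::cor(x, y, method = "spearman")
}

# Unweighted kappa from the raw contingency table.
oracle_kappa <- function(a, b, levels) {
  tab <- table(factor(a, levels = levels), factor(b, levels = levels))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# Direct double sum over the K x K table for the quadratic-weighted kappa.
oracle_wkappa <- function(a, b, K) {
  n <- length(a)
  o <- matrix(0, K, K)
  for (t in seq_len(n)) o[a[t], b[t]] <- o[a[t], b[t]] + 1 / n
  ra <- rowSums(o)
  rb <- colSums(o)
  num <- 0
  den <- 0
  for (i in 1:K) {
    for (j in 1:K) {
      v <- ((i - j) / (K - 1))^2
      num <- num + v * o[i, j]
      den <- den + v * ra[i] * rb[j]
    }
  }
  1 - num / den
}

# Long-format questionnaire fixture: one participant x administration.
make_response <- function(id = "P1", group = "children", administration = "Q1",
                          weekday = c(30, 30, 30, 30), weekend = c(30, 30, 30, 30)) {
  tibble::tibble(
    participant_id = id,
    group = group,
    respondent = if (group == "children") "parent_proxy" else "self",
    administration = administration,
    item = sb_items(group),
    weekday_min = weekday,
    weekend_min = weekend
  )
}
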