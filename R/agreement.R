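# Agreement statistics for method-comparison studies, implemented from
# first principles: Spearman rank correlation, Cohen's kappa (unweighted
# and quadratic-weighted on quartiles), Bland-Altman bias with 95% limits
# of agreement, the Pitman trend test for heteroscedasticity, and the
# chi-square goodness-of-fit test. p-values use t-approximations (the
# conventional choice at the sample sizes of field validation studies);
# an exact permutation p-value is available for very small n.

complete_pairs <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  list(x = x[keep], y = y[keep], n = sum(keep))
}

pearson_r <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  sum(xc * yc) / (sx * sy)
}

r_pvalue_t <- function(r, n) {
  # two-sided p from the t-approximation with n - 2 df
  if (abs(r) >= 1) {
    return(0)
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Spearman rank correlation with tie-aware ranks
#'
#' Computes rho as the Pearson correlation of mid-ranks (ties receive
#' their average rank) and a two-sided p-value from the t-approximation
#' with n - 2 degrees of freedom. For `method = "permutation"` the exact
#' permutation p-value is computed by full enumeration (n <= 8 only).
#' A helper flag marks rho >= 0.30, the conventional threshold for
#' acceptable agreement in questionnaire validation.
#'
#' @param x,y Paired continuous measurements; incomplete pairs dropped.
#' @param method `"t"` (default) or `"permutation"`.
#' @return A list: `rho`, `p`, `n`, `acceptable` (rho >= 0.30).
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))$rho # 0.8
spearman_rho <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  p <- complete_pairs(x, y)
  if (p$n < 3) {
    stop_insufficient_data("Spearman correlation needs at least 3 complete pairs")
  }
  rx <- rank(p$x, ties.method = "average")
  ry <- rank(p$y, ties.method = "average")
  rho <- pearson_r(rx, ry)
  pval <- if (method == "t") {
    r_pvalue_t(rho, p$n)
  } else {
    if (p$n > 8) {
      stop("exact permutation p-value supported for n <= 8 only", call. = FALSE)
    }
    perms <- permutations_of(p$n)
    null_rhos <- apply(perms, 1, function(idx) pearson_r(rx, ry[idx]))
    mean(abs(null_rhos) >= abs(rho) - 1e-12)
  }
  list(rho = rho, p = pval, n = p$n, acceptable = rho >= 0.30)
}

permutations_of <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Rank-based quartile labels
#'
#' Assigns each value to a quartile by splitting the sorted positions
#' into four equal blocks: label = ceiling(4 * rank / n), with tied
#' values sharing the bin of their average rank. This makes the marginal
#' distribution as uniform as ties permit, which is the intent when two
#' methods are each binned on their own distribution before a quartile
#' agreement analysis. A sample-quantile cut (`method = "quantile"`) is
#' provided for sensitivity analysis.
#'
#' @param values Numeric vector, n >= 4.
#' @param n_bins Number of bins (default 4).
#' @param method `"rank"` (default) or `"quantile"`.
#' @return Integer labels in `1:n_bins`.
#' @export
#' @examples
#' quartile_bins(1:8) # 1 1 2 2 3 3 4 4
quartile_bins <- function(values, n_bins = 4, method = c("rank", "quantile")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < n_bins) {
    stop_insufficient_data(sprintf("need at least %d values to form %d bins", n_bins, n_bins))
  }
  if (method == "rank") {
    r <- rank(values, ties.method = "average")
    as.integer(ceiling(n_bins * r / n))
  } else {
    qs <- stats::quantile(values, probs = seq_len(n_bins - 1) / n_bins, names = FALSE)
    as.integer(cut(values, breaks = c(-Inf, qs, Inf), labels = FALSE))
  }
}

kappa_table <- function(a, b, levels = NULL) {
  if (length(a) != length(b)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  levels <- levels %||% sort(unique(c(a, b)))
  tab <- table(factor(a, levels = levels), factor(b, levels = levels))
  tab / sum(tab)
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement from the product of the marginals. Used here to compare
#' guideline classifications (meeting vs not meeting 120 min/day)
#' between two methods or administrations. A helper flag marks
#' k >= 0.40, the conventional acceptability threshold.
#'
#' @param a,b Equal-length label vectors over a shared category set.
#' @param levels Optional explicit category set.
#' @return A list: `kappa`, `p_o`, `p_e`, `n`, `acceptable`.
#' @export
cohen_kappa <- function(a, b, levels = NULL) {
  props <- kappa_table(a, b, levels)
  p_o <- sum(diag(props))
  p_e <- sum(rowSums(props) * colSums(props))
  if (1 - p_e < .Machine$double.eps) {
    stop("kappa undefined: both raters constant and identical", call. = FALSE)
  }
  k <- (p_o - p_e) / (1 - p_e)
  list(
    kappa = k, p_o = p_o, p_e = p_e,
    n = sum(!is.na(a) & !is.na(b)), acceptable = k >= 0.40
  )
}

#' Quadratic-weighted Cohen's kappa for ordinal categories
#'
#' Agreement for ordinal labels `1:K` penalising disagreements by squared
#' category distance: disagreement weights `v_ij = ((i - j) / (K - 1))^2`
#' and `kappa = 1 - sum(v * observed) / sum(v * expected)`. With K = 2
#' this reduces exactly to the unweighted kappa. Used here for quartile
#' agreement between methods.
#'
#' @param a,b Ordinal labels (integers in `1:K`).
#' @param K Number of ordered categories; defaults to the largest label.
#' @return A list: `kappa`, `n`, `acceptable` (k >= 0.40).
#' @export
weighted_kappa_quadratic <- function(a, b, K = NULL) {
  keep <- !is.na(a) & !is.na(b)
  a <- as.integer(a[keep])
  b <- as.integer(b[keep])
  K <- K %||% max(a, b)
  if (K < 2) {
    stop("weighted kappa needs at least 2 ordered categories", call. = FALSE)
  }
  if (any(c(a, b) < 1L) || any(c(a, b) > K)) {
    stop("labels must lie in 1..K", call. = FALSE)
  }
  props <- kappa_table(a, b, levels = seq_len(K))
  i <- matrix(seq_len(K), K, K)
  v <- ((i - t(i)) / (K - 1))^2
  expected <- outer(rowSums(props), colSums(props))
  denom <- sum(v * expected)
  if (denom < .Machine$double.eps) {
    stop("kappa undefined: both raters constant and identical", call. = FALSE)
  }
  k <- 1 - sum(v * props) / denom
  list(kappa = k, n = length(a), acceptable = k >= 0.40)
}

#' Bland-Altman analysis of paired differences
#'
#' Bias is the mean of the differences `d = x - y`, with the 95% limits
#' of agreement `bias +/- 1.96 * sd(d)` (sample SD, n - 1 denominator;
#' 1.96 used verbatim rather than a t-quantile, per the classical
#' definition). Orient `x` as the questionnaire and `y` as the reference
#' so that under-reporting yields a negative bias.
#'
#' @param x,y Paired measurements; incomplete pairs dropped.
#' @return A list: `bias`, `sd_diff`, `loa_low`, `loa_high`, `n`, plus
#'   `differences` and `means` for plotting.
#' @export
bland_altman <- function(x, y) {
  p <- complete_pairs(x, y)
  if (p$n < 2) {
    stop_insufficient_data("Bland-Altman analysis needs at least 2 complete pairs")
  }
  d <- p$x - p$y
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  list(
    bias = bias, sd_diff = sd_diff,
    loa_low = bias - 1.96 * sd_diff, loa_high = bias + 1.96 * sd_diff,
    n = p$n, differences = d, means = (p$x + p$y) / 2
  )
}

#' Pitman trend test for heteroscedasticity between paired methods
#'
#' Checks whether the disagreement between two methods grows with the
#' magnitude of what is being measured. Two variants: `"classic"`
#' correlates the signed difference `x - y` with the pair mean
#' `(x + y) / 2`; `"absolute"` (default) correlates the absolute
#' difference `|x - y|` with the pair mean, the form usually reported
#' alongside Bland-Altman tables. Heteroscedasticity is declared when
#' r > 0 with two-sided p < 0.05.
#'
#' @param x,y Paired measurements; incomplete pairs dropped.
#' @param variant `"absolute"` (default) or `"classic"`.
#' @return A list: `r`, `p`, `heteroscedastic`, `variant`, `n`.
#' @export
pitman_trend <- function(x, y, variant = c("absolute", "classic")) {
  variant <- match.arg(variant)
  p <- complete_pairs(x, y)
  if (p$n < 3) {
    stop_insufficient_data("Pitman trend test needs at least 3 complete pairs")
  }
  d <- p$x - p$y
  if (variant == "absolute") d <- abs(d)
  m <- (p$x + p$y) / 2
  r <- pearson_r(d, m)
  pval <- r_pvalue_t(r, p$n)
  list(
    r = r, p = pval, heteroscedastic = r > 0 && pval < 0.05,
    variant = variant, n = p$n
  )
}

#' Chi-square goodness-of-fit test
#'
#' Compares observed category counts against expected proportions:
#' `stat = sum((O - E)^2 / E)` with `categories - 1` degrees of freedom.
#' Used to check whether a reliability or validity subsample has the same
#' composition (sex, age band, school type) as the full first-survey
#' sample.
#'
#' @param observed_counts Non-negative integer counts per category.
#' @param expected_props Expected proportions; must sum to 1 with all
#'   resulting expected counts positive.
#' @return A list: `stat`, `df`, `p`, `expected`.
#' @export
#' @examples
#' chi2_gof(c(60, 40), c(0.5, 0.5))$stat # 4
chi2_gof <- function(observed_counts, expected_props) {
  if (length(observed_counts) != length(expected_props)) {
    stop("observed and expected must have equal length", call. = FALSE)
  }
  if (abs(sum(expected_props) - 1) > 1e-8) {
    stop("expected proportions must sum to 1", call. = FALSE)
  }
  n <- sum(observed_counts)
  expected <- n * expected_props
  if (any(expected <= 0)) {
    stop("all expected counts must be positive", call. = FALSE)
  }
  stat <- sum((observed_counts - expected)^2 / expected)
  df <- length(observed_counts) - 1L
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE), expected = expected)
}

#' Full paired-method agreement panel
#'
#' Convenience wrapper computing, for one pair of continuous
#' measurements, every statistic reported in a validity table: Spearman
#' rho, binary kappa on guideline classification, quadratic-weighted
#' kappa on quartiles (each method binned on its own distribution),
#' Bland-Altman bias with limits of agreement, and the Pitman trend
#' correlation.
#'
#' @param x Questionnaire-side measurements (min/day).
#' @param y Reference-side measurements (min/day).
#' @param guideline_limit Guideline cut-off for the binary kappa.
#' @param trend_variant Variant passed to [pitman_trend()].
#' @return A one-row tibble of class `agreement_result`.
#' @export
agreement_result <- function(x, y, guideline_limit = 120,
                             trend_variant = "absolute") {
  p <- complete_pairs(x, y)
  if (p$n < 4) {
    stop_insufficient_data("agreement panel needs at least 4 complete pairs")
  }
  sp <- spearman_rho(p$x, p$y)
  kq <- weighted_kappa_quadratic(quartile_bins(p$x), quartile_bins(p$y), K = 4)
  kb <- tryCatch(
    cohen_kappa(
      classify_guideline(p$x, guideline_limit),
      classify_guideline(p$y, guideline_limit),
      levels = c(FALSE, TRUE)
    )$kappa,
    error = function(e) NA_real_
  )
  ba <- bland_altman(p$x, p$y)
  tr <- tryCatch(pitman_trend(p$x, p$y, trend_variant), error = function(e) NULL)
  out <- tibble::tibble(
    n = p$n,
    rho = sp$rho, rho_p = sp$p,
    kappa_binary = kb,
    kappa_quartile = kq$kappa,
    bias = ba$bias, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    trend_r = if (is.null(tr)) NA_real_ else tr$r,
    trend_p = if (is.null(tr)) NA_real_ else tr$p
  )
  class(out) <- c("agreement_result", class(out))
  out
}

#' Bland-Altman plot
#'
#' Scatter of paired differences against pair means with the bias and
#' 95% limits of agreement drawn as horizontal lines.
#'
#' @param x,y Paired measurements, oriented as in [bland_altman()].
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x, y, xlab = "Mean of methods (min/day)",
                              ylab = "Difference (min/day)") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_bland_altman() requires the ggplot2 package", call. = FALSE)
  }
  ba <- bland_altman(x, y)
  df <- tibble::tibble(mean = ba$means, diff = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high), linetype = "dashed") +
    ggplot2::labs(x = xlab, y = ylab)
}
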