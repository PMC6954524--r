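# Agreement statistics against hand computations, base-R cross-checks
# and brute-force oracles.

test_that("Spearman rho handles monotone data, a hand-computed case, and ties", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  # d = rank differences (1,-1,1,-1,0): rho = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(1:10, n, replace = TRUE) # ties on purpose
    y <- x + rnorm(n, 0, 3)
    expect_equal(spearman_rho(x, y)$rho, oracle_spearman(x, y), tolerance = 1e-12)
  }
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 2:1), class = "sedvalid_insufficient_data")
  expect_true(spearman_rho(1:20, 1:20 + rnorm(20, 0, 2))$acceptable)
})

test_that("the t-approximation p-value matches cor.test and permutation matches exact enumeration", {
  set.seed(2)
  x <- rnorm(15)
  y <- x + rnorm(15)
  ours <- spearman_rho(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)

  x6 <- c(1.2, 3.4, 2.2, 5.9, 4.4, 0.3)
  y6 <- c(2.0, 3.1, 2.5, 4.0, 5.5, 1.0)
  p_perm <- spearman_rho(x6, y6, method = "permutation")$p
  ref6 <- stats::cor.test(x6, y6, method = "spearman", exact = TRUE)
  expect_equal(p_perm, ref6$p.value, tolerance = 1e-10)
  expect_error(spearman_rho(rnorm(9), rnorm(9), method = "permutation"), "n <= 8")
})

test_that("rank-based quartile bins follow the ceiling rule and are rank-invariant", {
  expect_equal(quartile_bins(1:8), c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_equal(length(unique(quartile_bins(rep(7, 10)))), 1L)
  set.seed(3)
  v <- rnorm(37)
  expect_equal(quartile_bins(v), quartile_bins(exp(v))) # monotone transform
  expect_equal(quartile_bins(v), quartile_bins(rank(v)))
  expect_error(quartile_bins(1:3), class = "sedvalid_insufficient_data")
  qq <- quartile_bins(1:8, method = "quantile")
  expect_equal(qq, c(1, 1, 2, 2, 3, 3, 4, 4))
})

test_that("Cohen's kappa matches the hand-computed 2x2 case and the contingency-table oracle", {
  expect_equal(cohen_kappa(1:4, 1:4)$kappa, 1)
  a <- c(rep("y", 4), "y", rep("n", 2), rep("n", 3))
  b <- c(rep("y", 4), "n", rep("y", 2), rep("n", 3))
  k <- cohen_kappa(a, b)
  expect_equal(k$p_o, 0.7)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.4)
  set.seed(4)
  for (i in 1:10) {
    aa <- sample(1:3, 40, replace = TRUE)
    bb <- sample(1:3, 40, replace = TRUE)
    expect_equal(cohen_kappa(aa, bb, levels = 1:3)$kappa,
      oracle_kappa(aa, bb, 1:3),
      tolerance = 1e-12
    )
  }
  expect_error(cohen_kappa(rep(1, 5), rep(1, 5)), "undefined")
})

test_that("kappa is near zero for independent labels", {
  set.seed(5)
  a <- sample(0:1, 10000, replace = TRUE)
  b <- sample(0:1, 10000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.03)
})

test_that("quadratic-weighted kappa matches a double-sum oracle and reduces to unweighted at K = 2", {
  expect_equal(weighted_kappa_quadratic(c(1, 2, 3, 4), c(1, 2, 3, 4))$kappa, 1)
  set.seed(6)
  for (i in 1:10) {
    a <- sample(1:4, 50, replace = TRUE)
    b <- pmin(4, pmax(1, a + sample(-1:1, 50, replace = TRUE)))
    expect_equal(weighted_kappa_quadratic(a, b, K = 4)$kappa,
      oracle_wkappa(a, b, 4),
      tolerance = 1e-12
    )
  }
  # exhaustive at K = 2 for n = 4, plus random larger cases
  grid <- expand.grid(rep(list(1:2), 8))
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, 1:4])
    b <- as.integer(grid[r, 5:8])
    wk <- tryCatch(weighted_kappa_quadratic(a, b, K = 2)$kappa, error = identity)
    uk <- tryCatch(cohen_kappa(a, b, levels = 1:2)$kappa, error = identity)
    if (inherits(wk, "error") || inherits(uk, "error")) {
      expect_true(inherits(wk, "error") && inherits(uk, "error"))
    } else {
      expect_equal(wk, uk, tolerance = 1e-12)
    }
  }
  set.seed(7)
  for (i in 1:20) {
    a <- sample(1:2, 30, replace = TRUE)
    b <- sample(1:2, 30, replace = TRUE)
    expect_equal(
      weighted_kappa_quadratic(a, b, K = 2)$kappa,
      cohen_kappa(a, b, levels = 1:2)$kappa,
      tolerance = 1e-12
    )
  }
})

test_that("both kappas agree with the e1071 cross-check on random tables", {
  set.seed(8)
  a <- sample(1:4, 200, replace = TRUE)
  b <- pmin(4, pmax(1, a + sample(-2:2, 200, replace = TRUE)))
  tab <- table(factor(a, levels = 1:4), factor(b, levels = 1:4))
  ref <- e1071::classAgreement(tab)
  expect_equal(cohen_kappa(a, b, levels = 1:4)$kappa, ref$kappa, tolerance = 1e-10)
})

test_that("Bland-Altman bias and limits of agreement match hand computations", {
  x <- c(5, 7, 9)
  same <- bland_altman(x, x)
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  off <- bland_altman(x + 5, x)
  expect_equal(off$bias, 5)
  expect_equal(off$sd_diff, 0)
  expect_equal(c(off$loa_low, off$loa_high), c(5, 5))

  # d = (-1, 0, 1): bias 0, sd 1, LOA -/+ 1.96
  ba <- bland_altman(c(0, 2, 4), c(1, 2, 3))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_low, ba$loa_high), c(-1.96, 1.96))

  expect_error(bland_altman(1, 2), class = "sedvalid_insufficient_data")
})

test_that("bias is antisymmetric in the method order and LOA mirror", {
  set.seed(9)
  x <- rnorm(40, 100, 20)
  y <- rnorm(40, 130, 25)
  fwd <- bland_altman(x, y)
  rev <- bland_altman(y, x)
  expect_equal(fwd$bias, -rev$bias)
  expect_equal(fwd$loa_low, -rev$loa_high)
  expect_equal(fwd$loa_high, -rev$loa_low)
})

test_that("Bland-Altman recovers a configured difference distribution", {
  set.seed(10)
  n <- 5000
  b <- -420
  s <- 100
  y <- rnorm(n, 530, 40)
  x <- y + rnorm(n, b, s)
  ba <- bland_altman(x, y)
  tol <- 3 * s / sqrt(n)
  expect_lt(abs(ba$bias - b), tol)
  expect_lt(abs(ba$loa_low - (b - 1.96 * s)), 3 * tol)
  expect_lt(abs(ba$loa_high - (b + 1.96 * s)), 3 * tol)
})

test_that("Pitman trend test flags proportional error and rejects degenerate input", {
  expect_error(pitman_trend(1:10 + 5, 1:10, variant = "classic"), "constant")
  set.seed(11)
  m <- runif(2000, 100, 600)
  x <- m + rnorm(2000, 0, 0.1 * m) # error grows with the mean
  y <- m + rnorm(2000, 0, 0.1 * m)
  tr <- pitman_trend(x, y, variant = "absolute")
  expect_gt(tr$r, 0)
  expect_lt(tr$p, 0.05)
  expect_true(tr$heteroscedastic)
  # classic variant sees no signed trend in the same construction
  cl <- pitman_trend(x, y, variant = "classic")
  expect_lt(abs(cl$r), 0.1)
})

test_that("chi-square goodness of fit matches hand computation and chisq.test", {
  id <- chi2_gof(c(25, 25, 50), c(0.25, 0.25, 0.5))
  expect_equal(id$stat, 0)
  expect_equal(id$p, 1)

  g <- chi2_gof(c(60, 40), c(0.5, 0.5))
  expect_equal(g$stat, 4)
  ref <- stats::chisq.test(c(60, 40), p = c(0.5, 0.5))
  expect_equal(g$stat, unname(ref$statistic))
  expect_equal(g$p, ref$p.value)

  expect_error(chi2_gof(c(1, 2), c(0.6, 0.5)), "sum to 1")
  expect_error(chi2_gof(c(1, 2), c(1, 0)), "positive")
})

test_that("rho and the kappas are invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rgamma(60, 3, 0.01)
  y <- x * exp(rnorm(60, 0, 0.3))
  f <- function(v) log(v + 1)
  expect_equal(spearman_rho(x, y)$rho, spearman_rho(f(x), f(y))$rho)
  expect_equal(
    weighted_kappa_quadratic(quartile_bins(x), quartile_bins(y), K = 4)$kappa,
    weighted_kappa_quadratic(quartile_bins(f(x)), quartile_bins(f(y)), K = 4)$kappa
  )
})

test_that("the agreement panel is self-consistent with its component statistics", {
  set.seed(13)
  y <- rnorm(80, 530, 50)
  x <- 0.25 * y + rnorm(80, 0, 25)
  panel <- agreement_result(x, y)
  expect_equal(panel$rho, spearman_rho(x, y)$rho)
  expect_equal(panel$bias, bland_altman(x, y)$bias)
  expect_equal(
    panel$kappa_quartile,
    weighted_kappa_quadratic(quartile_bins(x), quartile_bins(y), K = 4)$kappa
  )
  expect_equal(panel$trend_r, pitman_trend(x, y)$r)
})
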