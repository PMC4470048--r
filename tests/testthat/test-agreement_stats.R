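test_that("exact signed-rank p matches the enumeration oracle", {
  # all-positive differences of 5 pairs: p = 2/32
  pm <- paired_measurements(c(2, 4, 6, 9, 11), c(1, 2, 3, 5, 6))
  w <- wilcoxon_paired(pm)
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$statistic, 15)
  expect_equal(w$method, "exact")
  # random datasets, n <= 10, including ties and zero differences
  set.seed(101)
  for (i in 1:30) {
    n <- sample(4:10, 1)
    x <- round(rnorm(n, sd = 3), sample(0:1, 1))
    y <- round(rnorm(n, sd = 3), 1)
    d <- x - y
    if (sum(d != 0) < 3) next
    p_pkg <- wilcoxon_paired(paired_measurements(x, y))$p_value
    expect_equal(p_pkg, brute_force_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("signed-rank agrees with the reference implementation", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)  # continuous: no ties, no zeros
    p_pkg <- wilcoxon_paired(paired_measurements(x, y))$p_value
    p_ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
})

test_that("signed-rank handles degenerate and symmetric cases", {
  x <- c(3, 1, 4, 1, 5)
  w0 <- wilcoxon_paired(paired_measurements(x, x))
  expect_equal(w0$p_value, 1)
  expect_match(w0$note, "all differences zero")
  y <- c(2, 3, 2, 5, 1)
  wxy <- wilcoxon_paired(paired_measurements(x, y))
  wyx <- wilcoxon_paired(paired_measurements(y, x))
  expect_equal(wxy$p_value, wyx$p_value)
  n <- wxy$n_effective
  expect_equal(wxy$statistic + wyx$statistic, n * (n + 1) / 2)
  # large-n normal approximation stays close to the reference
  set.seed(2)
  x <- rnorm(40); y <- rnorm(40, 0.3)
  p_pkg <- wilcoxon_paired(paired_measurements(x, y))$p_value
  p_ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                              correct = TRUE)$p.value
  expect_lt(abs(p_pkg - p_ref), 1e-6)
})

test_that("Bland-Altman matches a two-pass oracle", {
  # constant offset: bias 1, sd 0, degenerate limits
  ba <- bland_altman(paired_measurements(c(2, 3, 4), c(1, 2, 3)))
  expect_equal(ba$bias, 1); expect_equal(ba$sd, 0)
  expect_equal(ba$loa, c(1, 1))
  ba0 <- bland_altman(paired_measurements(1:5, 1:5))
  expect_equal(ba0$bias, 0); expect_equal(ba0$sd, 0)
  set.seed(33)
  x <- rnorm(50, 90, 15); y <- x + rnorm(50, 2, 5)
  pm <- paired_measurements(x, y)
  ba <- bland_altman(pm)
  d <- x - y
  m1 <- sum(d) / length(d)
  s2 <- sum((d - m1)^2) / (length(d) - 1)
  expect_equal(ba$bias, m1, tolerance = 1e-12)
  expect_equal(ba$sd, sqrt(s2), tolerance = 1e-12)
  expect_equal(ba$loa, m1 + c(-1.96, 1.96) * sqrt(s2), tolerance = 1e-12)
  expect_equal(ba$pct_bias, mean(100 * d / ((x + y) / 2)),
               tolerance = 1e-12)
  # antisymmetry of the bias, symmetry of the SD
  ba_swap <- bland_altman(paired_measurements(y, x))
  expect_equal(ba_swap$bias, -ba$bias)
  expect_equal(ba_swap$sd, ba$sd)
  # zero-denominator pairs are excluded with a warning
  expect_warning(
    bz <- bland_altman(paired_measurements(c(1, 2, -3), c(1, 2, 3))),
    "zero denominator")
  expect_equal(bz$pct_bias, 0)
  bd <- bland_altman(pm, denominator = "second")
  expect_equal(bd$pct_bias, mean(100 * d / y), tolerance = 1e-12)
})

test_that("correlation and regression recover exact lines", {
  x <- c(1, 2, 3, 4, 7)
  co <- correlate(paired_measurements(x, 2 * x + 1))
  expect_equal(co$r, 1); expect_equal(co$slope, 2)
  expect_equal(co$intercept, 1); expect_equal(co$r2, 1)
  expect_equal(co$p_value, 0)
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  c1 <- correlate(paired_measurements(a, b))
  c2 <- correlate(paired_measurements(b, a))
  expect_equal(c1$r, c2$r, tolerance = 1e-12)
  expect_equal(c1$r2, c1$r^2, tolerance = 1e-12)
  ref <- stats::cor.test(a, b)
  expect_equal(c1$p_value, ref$p.value, tolerance = 1e-12)
  fit <- stats::lm(b ~ a)
  expect_equal(c1$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_error(correlate(paired_measurements(rep(1, 5), rnorm(5))),
               "zero variance")
})

test_that("the report layer produces the combined comparison table", {
  set.seed(9)
  rec <- expand.grid(subject = paste0("s", 1:8),
                     condition = c("gated", "nongated"),
                     metric = c("sv", "mean_ke"),
                     stringsAsFactors = FALSE)
  rec$value <- rnorm(nrow(rec), 90, 10)
  rec$units <- "ml"
  tab <- agreement_table(rec, "gated", "nongated")
  expect_equal(nrow(tab), 2L)
  expect_setequal(tab$metric, c("sv", "mean_ke"))
  expect_true(all(c("bias", "sd", "pct_bias", "r2", "wilcoxon_p") %in%
                    names(tab)))
  rep1 <- agreement_report(paired_measurements(rnorm(10), rnorm(10)))
  expect_equal(rep1$loa[2] - rep1$bias, 1.96 * rep1$sd, tolerance = 1e-12)
  expect_equal(rep1$r2, rep1$r^2, tolerance = 1e-12)
})

test_that("paired measurements are validated", {
  expect_error(paired_measurements(1:3, 1:4), "equal length")
  expect_error(paired_measurements(1:2, 1:2), "at least 3")
  expect_error(paired_measurements(c(1, NA, 3), 1:3), "missing")
})
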