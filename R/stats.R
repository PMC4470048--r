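#' Paired measurements of one metric under two conditions
#'
#' @param x,y numeric vectors of the same metric under two conditions
#'   (same units), paired by position. Missing values must be excluded
#'   explicitly by the caller.
#' @param labels optional subject identifiers.
#' @export
paired_measurements <- function(x, y, labels = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (anyNA(x) || anyNA(y))
    stop("missing values present; exclude pairs explicitly first")
  if (is.null(labels)) labels <- as.character(seq_along(x))
  structure(list(x = x, y = y, labels = labels, n = length(x)),
            class = "paired_measurements")
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed paired signed-rank test. Zero differences are dropped
#' (Wilcoxon's original rule). For n <= 25 effective pairs the p value
#' is exact, from the full distribution of the positive-rank sum under
#' sign exchange (dynamic programming over the doubled midranks, valid
#' with ties): `p = Pr(|W - mu| >= |w_obs - mu|)`, `mu = n(n+1)/4`. For
#' larger n the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param pm a [paired_measurements()].
#' @return list with `statistic` (positive-rank sum W), `p_value`,
#'   `n_effective`, `method`, and `note` when all differences are zero.
#' @export
wilcoxon_paired <- function(pm) {
  stopifnot(inherits(pm, "paired_measurements"))
  d <- pm$x - pm$y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1, n_effective = 0L,
                method = "degenerate",
                note = "all differences zero; p = 1"))
  if (n < 3L) stop("fewer than 3 nonzero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 25L) {
    w2 <- as.integer(round(2 * r))     # doubled midranks are integers
    tot <- sum(w2)
    f <- numeric(tot + 1)              # f[s+1] = #assignments with sum s
    f[1] <- 1
    for (w in w2) {
      g <- f
      g[(w + 1):(tot + 1)] <- g[(w + 1):(tot + 1)] + f[1:(tot + 1 - w)]
      f <- g
    }
    s <- 0:tot
    dev <- abs(s - 2 * mu)
    obs <- abs(2 * W - 2 * mu)
    p <- sum(f[dev >= obs - 1e-9]) / 2^n
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = W, p_value = p, n_effective = n, method = method)
}

#' Bland-Altman agreement
#'
#' Agreement between two measurements of the same quantity: bias (mean
#' of the differences, first condition minus second), SD of the
#' differences, limits of agreement `bias +/- 1.96 SD`, and the
#' percentage bias. The percentage difference of a pair defaults to
#' `100 (x - y) / ((x + y) / 2)`; pairs with `x + y = 0` are excluded
#' from the percentage with a warning. `denominator = "second"` divides
#' by `y` instead.
#'
#' @param pm a [paired_measurements()].
#' @param denominator `"mean"` or `"second"`.
#' @return list with `bias`, `sd`, `loa` (length 2), `pct_bias`, `n`.
#' @export
bland_altman <- function(pm, denominator = c("mean", "second")) {
  stopifnot(inherits(pm, "paired_measurements"))
  denominator <- match.arg(denominator)
  d <- pm$x - pm$y
  bias <- mean(d)
  s <- stats::sd(d)
  den <- if (denominator == "mean") (pm$x + pm$y) / 2 else pm$y
  bad <- den == 0
  if (any(bad))
    warning(sum(bad), " pair(s) with zero denominator excluded from ",
            "percentage bias")
  pct <- mean(100 * d[!bad] / den[!bad])
  list(bias = bias, sd = s, loa = bias + c(-1.96, 1.96) * s,
       pct_bias = pct, n = pm$n)
}

#' Pearson correlation and linear regression
#'
#' Pearson r (with r^2), ordinary least-squares regression of y on x,
#' and the two-tailed p value from the t distribution with n - 2
#' degrees of freedom.
#'
#' @param pm a [paired_measurements()].
#' @return list with `r`, `r2`, `slope`, `intercept`, `p_value`, `n`.
#' @export
correlate <- function(pm) {
  stopifnot(inherits(pm, "paired_measurements"))
  if (stats::var(pm$x) == 0) stop("x has zero variance")
  n <- pm$n
  r <- stats::cor(pm$x, pm$y)
  slope <- r * stats::sd(pm$y) / stats::sd(pm$x)
  intercept <- mean(pm$y) - slope * mean(pm$x)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, r2 = r^2, slope = slope, intercept = intercept,
       p_value = p, n = n)
}

#' Full agreement report for one paired metric
#'
#' Combines [bland_altman()], [correlate()] and [wilcoxon_paired()]
#' into the standard comparison row: bias +/- SD, limits of agreement,
#' percentage bias, r/r^2, regression line, Wilcoxon p.
#'
#' @param pm a [paired_measurements()].
#' @param denominator passed to [bland_altman()].
#' @return An object of class `agreement_report` (a named list).
#' @export
agreement_report <- function(pm, denominator = "mean") {
  ba <- bland_altman(pm, denominator)
  co <- correlate(pm)
  wi <- wilcoxon_paired(pm)
  structure(c(ba, co[c("r", "r2", "slope", "intercept")],
              list(regression_p = co$p_value, wilcoxon_p = wi$p_value,
                   wilcoxon_statistic = wi$statistic)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<agreement_report> n = %d\n",
    "  bias %.3g +/- %.3g (LoA %.3g to %.3g), %%bias %.3g\n",
    "  r = %.3f (r2 = %.3f), y = %.3g + %.3g x, Wilcoxon p = %.3g\n"),
    x$n, x$bias, x$sd, x$loa[1], x$loa[2], x$pct_bias,
    x$r, x$r2, x$intercept, x$slope, x$wilcoxon_p))
  invisible(x)
}

#' Agreement table across metrics (absolute and percentage bias)
#'
#' Builds the per-metric comparison table from a long metric table:
#' one row per metric with bias +/- SD in absolute units, percentage
#' bias, r^2 and Wilcoxon p between two condition labels.
#'
#' @param records data.frame with columns subject, condition, metric,
#'   value.
#' @param condition_a,condition_b labels to compare (difference is
#'   a - b).
#' @return data.frame, one row per metric.
#' @export
agreement_table <- function(records, condition_a, condition_b) {
  metrics <- sort(unique(records$metric))
  rows <- lapply(metrics, function(m) {
    a <- records[records$metric == m & records$condition == condition_a, ]
    b <- records[records$metric == m & records$condition == condition_b, ]
    common <- intersect(a$subject, b$subject)
    if (length(common) < 3L) return(NULL)
    pm <- paired_measurements(
      a$value[match(common, a$subject)],
      b$value[match(common, b$subject)], labels = common)
    rep_ <- agreement_report(pm)
    data.frame(metric = m, n = rep_$n, bias = rep_$bias, sd = rep_$sd,
               pct_bias = rep_$pct_bias, r2 = rep_$r2,
               wilcoxon_p = rep_$wilcoxon_p)
  })
  do.call(rbind, rows)
}
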