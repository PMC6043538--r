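#' One-sample t-test with Cohen's d
#'
#' Wraps [stats::t.test()] and augments it with the one-sample effect size
#' `d = (mean - mu0) / sd` (so that `d = t / sqrt(n)` exactly) and the
#' two-sided 95% CI of the mean. Hypothesis-driven analyses in this
#' pipeline use one-sided p-values (`sidedness = "greater"`), exploratory
#' ones two-sided.
#'
#' @param values Numeric vector of per-participant statistics.
#' @param mu0 Null value.
#' @param sidedness `"two.sided"`, `"greater"`, or `"less"`.
#' @return One-row tibble: `statistic` (t), `df`, `p`, `effect_size`
#'   (Cohen's d), `ci95_low`, `ci95_high`, `n`, `mean`, `sd`, `sidedness`.
#' @export
one_sample_t <- function(values, mu0 = 0, sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) abort("need at least 2 finite values", class = "membias_config_error")
  s <- sd(values)
  if (s == 0) abort("values have zero variance", class = "membias_degenerate_error")
  tt <- t.test(values, mu = mu0, alternative = sidedness)
  ci <- t.test(values, mu = mu0, alternative = "two.sided", conf.level = 0.95)$conf.int
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, effect_size = (mean(values) - mu0) / s,
         ci95_low = ci[1], ci95_high = ci[2], n = n,
         mean = mean(values), sd = s, sidedness = sidedness)
}

#' Pearson product-moment correlation test
#'
#' Wraps [stats::cor.test()]; the 95% CI of r is computed on the Fisher-z
#' scale regardless of sidedness.
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped).
#' @param sidedness `"two.sided"`, `"greater"`, or `"less"`.
#' @return One-row tibble: `statistic` (r), `df` (n - 2), `p`, `ci95_low`,
#'   `ci95_high`, `n`, `sidedness`.
#' @export
pearson_r <- function(x, y, sidedness = c("two.sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  if (length(x) != length(y)) abort("x and y lengths differ", class = "membias_config_error")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete pairs", class = "membias_config_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input; correlation undefined", class = "membias_degenerate_error")
  }
  ct <- cor.test(x, y, alternative = sidedness, method = "pearson")
  r <- unname(ct$estimate)
  ci <- if (n > 3) tanh(atanh(r) + c(-1, 1) * qnorm(0.975) / sqrt(n - 3)) else c(NA_real_, NA_real_)
  tibble(statistic = r, df = unname(ct$parameter), p = ct$p.value,
         ci95_low = ci[1], ci95_high = ci[2], n = n, sidedness = sidedness)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of the standardized values against the standard
#' normal CDF. Because the mean and SD are estimated from the same data,
#' the plain KS p-value is conservative; `lilliefors = TRUE` applies the
#' Lilliefors correction (via the nortest package) instead.
#'
#' @param values Numeric vector (n >= 5).
#' @param lilliefors Use the Lilliefors-corrected test.
#' @return One-row tibble: `statistic`, `p`, `n`, `method`.
#' @export
ks_normality <- function(values, lilliefors = FALSE) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 5L) abort("need at least 5 values", class = "membias_config_error")
  if (sd(values) == 0) abort("values have zero variance", class = "membias_degenerate_error")
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      abort("the Lilliefors variant needs the nortest package",
            class = "membias_config_error")
    }
    kt <- nortest::lillie.test(values)
    return(tibble(statistic = unname(kt$statistic), p = kt$p.value, n = n,
                  method = "lilliefors"))
  }
  z <- (values - mean(values)) / sd(values)
  kt <- suppressWarnings(ks.test(z, "pnorm"))
  tibble(statistic = unname(kt$statistic), p = kt$p.value, n = n,
         method = "ks_standard_normal")
}

#' Power of the Pearson correlation test
#'
#' Fisher-z approximation with the small-sample bias correction
#' `r / (2(n-1))`, evaluated against the critical r implied by the t
#' threshold at `n - 2` degrees of freedom (the formulation used by
#' pwr-style correlation power analysis).
#'
#' @param n Sample size (> 3; may be fractional).
#' @param r True correlation under the alternative.
#' @param alpha Significance level.
#' @param sidedness `"greater"` (one-sided, default here) or `"two.sided"`.
#' @return Power as a probability.
#' @export
power_correlation <- function(n, r, alpha = 0.05,
                              sidedness = c("greater", "two.sided")) {
  sidedness <- match.arg(sidedness)
  r <- abs(r)
  sig <- if (sidedness == "two.sided") alpha / 2 else alpha
  ttt <- qt(sig, df = n - 2, lower.tail = FALSE)
  rc <- ttt / sqrt(ttt^2 + n - 2)
  zr <- atanh(r) + r / (2 * (n - 1))
  zrc <- atanh(rc)
  pow <- pnorm((zr - zrc) * sqrt(n - 3))
  if (sidedness == "two.sided") pow <- pow + pnorm((-zr - zrc) * sqrt(n - 3))
  pow
}

#' Sample size for a correlation test
#'
#' Smallest integer n whose power under [power_correlation()] reaches the
#' target (the continuous solution of the power equation, rounded up).
#'
#' @param r Correlation under the alternative (0 < r < 1).
#' @param alpha Significance level.
#' @param power Target power.
#' @param sidedness `"greater"` (one-sided) or `"two.sided"`.
#' @return Integer sample size.
#' @export
correlation_sample_size <- function(r, alpha = 0.05, power = 0.80,
                                    sidedness = c("greater", "two.sided")) {
  sidedness <- match.arg(sidedness)
  if (!is.finite(r) || r <= 0 || r >= 1) {
    abort("r must lie strictly between 0 and 1", class = "membias_config_error")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("alpha and power must lie strictly between 0 and 1",
          class = "membias_config_error")
  }
  f <- function(n) power_correlation(n, r, alpha, sidedness) - power
  if (f(4) >= 0) return(4L)
  if (f(1e7) < 0) {
    abort("target power unattainable below n = 1e7", class = "membias_config_error")
  }
  as.integer(ceiling(uniroot(f, c(4, 1e7), tol = 1e-8)$root))
}
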