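#' Method-comparison statistics for device validation
#'
#' The statistics used to compare a new measurement device against a gold
#' standard: the interpolation line of device on gold (slope m, intercept
#' q, coefficient of determination r^2), Bland-Altman bias and limits of
#' agreement on the gold-minus-device differences, relative percentage
#' error, and a normality-gated two-sample comparison (t-test when both
#' samples pass Shapiro-Wilk, Mann-Whitney rank-sum otherwise).
#'
#' @name agreement_stats
NULL

check_pairs <- function(gold, device, min_n = 2) {
  if (length(gold) != length(device)) {
    stop("gold and device sequences differ in length")
  }
  if (length(gold) < min_n) {
    stop("insufficient data: need at least ", min_n, " pairs")
  }
  if (any(!is.finite(gold)) || any(!is.finite(device))) {
    stop("non-finite values in input")
  }
  invisible(NULL)
}

#' Correlation line between gold standard and device
#'
#' Ordinary least squares of `device` on `gold`; `r2` is the squared sample
#' correlation.
#'
#' @param gold,device equal-length numeric vectors of paired measurements.
#' @return list with slope `m`, intercept `q` and `r2`.
#' @export
#' @examples
#' linear_agreement(c(1, 2, 3), c(3, 5, 7))
linear_agreement <- function(gold, device) {
  check_pairs(gold, device)
  if (stats::sd(gold) == 0) {
    stop("degenerate regressor: gold standard values are constant")
  }
  fit <- stats::lm(device ~ gold)
  r2 <- if (stats::sd(device) == 0) 1
        else stats::cor(gold, device)^2
  list(m = unname(stats::coef(fit)[2]), q = unname(stats::coef(fit)[1]),
       r2 = r2)
}

#' Bland-Altman analysis
#'
#' Differences are oriented gold minus device. The limits of agreement use
#' the conventional 1.96 multiplier and the sample (n-1) standard
#' deviation.
#'
#' @param gold,device equal-length numeric vectors of paired measurements.
#' @return list with `ba_mean` (bias), `ba_sd`, and `ba_loa` (lower, upper
#'   limits of agreement).
#' @export
bland_altman <- function(gold, device) {
  check_pairs(gold, device)
  d <- gold - device
  m <- mean(d)
  s <- stats::sd(d)
  list(ba_mean = m, ba_sd = s, ba_loa = c(m - 1.96 * s, m + 1.96 * s))
}

#' Relative percentage error against a gold standard
#'
#' Per pair, `100 * |device - gold| / |gold|`. Pairs with `|gold| <=
#' epsilon` are excluded (the ratio is undefined at zero) and counted.
#'
#' @param gold,device equal-length numeric vectors.
#' @param epsilon exclusion threshold on `|gold|`, same units, default
#'   1e-6.
#' @return list with `pct_error_mean`, `pct_error_sd`, per-pair `values`
#'   (percent, `NA` for excluded pairs) and `n_excluded`.
#' @export
percentage_error <- function(gold, device, epsilon = 1e-6) {
  check_pairs(gold, device, min_n = 1)
  keep <- abs(gold) > epsilon
  if (!any(keep)) {
    stop("insufficient data: all pairs excluded (|gold| <= epsilon)")
  }
  vals <- rep(NA_real_, length(gold))
  vals[keep] <- 100 * abs(device[keep] - gold[keep]) / abs(gold[keep])
  kept <- vals[keep]
  list(pct_error_mean = mean(kept),
       pct_error_sd = if (length(kept) >= 2) stats::sd(kept) else NA_real_,
       values = vals,
       n_excluded = sum(!keep))
}

#' Full agreement report
#'
#' Bundles [linear_agreement()], [bland_altman()] and [percentage_error()]
#' for one gold/device comparison.
#'
#' @inheritParams percentage_error
#' @return an object of class `agreement_report`.
#' @export
agreement_report <- function(gold, device, epsilon = 1e-6) {
  la <- linear_agreement(gold, device)
  ba <- bland_altman(gold, device)
  pe <- percentage_error(gold, device, epsilon)
  structure(c(la, ba,
              list(pct_error_mean = pe$pct_error_mean,
                   pct_error_sd = pe$pct_error_sd,
                   n = length(gold))),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report>\n")
  cat(sprintf("  line: device = %.4f * gold + %.4f   (r2 = %.4f)\n",
              x$m, x$q, x$r2))
  cat(sprintf("  Bland-Altman (gold - device): bias %.4f, SD %.4f, LoA [%.4f, %.4f]\n",
              x$ba_mean, x$ba_sd, x$ba_loa[1], x$ba_loa[2]))
  cat(sprintf("  percentage error: %.2f%% +/- %.2f%%  (n = %d)\n",
              x$pct_error_mean, x$pct_error_sd, x$n))
  invisible(x)
}

#' Normality-gated two-sample comparison
#'
#' Shapiro-Wilk normality is tested on each sample; if both p-values are at
#' least 0.05 an unpaired two-sided Welch t-test is used, otherwise the
#' Mann-Whitney rank-sum test. Significance is declared at `p < alpha`.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 3.
#' @param alpha significance level, default 0.05.
#' @param paired use the paired variants (equal lengths required).
#' @return an object of class `comparison_result`: list with `test_used`
#'   (`"t_test"` or `"mann_whitney"`), `statistic`, `p_value`,
#'   `significant`, and `normality_p` (pair of Shapiro-Wilk p-values).
#' @export
compare_conditions <- function(sample_a, sample_b, alpha = 0.05,
                               paired = FALSE) {
  if (length(sample_a) < 3 || length(sample_b) < 3) {
    stop("insufficient data: each sample needs at least 3 values")
  }
  if (any(!is.finite(sample_a)) || any(!is.finite(sample_b))) {
    stop("non-finite values in input")
  }
  norm_p <- c(a = shapiro_p(sample_a), b = shapiro_p(sample_b))
  if (all(norm_p >= 0.05)) {
    ht <- stats::t.test(sample_a, sample_b, paired = paired)
    used <- "t_test"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(sample_a, sample_b, paired = paired))
    used <- "mann_whitney"
  }
  structure(list(test_used = used,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 significant = ht$p.value < alpha,
                 normality_p = norm_p),
            class = "comparison_result")
}

# shapiro.test errors on constant input; a constant sample is treated as
# maximally non-normal (degenerate), routing to the rank-sum test
shapiro_p <- function(x) {
  if (stats::sd(x) == 0) return(0)
  stats::shapiro.test(x)$p.value
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4f, p = %.4g (%s)\n",
              x$test_used, x$statistic, x$p_value,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Serialize an agreement report or comparison result as JSON
#'
#' @param x an `agreement_report` or `comparison_result`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
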