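#' Two-sample Student's t test from summary statistics
#'
#' Pooled-variance two-sided t test computed directly from per-group mean, SD
#' and n, as needed when only published summaries are available. The default
#' pooled-variance form reproduces printed confidence intervals computed from
#' group summaries; Welch's unequal-variance form is available via
#' `pooled = FALSE`.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param conf_level Confidence level for the CI on the mean difference.
#' @param pooled Use the pooled-variance (Student) form; `FALSE` gives Welch.
#' @return A `t1d_comparison` list: `estimate` (mean1 - mean2), `ci_low`,
#'   `ci_high`, `statistic`, `df`, `p_value`, `method`.
#' @examples
#' t_test_summary(0.271, 0.026, 894, 0.243, 0.036, 218)
#' @export
t_test_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                           conf_level = 0.95, pooled = TRUE) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be non-negative")
  if (sd1 == 0 && sd2 == 0) stop("both SDs are zero; t test undefined")
  diff <- mean1 - mean2
  if (pooled) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    method <- "Student t (pooled variance, summary input)"
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    method <- "Welch t (summary input)"
  }
  tstat <- diff / se
  crit <- stats::qt(1 - (1 - conf_level) / 2, df)
  p <- 2 * stats::pt(-abs(tstat), df)
  comparison_result(estimate = diff, ci_low = diff - crit * se,
                    ci_high = diff + crit * se, statistic = tstat,
                    df = df, p_value = p, method = method)
}

#' Two-sample t test on raw values
#'
#' Thin convenience over [t_test_summary()]: summarises each vector and runs
#' the summary-input path, so raw and summary interfaces cannot diverge.
#'
#' @param x,y Numeric vectors.
#' @inheritParams t_test_summary
#' @return A `t1d_comparison` list.
#' @export
t_test_groups <- function(x, y, conf_level = 0.95, pooled = TRUE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  t_test_summary(mean(x), stats::sd(x), length(x),
                 mean(y), stats::sd(y), length(y),
                 conf_level = conf_level, pooled = pooled)
}

#' Pearson chi-square test on a contingency table
#'
#' Wrapper around `stats::chisq.test` without continuity correction (the
#' default choice for the large tables this package targets; Yates'
#' correction is available via `correct = TRUE`).
#'
#' @param counts Matrix of non-negative counts, at least 2x2.
#' @param correct Apply Yates' continuity correction (2x2 only).
#' @return A `t1d_comparison` list with `statistic`, `df`, `p_value`.
#' @export
chi_square <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) stop("need at least a 2x2 table")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("empty table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal total; chi-square undefined")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  comparison_result(estimate = unname(ht$statistic), ci_low = NA_real_,
                    ci_high = NA_real_, statistic = unname(ht$statistic),
                    df = unname(ht$parameter), p_value = ht$p.value,
                    method = if (correct) "chi-square (Yates)" else "chi-square")
}

#' Wald binomial confidence interval for a proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`, clamped to
#' `[0,1]`. For the conventional 95% level `z` is fixed at 1.96 (the value
#' used in printed epidemiological tables); other levels use the exact normal
#' quantile.
#'
#' @param p_hat Observed proportion in `[0,1]`.
#' @param n Denominator (>= 1).
#' @param conf_level Confidence level.
#' @return Named numeric `c(low, high)`.
#' @export
wald_ci <- function(p_hat, n, conf_level = 0.95) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be a positive integer")
  if (p_hat < 0 || p_hat > 1) stop("p_hat must lie in [0,1]")
  z <- if (identical(conf_level, 0.95)) 1.96 else stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(p_hat * (1 - p_hat) / n)
  c(low = max(0, p_hat - z * se), high = min(1, p_hat + z * se))
}

#' Split values at their median
#'
#' Partition used for age-stratified sensitivity analyses: the lower stratum
#' is `value <= median`, the upper stratum `value > median`.
#'
#' @param values Non-empty numeric vector.
#' @return List with `median`, logical `lower` (TRUE where `<=` median), and
#'   the two index vectors `lower_idx`, `upper_idx`.
#' @export
median_split <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("median_split needs a non-empty vector")
  m <- stats::median(values, na.rm = TRUE)
  lower <- !is.na(values) & values <= m
  upper <- !is.na(values) & values > m
  list(median = m, lower = lower,
       lower_idx = which(lower), upper_idx = which(upper))
}

#' One-way comparison across more than two groups
#'
#' Thin utility: one-way ANOVA (equivalently, a linear model on the group
#' factor) for continuous outcomes across 3+ groups.
#'
#' @param values Numeric outcome.
#' @param groups Group labels (coerced to factor).
#' @return A `t1d_comparison` with the F statistic, df and p value.
#' @export
anova_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  comparison_result(estimate = s$`F value`[1], ci_low = NA_real_,
                    ci_high = NA_real_, statistic = s$`F value`[1],
                    df = s$Df[1], p_value = s$`Pr(>F)`[1],
                    method = "one-way ANOVA")
}

comparison_result <- function(estimate, ci_low, ci_high, statistic, df,
                              p_value, method) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 statistic = statistic, df = df, p_value = p_value,
                 method = method),
            class = "t1d_comparison")
}

#' @export
print.t1d_comparison <- function(x, ...) {
  cat(x$method, "\n")
  if (!is.na(x$ci_low)) {
    cat(sprintf("  estimate %.4g  95%% CI (%.4g, %.4g)\n",
                x$estimate, x$ci_low, x$ci_high))
  } else {
    cat(sprintf("  statistic %.4g  df %.4g\n", x$statistic, x$df))
  }
  cat(" ", format_p(x$p_value), "\n")
  invisible(x)
}

#' Format a p value for display
#'
#' Values below 1e-4 print as `p<0.0001`, matching common table conventions;
#' the exact value is kept in machine-readable output.
#'
#' @param p A p value.
#' @return Character scalar.
#' @export
format_p <- function(p) {
  if (is.na(p)) return("p=NA")
  if (p < 1e-4) "p<0.0001" else sprintf("p=%.4g", p)
}

#' Tidy one or more comparison results
#'
#' @param x A `t1d_comparison` or list of them (optionally named).
#' @return Data frame with columns `label`, `estimate`, `ci_low`, `ci_high`,
#'   `statistic`, `df`, `p_value`, `method`.
#' @export
tidy_comparisons <- function(x) {
  if (inherits(x, "t1d_comparison")) x <- list(result = x)
  labs <- names(x)
  if (is.null(labs)) labs <- paste0("comparison_", seq_along(x))
  do.call(rbind, lapply(seq_along(x), function(i) {
    r <- x[[i]]
    data.frame(label = labs[i], estimate = r$estimate, ci_low = r$ci_low,
               ci_high = r$ci_high, statistic = r$statistic, df = r$df,
               p_value = r$p_value, method = r$method,
               stringsAsFactors = FALSE)
  }))
}
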