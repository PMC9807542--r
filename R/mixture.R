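#' Means-based two-component mixture proportions
#'
#' The estimator at the heart of the package. An autoantibody-negative group
#' with mean genetic risk score `m` is modelled as a mixture of two reference
#' populations: autoimmune type 1 diabetes (mean `mu_pos`, from
#' autoantibody-positive cases) and non-autoimmune diabetes (mean `mu_ctrl`,
#' from a type 2 diabetes control cohort). By linearity of expectation,
#' `m = w * mu_pos + (1 - w) * mu_ctrl`, so the type 1 weight is
#'
#'   `p_t1d = (m - mu_ctrl) / (mu_pos - mu_ctrl)`
#'
#' and the non-autoimmune proportion is `1 - p_t1d`. No individual-level score
#' cut-off is involved: the estimate is a group-level deconvolution. Sampling
#' noise can push the raw ratio outside `[0,1]`; such estimates are clamped
#' and flagged, never silently returned out of range.
#'
#' @param mean_mix Mean score of the mixed (autoantibody-negative) group.
#' @param mean_pos Mean score of the type 1 reference group.
#' @param mean_ctrl Mean score of the non-autoimmune reference group.
#' @param eps Degeneracy guard: reference means closer than this are an error.
#' @return List with `p_t1d`, `p_non_autoimmune` and logical `clamped`.
#' @examples
#' estimate_mixture_proportions(0.243, 0.271, 0.229)  # p_non_autoimmune 2/3
#' @export
estimate_mixture_proportions <- function(mean_mix, mean_pos, mean_ctrl,
                                         eps = 1e-6) {
  stopifnot(is.finite(mean_mix), is.finite(mean_pos), is.finite(mean_ctrl))
  if (abs(mean_pos - mean_ctrl) <= eps) {
    stop("reference groups indistinguishable: |mean_pos - mean_ctrl| <= ", eps)
  }
  p <- (mean_mix - mean_ctrl) / (mean_pos - mean_ctrl)
  clamped <- p < 0 || p > 1
  if (clamped) {
    warning("mixture proportion ", signif(p, 4), " outside [0,1]; clamped")
    p <- min(1, max(0, p))
  }
  list(p_t1d = p, p_non_autoimmune = 1 - p, clamped = clamped)
}

#' Mixture proportions from mean differences
#'
#' Algebraically identical reparameterisation used for stratified summaries
#' that publish differences rather than means: with
#' `d_neg_ctrl = mean_mix - mean_ctrl` and `d_pos_neg = mean_pos - mean_mix`,
#' `p_t1d = d_neg_ctrl / (d_neg_ctrl + d_pos_neg)`.
#'
#' @param d_neg_ctrl Mean difference, mixed group minus non-autoimmune
#'   reference.
#' @param d_pos_neg Mean difference, type 1 reference minus mixed group.
#' @inheritParams estimate_mixture_proportions
#' @return As [estimate_mixture_proportions()].
#' @export
estimate_from_differences <- function(d_neg_ctrl, d_pos_neg, eps = 1e-6) {
  estimate_mixture_proportions(mean_mix = d_neg_ctrl, mean_pos = d_neg_ctrl + d_pos_neg,
                               mean_ctrl = 0, eps = eps)
}

# round half away from zero, the convention used for reported counts and
# integer percentages (base round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Fit the group-level mixture model
#'
#' The fitting front end. Two input modes:
#' \describe{
#'   \item{summary}{`neg`, `pos`, `ctrl` are the three group means (scalars)
#'     and `n` is the size of the mixed group. Wald confidence intervals only.}
#'   \item{raw}{`neg`, `pos`, `ctrl` are per-individual score vectors; means
#'     and `n = length(neg)` are taken from the data, and a percentile
#'     bootstrap CI (resampling all three groups) is available.}
#' }
#' The confidence interval is placed on the non-autoimmune proportion. The
#' default is a Wald binomial interval with the mixed group's `n` as
#' denominator, the recipe that reproduces published intervals for this
#' estimator; `ci_method = "bootstrap"` recomputes the estimator on
#' resamples-with-replacement of all three groups. Counts are the proportion
#' times `n`, rounded half up, as are the count CI bounds.
#'
#' @param neg,pos,ctrl Scalars (summary mode) or numeric vectors (raw mode):
#'   mixed autoantibody-negative group, type 1 reference, non-autoimmune
#'   reference.
#' @param n Mixed-group size; required in summary mode, ignored in raw mode.
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"wald"` or `"bootstrap"` (raw mode only).
#' @param boot_reps Bootstrap resamples (>= 100).
#' @param seed Optional seed for the bootstrap, for reproducibility.
#' @param eps Degeneracy guard on the reference mean difference.
#' @return An object of class `grs_mixture`: a list with elements `p_t1d`,
#'   `p_non_autoimmune`, `clamped`, `n_group`, `counts` (point and CI, on the
#'   non-autoimmune side and the type 1 complement), `ci` (on
#'   `p_non_autoimmune`), `ci_method`, `conf_level`, `means`, `mode`, `call`.
#' @examples
#' fit <- grs_mixture(0.243, 0.271, 0.229, n = 218)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
grs_mixture <- function(neg, pos, ctrl, n = NULL, conf_level = 0.95,
                        ci_method = c("wald", "bootstrap"),
                        boot_reps = 2000, seed = NULL, eps = 1e-6) {
  ci_method <- match.arg(ci_method)
  raw_mode <- length(neg) > 1 || length(pos) > 1 || length(ctrl) > 1
  if (raw_mode) {
    neg <- neg[!is.na(neg)]; pos <- pos[!is.na(pos)]; ctrl <- ctrl[!is.na(ctrl)]
    if (length(neg) < 1 || length(pos) < 1 || length(ctrl) < 1) {
      stop("raw mode needs non-empty score vectors for all three groups")
    }
    means <- c(mix = mean(neg), pos = mean(pos), ctrl = mean(ctrl))
    n_group <- length(neg)
  } else {
    if (is.null(n)) stop("summary mode needs the mixed-group size n")
    means <- c(mix = as.numeric(neg), pos = as.numeric(pos), ctrl = as.numeric(ctrl))
    n_group <- as.integer(n)
    if (n_group < 1) stop("n must be >= 1")
    if (ci_method == "bootstrap") {
      stop("bootstrap CI needs raw scores; use ci_method = \"wald\" with summaries")
    }
  }

  est <- estimate_mixture_proportions(means[["mix"]], means[["pos"]],
                                      means[["ctrl"]], eps = eps)
  ci <- if (ci_method == "wald") {
    wald_ci(est$p_non_autoimmune, n_group, conf_level = conf_level)
  } else {
    mixture_bootstrap_ci(neg, pos, ctrl, reps = boot_reps, seed = seed,
                         conf_level = conf_level, eps = eps)
  }

  counts <- list(
    non_autoimmune = round_half_up(est$p_non_autoimmune * n_group),
    t1d = n_group - round_half_up(est$p_non_autoimmune * n_group),
    non_autoimmune_ci = round_half_up(as.numeric(ci) * n_group)
  )

  structure(list(
    p_t1d = est$p_t1d,
    p_non_autoimmune = est$p_non_autoimmune,
    clamped = est$clamped,
    n_group = n_group,
    counts = counts,
    ci = c(low = unname(ci[1]), high = unname(ci[2])),
    ci_method = ci_method,
    conf_level = conf_level,
    means = means,
    mode = if (raw_mode) "raw" else "summary",
    scores = if (raw_mode) list(neg = neg, pos = pos, ctrl = ctrl) else NULL,
    call = match.call()
  ), class = "grs_mixture")
}

#' Percentile bootstrap CI for the mixture proportion
#'
#' Resamples each of the three groups with replacement, recomputes the
#' estimator on the resampled means, and returns the percentile interval of
#' the non-autoimmune proportion. Resamples where the reference means
#' degenerate are dropped and counted; if all fail, an error is raised.
#'
#' @param neg,pos,ctrl Raw score vectors.
#' @param reps Number of resamples (>= 100).
#' @param seed Optional seed.
#' @param conf_level Confidence level.
#' @param eps Degeneracy guard.
#' @return `c(low, high)` with attribute `failures` (dropped resamples).
#' @export
mixture_bootstrap_ci <- function(neg, pos, ctrl, reps = 2000, seed = NULL,
                                 conf_level = 0.95, eps = 1e-6) {
  if (reps < 100) stop("bootstrap needs at least 100 resamples")
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(seq_len(reps), function(i) {
    m_mix <- mean(sample(neg, replace = TRUE))
    m_pos <- mean(sample(pos, replace = TRUE))
    m_ctrl <- mean(sample(ctrl, replace = TRUE))
    if (abs(m_pos - m_ctrl) <= eps) return(NA_real_)
    p <- (m_mix - m_ctrl) / (m_pos - m_ctrl)
    1 - min(1, max(0, p))
  }, numeric(1))
  failures <- sum(is.na(draws))
  if (failures == reps) {
    stop("estimator undefined in every resample (", failures, " failures)")
  }
  alpha <- 1 - conf_level
  q <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                       names = FALSE)
  structure(c(low = q[1], high = q[2]), failures = failures)
}

#' Misclassification-adjusted autoantibody prevalence
#'
#' Autoantibody positivity recomputed after removing the estimated
#' non-autoimmune individuals (all of whom are antibody-negative by
#' construction) from the denominator:
#' `prevalence = n_ab_pos / (n_total - count_non_autoimmune)`, with a Wald CI
#' at the adjusted denominator.
#'
#' @param n_ab_pos Number of antibody-positive individuals.
#' @param n_total Total group size.
#' @param count_non_autoimmune Estimated non-autoimmune count among the
#'   antibody-negative; must not exceed `n_total - n_ab_pos`.
#' @param conf_level Confidence level.
#' @return List with `prevalence`, `numerator`, `denominator`, `ci`.
#' @examples
#' adjusted_prevalence(894, 1112, 147)  # 894/965, prints as 93%
#' @export
adjusted_prevalence <- function(n_ab_pos, n_total, count_non_autoimmune,
                                conf_level = 0.95) {
  if (count_non_autoimmune > n_total - n_ab_pos) {
    stop("count_non_autoimmune exceeds the antibody-negative group size")
  }
  if (count_non_autoimmune < 0) stop("count_non_autoimmune must be >= 0")
  denom <- n_total - count_non_autoimmune
  prev <- n_ab_pos / denom
  list(prevalence = prev, numerator = n_ab_pos, denominator = denom,
       ci = wald_ci(prev, denom, conf_level = conf_level))
}

#' Stratified mixture estimates
#'
#' Applies the mixture estimator per stratum. Each stratum row supplies
#' either the three means (`mean_mix`, `mean_pos`, `mean_ctrl`) or the two
#' mean differences (`d_neg_ctrl`, `d_pos_neg`), plus the stratum's
#' mixed-group size `n` and a `label`.
#'
#' @param strata Data frame as described above.
#' @param conf_level Confidence level.
#' @return List of [grs_mixture()] fits, named by stratum label.
#' @examples
#' grs_mixture_strata(data.frame(
#'   label = c("18-30.95", ">30.95"),
#'   d_neg_ctrl = c(0.023, 0.009), d_pos_neg = c(0.019, 0.032),
#'   n = c(67, 151)))
#' @export
grs_mixture_strata <- function(strata, conf_level = 0.95) {
  stopifnot(is.data.frame(strata), "label" %in% names(strata), "n" %in% names(strata))
  use_diff <- all(c("d_neg_ctrl", "d_pos_neg") %in% names(strata))
  use_means <- all(c("mean_mix", "mean_pos", "mean_ctrl") %in% names(strata))
  if (!use_diff && !use_means) {
    stop("strata need mean_mix/mean_pos/mean_ctrl or d_neg_ctrl/d_pos_neg columns")
  }
  fits <- lapply(seq_len(nrow(strata)), function(i) {
    if (use_means) {
      grs_mixture(strata$mean_mix[i], strata$mean_pos[i], strata$mean_ctrl[i],
                  n = strata$n[i], conf_level = conf_level)
    } else {
      # difference parameterisation maps onto means with mean_ctrl = 0
      grs_mixture(strata$d_neg_ctrl[i],
                  strata$d_neg_ctrl[i] + strata$d_pos_neg[i], 0,
                  n = strata$n[i], conf_level = conf_level)
    }
  })
  names(fits) <- as.character(strata$label)
  fits
}

#' Mixture estimate under an alternative type 1 reference rule
#'
#' Sensitivity analysis on the choice of type 1 reference group: the primary
#' analysis uses all antibody-positive individuals (`"any_positive"`), the
#' alternative restricts to individuals positive for all three antibodies
#' (`"triple_positive"`), reducing the impact of false-positive antibody
#' calls. Both fits are returned side by side.
#'
#' @param neg Scores of the antibody-negative (mixed) group.
#' @param pos Scores of all antibody-positive individuals.
#' @param ctrl Scores of the non-autoimmune control group.
#' @param n_antibodies Number of positive antibodies per individual in `pos`
#'   (same length as `pos`); needed for the triple-positive rule.
#' @param reference_rule `"any_positive"` or `"triple_positive"`.
#' @param conf_level Confidence level.
#' @return List with elements `primary` and `alternative` ([grs_mixture()]
#'   fits; `alternative` is `NULL` when the rule is `"any_positive"`).
#' @export
sensitivity_reference <- function(neg, pos, ctrl, n_antibodies = NULL,
                                  reference_rule = c("triple_positive", "any_positive"),
                                  conf_level = 0.95) {
  reference_rule <- match.arg(reference_rule)
  primary <- grs_mixture(neg, pos, ctrl, conf_level = conf_level)
  if (reference_rule == "any_positive") {
    return(list(primary = primary, alternative = NULL, rule = reference_rule))
  }
  if (is.null(n_antibodies) || length(n_antibodies) != length(pos)) {
    stop("triple_positive rule needs n_antibodies aligned with pos")
  }
  triple <- pos[n_antibodies >= 3]
  if (length(triple) == 0) stop("reference rule selects an empty subset")
  alt <- grs_mixture(neg, triple, ctrl, conf_level = conf_level)
  list(primary = primary, alternative = alt, rule = reference_rule)
}

# ---- S3 methods -----------------------------------------------------------

#' @export
print.grs_mixture <- function(x, ...) {
  cat("Group-level GRS mixture deconvolution (", x$mode, " input)\n", sep = "")
  cat(sprintf("  group means: mixed %.4g, type 1 ref %.4g, non-autoimmune ref %.4g\n",
              x$means[["mix"]], x$means[["pos"]], x$means[["ctrl"]]))
  cat(sprintf("  non-autoimmune: %.1f%% (%s %g%% CI %.1f%%, %.1f%%)\n",
              100 * x$p_non_autoimmune, x$ci_method, 100 * x$conf_level,
              100 * x$ci[["low"]], 100 * x$ci[["high"]]))
  cat(sprintf("  counts (n = %d): %d non-autoimmune (CI %d, %d), %d type 1\n",
              x$n_group, x$counts$non_autoimmune,
              x$counts$non_autoimmune_ci[1], x$counts$non_autoimmune_ci[2],
              x$counts$t1d))
  if (x$clamped) cat("  note: estimate clamped to [0,1]\n")
  invisible(x)
}

#' @export
summary.grs_mixture <- function(object, ...) {
  out <- data.frame(
    quantity = c("p_t1d", "p_non_autoimmune"),
    estimate = c(object$p_t1d, object$p_non_autoimmune),
    ci_low = c(1 - object$ci[["high"]], object$ci[["low"]]),
    ci_high = c(1 - object$ci[["low"]], object$ci[["high"]]),
    count = c(object$counts$t1d, object$counts$non_autoimmune),
    n = object$n_group,
    pct_display = round_half_up(100 * c(object$p_t1d, object$p_non_autoimmune)),
    stringsAsFactors = FALSE
  )
  attr(out, "ci_method") <- object$ci_method
  out
}

#' @export
coef.grs_mixture <- function(object, ...) {
  c(p_t1d = object$p_t1d, p_non_autoimmune = object$p_non_autoimmune)
}

#' @export
confint.grs_mixture <- function(object, parm = "p_non_autoimmune",
                                level = NULL, ...) {
  ci <- object$ci
  if (!is.null(level) && !identical(level, object$conf_level)) {
    if (object$ci_method != "wald") {
      stop("refit with the desired conf_level to change a bootstrap interval")
    }
    ci <- wald_ci(object$p_non_autoimmune, object$n_group, conf_level = level)
  }
  out <- rbind(p_non_autoimmune = c(ci[["low"]], ci[["high"]]),
               p_t1d = c(1 - ci[["high"]], 1 - ci[["low"]]))
  colnames(out) <- c("low", "high")
  out[parm, , drop = FALSE]
}

#' @export
plot.grs_mixture <- function(x, ...) {
  if (x$mode != "raw") {
    stop("plot needs a raw-mode fit (per-individual scores)")
  }
  s <- x$scores
  dn <- stats::density(s$neg); dp <- stats::density(s$pos); dc <- stats::density(s$ctrl)
  ylim <- range(0, dn$y, dp$y, dc$y)
  xlim <- range(dn$x, dp$x, dc$x)
  plot(dc, col = "grey40", xlim = xlim, ylim = ylim, main = "GRS mixture fit",
       xlab = "genetic risk score", ...)
  graphics::lines(dp, col = "firebrick")
  graphics::lines(dn, col = "dodgerblue3")
  graphics::abline(v = x$means, lty = 3,
                   col = c("dodgerblue3", "firebrick", "grey40"))
  graphics::legend("topright", bty = "n",
                   legend = c("antibody-negative (mixed)", "type 1 reference",
                              "non-autoimmune reference"),
                   col = c("dodgerblue3", "firebrick", "grey40"), lty = 1)
  invisible(x)
}
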