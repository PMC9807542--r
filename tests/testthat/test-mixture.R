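test_that("the means-based formula reproduces the published proportions", {
  est <- estimate_mixture_proportions(0.243, 0.271, 0.229)
  expect_equal(est$p_t1d, (0.243 - 0.229) / (0.271 - 0.229))
  expect_equal(round(100 * est$p_non_autoimmune), 67)
  expect_false(est$clamped)

  expect_equal(estimate_mixture_proportions(0.271, 0.271, 0.229)$p_t1d, 1)
  expect_equal(estimate_mixture_proportions(0.229, 0.271, 0.229)$p_t1d, 0)
  expect_error(estimate_mixture_proportions(0.25, 0.25, 0.25),
               "indistinguishable")
})

test_that("mixture weights are recovered exactly from exact mixture means", {
  set.seed(101)
  for (i in 1:200) {
    mu_pos <- stats::runif(1, 0.2, 0.4)
    mu_ctrl <- mu_pos - stats::runif(1, 0.01, 0.2)
    w <- stats::runif(1)
    m <- w * mu_pos + (1 - w) * mu_ctrl
    est <- estimate_mixture_proportions(m, mu_pos, mu_ctrl)
    expect_equal(est$p_t1d, w, tolerance = 1e-12)
  }
})

test_that("the estimator is invariant to affine rescaling of the score", {
  set.seed(7)
  for (i in 1:50) {
    a <- stats::runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    b <- stats::runif(1, -5, 5)
    base <- estimate_mixture_proportions(0.243, 0.271, 0.229)
    mapped <- estimate_mixture_proportions(a * 0.243 + b, a * 0.271 + b,
                                           a * 0.229 + b)
    expect_equal(mapped$p_t1d, base$p_t1d, tolerance = 1e-10)
  }
})

test_that("out-of-range estimates are clamped with a warning, never silent", {
  expect_warning(est <- estimate_mixture_proportions(0.28, 0.271, 0.229),
                 "clamped")
  expect_equal(est$p_t1d, 1)
  expect_true(est$clamped)
  expect_warning(est2 <- estimate_mixture_proportions(0.21, 0.271, 0.229))
  expect_equal(est2$p_t1d, 0)
})

test_that("grs_mixture summary fit carries counts, CI and display quantities", {
  fit <- grs_mixture(0.243, 0.271, 0.229, n = 218)
  expect_s3_class(fit, "grs_mixture")
  expect_equal(fit$counts$non_autoimmune + fit$counts$t1d, 218)
  expect_lte(fit$ci[["low"]], fit$p_non_autoimmune)
  expect_gte(fit$ci[["high"]], fit$p_non_autoimmune)
  expect_equal(unname(coef(fit)), c(fit$p_t1d, fit$p_non_autoimmune))
  expect_equal(sum(coef(fit)), 1)

  ci <- confint(fit)
  expect_equal(unname(ci["p_non_autoimmune", ]), unname(fit$ci))
  s <- summary(fit)
  expect_equal(s$pct_display[s$quantity == "p_non_autoimmune"], 67)
  expect_output(print(fit), "non-autoimmune")
  expect_error(grs_mixture(0.243, 0.271, 0.229), "needs the mixed-group size")
})

test_that("Wald machinery reproduces the published count interval recipe", {
  ci <- wald_ci(147 / 218, 218)
  expect_equal(round(100 * ci[["low"]]), 61)
  counts <- vapply(ci, function(p) t1dmix:::round_half_up(p * 218), numeric(1))
  expect_equal(unname(counts[1]), 133)

  share <- 147 / 1112
  ci_all <- wald_ci(share, 1112)
  expect_equal(round(100 * share), 13)
  expect_equal(round(100 * ci_all[["low"]]), 11)
  expect_equal(round(100 * ci_all[["high"]]), 15)
})

test_that("adjusted prevalence removes the estimated non-autoimmune denominator", {
  adj <- adjusted_prevalence(894, 1112, 147)
  expect_equal(adj$denominator, 965)
  expect_equal(round(100 * adj$prevalence), 93)
  expect_equal(round(100 * adj$ci[["low"]]), 91)
  expect_equal(round(100 * adj$ci[["high"]]), 94)

  unchanged <- adjusted_prevalence(894, 1112, 0)
  expect_equal(unchanged$prevalence, 894 / 1112)
  all_reclassified <- adjusted_prevalence(894, 1112, 218)
  expect_equal(all_reclassified$prevalence, 1)
  expect_error(adjusted_prevalence(894, 1112, 219), "exceeds")
})

test_that("stratified estimates accept the mean-difference parameterisation", {
  est <- estimate_from_differences(0.023, 0.019)
  expect_equal(round(100 * est$p_non_autoimmune), 45)
  expect_equal(estimate_from_differences(0.02, 0.02)$p_t1d, 0.5)

  fits <- grs_mixture_strata(data.frame(
    label = c("younger", "older"),
    d_neg_ctrl = c(0.023, 0.009),
    d_pos_neg = c(0.019, 0.032),
    n = c(67, 151)))
  expect_named(fits, c("younger", "older"))
  expect_equal(round(100 * fits$younger$p_non_autoimmune), 45)
  expect_gt(fits$older$p_non_autoimmune, fits$younger$p_non_autoimmune)

  # means and differences parameterisations agree
  means_fit <- grs_mixture_strata(data.frame(
    label = "all", mean_mix = 0.243, mean_pos = 0.271, mean_ctrl = 0.229,
    n = 218))$all
  diff_fit <- grs_mixture_strata(data.frame(
    label = "all", d_neg_ctrl = 0.243 - 0.229, d_pos_neg = 0.271 - 0.243,
    n = 218))$all
  expect_equal(means_fit$p_t1d, diff_fit$p_t1d, tolerance = 1e-12)
  # single whole-cohort stratum equals the unstratified fit
  expect_equal(means_fit$p_t1d, grs_mixture(0.243, 0.271, 0.229, n = 218)$p_t1d)
})

test_that("bootstrap CI is seeded, guarded, and consistent with the Wald CI", {
  set.seed(3)
  neg <- sample_mixture(218, 71 / 218, list(mean = 0.271, sd = 0.026),
                        list(mean = 0.229, sd = 0.034))$scores
  pos <- sample_scores(894, 0.271, 0.026)
  ctrl <- sample_scores(1924, 0.229, 0.034)

  fit_b <- grs_mixture(neg, pos, ctrl, ci_method = "bootstrap",
                       boot_reps = 500, seed = 12)
  fit_b2 <- grs_mixture(neg, pos, ctrl, ci_method = "bootstrap",
                        boot_reps = 500, seed = 12)
  expect_identical(fit_b$ci, fit_b2$ci)

  fit_w <- grs_mixture(neg, pos, ctrl)
  overlap <- min(fit_b$ci[["high"]], fit_w$ci[["high"]]) -
    max(fit_b$ci[["low"]], fit_w$ci[["low"]])
  expect_gt(overlap / diff(range(fit_w$ci)), 0.5)

  expect_error(mixture_bootstrap_ci(neg, pos, ctrl, reps = 50), "at least 100")
  cst <- rep(0.25, 30)
  expect_error(mixture_bootstrap_ci(cst, cst, cst, reps = 100, seed = 1),
               "every resample")
  expect_error(grs_mixture(0.243, 0.271, 0.229, n = 218, ci_method = "bootstrap"),
               "raw scores")
})

test_that("sensitivity analysis swaps in the triple-positive reference group", {
  set.seed(21)
  neg <- stats::rnorm(200, 0.243, 0.036)
  pos <- stats::rnorm(800, 0.271, 0.026)
  ctrl <- stats::rnorm(1900, 0.229, 0.034)
  n_ab <- sample(1:3, 800, replace = TRUE)

  out <- sensitivity_reference(neg, pos, ctrl, n_antibodies = n_ab)
  expect_equal(out$primary$p_non_autoimmune,
               grs_mixture(neg, pos, ctrl)$p_non_autoimmune)
  manual <- grs_mixture(neg, pos[n_ab >= 3], ctrl)
  expect_equal(out$alternative$p_non_autoimmune, manual$p_non_autoimmune)
  # triple positives drawn from the same distribution: similar estimates
  expect_lt(abs(out$alternative$p_non_autoimmune - out$primary$p_non_autoimmune),
            0.05)

  ident <- sensitivity_reference(neg, pos, ctrl, reference_rule = "any_positive")
  expect_null(ident$alternative)
  expect_error(sensitivity_reference(neg, pos, ctrl,
                                     n_antibodies = rep(1, length(pos))),
               "empty subset")
})
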