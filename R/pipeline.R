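#' Classify an HLA class II haplotype pair into a risk category
#'
#' Four mutually exclusive categories, in precedence order:
#' \enumerate{
#'   \item `DR3_DR4_het` — the DR3-DQ2/DR4-DQ8 compound heterozygote, the
#'     highest-risk genotype;
#'   \item `DR15_carrier` — at least one copy of the strongly protective
#'     DR15-DQ6 haplotype (carriers are excluded from the risk-carrier
#'     category even when they also carry DR3-DQ2 or DR4-DQ8);
#'   \item `DR3_or_DR4_no_DR15` — DR3-DQ2 or DR4-DQ8, homozygous or
#'     heterozygous with X, without DR15-DQ6;
#'   \item `neutral_XX` — any other genotype (`X` = any haplotype outside the
#'     modelled set).
#' }
#'
#' @param hap1,hap2 Haplotype labels, each one of `"DR3-DQ2"`, `"DR4-DQ8"`,
#'   `"DR15-DQ6"`, `"X"`. Vectorised.
#' @return Character vector of category names.
#' @examples
#' classify_hla("DR3-DQ2", "DR4-DQ8")   # DR3_DR4_het
#' classify_hla("DR3-DQ2", "DR15-DQ6")  # DR15_carrier
#' @export
classify_hla <- function(hap1, hap2) {
  known <- c("DR3-DQ2", "DR4-DQ8", "DR15-DQ6", "X")
  labs <- cbind(as.character(hap1), as.character(hap2))
  bad <- !(labs %in% known)
  if (any(bad)) {
    stop("unknown haplotype label(s): ", paste(unique(labs[bad]), collapse = ", "))
  }
  vapply(seq_len(nrow(labs)), function(i) {
    pair <- labs[i, ]
    if (all(c("DR3-DQ2", "DR4-DQ8") %in% pair)) return("DR3_DR4_het")
    if ("DR15-DQ6" %in% pair) return("DR15_carrier")
    if (any(pair %in% c("DR3-DQ2", "DR4-DQ8"))) return("DR3_or_DR4_no_DR15")
    "neutral_XX"
  }, character(1))
}

is_control_group <- function(group) grepl("t2d|control", group, ignore.case = TRUE)

group_summary <- function(x) {
  x <- x[!is.na(x)]
  list(n = length(x), mean = mean(x), sd = stats::sd(x))
}

clinical_2x2 <- function(flag_pos, flag_neg) {
  matrix(c(sum(flag_pos, na.rm = TRUE), sum(!flag_pos, na.rm = TRUE),
           sum(flag_neg, na.rm = TRUE), sum(!flag_neg, na.rm = TRUE)),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("ab_positive", "ab_negative"), c("yes", "no")))
}

#' Run the full immunogenetic analysis on a cohort
#'
#' End-to-end orchestration: drops individuals with missing antibody or score
#' data (logged), summarises the genetic risk score per group, runs the
#' group comparisons (pooled t tests on scores, chi-square on each clinical
#' flag), tabulates HLA risk-category frequencies, quantifies the added
#' value of ZnT8A over GADA+IA2A, fits the mixture deconvolution (overall,
#' per age stratum at the adult median, and under the triple-positive
#' sensitivity reference), and computes the misclassification-adjusted
#' antibody prevalence. When the cohort carries a latent `true_class` column
#' (synthetic data), a separate validation block compares the estimator with
#' the simulation truth; the analysis path itself never reads that column.
#'
#' @param cohort A cohort data frame (see [generate_cohort()] for the column
#'   dictionary). Control individuals are recognised by a group label
#'   matching `"t2d"` or `"control"`.
#' @param control_summary Optional list `(mean, sd, n)` describing the
#'   non-autoimmune control score distribution, used when the cohort contains
#'   no control rows.
#' @param conf_level Confidence level for all intervals.
#' @param age_boundary Adult stratification boundary in years; default is the
#'   median age of the adult case group.
#' @return An object of class `t1d_report`.
#' @export
run_full_analysis <- function(cohort, control_summary = NULL,
                              conf_level = 0.95, age_boundary = NULL) {
  cohort <- as.data.frame(cohort)
  required <- c("age_at_diagnosis", "grs")
  miss <- setdiff(required, names(cohort))
  if (length(miss) > 0) stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  if (!"adult" %in% names(cohort)) cohort$adult <- cohort$age_at_diagnosis >= 18
  if (!"group" %in% names(cohort)) cohort$group <- "case"
  if (!"ab_positive" %in% names(cohort)) {
    ab_cols <- intersect(c("gada", "ia2a", "znt8a"), names(cohort))
    if (length(ab_cols) == 0) stop("cohort needs ab_positive or antibody status columns")
    cohort$ab_positive <- rowSums(cohort[, ab_cols, drop = FALSE]) > 0
  }

  is_ctrl <- is_control_group(cohort$group)
  cases <- cohort[!is_ctrl, ]
  ctrl_scores <- cohort$grs[is_ctrl & !is.na(cohort$grs)]

  # exclusion flow: cases missing antibody or genetic data are dropped
  drop_ab <- is.na(cases$ab_positive)
  drop_grs <- is.na(cases$grs)
  excluded <- list(missing_antibody = sum(drop_ab),
                   missing_genetic = sum(drop_grs & !drop_ab))
  cases <- cases[!(drop_ab | drop_grs), ]
  if (nrow(cases) == 0) stop("no analysable cases after exclusions")

  adults <- cases[cases$adult, ]
  children <- cases[!cases$adult, ]
  a_pos <- adults[adults$ab_positive, ]
  a_neg <- adults[!adults$ab_positive, ]
  if (nrow(a_pos) == 0 || nrow(a_neg) == 0) {
    stop("need at least one antibody-positive and one antibody-negative adult")
  }

  if (length(ctrl_scores) == 0) {
    if (is.null(control_summary)) {
      stop("no control group in the cohort: supply control_summary = list(mean, sd, n)")
    }
    ctrl_mean <- control_summary$mean
  } else {
    ctrl_mean <- mean(ctrl_scores)
  }

  summaries <- list(
    adult_abpos = group_summary(a_pos$grs),
    adult_abneg = group_summary(a_neg$grs),
    child_abpos = group_summary(children$grs[children$ab_positive]),
    child_abneg = group_summary(children$grs[!children$ab_positive]),
    control = if (length(ctrl_scores) > 0) group_summary(ctrl_scores) else control_summary
  )

  comparisons <- list(
    adult_neg_vs_pos = t_test_groups(a_neg$grs, a_pos$grs, conf_level = conf_level)
  )
  if (length(ctrl_scores) > 0) {
    comparisons$adult_neg_vs_control <-
      t_test_groups(a_neg$grs, ctrl_scores, conf_level = conf_level)
  } else {
    cs <- control_summary
    comparisons$adult_neg_vs_control <-
      t_test_summary(mean(a_neg$grs), stats::sd(a_neg$grs), nrow(a_neg),
                     cs$mean, cs$sd, cs$n, conf_level = conf_level)
  }
  if (sum(children$ab_positive) >= 2 && sum(!children$ab_positive) >= 2) {
    comparisons$child_neg_vs_pos <-
      t_test_groups(children$grs[!children$ab_positive],
                    children$grs[children$ab_positive], conf_level = conf_level)
  }

  clinical <- NULL
  flags <- intersect(c("dka", "weight_loss", "polyuria_polydipsia",
                       "hospitalised", "other_autoimmune", "parent_diabetes"),
                     names(adults))
  rows <- list()
  if ("sex" %in% names(adults)) {
    tab <- clinical_2x2(a_pos$sex == "male", a_neg$sex == "male")
    rows$sex_male <- c(list(n_pos = sum(a_pos$sex == "male"),
                            n_neg = sum(a_neg$sex == "male")), chi_square(tab))
  }
  for (f in flags) {
    tab <- clinical_2x2(a_pos[[f]], a_neg[[f]])
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    rows[[f]] <- c(list(n_pos = sum(a_pos[[f]], na.rm = TRUE),
                        n_neg = sum(a_neg[[f]], na.rm = TRUE)), chi_square(tab))
  }
  for (v in intersect(c("age_at_diagnosis", "bmi"), names(adults))) {
    rows[[v]] <- t_test_groups(a_pos[[v]], a_neg[[v]], conf_level = conf_level)
  }
  clinical <- rows

  hla_freq <- NULL
  if (all(c("hla_1", "hla_2") %in% names(cohort)) && !all(is.na(cohort$hla_1))) {
    with_hla <- cohort[!is.na(cohort$hla_1) & !is.na(cohort$hla_2), ]
    cat_of <- classify_hla(with_hla$hla_1, with_hla$hla_2)
    key <- ifelse(is_control_group(with_hla$group), "control",
                  paste0(ifelse(with_hla$adult, "adult", "child"), "_",
                         ifelse(with_hla$ab_positive, "abpos", "abneg")))
    key[is.na(with_hla$ab_positive) & !is_control_group(with_hla$group)] <- NA
    keep <- !is.na(key)
    hla_freq <- table(group = key[keep],
                      category = factor(cat_of[keep], levels = names(hla_category_pairs)))
  }

  znt8a <- NULL
  if (all(c("gada", "ia2a", "znt8a") %in% names(adults)) && !all(is.na(adults$znt8a))) {
    znt8a <- antibody_added_value(adults[, c("gada", "ia2a", "znt8a")], added = "znt8a")
  }

  # ---- mixture deconvolution ------------------------------------------------
  if (length(ctrl_scores) > 0) {
    mixture <- grs_mixture(a_neg$grs, a_pos$grs, ctrl_scores,
                           conf_level = conf_level)
  } else {
    mixture <- grs_mixture(mean(a_neg$grs), mean(a_pos$grs), ctrl_mean,
                           n = nrow(a_neg), conf_level = conf_level)
  }
  count_non <- mixture$counts$non_autoimmune
  n_adults <- nrow(adults)

  all_adult_share <- list(
    proportion = count_non / n_adults,
    numerator = count_non, denominator = n_adults,
    ci = wald_ci(count_non / n_adults, n_adults, conf_level = conf_level)
  )
  adj_prev <- adjusted_prevalence(nrow(a_pos), n_adults, count_non,
                                  conf_level = conf_level)
  observed_prev <- list(proportion = nrow(a_pos) / n_adults,
                        numerator = nrow(a_pos), denominator = n_adults,
                        ci = wald_ci(nrow(a_pos) / n_adults, n_adults,
                                     conf_level = conf_level))

  boundary <- if (is.null(age_boundary)) {
    stats::median(adults$age_at_diagnosis)
  } else age_boundary
  lower <- adults$age_at_diagnosis <= boundary
  strata <- list()
  for (s in c("lower", "upper")) {
    idx <- if (s == "lower") lower else !lower
    sn <- adults[idx & !adults$ab_positive, ]
    sp <- adults[idx & adults$ab_positive, ]
    if (nrow(sn) < 2 || nrow(sp) < 2) next
    fit <- if (length(ctrl_scores) > 0) {
      grs_mixture(sn$grs, sp$grs, ctrl_scores, conf_level = conf_level)
    } else {
      grs_mixture(mean(sn$grs), mean(sp$grs), ctrl_mean, n = nrow(sn),
                  conf_level = conf_level)
    }
    strata[[if (s == "lower") sprintf("age<=%.2f", boundary)
            else sprintf("age>%.2f", boundary)]] <- fit
  }

  sensitivity <- NULL
  if ("n_antibodies" %in% names(a_pos) && any(a_pos$n_antibodies >= 3) &&
      length(ctrl_scores) > 0) {
    sensitivity <- sensitivity_reference(a_neg$grs, a_pos$grs, ctrl_scores,
                                         n_antibodies = a_pos$n_antibodies,
                                         reference_rule = "triple_positive",
                                         conf_level = conf_level)
  }

  validation <- NULL
  if ("true_class" %in% names(a_neg) && !all(is.na(a_neg$true_class))) {
    truth <- mean(a_neg$true_class == "non_autoimmune", na.rm = TRUE)
    validation <- list(true_p_non_autoimmune = truth,
                       estimated_p_non_autoimmune = mixture$p_non_autoimmune,
                       absolute_error = abs(truth - mixture$p_non_autoimmune))
  }

  structure(list(
    excluded = excluded,
    summaries = summaries,
    comparisons = comparisons,
    clinical = clinical,
    hla_frequencies = hla_freq,
    znt8a_added_value = znt8a,
    mixture = mixture,
    all_adult_share = all_adult_share,
    observed_prevalence = observed_prev,
    adjusted_prevalence = adj_prev,
    age_boundary = boundary,
    strata = strata,
    sensitivity = sensitivity,
    validation = validation,
    provenance = list(seed = attr(cohort, "seed"),
                      package_version = as.character(utils::packageVersion("t1dmix")),
                      conf_level = conf_level,
                      hla_precedence = "DR3/DR4 het > DR15 carrier > DR3 or DR4 carrier > neutral")
  ), class = "t1d_report")
}

pct <- function(x) round_half_up(100 * x)

#' @export
print.t1d_report <- function(x, ...) {
  cat("== Immunogenetic analysis report ==\n")
  cat(sprintf("excluded: %d missing antibody data, %d missing genetic data\n",
              x$excluded$missing_antibody, x$excluded$missing_genetic))
  cat("\nGRS by group (n, mean, SD):\n")
  for (g in names(x$summaries)) {
    s <- x$summaries[[g]]
    if (is.null(s) || s$n == 0) next
    cat(sprintf("  %-12s n=%4d  mean %.3f  SD %.3f\n", g, s$n, s$mean, s$sd))
  }
  cat("\nScore comparisons:\n")
  for (nm in names(x$comparisons)) {
    r <- x$comparisons[[nm]]
    cat(sprintf("  %-22s diff %.3f (95%% CI %.3f, %.3f) %s\n",
                nm, r$estimate, r$ci_low, r$ci_high, format_p(r$p_value)))
  }
  if (!is.null(x$znt8a_added_value)) {
    z <- x$znt8a_added_value
    cat(sprintf("\nZnT8A added value: %d/%d (%d%%) of GADA-/IA2A- adults positive only by ZnT8A\n",
                z$n_added_positive, z$n_base_negative, pct(z$proportion)))
  }
  m <- x$mixture
  cat(sprintf("\nMixture deconvolution (antibody-negative adults, n=%d):\n", m$n_group))
  cat(sprintf("  non-autoimmune %d%% (95%% CI %d%%, %d%%); counts %d/%d (CI %d, %d)\n",
              pct(m$p_non_autoimmune), pct(m$ci[["low"]]), pct(m$ci[["high"]]),
              m$counts$non_autoimmune, m$n_group,
              m$counts$non_autoimmune_ci[1], m$counts$non_autoimmune_ci[2]))
  a <- x$all_adult_share
  cat(sprintf("  share of all adults: %d%% (%d/%d, 95%% CI %d%%, %d%%)\n",
              pct(a$proportion), a$numerator, a$denominator,
              pct(a$ci[["low"]]), pct(a$ci[["high"]])))
  p <- x$adjusted_prevalence
  cat(sprintf("  adjusted antibody prevalence: %d%% (%d/%d, 95%% CI %d%%, %d%%)\n",
              pct(p$prevalence), p$numerator, p$denominator,
              pct(p$ci[["low"]]), pct(p$ci[["high"]])))
  if (length(x$strata) > 0) {
    cat(sprintf("  age strata (boundary %.2f y):\n", x$age_boundary))
    for (nm in names(x$strata)) {
      f <- x$strata[[nm]]
      cat(sprintf("    %-14s non-autoimmune %d%% (95%% CI %d%%, %d%%) n=%d\n",
                  nm, pct(f$p_non_autoimmune), pct(f$ci[["low"]]),
                  pct(f$ci[["high"]]), f$n_group))
    }
  }
  if (!is.null(x$sensitivity) && !is.null(x$sensitivity$alternative)) {
    cat(sprintf("  triple-positive reference: non-autoimmune %d%% (primary %d%%)\n",
                pct(x$sensitivity$alternative$p_non_autoimmune),
                pct(x$sensitivity$primary$p_non_autoimmune)))
  }
  if (!is.null(x$validation)) {
    v <- x$validation
    cat(sprintf("\nValidation vs latent truth: true %d%%, estimated %d%% (abs error %.3f)\n",
                pct(v$true_p_non_autoimmune), pct(v$estimated_p_non_autoimmune),
                v$absolute_error))
  }
  invisible(x)
}

#' Serialise an analysis report to JSON
#'
#' Full-precision machine-readable form of every block in the report; every
#' reported proportion is accompanied by its numerator and denominator.
#'
#' @param report A `t1d_report`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
report_to_json <- function(report, path = NULL) {
  strip <- function(x) {
    if (inherits(x, "grs_mixture")) {
      x <- x[c("p_t1d", "p_non_autoimmune", "clamped", "n_group", "counts",
               "ci", "ci_method", "conf_level", "means", "mode")]
    } else if (inherits(x, "t1d_comparison")) {
      x <- unclass(x)
    } else if (is.table(x)) {
      return(as.data.frame(x, stringsAsFactors = FALSE))
    }
    if (is.list(x)) lapply(x, strip) else x
  }
  json <- jsonlite::toJSON(strip(unclass(report)), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
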