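#' Draw group scores from a normal distribution
#'
#' Score-level simulation of one analysis group: the genetic risk score of a
#' homogeneous group is modelled as Normal(mean, sd), which matches how such
#' scores are summarised (group mean and SD) and is adequate for a sum of
#' many small allelic effects.
#'
#' @param n Number of draws (>= 1).
#' @param mean,sd Normal parameters; `sd > 0`.
#' @param seed Optional seed (set locally if supplied).
#' @return Numeric vector of length `n`.
#' @export
sample_scores <- function(n, mean, sd, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, mean, sd)
}

#' Draw scores from a two-component mixture with latent labels
#'
#' Emulates an antibody-negative group containing both true type 1 diabetes
#' (false-negative antibodies) and non-autoimmune diabetes. With
#' `method = "fixed"` (default) the component counts are deterministic,
#' `round(weight_t1d * n)` type 1 draws and the rest control draws, shuffled;
#' this makes the latent composition exact, which is what a simulation truth
#' should be. `method = "binomial"` assigns each draw independently.
#'
#' @param n Group size.
#' @param weight_t1d Mixture weight on the type 1 component, in `[0,1]`.
#' @param params_t1d,params_ctrl Lists with `mean` and `sd` for the two
#'   components.
#' @param seed Optional seed.
#' @param method `"fixed"` or `"binomial"` component assignment.
#' @return List with `scores` (numeric) and `labels` (character,
#'   `"t1d"`/`"non_autoimmune"`), both length `n`.
#' @export
sample_mixture <- function(n, weight_t1d, params_t1d, params_ctrl,
                           seed = NULL, method = c("fixed", "binomial")) {
  method <- match.arg(method)
  if (n < 1) stop("n must be >= 1")
  if (!is.finite(weight_t1d) || weight_t1d < 0 || weight_t1d > 1) {
    stop("weight_t1d must lie in [0,1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n_t1d <- if (method == "fixed") {
    as.integer(round_half_up(weight_t1d * n))
  } else {
    stats::rbinom(1, n, weight_t1d)
  }
  labels <- c(rep("t1d", n_t1d), rep("non_autoimmune", n - n_t1d))
  scores <- c(stats::rnorm(n_t1d, params_t1d$mean, params_t1d$sd),
              stats::rnorm(n - n_t1d, params_ctrl$mean, params_ctrl$sd))
  ord <- sample.int(n)
  list(scores = scores[ord], labels = labels[ord])
}

# right-skewed age-at-onset model: a gamma distribution shifted to the lower
# age bound, moment-matched to the requested mean/SD, truncated at the upper
# bound by resampling. Right skew puts the median below the mean, as in real
# age-at-diagnosis distributions.
sample_ages <- function(n, min_age, max_age, mean, sd) {
  stopifnot(mean > min_age, sd > 0, max_age > min_age)
  shape <- ((mean - min_age) / sd)^2
  scale <- sd^2 / (mean - min_age)
  x <- min_age + stats::rgamma(n, shape = shape, scale = scale)
  for (i in 1:50) {
    bad <- x > max_age
    if (!any(bad)) break
    x[bad] <- min_age + stats::rgamma(sum(bad), shape = shape, scale = scale)
  }
  pmin(x, max_age)
}

sample_truncated_normal <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- x < lower
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmax(x, lower)
}

# representative haplotype pair for each HLA risk category
hla_category_pairs <- list(
  DR3_DR4_het = c("DR3-DQ2", "DR4-DQ8"),
  DR3_or_DR4_no_DR15 = c("DR3-DQ2", "X"),
  DR15_carrier = c("DR15-DQ6", "X"),
  neutral_XX = c("X", "X")
)

#' Read a synthetic-cohort configuration
#'
#' The configuration fully parameterises [generate_cohort()]: a global seed,
#' an output `mode` (`"score"` or `"genotype"`) and one spec per group with
#' its size, score distribution (normal parameters or a two-component
#' mixture), age range and moments, clinical-feature rates, per-antibody
#' positivity rates and HLA category frequencies. JSON and YAML are accepted.
#'
#' @param path Config file path.
#' @return A list of class `t1d_cohort_config`.
#' @seealso [default_cohort_config()] for the shipped configuration.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs require the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  validate_cohort_config(cfg)
}

#' The shipped paper-like cohort configuration
#'
#' Group sizes, score means/SDs, the antibody-negative mixture composition,
#' adult clinical-feature rates and adult HLA category frequencies follow the
#' published adult-onset type 1 diabetes cohort this package models; child
#' clinical rates and some per-antibody rates are not published at group
#' level and are marked `illustrative` in the file.
#'
#' @return A `t1d_cohort_config`.
#' @export
default_cohort_config <- function() {
  read_cohort_config(system.file("extdata", "config-paper-like.json",
                                 package = "t1dmix", mustWork = TRUE))
}

validate_cohort_config <- function(cfg) {
  if (is.null(cfg$groups) || length(cfg$groups) == 0) stop("config has no groups")
  if (is.null(cfg$seed)) stop("config needs a seed")
  cfg$mode <- if (is.null(cfg$mode)) "score" else match.arg(cfg$mode, c("score", "genotype"))
  for (g in cfg$groups) {
    if (is.null(g$label) || is.null(g$n)) stop("every group needs label and n")
    if (g$n < 1) stop("group ", g$label, ": n must be >= 1")
    has_grs <- !is.null(g$grs)
    has_mix <- !is.null(g$mixture)
    if (cfg$mode == "score" && !has_grs && !has_mix) {
      stop("group ", g$label, ": score mode needs 'grs' or 'mixture'")
    }
    if (has_grs && (is.null(g$grs$sd) || g$grs$sd <= 0)) {
      stop("group ", g$label, ": grs sd must be > 0")
    }
    if (has_mix) {
      w <- g$mixture$weight_t1d
      if (is.null(w) || w < 0 || w > 1) {
        stop("group ", g$label, ": mixture weight_t1d must lie in [0,1]")
      }
    }
    for (p in unlist(g$clinical[c("male", "dka", "weight_loss",
                                  "polyuria_polydipsia", "hospitalised",
                                  "other_autoimmune", "parent_diabetes")])) {
      if (!is.null(p) && (p < 0 || p > 1)) {
        stop("group ", g$label, ": clinical probabilities must lie in [0,1]")
      }
    }
  }
  labels <- vapply(cfg$groups, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate group labels in config")
  class(cfg) <- c("t1d_cohort_config", "list")
  cfg
}

# deterministic per-group child seed so adding a group at the end of the
# config never perturbs earlier groups
group_seed <- function(seed, index) as.integer(seed) + 100003L * as.integer(index)

sample_antibody_status <- function(n, spec) {
  if (is.null(spec) || identical(spec$status, "unmeasured")) {
    return(data.frame(gada = NA, ia2a = NA, znt8a = NA)[rep(1, n), , drop = FALSE])
  }
  if (identical(spec$status, "negative")) {
    return(data.frame(gada = FALSE, ia2a = FALSE, znt8a = FALSE)[rep(1, n), , drop = FALSE])
  }
  rates <- unlist(spec$rates)[c("gada", "ia2a", "znt8a")]
  if (anyNA(rates)) stop("positive group needs gada/ia2a/znt8a rates")
  draw <- function(k) {
    cbind(gada = stats::rbinom(k, 1, rates["gada"]),
          ia2a = stats::rbinom(k, 1, rates["ia2a"]),
          znt8a = stats::rbinom(k, 1, rates["znt8a"])) == 1
  }
  m <- draw(n)
  # the group is antibody-positive by definition: redraw all-negative rows
  for (i in 1:100) {
    none <- rowSums(m) == 0
    if (!any(none)) break
    m[none, ] <- draw(sum(none))
  }
  if (any(rowSums(m) == 0)) m[rowSums(m) == 0, "gada"] <- TRUE
  as.data.frame(m)
}

sample_hla_pairs <- function(n, hla_probs) {
  if (is.null(hla_probs)) {
    return(data.frame(hla_1 = NA_character_, hla_2 = NA_character_)[rep(1, n), ])
  }
  probs <- unlist(hla_probs)
  cats <- names(hla_category_pairs)
  missing_cat <- setdiff(cats, names(probs))
  if (length(missing_cat) > 0) {
    stop("hla frequencies missing categories: ", paste(missing_cat, collapse = ", "))
  }
  probs <- probs[cats] / sum(probs[cats])
  drawn <- sample(cats, n, replace = TRUE, prob = probs)
  data.frame(
    hla_1 = vapply(drawn, function(cc) hla_category_pairs[[cc]][1], character(1)),
    hla_2 = vapply(drawn, function(cc) hla_category_pairs[[cc]][2], character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

generate_group_genotypes <- function(n, weights, eaf_shift = 0) {
  eaf <- pmin(0.99, pmax(0.01, weights$eaf + eaf_shift))
  m <- vapply(seq_len(nrow(weights)), function(j) stats::rbinom(n, 2, eaf[j]),
              numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- weights$variant_id
  as.data.frame(m)
}

#' Generate a synthetic cohort
#'
#' Builds a per-individual table with the statistical structure the analysis
#' pipeline assumes: exact group sizes; normal (or two-component mixture)
#' genetic risk scores; right-skewed ages at diagnosis; Bernoulli clinical
#' flags; antibody statuses consistent with the group definition
#' (antibody-negative groups are all-negative by construction,
#' antibody-positive groups have at least one positive antibody); HLA risk
#' category assignments; and, for mixture groups, a latent `true_class`
#' column holding the simulation truth that downstream analysis must ignore.
#' Fully deterministic given the config seed: each group draws from its own
#' child seed, so groups can be added without perturbing existing ones.
#'
#' In `mode = "genotype"` the scores are not drawn directly: per-variant
#' dosages are sampled from group-level effect-allele frequencies and scored
#' through [compute_grs()] with the supplied weight and HLA tables.
#'
#' @param config A [read_cohort_config()] object (or
#'   [default_cohort_config()]).
#' @param weights,hla Weight and HLA tables, required for genotype mode.
#' @return Data frame of class `t1d_cohort`, one row per individual.
#' @export
generate_cohort <- function(config = default_cohort_config(),
                            weights = NULL, hla = NULL) {
  config <- validate_cohort_config(unclass(config))
  if (config$mode == "genotype" && is.null(weights)) {
    stop("genotype mode needs a weight table")
  }
  out <- vector("list", length(config$groups))
  for (i in seq_along(config$groups)) {
    g <- config$groups[[i]]
    set.seed(group_seed(config$seed, i))
    n <- as.integer(g$n)

    if (!is.null(g$mixture)) {
      mx <- sample_mixture(n, g$mixture$weight_t1d, g$mixture$t1d, g$mixture$ctrl)
      score <- mx$scores
      true_class <- mx$labels
    } else if (!is.null(g$grs)) {
      score <- sample_scores(n, g$grs$mean, g$grs$sd)
      true_class <- rep(if (isTRUE(g$non_autoimmune)) "non_autoimmune" else "t1d", n)
    } else {
      score <- rep(NA_real_, n)
      true_class <- rep(NA_character_, n)
    }

    age_spec <- g$age
    age <- sample_ages(n, age_spec$min, age_spec$max, age_spec$mean, age_spec$sd)
    cl <- g$clinical
    ab <- sample_antibody_status(n, g$antibodies)
    hla_pairs <- sample_hla_pairs(n, g$hla)

    geno_scores <- NULL
    if (config$mode == "genotype") {
      shift <- if (is.null(g$eaf_shift)) 0 else g$eaf_shift
      geno <- generate_group_genotypes(n, weights, shift)
      geno$sample_id <- sprintf("%s_%04d", g$label, seq_len(n))
      if (!is.null(hla)) {
        geno$hla_1 <- hla_pairs$hla_1
        geno$hla_2 <- hla_pairs$hla_2
      }
      geno_scores <- compute_grs(geno, weights, hla)
      score <- geno_scores$normalized
    }

    out[[i]] <- data.frame(
      id = sprintf("%s_%04d", g$label, seq_len(n)),
      group = g$label,
      age_at_diagnosis = round(age, 2),
      adult = age >= 18,
      sex = ifelse(stats::rbinom(n, 1, cl$male %||% 0.5) == 1, "male", "female"),
      bmi = round(sample_truncated_normal(n, cl$bmi_mean %||% 25,
                                          cl$bmi_sd %||% 5, lower = 12), 1),
      dka = stats::rbinom(n, 1, cl$dka %||% 0) == 1,
      weight_loss = stats::rbinom(n, 1, cl$weight_loss %||% 0) == 1,
      polyuria_polydipsia = stats::rbinom(n, 1, cl$polyuria_polydipsia %||% 0) == 1,
      hospitalised = stats::rbinom(n, 1, cl$hospitalised %||% 0) == 1,
      other_autoimmune = stats::rbinom(n, 1, cl$other_autoimmune %||% 0) == 1,
      parent_diabetes = stats::rbinom(n, 1, cl$parent_diabetes %||% 0) == 1,
      gada = ab$gada,
      ia2a = ab$ia2a,
      znt8a = ab$znt8a,
      hla_1 = hla_pairs$hla_1,
      hla_2 = hla_pairs$hla_2,
      grs = score,
      true_class = true_class,
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }
  cohort <- do.call(rbind, out)
  cohort$n_antibodies <- rowSums(cohort[, c("gada", "ia2a", "znt8a")])
  cohort$ab_positive <- cohort$n_antibodies > 0
  class(cohort) <- c("t1d_cohort", "data.frame")
  attr(cohort, "seed") <- config$seed
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a cohort CSV
#'
#' Plain-text round trip of a generated or assembled cohort table. `grs` is
#' written at full precision so write-then-read reproduces every field.
#'
#' @param cohort A cohort data frame.
#' @param path CSV path.
#' @return `path` (write) or the cohort data frame (read).
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$grs <- sprintf("%.15g", df$grs)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("adult", "dka", "weight_loss", "polyuria_polydipsia",
                "hospitalised", "other_autoimmune", "parent_diabetes",
                "gada", "ia2a", "znt8a", "ab_positive")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  class(df) <- c("t1d_cohort", "data.frame")
  df
}
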