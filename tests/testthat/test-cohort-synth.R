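test_that("sample_scores hits the requested moments and is seed-deterministic", {
  x <- sample_scores(1e5, 0.271, 0.026, seed = 3)
  expect_lt(abs(mean(x) - 0.271), 4 * 0.026 / sqrt(1e5))
  expect_lt(abs(stats::sd(x) - 0.026), 0.001)

  expect_identical(sample_scores(50, 0, 1, seed = 9), sample_scores(50, 0, 1, seed = 9))
  tiny <- sample_scores(100, 0.25, 1e-12, seed = 1)
  expect_true(all(abs(tiny - 0.25) < 1e-9))
  expect_error(sample_scores(10, 0, 0), "sd must be")
  expect_error(sample_scores(0, 0, 1), "n must be")
})

test_that("sample_mixture labels its components and honours the weight", {
  p1 <- list(mean = 0.271, sd = 0.026)
  p0 <- list(mean = 0.229, sd = 0.034)

  # at the published composition the mixture mean sits at the observed value
  mx <- sample_mixture(2e5, 71 / 218, p1, p0, seed = 17)
  expect_equal(mean(mx$scores), 71 / 218 * 0.271 + 147 / 218 * 0.229,
               tolerance = 0.002)
  # deterministic component counts: exactly round(w*n) type 1 draws
  expect_equal(sum(mx$labels == "t1d"), round(71 / 218 * 2e5))

  # boundary: weight 1 reduces to the pure type 1 distribution
  w1 <- sample_mixture(1000, 1, p1, p0, seed = 5)
  expect_true(all(w1$labels == "t1d"))
  expect_identical(sort(w1$scores), sort(sample_scores(1000, p1$mean, p1$sd, seed = 5)))

  # symmetric point masses
  pm <- sample_mixture(1000, 0.5, list(mean = 1, sd = 1e-12),
                       list(mean = 0, sd = 1e-12), seed = 2)
  expect_equal(mean(pm$scores), 0.5, tolerance = 1e-6)

  expect_error(sample_mixture(10, 1.2, p1, p0), "weight_t1d")
})

test_that("generate_cohort enforces sizes, group structure and latent truth", {
  cfg <- scaled_config(seed = 42, scale = 0.25)
  co <- generate_cohort(cfg)
  sizes <- vapply(cfg$groups, `[[`, numeric(1), "n")
  expect_equal(as.integer(table(co$group)[vapply(cfg$groups, `[[`, character(1), "label")]),
               as.integer(sizes))

  neg <- co[co$group == "adult_abneg", ]
  pos <- co[co$group == "adult_abpos", ]
  expect_true(all(!neg$ab_positive))             # negative by construction
  expect_true(all(pos$n_antibodies >= 1))        # positive groups have >=1 antibody
  w <- 71 / 218
  expect_equal(mean(neg$true_class == "non_autoimmune"),
               1 - round(w * nrow(neg)) / nrow(neg))  # exact assigned fraction
  expect_true(all(co$adult == (co$age_at_diagnosis >= 18)))
  expect_true(all(co$bmi > 0))
})

test_that("cohorts are reproducible and survive a CSV round trip byte-for-byte", {
  cfg <- scaled_config(seed = 11, scale = 0.1)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(generate_cohort(cfg), f1)
  write_cohort_csv(generate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))

  co <- read_cohort_csv(f1)
  f3 <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f3)
  expect_identical(readLines(f1), readLines(f3))
  expect_type(co$gada, "logical")
  expect_type(co$grs, "double")
})

test_that("per-group child seeds keep earlier groups stable when groups are added", {
  cfg <- scaled_config(seed = 8, scale = 0.1)
  cfg_more <- cfg
  cfg_more$groups <- c(cfg$groups, list(list(
    label = "extra", n = 25, grs = list(mean = 0.25, sd = 0.03),
    age = list(min = 18, max = 75, mean = 40, sd = 10),
    clinical = list(male = 0.5, bmi_mean = 25, bmi_sd = 4),
    antibodies = list(status = "unmeasured")
  )))
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg_more)
  expect_identical(a$grs, b$grs[b$group != "extra"])
})

test_that("group summaries converge to the configured parameters", {
  big <- sample_scores(1e5, 0.243, 0.036, seed = 23)
  expect_lt(abs(mean(big) - 0.243), 4 * 0.036 / sqrt(1e5))
  expect_lt(abs(stats::sd(big) - 0.036), 0.001)

  cfg <- default_cohort_config()
  cfg$seed <- 12
  co <- generate_cohort(cfg)
  for (g in cfg$groups) {
    got <- co$grs[co$group == g$label]
    want_mean <- if (!is.null(g$mixture)) {
      w <- g$mixture$weight_t1d
      w * g$mixture$t1d$mean + (1 - w) * g$mixture$ctrl$mean
    } else g$grs$mean
    want_sd <- if (!is.null(g$mixture)) 0.04 else g$grs$sd
    expect_lt(abs(mean(got) - want_mean), 4 * want_sd / sqrt(g$n))
  }
})

test_that("n = 1 per group still yields fully populated records", {
  cfg <- scaled_config(seed = 3)
  cfg$groups <- lapply(cfg$groups, function(g) { g$n <- 1; g })
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), length(cfg$groups))
  expect_false(anyNA(co$grs))
  expect_false(anyNA(co$age_at_diagnosis))
})

test_that("genotype mode scores dosages through the GRS engine", {
  w <- read_weight_table(system.file("extdata", "weights-synthetic-30.tsv",
                                     package = "t1dmix"))
  h <- read_hla_table(system.file("extdata", "hla-weights-synthetic.json",
                                  package = "t1dmix"))
  cfg <- scaled_config(seed = 5, scale = 0.05)
  cfg$mode <- "genotype"
  cfg$groups <- lapply(cfg$groups, function(g) {
    g$mixture <- NULL
    if (is.null(g$grs)) g$grs <- list(mean = 0.23, sd = 0.03)
    g$eaf_shift <- if (grepl("t2d", g$label)) -0.05 else 0.05
    g
  })
  co1 <- generate_cohort(cfg, weights = w, hla = h)
  co2 <- generate_cohort(cfg, weights = w, hla = h)
  expect_identical(co1$grs, co2$grs)
  expect_true(all(co1$grs >= 0 & co1$grs <= 1))
  # risk-shifted case groups should outscore the frequency-lowered controls
  expect_gt(mean(co1$grs[co1$group == "adult_abpos"]),
            mean(co1$grs[co1$group == "t2d_control"]))
  expect_error(generate_cohort(cfg), "weight table")
})

test_that("configs validate group parameters", {
  cfg <- scaled_config()
  cfg$groups[[1]]$n <- 0
  expect_error(generate_cohort(cfg), "n must be >= 1")
  cfg <- scaled_config()
  cfg$groups[[2]]$mixture$weight_t1d <- 1.4
  expect_error(generate_cohort(cfg), "weight_t1d")
  cfg <- scaled_config()
  cfg$groups[[1]]$clinical$male <- 1.7
  expect_error(generate_cohort(cfg), "probabilities")
})
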