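# shared fixtures, built in code

make_test_weights <- function(ids = c("A", "B"), weights = c(0.5, 1.0),
                              is_hla = rep(FALSE, length(ids)),
                              eaf = rep(0.3, length(ids))) {
  as_weight_table(data.frame(
    variant_id = ids,
    effect_allele = rep("G", length(ids)),
    weight = weights,
    is_hla = is_hla,
    eaf = eaf,
    stringsAsFactors = FALSE
  ))
}

make_test_hla <- function() {
  as_hla_table(
    additive = c("DR3-DQ2" = 1.0, "DR4-DQ8" = 1.2, "DR15-DQ6" = 0, "X" = 0),
    pairs = c("DR3-DQ2|DR4-DQ8" = 3.0, "DR4-DQ8|DR4-DQ8" = 2.6)
  )
}

# random genotype records for property tests
random_records <- function(n, weights, seed = 1) {
  set.seed(seed)
  haps <- c("DR3-DQ2", "DR4-DQ8", "DR15-DQ6", "X")
  g <- data.frame(sample_id = sprintf("s%04d", seq_len(n)),
                  hla_1 = sample(haps, n, replace = TRUE),
                  hla_2 = sample(haps, n, replace = TRUE),
                  stringsAsFactors = FALSE)
  for (v in weights$variant_id) g[[v]] <- round(stats::runif(n, 0, 2), 3)
  g
}

# independent brute-force scorer: plain loops, no matrix algebra
brute_force_grs <- function(record, weights, hla) {
  non_hla <- 0
  hla_snp <- 0
  for (i in seq_len(nrow(weights))) {
    contrib <- weights$weight[i] * record[[weights$variant_id[i]]]
    if (weights$is_hla[i]) hla_snp <- hla_snp + contrib else non_hla <- non_hla + contrib
  }
  key <- paste(sort(c(record$hla_1, record$hla_2)), collapse = "|")
  geno <- if (key %in% names(hla$pairs)) {
    hla$pairs[[key]]
  } else {
    hla$additive[[record$hla_1]] + hla$additive[[record$hla_2]]
  }
  c(non_hla = non_hla, hla = hla_snp + geno, raw = non_hla + hla_snp + geno)
}

# small paper-like config scaled down for fast end-to-end tests
scaled_config <- function(seed = 7, scale = 0.2) {
  cfg <- default_cohort_config()
  cfg$seed <- seed
  cfg$groups <- lapply(cfg$groups, function(g) {
    g$n <- max(20, round(g$n * scale))
    g
  })
  cfg
}
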