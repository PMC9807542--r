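#' Read and validate a variant weight table
#'
#' The type 1 diabetes genetic risk score (T1DGRS) is a weighted sum of
#' effect-allele dosages over a panel of risk loci. The published weights are
#' assay- and reference-specific, so the engine takes them as configuration:
#' a TSV or JSON table with one row per variant.
#'
#' Required columns/fields: `variant_id` (unique), `effect_allele`, `weight`
#' (non-negative, log-odds scale) and `is_hla` (logical; `TRUE` for variants
#' whose dosage contribution belongs to the HLA component of the score). An
#' optional `eaf` column (effect-allele frequency in `[0,1]`) supports lenient
#' imputation of missing dosages via [compute_grs()].
#'
#' @param path Path to a `.tsv`/`.txt` (tab-separated, header) or `.json`
#'   (array of objects) weight table.
#' @return A `data.frame` of class `t1d_weight_table` with columns
#'   `variant_id`, `effect_allele`, `weight`, `is_hla` (and `eaf` if supplied).
#' @seealso [compute_grs()], [read_hla_table()]
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stop("weight table not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tab <- jsonlite::fromJSON(path)
    if (!is.data.frame(tab)) stop("weight table JSON must be an array of objects: ", path)
  } else {
    tab <- tryCatch(
      utils::read.delim(path, stringsAsFactors = FALSE),
      error = function(e) stop("failed to parse weight table ", path, ": ", conditionMessage(e))
    )
  }
  as_weight_table(tab, source = path)
}

#' Construct a weight table from a data frame
#'
#' @param tab Data frame with columns `variant_id`, `effect_allele`, `weight`,
#'   `is_hla` and optionally `eaf`.
#' @param source Optional provenance string kept as an attribute.
#' @return A validated `t1d_weight_table`.
#' @export
as_weight_table <- function(tab, source = NULL) {
  required <- c("variant_id", "effect_allele", "weight", "is_hla")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("weight table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab$variant_id <- as.character(tab$variant_id)
  tab$weight <- as.numeric(tab$weight)
  tab$is_hla <- as.logical(tab$is_hla)
  if (anyNA(tab$weight)) {
    stop("weight table has non-numeric weight at line(s) ",
         paste(which(is.na(tab$weight)) + 1L, collapse = ", "))
  }
  if (any(tab$weight < 0)) {
    stop("negative weight(s) for variant(s): ",
         paste(tab$variant_id[tab$weight < 0], collapse = ", "))
  }
  if (anyDuplicated(tab$variant_id)) {
    stop("duplicate variant_id in weight table: ",
         paste(unique(tab$variant_id[duplicated(tab$variant_id)]), collapse = ", "))
  }
  if (anyNA(tab$is_hla)) stop("is_hla must be TRUE/FALSE for every variant")
  if ("eaf" %in% names(tab)) {
    tab$eaf <- as.numeric(tab$eaf)
    bad <- !is.na(tab$eaf) & (tab$eaf < 0 | tab$eaf > 1)
    if (any(bad)) stop("eaf outside [0,1] for: ", paste(tab$variant_id[bad], collapse = ", "))
  }
  rownames(tab) <- NULL
  class(tab) <- c("t1d_weight_table", "data.frame")
  attr(tab, "source") <- source
  tab
}

#' Read an HLA haplotype weight table
#'
#' HLA class II risk in the T1DGRS is genotype-level: certain haplotype pairs
#' (classically DR3-DQ2/DR4-DQ8) carry a synergistic weight that an additive
#' per-haplotype model misses. The table therefore has two parts:
#' `additive`, a map from haplotype label to a per-copy weight (the label
#' `"X"` denotes any haplotype outside the modelled set and conventionally
#' has weight 0), and `pairs`, a map from an unordered haplotype pair (JSON
#' key `"HAP1|HAP2"`, canonicalised by sorting) to a genotype weight that
#' overrides the additive sum for that pair.
#'
#' @param path Path to a JSON file with fields `additive` and `pairs`.
#' @return A list of class `t1d_hla_table` with elements `additive` (named
#'   numeric) and `pairs` (named numeric, keys sorted within each pair).
#' @export
read_hla_table <- function(path) {
  if (!file.exists(path)) stop("HLA table not found: ", path)
  raw <- jsonlite::fromJSON(path)
  as_hla_table(additive = unlist(raw$additive), pairs = unlist(raw$pairs))
}

#' Construct an HLA weight table
#'
#' @param additive Named numeric vector of per-copy haplotype weights.
#' @param pairs Named numeric vector of genotype weights; names are
#'   `"HAP1|HAP2"` keys, canonicalised here by sorting the two labels.
#' @return A `t1d_hla_table`.
#' @export
as_hla_table <- function(additive, pairs = numeric(0)) {
  if (is.null(additive) || length(additive) == 0 || is.null(names(additive))) {
    stop("HLA table needs a named 'additive' weight vector")
  }
  additive <- vapply(additive, as.numeric, numeric(1))
  if (any(additive < 0)) {
    warning("negative additive HLA weight(s); normalized scores may fall below 0")
  }
  pairs <- if (length(pairs) > 0) vapply(pairs, as.numeric, numeric(1)) else numeric(0)
  if (length(pairs) > 0) {
    key_parts <- strsplit(names(pairs), "|", fixed = TRUE)
    bad <- vapply(key_parts, length, integer(1)) != 2L
    if (any(bad)) stop("pair key(s) not of the form 'HAP1|HAP2': ",
                       paste(names(pairs)[bad], collapse = ", "))
    names(pairs) <- vapply(key_parts, function(p) paste(sort(p), collapse = "|"), character(1))
    referenced <- unique(unlist(key_parts))
    unknown <- setdiff(referenced, names(additive))
    if (length(unknown) > 0) {
      stop("pair table references haplotype(s) without an additive weight: ",
           paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(names(pairs))) {
      stop("duplicate (unordered) pair key(s): ",
           paste(unique(names(pairs)[duplicated(names(pairs))]), collapse = ", "))
    }
  }
  structure(list(additive = additive, pairs = pairs), class = "t1d_hla_table")
}

#' HLA genotype weight for one haplotype pair
#'
#' Looks up the unordered pair in the genotype-level table; pairs not listed
#' there score as the sum of the two per-copy additive weights.
#'
#' @param hap1,hap2 Haplotype labels (e.g. `"DR3-DQ2"`, `"X"`).
#' @param hla A [as_hla_table()] object.
#' @return Numeric genotype weight.
#' @export
hla_pair_weight <- function(hap1, hap2, hla) {
  stopifnot(inherits(hla, "t1d_hla_table"))
  labs <- c(as.character(hap1), as.character(hap2))
  if (any(is.na(labs)) || any(!nzchar(labs))) stop("both haplotype slots must be populated")
  unknown <- setdiff(labs, names(hla$additive))
  if (length(unknown) > 0) {
    stop("unknown haplotype label(s): ", paste(unknown, collapse = ", "))
  }
  key <- paste(sort(labs), collapse = "|")
  if (key %in% names(hla$pairs)) {
    unname(hla$pairs[[key]])
  } else {
    unname(hla$additive[[labs[1]]] + hla$additive[[labs[2]]])
  }
}

# Divisor of the normalized score: twice the sum of all variant weights plus
# the largest HLA genotype weight attainable from the table. With nonnegative
# weights this bounds the raw score, so normalized scores lie in [0,1].
grs_divisor <- function(weights, hla) {
  hla_cap <- 0
  if (!is.null(hla)) {
    caps <- c(0, hla$pairs, 2 * hla$additive)
    hla_cap <- max(caps)
  }
  2 * sum(weights$weight) + hla_cap
}

#' Compute the T1DGRS and its HLA / non-HLA components
#'
#' For each sample the non-HLA component is the dosage-weighted sum over
#' variants with `is_hla = FALSE`; the HLA component is the genotype-level
#' haplotype-pair weight from [hla_pair_weight()] plus the dosage-weighted sum
#' over `is_hla = TRUE` variants (tag variants outside the modelled class II
#' haplotypes). The raw score is their sum and the normalized score divides by
#' a fixed table-wide maximum (twice the summed variant weights plus the
#' largest genotype weight), so any affine rescaling convention can be layered
#' on top without affecting group-level analyses.
#'
#' @param genotypes Data frame with columns `sample_id`, `hla_1`, `hla_2` and
#'   one numeric dosage column (in `[0,2]`, effect-allele count) per variant.
#'   `hla_1`/`hla_2` may be omitted if `hla = NULL`.
#' @param weights A [read_weight_table()] table.
#' @param hla A [read_hla_table()] table, or `NULL` to score the HLA
#'   haplotype contribution as zero.
#' @param strict If `TRUE` (default) a missing dosage for any weighted variant
#'   is an error naming the variants; if `FALSE`, missing dosages are imputed
#'   as `2 * eaf` from the weight table's `eaf` column (error if absent) and
#'   the imputations are recorded in the `imputed` attribute.
#' @return Data frame of class `t1d_grs` with columns `sample_id`, `raw`,
#'   `normalized`, `hla`, `non_hla`.
#' @examples
#' w <- as_weight_table(data.frame(
#'   variant_id = c("A", "B"), effect_allele = c("G", "T"),
#'   weight = c(0.5, 1.0), is_hla = FALSE))
#' g <- data.frame(sample_id = "s1", A = 2, B = 1)
#' compute_grs(g, w)  # raw 2.0, normalized 2/3
#' @export
compute_grs <- function(genotypes, weights, hla = NULL, strict = TRUE) {
  stopifnot(inherits(weights, "t1d_weight_table"))
  if (!"sample_id" %in% names(genotypes)) stop("genotypes need a sample_id column")
  n <- nrow(genotypes)
  have_hla_cols <- all(c("hla_1", "hla_2") %in% names(genotypes))
  if (!is.null(hla) && !have_hla_cols) {
    stop("HLA table supplied but genotypes lack hla_1/hla_2 columns")
  }

  ids <- weights$variant_id
  missing_vars <- setdiff(ids, names(genotypes))
  dosage <- matrix(NA_real_, nrow = n, ncol = length(ids),
                   dimnames = list(NULL, ids))
  for (v in intersect(ids, names(genotypes))) dosage[, v] <- as.numeric(genotypes[[v]])

  imputed <- list()
  if (length(missing_vars) > 0 || anyNA(dosage)) {
    if (strict) {
      bad <- unique(c(missing_vars, ids[apply(dosage, 2, anyNA)]))
      stop("missing dosage(s) in strict mode for variant(s): ",
           paste(bad, collapse = ", "))
    }
    if (!"eaf" %in% names(weights)) {
      stop("lenient mode imputation needs an 'eaf' column in the weight table")
    }
    for (v in ids) {
      na_rows <- which(is.na(dosage[, v]))
      if (length(na_rows) > 0) {
        eaf <- weights$eaf[match(v, ids)]
        if (is.na(eaf)) stop("no eaf available to impute variant ", v)
        dosage[na_rows, v] <- 2 * eaf
        imputed[[v]] <- genotypes$sample_id[na_rows]
      }
    }
  }
  out_of_range <- dosage < 0 | dosage > 2
  if (any(out_of_range)) {
    stop("dosage outside [0,2] for variant(s): ",
         paste(unique(colnames(dosage)[which(out_of_range, arr.ind = TRUE)[, 2]]),
               collapse = ", "))
  }

  w_non <- weights$weight[!weights$is_hla]
  w_hla <- weights$weight[weights$is_hla]
  non_hla <- as.numeric(dosage[, !weights$is_hla, drop = FALSE] %*% w_non)
  hla_snp <- if (any(weights$is_hla)) {
    as.numeric(dosage[, weights$is_hla, drop = FALSE] %*% w_hla)
  } else rep(0, n)
  hla_geno <- if (!is.null(hla)) {
    vapply(seq_len(n), function(i) {
      hla_pair_weight(genotypes$hla_1[i], genotypes$hla_2[i], hla)
    }, numeric(1))
  } else rep(0, n)

  hla_comp <- hla_snp + hla_geno
  raw <- hla_comp + non_hla
  res <- data.frame(
    sample_id = as.character(genotypes$sample_id),
    raw = raw,
    normalized = raw / grs_divisor(weights, hla),
    hla = hla_comp,
    non_hla = non_hla,
    stringsAsFactors = FALSE
  )
  class(res) <- c("t1d_grs", "data.frame")
  attr(res, "imputed") <- imputed
  res
}

#' Read genotype dosages from a wide TSV
#'
#' Expects a header row with `sample_id`, optional `hla_1`/`hla_2` haplotype
#' label columns, and one column per variant containing effect-allele dosages
#' in `[0,2]`.
#'
#' @param path TSV path.
#' @return Data frame suitable for [compute_grs()].
#' @export
read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  g <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(g)) stop("genotype TSV needs a sample_id column")
  g$sample_id <- as.character(g$sample_id)
  g
}

#' Read genotype dosages from a VCF
#'
#' Uses the `DS` FORMAT field when present, otherwise converts `GT` calls to
#' effect-allele counts assuming the ALT allele is the effect allele (rows
#' where it is not should be pre-flipped or supplied via TSV). HLA haplotype
#' labels cannot be carried in a VCF; supply them through `hla_labels`.
#'
#' @param path VCF path (plain or bgzipped).
#' @param hla_labels Optional data frame `sample_id`, `hla_1`, `hla_2` merged
#'   onto the dosage table.
#' @return Data frame suitable for [compute_grs()]; variant columns are named
#'   by the VCF ID field.
#' @export
read_genotypes_vcf <- function(path, hla_labels = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF genotypes requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  fmt <- vcfR::vcf_field_names(v, tag = "FORMAT")
  has_ds <- "DS" %in% fmt$ID
  if (has_ds) {
    m <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    m <- apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
    })
  }
  rownames(m) <- ids
  g <- data.frame(sample_id = colnames(m), t(m),
                  stringsAsFactors = FALSE, check.names = FALSE)
  rownames(g) <- NULL
  if (!is.null(hla_labels)) g <- merge(g, hla_labels, by = "sample_id", sort = FALSE)
  g
}

#' Write per-sample scores to CSV
#'
#' @param scores A [compute_grs()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grs_csv <- function(scores, path) {
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Scale values to mean 0, SD 1
#'
#' The HLA and non-HLA score components are conventionally standardised
#' before plotting or comparison across cohorts.
#'
#' @param x Numeric vector, length at least 2, non-constant.
#' @return `(x - mean(x)) / sd(x)`, order preserved.
#' @export
zscale <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("zscale needs at least 2 values")
  s <- stats::sd(x)
  if (!is.finite(s) || s <= .Machine$double.eps^0.5 * max(1, abs(mean(x)))) {
    stop("zscale undefined for (near-)constant input: SD is zero")
  }
  (x - mean(x)) / s
}
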