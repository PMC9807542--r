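#' Default islet-autoantibody centiles
#'
#' Positivity thresholds for the three-marker islet autoantibody panel are
#' defined as centiles of non-diabetic control titre distributions: the 97th
#' for GADA, 98th for IA2A and 97.5th for ZnT8A.
#'
#' @return Named numeric vector of centiles, names `gada`, `ia2a`, `znt8a`.
#' @export
default_antibody_centiles <- function() {
  c(gada = 97, ia2a = 98, znt8a = 97.5)
}

#' Derive an antibody positivity threshold from control titres
#'
#' The threshold is the given centile of the non-diabetic control titre
#' distribution. The default percentile definition is nearest-rank (the
#' `ceiling(centile/100 * n)`-th order statistic), which always returns an
#' observed titre and is reproducible across software; linear interpolation
#' (`stats::quantile` type 7) is available for sensitivity checks.
#'
#' @param control_titres Non-negative control titres (>= 20 values).
#' @param centile Centile in (0, 100), e.g. 97.
#' @param method `"nearest_rank"` (default) or `"interpolate"`.
#' @return The threshold titre.
#' @export
derive_threshold <- function(control_titres,
                             centile,
                             method = c("nearest_rank", "interpolate")) {
  method <- match.arg(method)
  x <- as.numeric(control_titres)
  if (length(x) == 0) stop("no control titres supplied")
  if (length(x) < 20) stop("need at least 20 control titres, got ", length(x))
  if (anyNA(x)) stop("control titres contain NA")
  if (!is.numeric(centile) || centile <= 0 || centile >= 100) {
    stop("centile must lie strictly between 0 and 100")
  }
  if (method == "nearest_rank") {
    k <- ceiling(centile / 100 * length(x))
    sort(x)[k]
  } else {
    unname(stats::quantile(x, centile / 100, type = 7))
  }
}

#' Call per-antibody and panel positivity
#'
#' An antibody is positive when its titre is greater than or equal to its
#' threshold (ties at the threshold are positive); the panel is positive when
#' any measured antibody is positive.
#'
#' @param titres Named numeric vector (or 1-row data frame) of titres; names
#'   must be a subset of the threshold names (e.g. `gada`, `ia2a`, `znt8a`).
#' @param thresholds Named numeric vector of per-antibody thresholds.
#' @return List with `status` (named logical), `n_positive` and
#'   `overall_positive`.
#' @export
call_panel <- function(titres, thresholds) {
  if (is.data.frame(titres)) titres <- unlist(titres[1, , drop = TRUE])
  if (is.null(names(titres)) || any(!nzchar(names(titres)))) {
    stop("titres must be named by antibody")
  }
  unknown <- setdiff(names(titres), names(thresholds))
  if (length(unknown) > 0) {
    stop("no threshold for antibody(ies): ", paste(unknown, collapse = ", "))
  }
  if (length(titres) < 1 || length(titres) > 3) {
    stop("panel must contain 1-3 antibodies")
  }
  status <- as.numeric(titres) >= as.numeric(thresholds[names(titres)])
  names(status) <- names(titres)
  list(status = status,
       n_positive = sum(status),
       overall_positive = any(status))
}

#' Panel positivity restricted to a subset of antibodies
#'
#' Recomputes the any-positive call using only the named antibodies. Used to
#' quantify the added value of one marker: individuals positive overall but
#' negative on the reduced panel are identified only by the excluded
#' antibody.
#'
#' @param status Named logical vector of per-antibody positivity (or the
#'   `status` element of [call_panel()]).
#' @param subset Character vector of antibody names to keep; must be a
#'   non-empty subset of `names(status)`.
#' @return Logical: any-positive over the subset.
#' @export
positivity_with_subset <- function(status, subset) {
  if (is.list(status) && !is.null(status$status)) status <- status$status
  if (length(subset) == 0) stop("subset must be non-empty")
  unknown <- setdiff(subset, names(status))
  if (length(unknown) > 0) {
    stop("subset names not in panel: ", paste(unknown, collapse = ", "))
  }
  any(status[subset])
}

#' Added-value analysis of one antibody over the rest of the panel
#'
#' Among individuals negative for every antibody in `base`, counts how many
#' are positive for `added`. Mirrors the clinical question of how many extra
#' positives a newly added marker contributes.
#'
#' @param status_matrix Logical matrix or data frame, one row per individual,
#'   columns named by antibody.
#' @param added Name of the additional antibody.
#' @param base Names of the baseline panel (default: all other columns).
#' @return List with `n_base_negative`, `n_added_positive` and `proportion`.
#' @export
antibody_added_value <- function(status_matrix, added,
                                 base = setdiff(colnames(status_matrix), added)) {
  sm <- as.matrix(as.data.frame(status_matrix))
  if (!added %in% colnames(sm)) stop("antibody not in panel: ", added)
  if (length(base) == 0 || any(!base %in% colnames(sm))) {
    stop("base panel names must be non-empty columns of the status matrix")
  }
  keep <- stats::complete.cases(sm[, c(added, base), drop = FALSE])
  sm <- sm[keep, , drop = FALSE]
  base_neg <- rowSums(sm[, base, drop = FALSE], na.rm = FALSE) == 0
  n_base_neg <- sum(base_neg)
  n_added <- sum(sm[base_neg, added])
  list(n_base_negative = n_base_neg,
       n_added_positive = n_added,
       proportion = if (n_base_neg > 0) n_added / n_base_neg else NA_real_)
}
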