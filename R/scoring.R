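#' Compute H-scores from staining-level fractions
#'
#' The semiquantitative H-score weights each staining intensity level by the
#' percentage of cells at that level. With two intensity levels above
#' background ("1" faint, "2" prominent) the score is
#' `0*p0 + 1*p1 + 2*p2`, giving a 0-200 scale: 0 when no cell stains, 200
#' when every cell stains prominently.
#'
#' @param p0,p1,p2 numeric vectors: percent of cells at staining level
#'   0, 1 and 2. Each must lie in `[0, 100]` and `p0 + p1 + p2` must equal
#'   100 (tolerance 1e-9).
#' @return numeric vector of H-scores in `[0, 200]`.
#' @examples
#' compute_hscore(100, 0, 0)   # 0
#' compute_hscore(0, 0, 100)   # 200
#' compute_hscore(30, 40, 30)  # 100
#' @export
compute_hscore <- function(p0, p1, p2) {
  n <- max(length(p0), length(p1), length(p2))
  p0 <- rep_len(as.numeric(p0), n)
  p1 <- rep_len(as.numeric(p1), n)
  p2 <- rep_len(as.numeric(p2), n)
  if (anyNA(p0) || anyNA(p1) || anyNA(p2)) {
    tma_stop("tmahet_validation_error", "staining fractions contain NA")
  }
  if (any(p0 < 0 | p1 < 0 | p2 < 0)) {
    tma_stop("tmahet_validation_error", "staining fractions must be non-negative")
  }
  off <- abs(p0 + p1 + p2 - 100) > 1e-9
  if (any(off)) {
    tma_stop("tmahet_validation_error",
             sprintf("staining fractions do not sum to 100 (element%s %s)",
                     if (sum(off) > 1) "s" else "",
                     paste(which(off), collapse = ", ")))
  }
  p1 + 2 * p2
}

#' Binarize H-scores at the positivity threshold
#'
#' A sample is scored positive when its H-score is greater than or equal to
#' the threshold (default 20, applied to every marker alike); the boundary
#' value is positive.
#'
#' @param h numeric vector of H-scores in `[0, 200]` (NA allowed: not
#'   assessed).
#' @param threshold non-negative positivity cut-off.
#' @return logical vector (`TRUE` = positive) with the threshold recorded
#'   in attribute `"threshold"`.
#' @examples
#' binarize(c(0, 19.9, 20, 200))
#' @export
binarize <- function(h, threshold = 20) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0) {
    tma_stop("tmahet_config_error", "`threshold` must be a single non-negative number")
  }
  h <- as.numeric(h)
  if (any(!is.na(h) & (h < 0 | h > 200))) {
    tma_stop("tmahet_validation_error", "H-score outside [0, 200]")
  }
  structure(h >= threshold, threshold = threshold)
}

#' Fill in H-score columns of a cohort from staining fractions
#'
#' For every marker with `<marker>_p0/_p1/_p2` columns, computes the
#' H-score on rows where no precomputed `<marker>_hscore` is present.
#' Precomputed H-scores are left untouched (they passed the same `[0,200]`
#' validation on entry).
#'
#' @param cohort a [cohort_table()].
#' @return the cohort with a complete `<marker>_hscore` column per marker
#'   that has any staining data.
#' @export
score_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  schema <- attr(cohort, "schema")
  for (m in schema$markers) {
    fr_cols <- paste0(m, c("_p0", "_p1", "_p2"))
    if (!all(fr_cols %in% names(cohort))) next
    hs_col <- paste0(m, "_hscore")
    h <- marker_hscore(cohort, m, compute = TRUE)
    cohort[[hs_col]] <- h
  }
  cohort
}
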