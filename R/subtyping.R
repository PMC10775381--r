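#' Classify a tumor into one of the four AR/NE molecular subtypes
#'
#' The AR axis summarises the androgen-receptor signaling markers (AR,
#' NKX3.1); the NE axis summarises the neuroendocrine markers (SYP, INSM1).
#' An axis is called positive when the aggregate of its marker H-scores
#' (default: the maximum) reaches the positivity threshold, and the subtype
#' is the cross of the two axis calls: adenocarcinoma `AR+/NE-`, NEPC
#' `AR-/NE+`, amphicrine `AR+/NE+`, double-negative `AR-/NE-`.
#'
#' A missing marker (`NA`) is tolerated as long as its axis retains one
#' measured marker; when both markers of an axis are missing the subtype is
#' indeterminate and a `tmahet_indeterminate_error` is raised.
#'
#' @param ar_h,nkx_h H-scores of AR and NKX3.1 (either may be `NA`).
#' @param syp_h,insm1_h H-scores of SYP and INSM1 (either may be `NA`).
#' @param axis_threshold positivity cut-off applied to the axis aggregate;
#'   default 20, the same cut-off used for all markers in the package.
#' @param aggregator how the two markers of an axis are combined: `"max"`
#'   (default; an axis is positive if either marker is) or `"mean"`.
#' @return an object of class `"subtype_call"`: list with `subtype` (one of
#'   [tma_subtypes()]), `ar_axis_score`, `ne_axis_score`, `source`
#'   (`"derived"`), `threshold` and `aggregator`.
#' @examples
#' classify_subtype(150, 100, 0, 0)$subtype   # "AR+/NE-"
#' classify_subtype(0, 0, 90, 120)$subtype    # "AR-/NE+"
#' classify_subtype(20, 0, 20, 0)$subtype     # boundary: "AR+/NE+"
#' @export
classify_subtype <- function(ar_h, nkx_h, syp_h, insm1_h,
                             axis_threshold = 20,
                             aggregator = c("max", "mean")) {
  aggregator <- match.arg(aggregator)
  if (axis_threshold < 0) {
    tma_stop("tmahet_config_error", "`axis_threshold` must be non-negative")
  }
  agg <- function(a, b, axis) {
    v <- c(a, b)
    v <- v[!is.na(v)]
    if (!length(v)) {
      tma_stop("tmahet_indeterminate_error",
               sprintf("both %s-axis markers missing: subtype indeterminate", axis))
    }
    if (any(v < 0 | v > 200)) {
      tma_stop("tmahet_validation_error", "H-score outside [0, 200]")
    }
    if (aggregator == "max") max(v) else mean(v)
  }
  ar_axis <- agg(ar_h, nkx_h, "AR")
  ne_axis <- agg(syp_h, insm1_h, "NE")
  subtype <- paste0("AR", if (ar_axis >= axis_threshold) "+" else "-",
                    "/NE", if (ne_axis >= axis_threshold) "+" else "-")
  structure(
    list(subtype = subtype, ar_axis_score = ar_axis, ne_axis_score = ne_axis,
         source = "derived", threshold = axis_threshold,
         aggregator = aggregator),
    class = "subtype_call"
  )
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("<subtype_call> %s (%s; AR axis %.4g, NE axis %.4g; threshold %g)\n",
              x$subtype, x$source, x$ar_axis_score, x$ne_axis_score,
              x$threshold))
  invisible(x)
}

#' Subtype every tumor block of a cohort
#'
#' Aggregates each subtype marker across the cores of a block (default:
#' maximum, so a block's axis is positive when any core expresses an axis
#' marker), then applies [classify_subtype()]. When the cohort carries a
#' `subtype_label` column, a block's provided label takes precedence over
#' the derived call (`source = "provided"`), allowing exact reproduction of
#' pathologist-scored cohorts.
#'
#' @param cohort a [cohort_table()] (scored or raw; H-scores are computed
#'   from fractions where needed).
#' @param core_aggregator how marker H-scores are reconciled across the
#'   cores of a block: `"max"` (default), `"mean"` or `"median"`.
#' @param axis_threshold,aggregator passed to [classify_subtype()].
#' @param indeterminate how to treat blocks whose subtype cannot be called
#'   (an axis with no measured marker): `"na"` (default; `NA` subtype) or
#'   `"error"`.
#' @return data.frame with one row per block: `patient_id`, `site_id`,
#'   `block_id`, `anatomic_site`, `n_cores`, `subtype`, `ar_axis_score`,
#'   `ne_axis_score`, `source`.
#' @export
subtype_blocks <- function(cohort, core_aggregator = c("max", "mean", "median"),
                           axis_threshold = 20, aggregator = c("max", "mean"),
                           indeterminate = c("na", "error")) {
  stopifnot(inherits(cohort, "cohort_table"))
  core_aggregator <- match.arg(core_aggregator)
  aggregator <- match.arg(aggregator)
  indeterminate <- match.arg(indeterminate)
  core_fun <- switch(core_aggregator, max = max, mean = mean,
                     median = stats::median)

  key <- block_key(cohort)
  idx <- split(seq_len(nrow(cohort)), key)
  # keep first-appearance order rather than alphabetical
  idx <- idx[unique(key)]
  mk <- function(marker, rows) {
    h <- marker_hscore(cohort, marker)[rows]
    h <- h[!is.na(h)]
    if (!length(h)) NA_real_ else core_fun(h)
  }
  has_label <- "subtype_label" %in% names(cohort)
  rows_out <- lapply(idx, function(rows) {
    first <- rows[1]
    provided <- NA_character_
    if (has_label) {
      lab <- unique(stats::na.omit(cohort$subtype_label[rows]))
      lab <- lab[nzchar(lab)]
      if (length(lab) > 1) {
        tma_stop("tmahet_integrity_error",
                 sprintf("conflicting subtype_label within block %s/%s/%s",
                         cohort$patient_id[first], cohort$site_id[first],
                         cohort$block_id[first]))
      }
      if (length(lab) == 1) provided <- lab
    }
    if (!is.na(provided)) {
      return(data.frame(
        patient_id = cohort$patient_id[first], site_id = cohort$site_id[first],
        block_id = cohort$block_id[first],
        anatomic_site = cohort$anatomic_site[first],
        n_cores = length(rows), subtype = provided,
        ar_axis_score = NA_real_, ne_axis_score = NA_real_,
        source = "provided", stringsAsFactors = FALSE))
    }
    call <- tryCatch(
      classify_subtype(mk("AR", rows), mk("NKX3.1", rows),
                       mk("SYP", rows), mk("INSM1", rows),
                       axis_threshold = axis_threshold,
                       aggregator = aggregator),
      tmahet_indeterminate_error = function(e) {
        if (indeterminate == "error") stop(e)
        NULL
      })
    data.frame(
      patient_id = cohort$patient_id[first], site_id = cohort$site_id[first],
      block_id = cohort$block_id[first],
      anatomic_site = cohort$anatomic_site[first],
      n_cores = length(rows),
      subtype = if (is.null(call)) NA_character_ else call$subtype,
      ar_axis_score = if (is.null(call)) NA_real_ else call$ar_axis_score,
      ne_axis_score = if (is.null(call)) NA_real_ else call$ne_axis_score,
      source = if (is.null(call)) "indeterminate" else "derived",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows_out)
  rownames(out) <- NULL
  attr(out, "core_aggregator") <- core_aggregator
  out
}

#' Subtype a single tumor block
#'
#' Convenience wrapper around [subtype_blocks()] for one block.
#'
#' @param cohort a [cohort_table()].
#' @param patient_id,site_id,block_id identifiers of the block.
#' @param ... passed to [subtype_blocks()].
#' @return a `"subtype_call"`-like one-row data.frame.
#' @export
subtype_block <- function(cohort, patient_id, site_id, block_id, ...) {
  sel <- cohort$patient_id == patient_id & cohort$site_id == site_id &
    cohort$block_id == block_id
  if (!any(sel)) {
    tma_stop("tmahet_integrity_error",
             sprintf("no such block: %s/%s/%s", patient_id, site_id, block_id))
  }
  sub <- cohort[sel, , drop = FALSE]
  attributes(sub)[c("schema", "genomic", "provenance")] <-
    attributes(cohort)[c("schema", "genomic", "provenance")]
  class(sub) <- class(cohort)
  subtype_blocks(sub, indeterminate = "error", ...)
}

# Per-sample subtype: every core inherits its block's subtype call.
sample_subtypes <- function(cohort, blocks = NULL, ...) {
  if (is.null(blocks)) blocks <- subtype_blocks(cohort, ...)
  bkey <- paste(blocks$patient_id, blocks$site_id, blocks$block_id, sep = "\r")
  blocks$subtype[match(block_key(cohort), bkey)]
}
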