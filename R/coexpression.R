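#' Binarized co-expression contingency table for a marker pair
#'
#' Cross-tabulates the binarized (H-score >= threshold) statuses of two
#' markers over the analysis units of a stratum. Units missing either
#' marker are excluded from the denominator. Percentages are reported
#' half-up at `digits` decimal places (default integer), matching the
#' convention of published IHC co-expression tables.
#'
#' @param cohort a [cohort_table()].
#' @param marker_a,marker_b marker names.
#' @param stratum `"all"` or one of [tma_subtypes()]; subtype strata are
#'   resolved through [subtype_blocks()] (provided labels take precedence).
#' @param unit analysis unit: `"core"` (default; every TMA sample counts)
#'   or `"block"` (cores reconciled by maximum H-score).
#' @param threshold positivity cut-off (default 20).
#' @param digits decimal places of the reported percentages (0 or 1).
#' @return object of class `"coexpression_table"`: counts and percentages
#'   for `both_positive`, `a_only`, `b_only`, `neither`, plus `total` and
#'   the table's settings.
#' @export
tabulate_coexpression <- function(cohort, marker_a, marker_b,
                                  stratum = "all",
                                  unit = c("core", "block"),
                                  threshold = 20, digits = 0) {
  stopifnot(inherits(cohort, "cohort_table"))
  unit <- match.arg(unit)
  if (!identical(stratum, "all") && !stratum %in% tma_subtypes()) {
    tma_stop("tmahet_config_error",
             sprintf("unknown stratum %s", shQuote(stratum)))
  }

  ha <- marker_hscore(cohort, marker_a)
  hb <- marker_hscore(cohort, marker_b)
  st <- if (identical(stratum, "all")) NULL else sample_subtypes(cohort)

  if (unit == "block") {
    key <- block_key(cohort)
    agg <- function(h) {
      v <- tapply(h, factor(key, levels = unique(key)), function(x) {
        x <- x[!is.na(x)]
        if (!length(x)) NA_real_ else max(x)
      })
      as.numeric(v)
    }
    first <- !duplicated(key)
    if (!is.null(st)) st <- st[first]
    ha <- agg(ha); hb <- agg(hb)
  }

  keep <- !is.na(ha) & !is.na(hb)
  if (!is.null(st)) keep <- keep & !is.na(st) & st == stratum
  if (!any(keep)) {
    tma_stop("tmahet_empty_stratum_error",
             sprintf("no %s with both %s and %s measured in stratum %s",
                     unit, marker_a, marker_b, shQuote(stratum)))
  }
  a <- ha[keep] >= threshold
  b <- hb[keep] >= threshold
  counts <- c(both_positive = sum(a & b), a_only = sum(a & !b),
              b_only = sum(!a & b), neither = sum(!a & !b))
  total <- sum(counts)
  structure(
    list(marker_a = marker_a, marker_b = marker_b, stratum = stratum,
         unit = unit, threshold = threshold, counts = counts, total = total,
         percentages = round_half_up(100 * counts / total, digits),
         digits = digits),
    class = "coexpression_table"
  )
}

#' @export
print.coexpression_table <- function(x, ...) {
  cat(sprintf("<coexpression_table> %s x %s (%s, unit = %s, n = %d)\n",
              x$marker_a, x$marker_b, x$stratum, x$unit, x$total))
  lab <- c(sprintf("%s+ %s+", x$marker_a, x$marker_b),
           sprintf("%s+ only", x$marker_a),
           sprintf("%s+ only", x$marker_b),
           "neither")
  for (i in seq_along(x$counts)) {
    cat(sprintf("  %-18s %4d/%d (%s%%)\n", lab[i], x$counts[i], x$total,
                format(x$percentages[i])))
  }
  invisible(x)
}

#' Classify one patient as non-expressor / heterogeneous / uniform-high
#'
#' Applies the three-way rule over a patient's per-unit H-scores for one
#' marker: `non_expressor` when every unit is below the threshold,
#' `uniform_high` when every unit reaches it, `heterogeneous` when both
#' kinds are present. The default unit is the metastatic site, with cores
#' reconciled by maximum (a site expresses the marker if any of its cores
#' does).
#'
#' @param cohort a [cohort_table()].
#' @param patient_id patient to classify.
#' @param marker marker name.
#' @param unit `"site"` (default), `"block"` or `"core"`.
#' @param site_aggregator reconciliation of cores into the unit score:
#'   `"max"` (default) or `"mean"`.
#' @param threshold positivity cut-off (default 20).
#' @return object of class `"patient_class"`: list with `patient_id`,
#'   `marker`, `class`, `n_units`, `unit`, `threshold`.
#' @export
classify_patient <- function(cohort, patient_id, marker,
                             unit = c("site", "block", "core"),
                             site_aggregator = c("max", "mean"),
                             threshold = 20) {
  stopifnot(inherits(cohort, "cohort_table"))
  unit <- match.arg(unit)
  site_aggregator <- match.arg(site_aggregator)
  agg_fun <- if (site_aggregator == "max") max else mean

  sel <- cohort$patient_id == patient_id
  if (!any(sel)) {
    tma_stop("tmahet_integrity_error",
             sprintf("no such patient: %s", patient_id))
  }
  h <- marker_hscore(cohort, marker)[sel]
  key <- switch(unit,
                core = seq_len(sum(sel)),
                block = block_key(cohort)[sel],
                site = paste(cohort$patient_id, cohort$site_id, sep = "\r")[sel])
  per_unit <- tapply(h, factor(key, levels = unique(key)), function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else agg_fun(x)
  })
  per_unit <- per_unit[!is.na(per_unit)]
  if (!length(per_unit)) {
    tma_stop("tmahet_not_evaluable_error",
             sprintf("patient %s has no measured %s unit", patient_id, marker))
  }
  pos <- per_unit >= threshold
  cls <- if (all(pos)) "uniform_high" else if (!any(pos)) "non_expressor"
         else "heterogeneous"
  structure(
    list(patient_id = patient_id, marker = marker, class = cls,
         n_units = length(per_unit), unit = unit, threshold = threshold),
    class = "patient_class"
  )
}

#' @export
print.patient_class <- function(x, ...) {
  cat(sprintf("<patient_class> %s / %s: %s (%d %ss)\n", x$patient_id,
              x$marker, x$class, x$n_units, x$unit))
  invisible(x)
}

#' Classify every patient of a cohort for one marker
#'
#' Runs [classify_patient()] over all patients. Patients with no measured
#' unit for the marker are not evaluable: they are excluded from the
#' returned table (and from any percentage computed on it) and listed in
#' the `"excluded"` attribute, keeping denominators explicit.
#'
#' @inheritParams classify_patient
#' @param digits decimal places of the summary percentages.
#' @return data.frame, one row per evaluable patient, with columns
#'   `patient_id`, `marker`, `class`, `n_units`; attribute `"summary"`
#'   holds per-class counts and half-up percentages over evaluable
#'   patients, attribute `"excluded"` the non-evaluable patient ids.
#' @export
classify_patients <- function(cohort, marker, unit = c("site", "block", "core"),
                              site_aggregator = c("max", "mean"),
                              threshold = 20, digits = 0) {
  stopifnot(inherits(cohort, "cohort_table"))
  unit <- match.arg(unit)
  site_aggregator <- match.arg(site_aggregator)
  patients <- unique(cohort$patient_id)
  res <- lapply(patients, function(p) {
    tryCatch(classify_patient(cohort, p, marker, unit = unit,
                              site_aggregator = site_aggregator,
                              threshold = threshold),
             tmahet_not_evaluable_error = function(e) NULL)
  })
  excluded <- patients[vapply(res, is.null, logical(1))]
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    tma_stop("tmahet_not_evaluable_error",
             sprintf("no patient evaluable for %s", marker))
  }
  out <- data.frame(
    patient_id = vapply(res, `[[`, character(1), "patient_id"),
    marker = marker,
    class = vapply(res, `[[`, character(1), "class"),
    n_units = vapply(res, `[[`, integer(1), "n_units"),
    stringsAsFactors = FALSE)
  lev <- c("non_expressor", "heterogeneous", "uniform_high")
  counts <- table(factor(out$class, levels = lev))
  summ <- data.frame(
    class = lev, n = as.integer(counts),
    total = nrow(out),
    percentage = round_half_up(100 * as.integer(counts) / nrow(out), digits),
    stringsAsFactors = FALSE)
  attr(out, "summary") <- summ
  attr(out, "excluded") <- excluded
  out
}

#' Marker positivity within a molecular subtype
#'
#' Proportion of units of a given subtype (or of all units) whose H-score
#' reaches the threshold, reported with numerator and denominator. The
#' `"patient"` unit scores a patient positive when any of their sites is
#' positive (any-site positivity).
#'
#' @param cohort a [cohort_table()].
#' @param marker marker name.
#' @param subtype one of [tma_subtypes()], or `"all"`.
#' @param unit `"block"` (default), `"core"` or `"patient"`.
#' @param threshold positivity cut-off.
#' @param digits decimal places of the percentage.
#' @return list with `n_positive`, `n_total`, `percentage`, and settings.
#' @export
subtype_positivity <- function(cohort, marker, subtype = "all",
                               unit = c("block", "core", "patient"),
                               threshold = 20, digits = 0) {
  stopifnot(inherits(cohort, "cohort_table"))
  unit <- match.arg(unit)
  h <- marker_hscore(cohort, marker)
  st <- if (identical(subtype, "all")) NULL else sample_subtypes(cohort)
  if (!identical(subtype, "all") && !subtype %in% tma_subtypes()) {
    tma_stop("tmahet_config_error", sprintf("unknown subtype %s", shQuote(subtype)))
  }

  key <- switch(unit,
                core = as.character(seq_len(nrow(cohort))),
                block = block_key(cohort),
                patient = cohort$patient_id)
  keep <- !is.na(h)
  if (!is.null(st)) keep <- keep & !is.na(st) & st == subtype
  if (!any(keep)) {
    tma_stop("tmahet_empty_stratum_error",
             sprintf("no evaluable %s for %s in subtype %s", unit, marker,
                     shQuote(subtype)))
  }
  pos <- tapply(h[keep] >= threshold, factor(key[keep], levels = unique(key[keep])),
                any)
  list(marker = marker, subtype = subtype, unit = unit,
       n_positive = sum(pos), n_total = length(pos),
       percentage = round_half_up(100 * sum(pos) / length(pos), digits),
       threshold = threshold)
}
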