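#' Construct a validated cohort table
#'
#' A cohort table holds one row per TMA core with its identifiers
#' (`patient_id`, `site_id`, `block_id`, `core_id`), its `anatomic_site`
#' label, optionally a provided `subtype_label`, and per-marker staining
#' data: either a precomputed H-score column `<marker>_hscore` or raw
#' staining-level fraction columns `<marker>_p0`, `<marker>_p1`,
#' `<marker>_p2` (percent of cells at intensity 0/1/2). Patient-level
#' genomic alteration flags ride along as a separate table.
#'
#' Validation is total: a malformed input raises a typed condition
#' (`tmahet_schema_error`, `tmahet_integrity_error`,
#' `tmahet_vocabulary_error` or `tmahet_validation_error`) listing every
#' offending row, and never returns a partially valid table.
#'
#' @param samples data.frame of per-core rows as described above.
#' @param genomic optional data.frame with `patient_id` and 0/1 columns
#'   named `gene_<GENE>` for genes in the schema's gene list.
#' @param schema a [schema_config()] object.
#' @param provenance optional list recorded as an attribute (source path,
#'   generator seed, ...).
#' @return a data.frame of class `"cohort_table"` with attributes
#'   `schema`, `genomic` and `provenance`.
#' @export
cohort_table <- function(samples, genomic = NULL, schema = schema_config(),
                         provenance = list()) {
  stopifnot(is.data.frame(samples))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  rownames(samples) <- NULL
  # canonicalise site spellings before validation
  if ("anatomic_site" %in% names(samples) && length(schema$site_aliases)) {
    al <- unlist(schema$site_aliases)
    hit <- samples$anatomic_site %in% names(al)
    samples$anatomic_site[hit] <- unname(al[samples$anatomic_site[hit]])
  }
  validate_cohort(samples, genomic, schema)
  structure(samples,
            class = c("cohort_table", "data.frame"),
            schema = schema, genomic = genomic,
            provenance = c(provenance,
                           list(schema_version = schema$schema_version)))
}

id_cols <- function() c("patient_id", "site_id", "block_id", "core_id")

# Columns carrying data for marker m, in the order they are written.
marker_cols <- function(m) {
  c(paste0(m, "_p0"), paste0(m, "_p1"), paste0(m, "_p2"), paste0(m, "_hscore"))
}

validate_cohort <- function(samples, genomic, schema) {
  cols <- names(samples)
  need <- c(id_cols(), "anatomic_site")
  missing_cols <- setdiff(need, cols)
  if (length(missing_cols)) {
    tma_stop("tmahet_schema_error",
             sprintf("missing mandatory column(s): %s",
                     paste(missing_cols, collapse = ", ")))
  }
  has_marker_col <- vapply(schema$markers, function(m) {
    any(marker_cols(m) %in% cols)
  }, logical(1))
  if (!any(has_marker_col)) {
    tma_stop("tmahet_schema_error",
             "no marker columns found (expected <marker>_hscore or <marker>_p0/_p1/_p2)")
  }

  n <- nrow(samples)
  if (n == 0) return(invisible(TRUE))

  bad <- function(rows, what, subclass) {
    if (length(rows)) {
      tma_stop(subclass,
               sprintf("%s (row%s %s)", what,
                       if (length(rows) > 1) "s" else "",
                       paste(rows, collapse = ", ")),
               rows = rows)
    }
  }

  for (cl in need) {
    v <- samples[[cl]]
    empty <- which(is.na(v) | !nzchar(as.character(v)))
    bad(empty, sprintf("empty value in `%s`", cl), "tmahet_validation_error")
  }

  unknown <- which(!samples$anatomic_site %in% schema$sites)
  if (length(unknown)) {
    vals <- unique(samples$anatomic_site[unknown])
    tma_stop("tmahet_vocabulary_error",
             sprintf("unknown anatomic site label(s): %s (rows %s)",
                     paste(shQuote(vals), collapse = ", "),
                     paste(unknown, collapse = ", ")),
             rows = unknown, values = vals)
  }

  key <- do.call(paste, c(samples[id_cols()], sep = "\r"))
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  bad(sort(unique(dup)),
      "duplicate (patient_id, site_id, block_id, core_id)",
      "tmahet_integrity_error")

  any_marker <- rep(FALSE, n)
  for (m in schema$markers) {
    hs_col <- paste0(m, "_hscore")
    fr_cols <- paste0(m, c("_p0", "_p1", "_p2"))
    if (hs_col %in% cols) {
      h <- samples[[hs_col]]
      if (!is.numeric(h)) {
        tma_stop("tmahet_schema_error",
                 sprintf("column `%s` is not numeric", hs_col))
      }
      out_of_range <- which(!is.na(h) & (h < 0 | h > 200))
      bad(out_of_range, sprintf("H-score outside [0, 200] in `%s`", hs_col),
          "tmahet_validation_error")
      any_marker <- any_marker | !is.na(h)
    }
    present_fr <- fr_cols[fr_cols %in% cols]
    if (length(present_fr) > 0 && length(present_fr) < 3) {
      tma_stop("tmahet_schema_error",
               sprintf("marker %s has fraction columns %s but not all of _p0/_p1/_p2",
                       m, paste(present_fr, collapse = ", ")))
    }
    if (length(present_fr) == 3) {
      fr <- samples[fr_cols]
      some <- rowSums(!is.na(fr)) > 0
      partial <- which(some & rowSums(!is.na(fr)) < 3)
      bad(partial, sprintf("incomplete staining fractions for %s", m),
          "tmahet_validation_error")
      full <- which(rowSums(!is.na(fr)) == 3)
      if (length(full)) {
        fr_full <- fr[full, , drop = FALSE]
        neg <- full[apply(fr_full < 0, 1, any) | apply(fr_full > 100, 1, any)]
        bad(neg, sprintf("staining fraction outside [0, 100] for %s", m),
            "tmahet_validation_error")
        off <- full[abs(rowSums(fr_full) - 100) > 1e-9]
        bad(off, sprintf("staining fractions for %s do not sum to 100", m),
            "tmahet_validation_error")
      }
      any_marker <- any_marker | some
    }
  }
  bad(which(!any_marker), "no marker measurement on row",
      "tmahet_validation_error")

  if ("subtype_label" %in% cols) {
    lab <- samples$subtype_label
    bad(which(!is.na(lab) & nzchar(lab) & !lab %in% tma_subtypes()),
        "subtype_label not one of the four canonical AR/NE labels",
        "tmahet_vocabulary_error")
  }

  if (!is.null(genomic)) {
    if (!"patient_id" %in% names(genomic)) {
      tma_stop("tmahet_schema_error", "genomic table lacks `patient_id`")
    }
    stray <- setdiff(genomic$patient_id, samples$patient_id)
    if (length(stray)) {
      tma_stop("tmahet_integrity_error",
               sprintf("genomic flags reference unknown patient(s): %s",
                       paste(stray, collapse = ", ")))
    }
    if (anyDuplicated(genomic$patient_id)) {
      tma_stop("tmahet_integrity_error",
               "duplicate patient_id in genomic flags table")
    }
    gcols <- setdiff(names(genomic), "patient_id")
    known <- paste0("gene_", schema$genes)
    if (length(setdiff(gcols, known))) {
      tma_stop("tmahet_vocabulary_error",
               sprintf("unknown gene column(s): %s",
                       paste(setdiff(gcols, known), collapse = ", ")))
    }
    for (g in gcols) {
      v <- genomic[[g]]
      if (!all(is.na(v) | v %in% c(0, 1))) {
        tma_stop("tmahet_validation_error",
                 sprintf("genomic flag `%s` has values other than 0/1", g))
      }
    }
  }
  invisible(TRUE)
}

#' Read a cohort from a delimited text file
#'
#' Reads the TSV/CSV interchange format (one row per TMA core; see
#' [cohort_table()] for the column contract). Patient-level genomic flags
#' are carried as wide columns `gene_<GENE>`, constant within a patient;
#' they are split off into the attached genomic table on read. Empty cells
#' are missing measurements ("not assessed") and are excluded from every
#' downstream denominator.
#'
#' @param path path to an existing file.
#' @param schema a [schema_config()]; also fixes the delimiter.
#' @return a validated [cohort_table()].
#' @export
read_cohort <- function(path, schema = schema_config()) {
  if (!file.exists(path)) {
    tma_stop("tmahet_io_error", sprintf("file not found: %s", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = schema$delimiter,
                          quote = "", comment.char = "", check.names = FALSE,
                          colClasses = "character", na.strings = "",
                          stringsAsFactors = FALSE)
  num_cols <- c(unlist(lapply(schema$markers, marker_cols)),
                paste0("gene_", schema$genes))
  for (cl in intersect(names(df), num_cols)) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (any(is.na(v) & !is.na(df[[cl]]))) {
      tma_stop("tmahet_schema_error",
               sprintf("non-numeric value in column `%s`", cl))
    }
    df[[cl]] <- v
  }

  gcols <- intersect(names(df), paste0("gene_", schema$genes))
  genomic <- NULL
  if (length(gcols)) {
    gen <- unique(df[c("patient_id", gcols)])
    if (anyDuplicated(gen$patient_id)) {
      p <- gen$patient_id[duplicated(gen$patient_id)]
      tma_stop("tmahet_integrity_error",
               sprintf("genomic flags differ across rows of patient(s): %s",
                       paste(unique(p), collapse = ", ")))
    }
    keep <- rowSums(!is.na(gen[gcols])) > 0
    # patients with all-missing flags simply have no genomic record
    genomic <- gen[keep, , drop = FALSE]
    rownames(genomic) <- NULL
    if (nrow(genomic) == 0) genomic <- NULL
    df <- df[setdiff(names(df), gcols)]
  }
  cohort_table(df, genomic = genomic, schema = schema,
               provenance = list(source = path))
}

#' Write a cohort to its delimited interchange format
#'
#' Writes columns in a fixed canonical order (identifiers, site, subtype
#' label, marker columns in schema order, then genomic flag columns), so
#' the output is byte-stable for a given cohort, and
#' `read_cohort(write_cohort(x))` reproduces `x` field for field.
#'
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  schema <- attr(cohort, "schema")
  df <- as.data.frame(cohort, stringsAsFactors = FALSE)
  ordered <- c(id_cols(), "anatomic_site",
               intersect("subtype_label", names(df)),
               unlist(lapply(schema$markers,
                             function(m) intersect(marker_cols(m), names(df)))))
  extra <- setdiff(names(df), ordered)
  out <- df[c(ordered, extra)]

  genomic <- attr(cohort, "genomic")
  if (!is.null(genomic) && nrow(genomic) > 0) {
    gcols <- intersect(paste0("gene_", schema$genes), names(genomic))
    idx <- match(out$patient_id, genomic$patient_id)
    for (g in gcols) out[[g]] <- genomic[[g]][idx]
  }

  num <- vapply(out, is.numeric, logical(1))
  for (cl in names(out)[num]) out[[cl]] <- fmt_num(out[[cl]])
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    tma_stop("tmahet_io_error", sprintf("directory does not exist: %s", dir))
  }
  utils::write.table(out, path, sep = schema$delimiter, quote = FALSE,
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  schema <- attr(x, "schema")
  measured <- vapply(schema$markers, function(m) {
    any(!is.na(marker_hscore(x, m, compute = FALSE)))
  }, logical(1))
  cat(sprintf("<cohort_table> %d samples / %d sites / %d patients\n",
              nrow(x),
              nrow(unique(x[c("patient_id", "site_id")])),
              length(unique(x$patient_id))))
  cat("  markers measured:",
      paste(schema$markers[measured], collapse = ", "), "\n")
  gen <- attr(x, "genomic")
  if (!is.null(gen)) {
    cat(sprintf("  genomic flags: %d patients x %d genes\n",
                nrow(gen), length(setdiff(names(gen), "patient_id"))))
  }
  invisible(x)
}

#' @export
summary.cohort_table <- function(object, ...) {
  schema <- attr(object, "schema")
  per_marker <- lapply(schema$markers, function(m) {
    h <- marker_hscore(object, m, compute = TRUE)
    c(n = sum(!is.na(h)),
      median = if (any(!is.na(h))) stats::median(h, na.rm = TRUE) else NA_real_,
      pct_pos = if (any(!is.na(h))) {
        100 * mean(h >= schema$threshold, na.rm = TRUE)
      } else NA_real_)
  })
  out <- do.call(rbind, per_marker)
  rownames(out) <- schema$markers
  out
}

# H-scores for one marker, one value per row of the cohort. With
# compute = TRUE, rows lacking a precomputed H-score fall back to the
# staining-fraction formula.
marker_hscore <- function(cohort, marker, compute = TRUE) {
  n <- nrow(cohort)
  hs_col <- paste0(marker, "_hscore")
  h <- if (hs_col %in% names(cohort)) as.numeric(cohort[[hs_col]]) else rep(NA_real_, n)
  if (compute) {
    fr_cols <- paste0(marker, c("_p0", "_p1", "_p2"))
    if (all(fr_cols %in% names(cohort))) {
      have <- is.na(h) & !is.na(cohort[[fr_cols[1]]])
      if (any(have)) {
        h[have] <- compute_hscore(cohort[[fr_cols[1]]][have],
                                  cohort[[fr_cols[2]]][have],
                                  cohort[[fr_cols[3]]][have])
      }
    }
  }
  h
}

# Globally unique block key (block_id is only unique within a site).
block_key <- function(cohort) {
  paste(cohort$patient_id, cohort$site_id, cohort$block_id, sep = "\r")
}

#' Patient-level genomic alteration flags of a cohort
#'
#' @param cohort a [cohort_table()].
#' @return the attached genomic data.frame, or `NULL` when the cohort
#'   carries no genomic flags.
#' @export
genomic_flags <- function(cohort) attr(cohort, "genomic")
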