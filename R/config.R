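#' Default cohort schema configuration
#'
#' The schema configuration fixes the controlled vocabularies and thresholds
#' every stage of the pipeline shares: the marker panel, the closed list of
#' 11 anatomic-site labels, the gene list for genomic alteration flags, the
#' H-score positivity threshold, and the file delimiter. Site labels in
#' incoming files can be remapped to the canonical vocabulary through
#' `site_aliases` (a named list: nonstandard spelling -> canonical label).
#'
#' @param markers character vector of marker names expected in cohort files.
#' @param sites character vector: closed anatomic-site vocabulary.
#' @param genes character vector of genes for patient-level alteration flags.
#' @param threshold H-score positivity cut-off; a sample is positive when its
#'   H-score is greater than or equal to this value. Default 20.
#' @param delimiter field delimiter of the interchange format: `"\t"`
#'   (default) or `","`.
#' @param site_aliases named list mapping nonstandard site spellings to
#'   canonical labels; empty by default.
#' @return a list of class `"tma_schema"`.
#' @seealso [read_cohort()], [write_cohort()]
#' @export
schema_config <- function(markers = c("TROP2", "PSMA", "DLL3", "CEACAM5",
                                      "AR", "NKX3.1", "SYP", "INSM1"),
                          sites = tma_sites(),
                          genes = c("AR", "BRCA2", "CHD1", "PTEN", "RB1",
                                    "SPOP", "TP53"),
                          threshold = 20,
                          delimiter = "\t",
                          site_aliases = list()) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    tma_stop("tmahet_config_error", "`threshold` must be a single non-negative number")
  }
  if (!delimiter %in% c("\t", ",")) {
    tma_stop("tmahet_config_error", "`delimiter` must be tab or comma")
  }
  if (anyDuplicated(markers) || anyDuplicated(sites) || anyDuplicated(genes)) {
    tma_stop("tmahet_config_error", "markers, sites and genes must be free of duplicates")
  }
  structure(
    list(markers = markers, sites = sites, genes = genes,
         threshold = threshold, delimiter = delimiter,
         site_aliases = site_aliases, schema_version = "1"),
    class = "tma_schema"
  )
}

#' Canonical anatomic-site vocabulary
#'
#' The 11 major metastatic-site categories used throughout the package.
#' Bone is split into vertebral and other bone because vertebral bone is the
#' reference site of the anatomic contrast models.
#'
#' @return character vector of 11 site labels.
#' @export
tma_sites <- function() {
  c("vertebral bone", "other bone", "liver", "lung", "lymph node",
    "prostate/prostate bed", "adrenal", "dura",
    "pelvic soft tissue", "abdominal soft tissue", "other soft tissue")
}

#' The four AR/NE molecular subtype labels
#'
#' Canonical strings for the four-quadrant CRPC classification by androgen
#' receptor axis (AR, NKX3.1) and neuroendocrine (SYP, INSM1) marker
#' expression: adenocarcinoma (AR+/NE-), neuroendocrine prostate cancer
#' (AR-/NE+), amphicrine (AR+/NE+) and double-negative (AR-/NE-).
#'
#' @return character vector of 4 subtype labels.
#' @export
tma_subtypes <- function() {
  c("AR+/NE-", "AR-/NE+", "AR+/NE+", "AR-/NE-")
}

#' Read or write a schema configuration as YAML
#'
#' @param path file path.
#' @return `read_schema_config()` returns a `"tma_schema"`;
#'   `write_schema_config()` returns `path` invisibly.
#' @rdname schema_yaml
#' @export
read_schema_config <- function(path) {
  if (!file.exists(path)) {
    tma_stop("tmahet_config_error", sprintf("config file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  delim <- raw$delimiter %||% "tab"
  schema_config(
    markers = as.character(raw$markers %||% schema_config()$markers),
    sites = as.character(raw$sites %||% tma_sites()),
    genes = as.character(raw$genes %||% schema_config()$genes),
    threshold = as.numeric(raw$threshold %||% 20),
    delimiter = if (identical(delim, "comma")) "," else "\t",
    site_aliases = raw$site_aliases %||% list()
  )
}

#' @param config a `"tma_schema"` object.
#' @rdname schema_yaml
#' @export
write_schema_config <- function(config, path) {
  stopifnot(inherits(config, "tma_schema"))
  out <- unclass(config)
  out$delimiter <- if (identical(config$delimiter, ",")) "comma" else "tab"
  yaml::write_yaml(out, path)
  invisible(path)
}
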