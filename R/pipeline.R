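#' Run the full analysis pipeline on a cohort file
#'
#' Orchestrates scoring -> subtyping -> co-expression -> patient
#' classification -> heterogeneity -> association over a cohort, writing
#' tidy TSV outputs per stage plus a JSON run manifest (tool version,
#' input hash, seed, per-stage status and output paths). Re-running with
#' the same inputs and seed reproduces byte-identical statistical outputs.
#'
#' Stages degrade gracefully where the data demand it: the association
#' stage is skipped with a notice when the cohort carries no genomic
#' flags, and marker/scope combinations without eligible pairs are dropped
#' from the heterogeneity table. Any hard stage failure aborts with the
#' stage name; stages already written remain on disk and the manifest
#' marks the run incomplete.
#'
#' @param cohort_path path to a cohort TSV (see [read_cohort()]), or a
#'   [cohort_table()] directly.
#' @param out_dir output directory (created if needed).
#' @param schema a [schema_config()].
#' @param seed integer seed for the bootstrap stage.
#' @param markers markers analysed in the co-expression, patient-class and
#'   heterogeneity stages; default: the surface-target panel intersected
#'   with measured markers.
#' @param coexpression_pairs list of 2-vectors of marker names; default
#'   `list(c("TROP2","PSMA"), c("DLL3","CEACAM5"))`.
#' @param n_pairs,n_boot bootstrap sizes (see [heterogeneity_bootstrap()]).
#' @param verbose print stage progress.
#' @return the run manifest (list), invisibly; written as
#'   `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(cohort_path, out_dir,
                         schema = schema_config(), seed = 1,
                         markers = NULL,
                         coexpression_pairs = list(c("TROP2", "PSMA"),
                                                   c("DLL3", "CEACAM5")),
                         n_pairs = 1000, n_boot = 1000,
                         verbose = TRUE) {
  t0 <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  manifest <- list(
    tool = "tmahet",
    version = as.character(utils::packageVersion("tmahet")),
    seed = seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    complete = FALSE,
    stages = list()
  )
  stage_path <- function(name) file.path(out_dir, paste0(name, ".tsv"))
  write_stage <- function(name, df) {
    p <- stage_path(name)
    num <- vapply(df, is.numeric, logical(1))
    out <- df
    for (cl in names(out)[num]) out[[cl]] <- fmt_num(out[[cl]])
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "", fileEncoding = "UTF-8")
    manifest$stages[[name]] <<- list(status = "ok", path = p,
                                     md5 = unname(tools::md5sum(p)))
    p
  }
  run_stage <- function(name, code) {
    say("stage %s ...", name)
    tryCatch(code, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      manifest$complete <<- FALSE
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      tma_stop("tmahet_pipeline_error",
               sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  # ingest
  cohort <- run_stage("ingest", {
    if (inherits(cohort_path, "cohort_table")) {
      manifest$input <- list(source = "in-memory cohort_table")
      cohort_path
    } else {
      manifest$input <- list(source = cohort_path,
                              md5 = unname(tools::md5sum(cohort_path)))
      read_cohort(cohort_path, schema = schema)
    }
  })
  schema <- attr(cohort, "schema")

  cohort <- run_stage("scoring", score_cohort(cohort))
  measured <- schema$markers[vapply(schema$markers, function(m) {
    any(!is.na(marker_hscore(cohort, m)))
  }, logical(1))]
  if (is.null(markers)) {
    markers <- intersect(c("TROP2", "PSMA", "DLL3", "CEACAM5"), measured)
  }

  blocks <- run_stage("subtyping", {
    b <- subtype_blocks(cohort)
    write_stage("subtypes", b)
    b
  })

  run_stage("coexpression", {
    tabs <- list()
    for (pr in coexpression_pairs) {
      if (!all(pr %in% measured)) next
      tab <- tryCatch(
        tabulate_coexpression(cohort, pr[1], pr[2], threshold = schema$threshold),
        tmahet_empty_stratum_error = function(e) NULL)
      if (is.null(tab)) next
      tabs[[length(tabs) + 1]] <- data.frame(
        marker_a = tab$marker_a, marker_b = tab$marker_b,
        stratum = tab$stratum, unit = tab$unit,
        cell = names(tab$counts), count = as.integer(tab$counts),
        total = tab$total, percentage = unname(tab$percentages),
        stringsAsFactors = FALSE)
    }
    if (length(tabs)) write_stage("coexpression", do.call(rbind, tabs))
    else manifest$stages[["coexpression"]] <- list(status = "skipped",
                                                    reason = "no evaluable marker pair")
  })

  run_stage("patient_classes", {
    cls <- list()
    for (m in markers) {
      pc <- tryCatch(classify_patients(cohort, m, threshold = schema$threshold),
                     tmahet_not_evaluable_error = function(e) NULL)
      if (is.null(pc)) next
      s <- attr(pc, "summary")
      s$marker <- m
      s$n_excluded <- length(attr(pc, "excluded"))
      cls[[length(cls) + 1]] <- s[c("marker", "class", "n", "total",
                                    "percentage", "n_excluded")]
    }
    if (length(cls)) write_stage("patient_classes", do.call(rbind, cls))
    else manifest$stages[["patient_classes"]] <- list(status = "skipped",
                                                       reason = "no evaluable marker")
  })

  run_stage("heterogeneity", {
    het <- tryCatch(
      heterogeneity_table(cohort, markers = markers,
                          threshold = schema$threshold, seed = seed,
                          n_pairs = n_pairs, n_boot = n_boot),
      tmahet_empty_pool_error = function(e) NULL)
    if (is.null(het)) {
      manifest$stages[["heterogeneity"]] <- list(status = "skipped",
                                                  reason = "no eligible pairs")
    } else write_stage("heterogeneity", het)
  })

  if (is.null(genomic_flags(cohort))) {
    say("stage association skipped: cohort has no genomic flags")
    manifest$stages[["association"]] <- list(status = "skipped",
                                             reason = "no genomic flags")
  } else {
    run_stage("association", {
      gen <- genomic_flags(cohort)
      genes <- sub("^gene_", "", setdiff(names(gen), "patient_id"))
      rows <- list()
      for (m in markers) {
        ctr <- tryCatch(site_mixed_model(cohort, m),
                        tmahet_error = function(e) NULL)
        if (!is.null(ctr)) {
          ctr2 <- as.data.frame(ctr)
          ctr2$marker <- m
          ctr2$term <- paste0("site:", ctr2$site)
          rows[[length(rows) + 1]] <- data.frame(
            model = "site_mixed_model", marker = m, term = ctr2$term,
            estimate = ctr2$mean_difference, ci_low = ctr2$ci_low,
            ci_high = ctr2$ci_high, p_value = ctr2$p_value, n = ctr2$n,
            flag = ifelse(ctr2$wide_ci, "wide_ci",
                          ifelse(attr(ctr, "singular"), "singular", "")),
            stringsAsFactors = FALSE)
        }
        for (g in genes) {
          as_ <- tryCatch(genomic_logistic(cohort, m, g,
                                           threshold = schema$threshold),
                          tmahet_error = function(e) NULL)
          if (is.null(as_)) next
          rows[[length(rows) + 1]] <- data.frame(
            model = "genomic_logistic", marker = m,
            term = paste0("gene:", g), estimate = as_$odds_ratio,
            ci_low = as_$ci_low, ci_high = as_$ci_high,
            p_value = as_$p_value, n = as_$n_altered + as_$n_wildtype,
            flag = if (as_$separation) "separation" else "",
            stringsAsFactors = FALSE)
        }
      }
      if (length(rows)) write_stage("association", do.call(rbind, rows))
      else manifest$stages[["association"]] <- list(status = "skipped",
                                                     reason = "no estimable model")
    })
  }

  manifest$complete <- TRUE
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("pipeline complete: %s", out_dir)
  invisible(manifest)
}
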