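# Fixture builders shared across the suite. All cohorts are built in code;
# nothing is read from disk except files the tests themselves write.

# Minimal single-marker cohort from explicit H-scores. `block` and `patient`
# control the grouping used by the pair-pool machinery.
toy_cohort <- function(h, patient = "P1", site = NULL, block = "B1",
                       marker = "M", anatomic_site = "liver",
                       extra = NULL) {
  n <- length(h)
  patient <- rep_len(patient, n)
  site <- if (is.null(site)) rep("S1", n) else rep_len(site, n)
  block <- rep_len(block, n)
  df <- data.frame(
    patient_id = patient, site_id = site, block_id = block,
    core_id = make.unique(rep("C", n), sep = ""),
    anatomic_site = rep_len(anatomic_site, n),
    stringsAsFactors = FALSE)
  df[[paste0(marker, "_hscore")]] <- h
  if (!is.null(extra)) df <- cbind(df, extra)
  if (anyNA(h)) df$AR_hscore <- 0  # keep not-assessed rows schema-valid
  cohort_table(df, schema = schema_config(markers = unique(c(
    marker, sub("_hscore$", "", grep("_hscore$", names(df), value = TRUE))))))
}

# Cohort of independent single-core blocks carrying one marker per pattern:
# statuses is a logical vector; one block of length(statuses) cores when
# one_block = TRUE, else one block per status.
status_cohort <- function(statuses, one_block = TRUE) {
  toy_cohort(ifelse(statuses, 100, 0),
             site = if (one_block) "S1" else sprintf("S%03d", seq_along(statuses)),
             block = "B1")
}

# Two-marker core-level cohort realising given joint binarized counts
# (both, a_only, b_only, neither), for contingency worked examples.
joint_cohort <- function(both, a_only, b_only, neither,
                         marker_a = "TROP2", marker_b = "PSMA",
                         subtype_label = NULL) {
  n <- both + a_only + b_only + neither
  a <- c(rep(100, both + a_only), rep(0, b_only + neither))
  b <- c(rep(100, both), rep(0, a_only), rep(100, b_only), rep(0, neither))
  df <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    site_id = "S1", block_id = "B1", core_id = "C1",
    anatomic_site = "liver", stringsAsFactors = FALSE)
  df[[paste0(marker_a, "_hscore")]] <- a
  df[[paste0(marker_b, "_hscore")]] <- b
  if (!is.null(subtype_label)) df$subtype_label <- subtype_label
  cohort_table(df, schema = schema_config(markers = c(marker_a, marker_b)))
}

# Patient-classification fixture: named list patient -> site H-score vector.
patient_cohort <- function(sites_by_patient, marker = "DLL3") {
  rows <- lapply(names(sites_by_patient), function(p) {
    h <- sites_by_patient[[p]]
    df <- data.frame(
      patient_id = p, site_id = sprintf("S%02d", seq_along(h)),
      block_id = "B1", core_id = "C1", anatomic_site = "liver",
      stringsAsFactors = FALSE)
    df[[paste0(marker, "_hscore")]] <- h
    df$AR_hscore <- 0  # filler so not-assessed rows stay schema-valid
    df
  })
  cohort_table(do.call(rbind, rows),
               schema = schema_config(markers = c(marker, "AR")))
}

# Small generator configuration for fast simulation-based tests.
small_config <- function(...) {
  generator_config(n_patients = 12, mean_sites = 4, ...)
}
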