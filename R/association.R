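#' Anatomic-site contrasts from a patient random-intercept linear model
#'
#' Fits `hscore ~ anatomic_site + (1 | patient_id)` by REML and reports
#' each site's mean H-score difference against the reference site
#' (default: vertebral bone) with Wald 95% confidence limits and two-sided
#' normal p-values. Repeated sampling of the same patient across sites is
#' absorbed by the random intercept. A random-effect variance estimated at
#' (or numerically near) zero is legitimate and reported through the
#' `singular` attribute; in that limit the fixed-effect estimates coincide
#' with ordinary least squares on the same design.
#'
#' @param cohort a [cohort_table()].
#' @param marker marker whose H-score is modelled.
#' @param reference_site reference level of the site factor.
#' @param level confidence level (default 0.95).
#' @return data.frame of class `"site_contrasts"`, one row per site
#'   (the reference row has `mean_difference` 0 and no test), columns
#'   `site`, `n`, `mean_difference`, `ci_low`, `ci_high`, `p_value`,
#'   `wide_ci` (flag for sites represented by a single sample).
#'   Attributes: `marker`, `reference_site`, `reference_mean` (with its CI),
#'   `singular`, `patient_sd`, `residual_sd`.
#' @export
site_mixed_model <- function(cohort, marker, reference_site = "vertebral bone",
                             level = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"))
  h <- marker_hscore(cohort, marker)
  keep <- !is.na(h)
  dat <- data.frame(h = h[keep],
                    site = cohort$anatomic_site[keep],
                    patient = cohort$patient_id[keep],
                    stringsAsFactors = FALSE)
  sites <- unique(dat$site)
  if (length(sites) < 2) {
    tma_stop("tmahet_degenerate_error",
             sprintf("only %d site(s) with %s data: no contrast estimable",
                     length(sites), marker))
  }
  if (length(unique(dat$patient)) < 2) {
    tma_stop("tmahet_degenerate_error", "need >= 2 patients")
  }
  if (!reference_site %in% sites) {
    tma_stop("tmahet_config_error",
             sprintf("reference site %s has no %s data", shQuote(reference_site),
                     marker))
  }
  dat$site <- stats::relevel(factor(dat$site), ref = reference_site)

  fit <- tryCatch(
    lme4::lmer(h ~ site + (1 | patient), data = dat, REML = TRUE),
    error = function(e) {
      tma_stop("tmahet_fit_error",
               sprintf("mixed model for %s failed to fit: %s", marker,
                       conditionMessage(e)))
    })
  singular <- lme4::isSingular(fit)

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  site_levels <- levels(dat$site)
  n_by_site <- table(dat$site)

  ref_mean <- unname(beta["(Intercept)"])
  ref_se <- unname(se["(Intercept)"])

  rows <- lapply(site_levels, function(s) {
    if (s == reference_site) {
      data.frame(site = s, n = as.integer(n_by_site[s]),
                 mean_difference = 0, ci_low = 0, ci_high = 0,
                 p_value = NA_real_, wide_ci = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      term <- paste0("site", s)
      est <- unname(beta[term]); s_e <- unname(se[term])
      data.frame(site = s, n = as.integer(n_by_site[s]),
                 mean_difference = est,
                 ci_low = est - zq * s_e, ci_high = est + zq * s_e,
                 p_value = 2 * stats::pnorm(-abs(est / s_e)),
                 wide_ci = n_by_site[s] < 2,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(out,
            class = c("site_contrasts", "data.frame"),
            marker = marker, reference_site = reference_site,
            reference_mean = c(mean = ref_mean,
                               ci_low = ref_mean - zq * ref_se,
                               ci_high = ref_mean + zq * ref_se),
            singular = singular,
            patient_sd = vc$sdcor[vc$grp == "patient"],
            residual_sd = vc$sdcor[vc$grp == "Residual"],
            level = level)
}

#' @export
print.site_contrasts <- function(x, ...) {
  rm <- attr(x, "reference_mean")
  cat(sprintf("<site_contrasts> %s vs %s (mean H-score %0.4g, CI %0.4g to %0.4g)%s\n",
              attr(x, "marker"), attr(x, "reference_site"),
              rm["mean"], rm["ci_low"], rm["ci_high"],
              if (attr(x, "singular")) " [singular fit: patient variance ~ 0]" else ""))
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Genomic-alteration association by random-intercept logistic regression
#'
#' Regresses binarized marker expression on a patient-level genomic
#' alteration flag and reports the odds ratio with Wald 95% limits. Two
#' analysis units are supported. `unit = "patient"` (default) collapses
#' each patient's expression to any-site positivity and fits an ordinary
#' logistic regression (one observation per patient needs no random
#' effect). `unit = "sample"` keeps every sample and fits a patient
#' random-intercept logistic model (`lme4::glmer`); if each patient happens
#' to contribute a single sample the model reduces identically to ordinary
#' logistic regression, which is then used directly.
#'
#' For protein data the dichotomization is H-score >= `threshold`; an
#' expression table in transcript mode (a data.frame with `patient_id`,
#' an FPKM column named after the marker, and `gene_<GENE>` flags) is
#' dichotomized at `fpkm_threshold` (expressed iff FPKM >= 1 by default).
#'
#' Complete separation (an empty cell of the collapsed 2x2 table) is
#' reported through the `separation` flag with the unstable estimate
#' attached, never silently.
#'
#' @param x a [cohort_table()] (protein mode) or a plain data.frame
#'   (transcript mode, see Details).
#' @param marker marker (protein) or transcript column name.
#' @param gene gene whose `gene_<gene>` flag is the exposure.
#' @param unit `"patient"` or `"sample"` (protein mode only).
#' @param threshold H-score positivity cut-off (protein mode).
#' @param fpkm_threshold transcript positivity cut-off (transcript mode).
#' @param level confidence level.
#' @return object of class `"genomic_assoc"`: list with `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `n_altered`, `n_wildtype`, `counts`
#'   (2x2 table), `separation`, `convergence_warnings` (captured `glmer`
#'   diagnostics, empty when clean), `engine`, `dichotomization`.
#' @export
genomic_logistic <- function(x, marker, gene,
                             unit = c("patient", "sample"),
                             threshold = 20, fpkm_threshold = 1,
                             level = 0.95) {
  unit <- match.arg(unit)
  gcol <- paste0("gene_", gene)

  if (inherits(x, "cohort_table")) {
    gen <- genomic_flags(x)
    if (is.null(gen) || !gcol %in% names(gen)) {
      tma_stop("tmahet_schema_error",
               sprintf("cohort has no genomic flag for %s", gene))
    }
    h <- marker_hscore(x, marker)
    keep <- !is.na(h)
    d <- data.frame(patient = x$patient_id[keep], y = h[keep] >= threshold,
                    stringsAsFactors = FALSE)
    d$g <- gen[[gcol]][match(d$patient, gen$patient_id)]
    d <- d[!is.na(d$g), , drop = FALSE]
    if (unit == "patient") {
      y <- tapply(d$y, d$patient, any)
      g <- tapply(d$g, d$patient, function(v) v[1])
      d <- data.frame(patient = names(y), y = as.logical(y), g = as.numeric(g),
                      stringsAsFactors = FALSE)
    }
    dich <- sprintf("H-score >= %g (%s level%s)", threshold, unit,
                    if (unit == "patient") ", any-site positivity" else "")
  } else {
    stopifnot(is.data.frame(x), "patient_id" %in% names(x))
    if (!marker %in% names(x) || !gcol %in% names(x)) {
      tma_stop("tmahet_schema_error",
               sprintf("expression table lacks column `%s` or `%s`", marker, gcol))
    }
    keep <- !is.na(x[[marker]]) & !is.na(x[[gcol]])
    d <- data.frame(patient = x$patient_id[keep],
                    y = x[[marker]][keep] >= fpkm_threshold,
                    g = as.numeric(x[[gcol]][keep]),
                    stringsAsFactors = FALSE)
    unit <- "patient"
    dich <- sprintf("FPKM >= %g", fpkm_threshold)
  }

  if (!nrow(d)) {
    tma_stop("tmahet_degenerate_error", "no evaluable observations")
  }
  if (length(unique(d$g)) < 2) {
    tma_stop("tmahet_degenerate_error",
             sprintf("only one %s class present: association not estimable", gene))
  }
  if (length(unique(d$y)) < 2) {
    tma_stop("tmahet_degenerate_error",
             "single-class outcome: association not estimable")
  }

  counts <- table(altered = factor(d$g, levels = c(0, 1)),
                  expressed = factor(d$y, levels = c(FALSE, TRUE)))
  separation <- any(counts == 0)

  fit_warnings <- character(0)
  one_per_patient <- !anyDuplicated(d$patient)
  if (unit == "sample" && !one_per_patient) {
    fit <- withCallingHandlers(
      suppressMessages(
        lme4::glmer(y ~ g + (1 | patient), data = d,
                    family = stats::binomial())),
      warning = function(w) {
        fit_warnings <<- c(fit_warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    beta <- lme4::fixef(fit)["g"]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))["g"]
    engine <- "glmer (patient random intercept)"
  } else {
    fit <- suppressWarnings(
      stats::glm(y ~ g, data = d, family = stats::binomial()))
    beta <- stats::coef(fit)["g"]
    se <- sqrt(diag(stats::vcov(fit)))["g"]
    engine <- "glm (one observation per patient)"
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(
    list(marker = marker, gene = gene,
         odds_ratio = unname(exp(beta)),
         ci_low = unname(exp(beta - zq * se)),
         ci_high = unname(exp(beta + zq * se)),
         p_value = unname(2 * stats::pnorm(-abs(beta / se))),
         log_or = unname(beta), se = unname(se),
         n_altered = sum(d$g == 1), n_wildtype = sum(d$g == 0),
         counts = counts, separation = separation,
         convergence_warnings = fit_warnings,
         unit = unit, engine = engine, dichotomization = dich,
         level = level),
    class = "genomic_assoc"
  )
}

#' @export
print.genomic_assoc <- function(x, ...) {
  cat(sprintf("<genomic_assoc> %s expression ~ %s alteration (%s)\n",
              x$marker, x$gene, x$dichotomization))
  cat(sprintf("  OR %.3g (%g%% CI %.3g to %.3g); p = %.3g; n = %d altered / %d wild-type%s\n",
              x$odds_ratio, 100 * x$level, x$ci_low, x$ci_high, x$p_value,
              x$n_altered, x$n_wildtype,
              if (x$separation) " [complete separation: estimate unstable]" else ""))
  if (length(x$convergence_warnings)) {
    cat("  [fit warnings:",
        paste(unique(x$convergence_warnings), collapse = "; "), "]\n")
  }
  invisible(x)
}
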