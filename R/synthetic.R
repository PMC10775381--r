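#' Configuration of the synthetic cohort generator
#'
#' The generator emulates a rapid-autopsy TMA cohort: patients carrying
#' several metastatic sites (one tumor block per site, 1-4 cores per
#' block), a dominant molecular subtype per patient with a per-block
#' switching probability (mixed-subtype patients), subtype-conditional
#' marker H-score distributions with point masses at 0 and 200 and skewed
#' interiors, additive anatomic-site shifts, patient- and core-level
#' Gaussian variation, and patient-level genomic alterations whose
#' prevalence depends on subtype and whose configured log-odds effects act
#' on marker positivity.
#'
#' Default sizes reproduce the shape of a 52-patient cohort with ~372
#' sites and ~753 samples; default location anchors put the marker medians
#' at their published subtype values (e.g. TROP2 ~200 in AR+/NE- and ~0 in
#' AR-/NE+ tumors, DLL3 ~90 and CEACAM5 ~60 in AR-/NE+, PSMA ~120 in
#' AR+/NE- and ~12 in AR-/NE-). Dispersion, mixing and effect-size
#' defaults are the package's own calibration choices (see the methods
#' vignette).
#'
#' @param n_patients number of patients (default 52).
#' @param mean_sites mean of the (zero-truncated) Poisson number of
#'   metastatic sites per patient; default 372/52.
#' @param cores_probs probabilities of 1..4 cores per block; the default
#'   gives ~2.02 expected cores, hence ~753 samples.
#' @param subtype_probs named probabilities of the patient's dominant
#'   subtype over [tma_subtypes()].
#' @param switch_prob probability that a block departs from its patient's
#'   dominant subtype.
#' @param site_probs named probabilities over [tma_sites()].
#' @param marker_model nested list `marker -> subtype -> parameters`
#'   (`p_pos`, `w_zero`, `w_max`, `a_pos`, `b_pos`); see
#'   [default_marker_model()].
#' @param site_effects list `marker -> named numeric` of additive H-score
#'   shifts by anatomic site.
#' @param patient_sd,core_sd standard deviations (H-score units) of the
#'   patient-level shift and the core-level measurement noise.
#' @param patient_logit_sd standard deviation of the patient-level random
#'   effect on the positivity log-odds, shared by all blocks of a patient;
#'   this carries the within-patient correlation of marker positivity that
#'   keeps inter-tumoral discordance realistic.
#' @param core_flip probability that a core is redrawn independently from
#'   its block's marker distribution (intra-tumoral discordance source).
#' @param genomic_prevalence list `gene -> named numeric by subtype` (or a
#'   single number) giving the alteration probability conditional on the
#'   patient's dominant subtype.
#' @param genomic_effects list `gene -> named numeric by marker` of
#'   log-odds effects of the alteration on marker positivity.
#' @param threshold positivity cut-off recorded in the ground truth.
#' @param seed default integer seed used by [generate_cohort()].
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(n_patients = 52,
                             mean_sites = 372 / 52,
                             cores_probs = c(0.33, 0.38, 0.22, 0.07),
                             subtype_probs = c("AR+/NE-" = 0.55,
                                               "AR-/NE+" = 0.18,
                                               "AR+/NE+" = 0.12,
                                               "AR-/NE-" = 0.15),
                             switch_prob = 0.03,
                             site_probs = default_site_probs(),
                             marker_model = default_marker_model(),
                             site_effects = default_site_effects(),
                             patient_sd = 10, core_sd = 8, core_flip = 0.05,
                             patient_logit_sd = 2,
                             genomic_prevalence = default_genomic_prevalence(),
                             genomic_effects = default_genomic_effects(),
                             threshold = 20, seed = NULL) {
  if (n_patients < 1) tma_stop("tmahet_config_error", "`n_patients` must be >= 1")
  if (mean_sites <= 0) tma_stop("tmahet_config_error", "`mean_sites` must be > 0")
  if (abs(sum(cores_probs) - 1) > 1e-8 || any(cores_probs < 0)) {
    tma_stop("tmahet_config_error", "`cores_probs` must be a probability vector")
  }
  if (!setequal(names(subtype_probs), tma_subtypes()) ||
      abs(sum(subtype_probs) - 1) > 1e-8 || any(subtype_probs < 0)) {
    tma_stop("tmahet_config_error",
             "`subtype_probs` must be probabilities over the four subtypes")
  }
  if (abs(sum(site_probs) - 1) > 1e-8 ||
      length(setdiff(names(site_probs), tma_sites()))) {
    tma_stop("tmahet_config_error",
             "`site_probs` must be probabilities over the site vocabulary")
  }
  if (switch_prob < 0 || switch_prob > 1 || core_flip < 0 || core_flip > 1) {
    tma_stop("tmahet_config_error", "probabilities must lie in [0, 1]")
  }
  for (m in names(marker_model)) {
    for (s in names(marker_model[[m]])) {
      p <- marker_model[[m]][[s]]
      if (any(p[c("p_pos", "w_zero", "w_max")] < 0) ||
          any(p[c("p_pos", "w_zero", "w_max")] > 1)) {
        tma_stop("tmahet_config_error",
                 sprintf("marker model probabilities out of [0,1] for %s/%s", m, s))
      }
    }
  }
  structure(
    list(n_patients = n_patients, mean_sites = mean_sites,
         cores_probs = cores_probs, subtype_probs = subtype_probs,
         switch_prob = switch_prob, site_probs = site_probs,
         marker_model = marker_model, site_effects = site_effects,
         patient_sd = patient_sd, core_sd = core_sd, core_flip = core_flip,
         patient_logit_sd = patient_logit_sd,
         genomic_prevalence = genomic_prevalence,
         genomic_effects = genomic_effects,
         threshold = threshold, seed = seed),
    class = "generator_config"
  )
}

#' @rdname generator_config
#' @export
default_site_probs <- function() {
  c("vertebral bone" = 0.20, "other bone" = 0.25, "liver" = 0.15,
    "lymph node" = 0.15, "lung" = 0.07, "prostate/prostate bed" = 0.05,
    "adrenal" = 0.04, "dura" = 0.02, "pelvic soft tissue" = 0.03,
    "abdominal soft tissue" = 0.02, "other soft tissue" = 0.02)
}

# One cell of the marker model: probability of positivity (H >= 20), the
# point-mass weights at 0 (within negatives) and 200 (within positives),
# and the Beta shape of the positive interior (scaled to [20, 200]).
mm_cell <- function(p_pos, w_zero = 0.85, w_max = 0, a_pos = 2, b_pos = 2) {
  c(p_pos = p_pos, w_zero = w_zero, w_max = w_max, a_pos = a_pos, b_pos = b_pos)
}

#' Default subtype-conditional marker distributions
#'
#' Positivity rates and value distributions per marker and AR/NE subtype,
#' anchored so that simulated medians land near the published
#' subtype-specific medians (see [generator_config()]).
#'
#' @return nested list `marker -> subtype -> parameter vector`.
#' @export
default_marker_model <- function() {
  adeno <- "AR+/NE-"; nepc <- "AR-/NE+"; amph <- "AR+/NE+"; dn <- "AR-/NE-"
  list(
    TROP2 = stats::setNames(list(
      mm_cell(0.99, w_max = 0.60, a_pos = 3.0, b_pos = 1.0),
      mm_cell(0.25, w_zero = 0.85, w_max = 0.05, a_pos = 1.5, b_pos = 1.5),
      mm_cell(0.97, w_max = 0.45, a_pos = 4.0, b_pos = 1.2),
      mm_cell(0.99, w_max = 0.60, a_pos = 3.0, b_pos = 1.0)
    ), c(adeno, nepc, amph, dn)),
    PSMA = stats::setNames(list(
      mm_cell(0.88, w_max = 0.15, a_pos = 1.8, b_pos = 1.4),
      mm_cell(0.05),
      mm_cell(0.70, w_max = 0.10, a_pos = 1.5, b_pos = 1.5),
      mm_cell(0.35, w_zero = 0.30, a_pos = 1.3, b_pos = 2.5)
    ), c(adeno, nepc, amph, dn)),
    DLL3 = stats::setNames(list(
      mm_cell(0.01),
      mm_cell(0.95, w_max = 0.05, a_pos = 1.5, b_pos = 1.7),
      mm_cell(0.15, w_max = 0.03, a_pos = 1.3, b_pos = 1.8),
      mm_cell(0.03)
    ), c(adeno, nepc, amph, dn)),
    CEACAM5 = stats::setNames(list(
      mm_cell(0.04),
      mm_cell(0.72, w_max = 0.05, a_pos = 1.3, b_pos = 1.5),
      mm_cell(0.10, a_pos = 1.2, b_pos = 1.8),
      mm_cell(0.20, a_pos = 1.2, b_pos = 1.8)
    ), c(adeno, nepc, amph, dn)),
    AR = stats::setNames(list(
      mm_cell(0.97, w_max = 0.30, a_pos = 3.0, b_pos = 1.0),
      mm_cell(0.03),
      mm_cell(0.95, w_max = 0.25, a_pos = 3.0, b_pos = 1.0),
      mm_cell(0.03)
    ), c(adeno, nepc, amph, dn)),
    NKX3.1 = stats::setNames(list(
      mm_cell(0.90, w_max = 0.20, a_pos = 2.5, b_pos = 1.2),
      mm_cell(0.04),
      mm_cell(0.88, w_max = 0.20, a_pos = 2.5, b_pos = 1.2),
      mm_cell(0.04)
    ), c(adeno, nepc, amph, dn)),
    SYP = stats::setNames(list(
      mm_cell(0.04),
      mm_cell(0.95, w_max = 0.25, a_pos = 2.5, b_pos = 1.0),
      mm_cell(0.90, w_max = 0.20, a_pos = 2.5, b_pos = 1.0),
      mm_cell(0.04)
    ), c(adeno, nepc, amph, dn)),
    INSM1 = stats::setNames(list(
      mm_cell(0.03),
      mm_cell(0.85, w_max = 0.15, a_pos = 2.0, b_pos = 1.2),
      mm_cell(0.80, w_max = 0.10, a_pos = 2.0, b_pos = 1.2),
      mm_cell(0.03)
    ), c(adeno, nepc, amph, dn))
  )
}

#' @rdname default_marker_model
#' @export
default_site_effects <- function() {
  list(
    TROP2 = c("liver" = -17, "lung" = -40),
    DLL3 = c("liver" = 11, "lung" = 14),
    CEACAM5 = c("prostate/prostate bed" = 19)
  )
}

#' @rdname default_marker_model
#' @export
default_genomic_prevalence <- function() {
  list(
    AR = c("AR+/NE-" = 0.55, "AR+/NE+" = 0.50, "AR-/NE-" = 0.30,
           "AR-/NE+" = 0.15),
    RB1 = c("AR+/NE-" = 0.20, "AR+/NE+" = 0.35, "AR-/NE-" = 0.30,
            "AR-/NE+" = 0.70),
    PTEN = 0.40, TP53 = 0.50, CHD1 = 0.07, BRCA2 = 0.08, SPOP = 0.10
  )
}

#' @rdname default_marker_model
#' @export
default_genomic_effects <- function() {
  list(
    AR = c(PSMA = 1.4, TROP2 = 0.7, DLL3 = -1.4, CEACAM5 = -1.0),
    RB1 = c(PSMA = -1.4, TROP2 = -1.4, DLL3 = 1.0),
    PTEN = c(CEACAM5 = 1.0)
  )
}

# Draw n H-scores from one marker-model cell (before site/patient shifts).
# Returns list(value, positive): `positive` is the latent component, which
# equals value >= threshold exactly (negatives live in [0, threshold),
# positives in [threshold, 200]).
draw_marker <- function(n, pars, threshold = 20) {
  pos <- stats::runif(n) < pars["p_pos"]
  v <- numeric(n)
  npos <- sum(pos); nneg <- n - npos
  if (nneg) {
    at0 <- stats::runif(nneg) < pars["w_zero"]
    vn <- threshold * stats::rbeta(nneg, 1, 3)
    vn[at0] <- 0
    v[!pos] <- vn
  }
  if (npos) {
    at200 <- stats::runif(npos) < pars["w_max"]
    vp <- threshold + (200 - threshold) *
      stats::rbeta(npos, pars["a_pos"], pars["b_pos"])
    vp[at200] <- 200
    v[pos] <- vp
  }
  list(value = v, positive = pos)
}

# Positivity is latent truth: level shifts (patient, site) and core noise
# perturb the H-score within its category; category changes arise only from
# the mixture draw itself (and core_flip redraws). Emitted H-scores are
# integers, as scored on slides; negatives occupy [0, threshold - 1].
settle_value <- function(v, pos, threshold) {
  neg_max <- max(0, ceiling(threshold) - 1)
  out <- ifelse(pos, clamp(v, threshold, 200), clamp(v, 0, neg_max))
  round(out)
}

#' Generate a synthetic cohort with ground truth
#'
#' Emits a schema-valid [cohort_table()] plus a `"cohort_truth"` object
#' recording, for every entity actually emitted, the block-level true
#' subtype, the per-sample positivity probability used for its block's
#' draw, the realized H-scores, the configured site shifts and genomic
#' log-odds effects, and the seed. Identical seeds give identical output.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; overrides `config$seed`; defaults to 1 when
#'   neither is given.
#' @return list with elements `cohort` (a [cohort_table()]) and `truth`
#'   (class `"cohort_truth"`: `blocks`, `samples`, `site_effects`,
#'   `genomic_effects`, `threshold`, `seed`).
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- seed %||% config$seed %||% 1
  markers <- names(config$marker_model)
  subtys <- tma_subtypes()
  genes <- names(config$genomic_prevalence) %||% character(0)

  with_seed(seed, {
    sample_rows <- list()
    block_rows <- list()
    genomic_rows <- list()
    for (p in seq_len(config$n_patients)) {
      pid <- sprintf("P%03d", p)
      dominant <- sample(names(config$subtype_probs), 1,
                         prob = config$subtype_probs)
      n_sites <- 0
      while (n_sites == 0) n_sites <- stats::rpois(1, config$mean_sites)
      patient_re <- stats::setNames(
        stats::rnorm(length(markers), 0, config$patient_sd), markers)
      patient_pos_re <- stats::setNames(
        stats::rnorm(length(markers), 0, config$patient_logit_sd), markers)

      flags <- vapply(genes, function(g) {
        prev <- config$genomic_prevalence[[g]]
        pr <- if (length(prev) == 1) unname(prev) else unname(prev[dominant])
        stats::rbinom(1, 1, pr)
      }, numeric(1))
      if (length(genes)) {
        genomic_rows[[p]] <- c(list(patient_id = pid),
                               as.list(stats::setNames(flags,
                                                       paste0("gene_", genes))))
      }

      for (s in seq_len(n_sites)) {
        sid <- sprintf("S%02d", s)
        site <- sample(names(config$site_probs), 1, prob = config$site_probs)
        subtype <- dominant
        if (stats::runif(1) < config$switch_prob && length(subtys) > 1) {
          subtype <- sample(setdiff(subtys, dominant), 1)
        }
        n_cores <- sample(seq_along(config$cores_probs), 1,
                          prob = config$cores_probs)

        block_p_pos <- numeric(0)
        core_vals <- matrix(NA_real_, nrow = n_cores, ncol = length(markers),
                            dimnames = list(NULL, markers))
        for (m in markers) {
          pars <- config$marker_model[[m]][[subtype]]
          eff <- 0
          for (g in genes) {
            e <- config$genomic_effects[[g]]
            if (!is.null(e) && m %in% names(e) && flags[[g]] == 1) {
              eff <- eff + unname(e[m])
            }
          }
          p_pos <- stats::plogis(stats::qlogis(clamp(unname(pars["p_pos"]),
                                                     1e-6, 1 - 1e-6)) +
                                 eff + unname(patient_pos_re[m]))
          pars_adj <- pars
          pars_adj["p_pos"] <- p_pos
          block_p_pos[m] <- p_pos

          shift <- unname(patient_re[m])
          se <- config$site_effects[[m]]
          if (!is.null(se) && site %in% names(se)) shift <- shift + unname(se[site])

          thr <- config$threshold
          # point masses at the scale ends (no staining at all / saturated
          # staining) are stable readings: level shifts and core noise act
          # only on interior values
          block_draw <- draw_marker(1, pars_adj, thr)
          pm_block <- block_draw$value %in% c(0, 200)
          block_value <- if (pm_block) block_draw$value else
            block_draw$value + shift
          flip <- stats::runif(n_cores) < config$core_flip
          vals <- if (pm_block) rep(block_value, n_cores) else
            block_value + stats::rnorm(n_cores, 0, config$core_sd)
          poss <- rep(block_draw$positive, n_cores)
          if (any(flip)) {
            redraw <- draw_marker(sum(flip), pars_adj, thr)
            pm_new <- redraw$value %in% c(0, 200)
            vals[flip] <- ifelse(pm_new, redraw$value, redraw$value + shift)
            poss[flip] <- redraw$positive
          }
          core_vals[, m] <- settle_value(vals, poss, thr)
        }

        block_rows[[length(block_rows) + 1]] <- data.frame(
          patient_id = pid, site_id = sid, block_id = "B1",
          anatomic_site = site, subtype = subtype,
          dominant_subtype = dominant,
          t(stats::setNames(block_p_pos, paste0("p_pos_", markers))),
          stringsAsFactors = FALSE, check.names = FALSE)

        df <- data.frame(
          patient_id = pid, site_id = sid, block_id = "B1",
          core_id = sprintf("C%d", seq_len(n_cores)),
          anatomic_site = site, stringsAsFactors = FALSE)
        for (m in markers) df[[paste0(m, "_hscore")]] <- core_vals[, m]
        sample_rows[[length(sample_rows) + 1]] <- df
      }
    }
    samples <- do.call(rbind, sample_rows)
    rownames(samples) <- NULL
    genomic <- if (length(genes)) {
      do.call(rbind, lapply(genomic_rows, as.data.frame,
                            stringsAsFactors = FALSE))
    } else NULL
    schema <- schema_config(markers = markers, genes = genes,
                            threshold = config$threshold)
    cohort <- cohort_table(samples, genomic = genomic, schema = schema,
                           provenance = list(source = "synthetic", seed = seed))
    truth <- structure(
      list(blocks = do.call(rbind, block_rows),
           samples = samples,
           site_effects = config$site_effects,
           genomic_effects = config$genomic_effects,
           threshold = config$threshold, seed = seed),
      class = "cohort_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d blocks / %d samples (seed %d, threshold %g)\n",
              nrow(x$blocks), nrow(x$samples), x$seed, x$threshold))
  print(table(x$blocks$subtype))
  invisible(x)
}

#' Exact heterogeneity from generator ground truth
#'
#' Computes the discordance probability for a marker and scope directly
#' from the realized statuses recorded in the ground truth, using the
#' closed-form pair counts (for each group of `n` samples with `k`
#' positives there are `k*(n-k)` discordant and `choose(n,2)` total pairs;
#' inter-tumoral pairs are the patient's cross-block pairs). This is the
#' same quantity as [heterogeneity_exact()] on the emitted cohort, computed
#' through an independent code path, and serves as the oracle for the
#' heterogeneity estimators.
#'
#' @param truth a `"cohort_truth"` from [generate_cohort()].
#' @param marker marker name.
#' @param scope `"intra_tumoral"` or `"inter_tumoral"`.
#' @param weighting `"pair"` (default) or `"group"`, as in
#'   [heterogeneity_exact()].
#' @return discordance probability in `[0, 1]`.
#' @export
truth_heterogeneity <- function(truth, marker,
                                scope = c("intra_tumoral", "inter_tumoral"),
                                weighting = c("pair", "group")) {
  stopifnot(inherits(truth, "cohort_truth"))
  scope <- match.arg(scope)
  weighting <- match.arg(weighting)
  s <- truth$samples
  h <- s[[paste0(marker, "_hscore")]]
  if (is.null(h)) {
    tma_stop("tmahet_schema_error", sprintf("truth has no marker %s", marker))
  }
  keep <- !is.na(h)
  status <- h[keep] >= truth$threshold
  blk <- paste(s$patient_id, s$site_id, s$block_id, sep = "\r")[keep]
  pat <- s$patient_id[keep]

  if (scope == "intra_tumoral") {
    kk <- tapply(status, blk, sum)
    nn <- tapply(status, blk, length)
    disc <- kk * (nn - kk)
    tot <- nn * (nn - 1) / 2
  } else {
    disc <- c(); tot <- c()
    for (g in unique(pat)) {
      i <- pat == g
      nb <- tapply(status[i], blk[i], length)
      kb <- tapply(status[i], blk[i], sum)
      t_all <- sum(nb); k_all <- sum(kb)
      tot <- c(tot, t_all * (t_all - 1) / 2 - sum(nb * (nb - 1) / 2))
      disc <- c(disc, k_all * (t_all - k_all) - sum(kb * (nb - kb)))
    }
  }
  ok <- tot > 0
  if (!any(ok)) {
    tma_stop("tmahet_empty_pool_error",
             sprintf("no eligible %s pairs for %s in truth", scope, marker))
  }
  if (weighting == "pair") sum(disc[ok]) / sum(tot[ok])
  else mean(disc[ok] / tot[ok])
}

#' Read or write a generator configuration as YAML
#'
#' Round-trips every field of [generator_config()] so a simulation's
#' resolved configuration can be archived next to its outputs.
#'
#' @param config a `"generator_config"`.
#' @param path file path.
#' @return `write_generator_config()` returns `path` invisibly;
#'   `read_generator_config()` returns a `"generator_config"`.
#' @rdname generator_yaml
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  to_yaml <- function(x) {
    if (is.list(x)) lapply(x, to_yaml)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_yaml(unclass(config)), path)
  invisible(path)
}

#' @rdname generator_yaml
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  num <- function(x) if (is.list(x)) unlist(x) else x
  generator_config(
    n_patients = raw$n_patients, mean_sites = raw$mean_sites,
    cores_probs = num(raw$cores_probs),
    subtype_probs = num(raw$subtype_probs),
    switch_prob = raw$switch_prob, site_probs = num(raw$site_probs),
    marker_model = lapply(raw$marker_model, function(m) lapply(m, num)),
    site_effects = lapply(raw$site_effects, num),
    patient_sd = raw$patient_sd, core_sd = raw$core_sd,
    core_flip = raw$core_flip, patient_logit_sd = raw$patient_logit_sd,
    genomic_prevalence = lapply(raw$genomic_prevalence, num),
    genomic_effects = lapply(raw$genomic_effects, num),
    threshold = raw$threshold, seed = raw$seed
  )
}
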