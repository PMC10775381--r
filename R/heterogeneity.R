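#' Enumerate the eligible sample pairs for a heterogeneity scope
#'
#' The heterogeneity index is defined over a finite population of unordered
#' sample pairs. At the `intra_tumoral` scope the eligible pairs are all
#' pairs of cores from the same tumor block; at the `inter_tumoral`
#' (intra-patient) scope they are all pairs of samples from the same
#' patient but different blocks. Samples missing the marker are excluded;
#' groups contributing fewer than two eligible samples (or, inter-tumorally,
#' a single block) contribute no pairs.
#'
#' @param cohort a [cohort_table()].
#' @param marker marker name.
#' @param scope `"intra_tumoral"` or `"inter_tumoral"`.
#' @param threshold positivity cut-off used to binarize H-scores.
#' @return object of class `"pair_pool"`: data.frame with one row per
#'   unordered pair (`group`, `status_i`, `status_j`, `discordant`) and
#'   attributes `scope`, `marker`, `threshold`, `n_samples`.
#' @export
enumerate_pairs <- function(cohort, marker,
                            scope = c("intra_tumoral", "inter_tumoral"),
                            threshold = 20) {
  stopifnot(inherits(cohort, "cohort_table"))
  scope <- match.arg(scope)
  h <- marker_hscore(cohort, marker)
  keep <- which(!is.na(h))
  status <- h[keep] >= threshold
  blk <- block_key(cohort)[keep]
  pat <- cohort$patient_id[keep]

  pairs_i <- integer(0); pairs_j <- integer(0); grp <- character(0)
  if (scope == "intra_tumoral") {
    for (g in unique(blk)) {
      members <- which(blk == g)
      if (length(members) < 2) next
      cmb <- utils::combn(members, 2)
      pairs_i <- c(pairs_i, cmb[1, ]); pairs_j <- c(pairs_j, cmb[2, ])
      grp <- c(grp, rep(g, ncol(cmb)))
    }
  } else {
    for (g in unique(pat)) {
      members <- which(pat == g)
      if (length(members) < 2) next
      cmb <- utils::combn(members, 2)
      cross <- blk[cmb[1, ]] != blk[cmb[2, ]]
      if (!any(cross)) next
      pairs_i <- c(pairs_i, cmb[1, cross]); pairs_j <- c(pairs_j, cmb[2, cross])
      grp <- c(grp, rep(g, sum(cross)))
    }
  }
  if (!length(pairs_i)) {
    tma_stop("tmahet_empty_pool_error",
             sprintf("no eligible %s pairs for %s", scope, marker))
  }
  pool <- data.frame(
    group = grp,
    sample_i = keep[pairs_i], sample_j = keep[pairs_j],
    status_i = status[pairs_i], status_j = status[pairs_j],
    stringsAsFactors = FALSE)
  pool$discordant <- pool$status_i != pool$status_j
  structure(pool, class = c("pair_pool", "data.frame"),
            scope = scope, marker = marker, threshold = threshold,
            n_samples = length(keep))
}

#' @export
print.pair_pool <- function(x, ...) {
  cat(sprintf("<pair_pool> %s / %s: %d pairs in %d groups (%d samples), %d discordant\n",
              attr(x, "marker"), attr(x, "scope"), nrow(x),
              length(unique(x$group)), attr(x, "n_samples"),
              sum(x$discordant)))
  invisible(x)
}

# Construct a pair_pool directly from per-sample statuses (used by the
# synthetic-truth oracle and by tests).
pool_from_statuses <- function(status, group, patient = NULL,
                               scope = "intra_tumoral", marker = "marker") {
  df <- data.frame(patient_id = patient %||% group, site_id = group,
                   block_id = "b", core_id = as.character(seq_along(status)),
                   anatomic_site = "liver",
                   M_hscore = ifelse(status, 100, 0),
                   stringsAsFactors = FALSE)
  sch <- schema_config(markers = "M")
  enumerate_pairs(cohort_table(df, schema = sch), "M", scope = scope)
}

#' Exact (finite-population) heterogeneity index
#'
#' The probability that a random eligible pair of samples is discordant in
#' binarized status, computed by complete enumeration — the
#' without-replacement ("hypergeometric") form of the index. Under pair
#' weighting every eligible pair is equally likely: the index is the
#' discordant fraction of the pooled pair population. Under group weighting
#' each group (tumor block, or patient) contributes its own discordant
#' fraction and groups are averaged unweighted; for a single block of `n`
#' samples with `k` positives the concordant fraction is
#' `(choose(k,2) + choose(n-k,2)) / choose(n,2)`.
#'
#' @param pool a [enumerate_pairs()] pool.
#' @param weighting `"pair"` (default) or `"group"`.
#' @return discordance probability in `[0, 1]`.
#' @export
heterogeneity_exact <- function(pool, weighting = c("pair", "group")) {
  weighting <- match.arg(weighting)
  if (!inherits(pool, "pair_pool") || nrow(pool) == 0) {
    tma_stop("tmahet_empty_pool_error", "empty pair pool")
  }
  if (weighting == "pair") {
    mean(pool$discordant)
  } else {
    mean(tapply(pool$discordant, pool$group, mean))
  }
}

#' Bootstrap heterogeneity estimate with BCa confidence limits
#'
#' Monte-Carlo counterpart of [heterogeneity_exact()]: each bootstrap
#' replicate draws `n_pairs` pairs uniformly with replacement from the pair
#' pool and records the discordant fraction; the point estimate is the mean
#' over replicates and the confidence interval is bias-corrected and
#' accelerated ([bca_interval()]). With `resample_unit = "pair"` the pair
#' is both the sampling and the resampling unit; `resample_unit = "group"`
#' resamples whole groups (patients, or blocks at the intra-tumoral scope)
#' before drawing pairs, respecting the clustering of pairs within
#' patients.
#'
#' @param pool a [enumerate_pairs()] pool.
#' @param n_pairs pairs drawn per replicate (default 1000). `NULL` uses the
#'   pool's own pair count (the canonical bootstrap resample size; use this
#'   when the interval must calibrate against the pool's sampling
#'   variability rather than approximate the pooled index).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed; drawn and recorded if omitted.
#' @param resample_unit `"pair"` (default) or `"group"`.
#' @param level confidence level (default 0.95).
#' @return object of class `"het_estimate"` with fields `point_estimate`,
#'   `ci_low`, `ci_high`, `observed` (exact pooled index),
#'   `n_pairs_population`, `n_pairs_sampled`, `n_boot`, `seed`, `scope`,
#'   `marker`, `resample_unit`, `level`, `degenerate`.
#' @export
heterogeneity_bootstrap <- function(pool, n_pairs = 1000, n_boot = 1000,
                                    seed = NULL,
                                    resample_unit = c("pair", "group"),
                                    level = 0.95) {
  resample_unit <- match.arg(resample_unit)
  if (!inherits(pool, "pair_pool") || nrow(pool) == 0) {
    tma_stop("tmahet_empty_pool_error", "empty pair pool")
  }
  m <- nrow(pool)
  if (is.null(n_pairs)) n_pairs <- m
  if (n_pairs < 1 || n_boot < 1) {
    tma_stop("tmahet_config_error", "`n_pairs` and `n_boot` must be >= 1")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  disc <- as.numeric(pool$discordant)
  observed <- mean(disc)

  res <- with_seed(seed, {
    if (resample_unit == "pair") {
      idx <- sample.int(m, n_pairs * n_boot, replace = TRUE)
      stats_b <- colMeans(matrix(disc[idx], nrow = n_pairs))
      jack <- (sum(disc) - disc) / (m - 1)
      list(stats = stats_b, jack = if (m > 1) jack else NULL)
    } else {
      by_grp <- split(disc, pool$group)
      G <- length(by_grp)
      stats_b <- vapply(seq_len(n_boot), function(b) {
        take <- sample.int(G, G, replace = TRUE)
        pooled <- unlist(by_grp[take], use.names = FALSE)
        mean(pooled[sample.int(length(pooled), n_pairs, replace = TRUE)])
      }, numeric(1))
      jack <- if (G > 1) {
        vapply(seq_len(G), function(g) {
          mean(unlist(by_grp[-g], use.names = FALSE))
        }, numeric(1))
      } else NULL
      list(stats = stats_b, jack = jack)
    }
  })

  ci <- bca_interval(res$stats, observed = observed, jackknife = res$jack,
                     level = level)
  structure(
    list(point_estimate = mean(res$stats),
         ci_low = ci[1], ci_high = ci[2],
         observed = observed,
         n_pairs_population = m, n_pairs_sampled = n_pairs,
         n_boot = n_boot, seed = seed,
         scope = attr(pool, "scope"), marker = attr(pool, "marker"),
         threshold = attr(pool, "threshold"),
         resample_unit = resample_unit, level = level,
         degenerate = isTRUE(attr(ci, "degenerate")),
         replicate_sd = stats::sd(res$stats)),
    class = "het_estimate"
  )
}

#' @export
print.het_estimate <- function(x, digits = 1, ...) {
  cat(sprintf("<het_estimate> %s heterogeneity of %s\n", x$scope, x$marker))
  cat(sprintf("  %s%% (%g%% CI %s to %s)%s\n",
              format(round_half_up(100 * x$point_estimate, digits)),
              100 * x$level,
              format(round_half_up(100 * x$ci_low, digits)),
              format(round_half_up(100 * x$ci_high, digits)),
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  pool: %d pairs; %d pairs/replicate x %d replicates; seed %d\n",
              x$n_pairs_population, x$n_pairs_sampled, x$n_boot, x$seed))
  invisible(x)
}

#' @export
summary.het_estimate <- function(object, ...) {
  data.frame(marker = object$marker, scope = object$scope,
             estimate = object$point_estimate,
             ci_low = object$ci_low, ci_high = object$ci_high,
             n_pairs_population = object$n_pairs_population,
             n_pairs_sampled = object$n_pairs_sampled,
             n_boot = object$n_boot, seed = object$seed,
             resample_unit = object$resample_unit,
             degenerate = object$degenerate,
             stringsAsFactors = FALSE)
}

#' @export
confint.het_estimate <- function(object, parm, level, ...) {
  out <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
                dimnames = list("discordance",
                                c(sprintf("%.1f %%", 100 * (1 - object$level) / 2),
                                  sprintf("%.1f %%", 100 * (1 + object$level) / 2))))
  out
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Standard BCa limits: the bias-correction constant `z0` is the normal
#' quantile of the fraction of replicates below the observed statistic,
#' counting ties with half weight (`P(t* < t0) + P(t* = t0)/2`); the
#' mid-probability tie convention coincides with the usual strict-less
#' definition for continuous statistics and removes the systematic bias the
#' strict count has on heavily tied replicate distributions, such as the
#' discordant-fraction statistic on small pair pools. The acceleration `a`
#' comes from the jackknife third-moment skewness formula
#' `a = sum((tbar - t_i)^3) / (6 * sum((tbar - t_i)^2)^(3/2))`; the
#' percentile endpoints are read at the adjusted levels
#' `pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))` from the sorted
#' replicates (index `ceiling(alpha * B)`, clamped to `[1, B]`).
#'
#' Degenerate situations are flagged rather than raised: when all
#' replicates are identical the interval collapses to that point mass, and
#' when the observed statistic falls outside the replicate range (infinite
#' `z0`) the plain percentile endpoints are returned; both carry
#' `attr(, "degenerate") = TRUE`.
#'
#' @param replicates numeric vector of bootstrap statistic draws.
#' @param observed the statistic on the original data.
#' @param jackknife optional numeric vector of leave-one-out statistics;
#'   when omitted the acceleration is 0 (bias-corrected percentile
#'   interval).
#' @param level confidence level (default 0.95).
#' @return numeric `c(low, high)` with attributes `z0`, `acceleration`,
#'   `degenerate`.
#' @export
bca_interval <- function(replicates, observed, jackknife = NULL,
                         level = 0.95) {
  b <- length(replicates)
  if (b < 2) {
    tma_stop("tmahet_config_error", "need at least 2 bootstrap replicates")
  }
  if (level <= 0 || level >= 1) {
    tma_stop("tmahet_config_error", "`level` must be in (0, 1)")
  }
  srt <- sort(replicates)
  pick <- function(alpha) srt[clamp(ceiling(alpha * b - 1e-9), 1, b)]
  alpha_lo <- (1 - level) / 2
  alpha_hi <- 1 - alpha_lo

  if (srt[1] == srt[b]) {
    return(structure(c(srt[1], srt[1]),
                     z0 = NA_real_, acceleration = NA_real_,
                     degenerate = TRUE))
  }
  z0 <- stats::qnorm(mean(replicates < observed) +
                       0.5 * mean(replicates == observed))
  if (!is.finite(z0)) {
    return(structure(c(pick(alpha_lo), pick(alpha_hi)),
                     z0 = z0, acceleration = NA_real_, degenerate = TRUE))
  }
  a <- 0
  if (!is.null(jackknife) && length(jackknife) > 1) {
    d <- mean(jackknife) - jackknife
    denom <- sum(d^2)^1.5
    if (denom > 0) a <- sum(d^3) / (6 * denom)
  }
  adj <- function(alpha) {
    z <- z0 + stats::qnorm(alpha)
    stats::pnorm(z0 + z / (1 - a * z))
  }
  structure(c(pick(adj(alpha_lo)), pick(adj(alpha_hi))),
            z0 = z0, acceleration = a, degenerate = FALSE)
}

#' Heterogeneity indices for several markers and scopes
#'
#' Convenience driver producing the cohort-level heterogeneity table: one
#' bootstrap estimate per marker per scope, with per-estimate seeds derived
#' deterministically from `seed`. Marker/scope combinations with an empty
#' pair pool are skipped with a message.
#'
#' @param cohort a [cohort_table()].
#' @param markers marker names (default: the schema's marker panel).
#' @param scopes scopes to estimate (default both).
#' @param threshold positivity cut-off.
#' @param seed master integer seed.
#' @param ... passed to [heterogeneity_bootstrap()].
#' @return data.frame with one row per estimate (see
#'   [summary.het_estimate()]).
#' @export
heterogeneity_table <- function(cohort,
                                markers = attr(cohort, "schema")$markers,
                                scopes = c("inter_tumoral", "intra_tumoral"),
                                threshold = 20, seed = 1, ...) {
  out <- list()
  k <- 0
  for (marker in markers) {
    for (scope in scopes) {
      k <- k + 1
      pool <- tryCatch(
        enumerate_pairs(cohort, marker, scope = scope, threshold = threshold),
        tmahet_empty_pool_error = function(e) NULL)
      if (is.null(pool)) {
        message(sprintf("skipping %s/%s: no eligible pairs", marker, scope))
        next
      }
      est <- heterogeneity_bootstrap(pool, seed = seed + k, ...)
      out[[length(out) + 1]] <- summary(est)
    }
  }
  if (!length(out)) {
    tma_stop("tmahet_empty_pool_error", "no marker/scope had eligible pairs")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
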