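# helper: balanced two-site cohort with known structure
balanced_site_cohort <- function(n_patients = 6, shift = -20, patient_sd = 0,
                                 noise_sd = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_patients)) {
    re <- rnorm(1, 0, patient_sd)
    for (s in c("vertebral bone", "liver")) {
      mu <- 100 + re + if (s == "liver") shift else 0
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("P%02d", p), site_id = if (s == "liver") "S2" else "S1",
        block_id = "B1", core_id = "C1", anatomic_site = s,
        TROP2_hscore = min(max(mu + rnorm(1, 0, noise_sd), 0), 200),
        stringsAsFactors = FALSE)
    }
  }
  cohort_table(do.call(rbind, rows), schema = schema_config(markers = "TROP2"))
}

test_that("with zero patient variance the contrasts equal raw site-mean differences", {
  co <- balanced_site_cohort(n_patients = 8, shift = -20, noise_sd = 3)
  fit <- site_mixed_model(co, "TROP2")
  h <- co$TROP2_hscore
  raw_diff <- mean(h[co$anatomic_site == "liver"]) -
    mean(h[co$anatomic_site == "vertebral bone"])
  liver <- fit[fit$site == "liver", ]
  expect_equal(liver$mean_difference, raw_diff, tolerance = 1e-6)
  # singular fit must match ordinary least squares
  if (attr(fit, "singular")) {
    ols <- lm(h ~ relevel(factor(co$anatomic_site), "vertebral bone"))
    expect_equal(liver$mean_difference, unname(coef(ols)[2]), tolerance = 1e-6)
  }
  ref <- fit[fit$site == "vertebral bone", ]
  expect_equal(ref$mean_difference, 0)
  expect_true(liver$ci_low <= liver$mean_difference &&
                liver$mean_difference <= liver$ci_high)
})

test_that("changing the reference site relabels contrasts by subtraction", {
  co <- balanced_site_cohort(n_patients = 10, shift = -15, patient_sd = 8,
                             noise_sd = 5, seed = 4)
  f1 <- site_mixed_model(co, "TROP2", reference_site = "vertebral bone")
  f2 <- site_mixed_model(co, "TROP2", reference_site = "liver")
  d1 <- f1$mean_difference[f1$site == "liver"]
  d2 <- f2$mean_difference[f2$site == "vertebral bone"]
  expect_equal(d1, -d2, tolerance = 1e-6)
  # fitted cell means invariant to the reference choice
  m1 <- attr(f1, "reference_mean")["mean"] + d1
  m2 <- attr(f2, "reference_mean")["mean"]
  expect_equal(unname(m1), unname(m2), tolerance = 1e-6)
})

test_that("degenerate site designs raise typed errors; lone-sample sites are flagged", {
  one_site <- toy_cohort(c(100, 120, 90), patient = c("P1", "P2", "P3"),
                         marker = "TROP2")
  expect_error(site_mixed_model(one_site, "TROP2"),
               class = "tmahet_degenerate_error")

  co <- balanced_site_cohort(n_patients = 6, noise_sd = 4)
  extra <- as.data.frame(co)
  extra <- rbind(extra, data.frame(patient_id = "P99", site_id = "S3",
                                   block_id = "B1", core_id = "C1",
                                   anatomic_site = "lung", TROP2_hscore = 80))
  co2 <- cohort_table(extra, schema = attr(co, "schema"))
  fit <- site_mixed_model(co2, "TROP2")
  expect_true(fit$wide_ci[fit$site == "lung"])
})

test_that("mixed-model site contrast covers the simulated truth (parameter recovery)", {
  # moderate-size recovery check; the acceptance suite runs the full design
  hits <- 0L
  for (r in 1:25) {
    co <- balanced_site_cohort(n_patients = 12, shift = -20, patient_sd = 10,
                               noise_sd = 8, seed = 100 + r)
    fit <- site_mixed_model(co, "TROP2")
    liver <- fit[fit$site == "liver", ]
    hits <- hits + (liver$ci_low <= -20 && -20 <= liver$ci_high)
  }
  expect_gte(hits, 20)
})

genomic_patient_cohort <- function(n = 80, log_or = log(4), base = -0.5,
                                   seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(base + log_or * g))
  df <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)), site_id = "S1",
    block_id = "B1", core_id = "C1", anatomic_site = "liver",
    PSMA_hscore = ifelse(y == 1, 150, 0), stringsAsFactors = FALSE)
  gen <- data.frame(patient_id = df$patient_id, gene_AR = g,
                    stringsAsFactors = FALSE)
  cohort_table(df, genomic = gen, schema = schema_config(markers = "PSMA"))
}

test_that("with one sample per patient the OR equals the classical 2x2 odds ratio", {
  co <- genomic_patient_cohort(n = 120, seed = 8)
  res <- genomic_logistic(co, "PSMA", "AR", unit = "sample")
  tab <- res$counts
  classical <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  expect_equal(res$odds_ratio, unname(classical), tolerance = 1e-6)
  expect_false(res$separation)
  expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)
})

test_that("null association yields a CI covering 1 at large n", {
  co <- genomic_patient_cohort(n = 400, log_or = 0, seed = 21)
  res <- genomic_logistic(co, "PSMA", "AR")
  expect_true(res$ci_low <= 1 && 1 <= res$ci_high)
})

test_that("complete separation is flagged, single-class designs error", {
  df <- data.frame(
    patient_id = sprintf("P%d", 1:8), site_id = "S1", block_id = "B1",
    core_id = "C1", anatomic_site = "liver",
    PSMA_hscore = c(150, 150, 150, 150, 0, 0, 0, 150),
    stringsAsFactors = FALSE)
  gen <- data.frame(patient_id = df$patient_id,
                    gene_AR = c(1, 1, 1, 1, 0, 0, 0, 0))
  co <- cohort_table(df, genomic = gen, schema = schema_config(markers = "PSMA"))
  res <- genomic_logistic(co, "PSMA", "AR")
  expect_true(res$separation)

  all_pos <- df; all_pos$PSMA_hscore <- 150
  co2 <- cohort_table(all_pos, genomic = gen,
                      schema = schema_config(markers = "PSMA"))
  expect_error(genomic_logistic(co2, "PSMA", "AR"),
               class = "tmahet_degenerate_error")
})

test_that("sample-level mode uses a patient random intercept and stays consistent", {
  set.seed(33)
  n <- 60
  g <- rbinom(n, 1, 0.5)
  u <- rnorm(n, 0, 1)
  rows <- list()
  for (p in seq_len(n)) {
    for (s in 1:3) {
      y <- rbinom(1, 1, plogis(-0.3 + log(4) * g[p] + u[p]))
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("P%03d", p), site_id = sprintf("S%d", s),
        block_id = "B1", core_id = "C1", anatomic_site = "liver",
        DLL3_hscore = ifelse(y == 1, 90, 0), stringsAsFactors = FALSE)
    }
  }
  gen <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), gene_RB1 = g)
  co <- cohort_table(do.call(rbind, rows), genomic = gen,
                     schema = schema_config(markers = "DLL3"))
  res <- genomic_logistic(co, "DLL3", "RB1", unit = "sample")
  expect_match(res$engine, "glmer")
  expect_gt(res$odds_ratio, 1)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("transcript tables are dichotomized at the FPKM threshold", {
  set.seed(2)
  expr <- data.frame(
    patient_id = sprintf("P%d", 1:40),
    CEACAM5 = sample(c(runif(20, 0, 0.9), runif(20, 1, 50))),
    gene_PTEN = rep(c(0, 1), 20), stringsAsFactors = FALSE)
  res <- genomic_logistic(expr, "CEACAM5", "PTEN")
  expect_equal(res$dichotomization, "FPKM >= 1")
  expect_equal(res$n_altered + res$n_wildtype, 40)
})
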