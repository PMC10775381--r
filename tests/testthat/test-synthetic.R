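test_that("generation is deterministic under seed and matches the configured shape", {
  g1 <- generate_cohort(generator_config(), seed = 1)
  g2 <- generate_cohort(generator_config(), seed = 1)
  expect_identical(as.data.frame(g1$cohort), as.data.frame(g2$cohort))
  expect_identical(g1$truth$blocks, g2$truth$blocks)
  expect_equal(length(unique(g1$cohort$patient_id)), 52)
  # distinct seeds give distinct cohorts
  g3 <- generate_cohort(generator_config(), seed = 2)
  expect_false(identical(as.data.frame(g1$cohort), as.data.frame(g3$cohort)))
})

test_that("generated cohorts survive the read/write round-trip", {
  g <- generate_cohort(small_config(), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(g$cohort, path)
  back <- read_cohort(path, schema = attr(g$cohort, "schema"))
  expect_equal(back$TROP2_hscore, g$cohort$TROP2_hscore)
  expect_equal(nrow(back), nrow(g$cohort))
  expect_equal(genomic_flags(back)$gene_RB1,
               genomic_flags(g$cohort)$gene_RB1)
})

test_that("zero switching probability makes every patient subtype-pure", {
  g <- generate_cohort(small_config(switch_prob = 0), seed = 3)
  per_patient <- tapply(g$truth$blocks$subtype, g$truth$blocks$patient_id,
                        function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
})

test_that("TROP2 median in adenocarcinoma blocks stays near its 200 anchor", {
  meds <- vapply(1:20, function(s) {
    g <- generate_cohort(generator_config(), seed = 1000 + s)
    st <- g$truth$blocks$subtype[match(
      paste(g$cohort$patient_id, g$cohort$site_id, g$cohort$block_id),
      paste(g$truth$blocks$patient_id, g$truth$blocks$site_id,
            g$truth$blocks$block_id))]
    median(g$cohort$TROP2_hscore[st == "AR+/NE-"])
  }, numeric(1))
  expect_true(all(abs(meds - 200) <= 20))
})

test_that("cohort size concentrates near the 753-sample anchor", {
  sizes <- vapply(1:5, function(s) {
    nrow(generate_cohort(generator_config(), seed = 2000 + s)$cohort)
  }, numeric(1))
  expect_true(all(sizes > 600 & sizes < 920))
  expect_lt(abs(mean(sizes) - 753), 80)
})

test_that("truth-based discordance equals the enumerating estimator bit for bit", {
  g <- generate_cohort(small_config(), seed = 7)
  for (m in c("TROP2", "DLL3")) {
    for (sc in c("intra_tumoral", "inter_tumoral")) {
      pool <- enumerate_pairs(g$cohort, m, sc)
      expect_identical(truth_heterogeneity(g$truth, m, sc),
                       heterogeneity_exact(pool))
      expect_identical(truth_heterogeneity(g$truth, m, sc, weighting = "group"),
                       heterogeneity_exact(pool, weighting = "group"))
    }
  }
})

test_that("truth heterogeneity handles hand-built and degenerate cases", {
  # 4 samples in one block, k = 2 -> 2/3 by enumeration
  truth <- structure(
    list(samples = data.frame(
      patient_id = "P1", site_id = "S1", block_id = "B1",
      core_id = sprintf("C%d", 1:4),
      M_hscore = c(100, 150, 0, 0), stringsAsFactors = FALSE),
      threshold = 20, seed = 0),
    class = "cohort_truth")
  expect_equal(truth_heterogeneity(truth, "M", "intra_tumoral"), 2 / 3)
  # all-positive marker has no discordance
  truth$samples$M_hscore <- rep(150, 4)
  expect_equal(truth_heterogeneity(truth, "M", "intra_tumoral"), 0)
})

test_that("subtype mixture and genomic prevalence respond to configuration", {
  cfg <- small_config(subtype_probs = c("AR+/NE-" = 0, "AR-/NE+" = 1,
                                        "AR+/NE+" = 0, "AR-/NE-" = 0),
                      switch_prob = 0)
  g <- generate_cohort(cfg, seed = 11)
  expect_true(all(g$truth$blocks$subtype == "AR-/NE+"))
  # RB1 prevalence should track its configured NEPC rate (0.7)
  flags <- genomic_flags(g$cohort)
  expect_gt(mean(flags$gene_RB1), 0.4)
})

test_that("infeasible configurations are rejected", {
  expect_error(generator_config(n_patients = 0), class = "tmahet_config_error")
  expect_error(generator_config(cores_probs = c(0.5, 0.1)),
               class = "tmahet_config_error")
  expect_error(generator_config(subtype_probs = c("AR+/NE-" = 1)),
               class = "tmahet_config_error")
})

test_that("generator configuration round-trips through YAML", {
  cfg <- small_config(switch_prob = 0.1, seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, path)
  back <- read_generator_config(path)
  expect_equal(back$switch_prob, 0.1)
  expect_equal(back$subtype_probs, cfg$subtype_probs)
  expect_equal(back$marker_model$TROP2, cfg$marker_model$TROP2)
  g1 <- generate_cohort(cfg, seed = 6)
  g2 <- generate_cohort(back, seed = 6)
  expect_identical(as.data.frame(g1$cohort), as.data.frame(g2$cohort))
})
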