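test_that("contingency counts and half-up percentages reproduce worked examples", {
  # adenocarcinoma TROP2/PSMA pattern: 233 both, 7 PSMA-only, 61 TROP2-only,
  # 3 neither, of 304 lesions
  co <- joint_cohort(233, 61, 7, 3, marker_a = "TROP2", marker_b = "PSMA")
  tab <- tabulate_coexpression(co, "TROP2", "PSMA")
  expect_equal(unname(tab$counts), c(233, 61, 7, 3))
  expect_equal(tab$total, 304)
  expect_equal(unname(tab$percentages), c(77, 20, 2, 1))

  # NEPC DLL3/CEACAM5 pattern over 71 tumors, 3/71 needing one decimal
  co2 <- joint_cohort(38, 21, 3, 9, marker_a = "DLL3", marker_b = "CEACAM5")
  tab0 <- tabulate_coexpression(co2, "DLL3", "CEACAM5")
  expect_equal(unname(tab0$percentages), c(54, 30, 4, 13))
  tab1 <- tabulate_coexpression(co2, "DLL3", "CEACAM5", digits = 1)
  expect_equal(unname(tab1$percentages)[3], 4.2)

  # all both-negative
  co3 <- joint_cohort(0, 0, 0, 12)
  tab3 <- tabulate_coexpression(co3, "TROP2", "PSMA")
  expect_equal(unname(tab3$counts), c(0, 0, 0, 12))
  expect_equal(unname(tab3$percentages), c(0, 0, 0, 100))
})

test_that("swapping the marker pair maps a_only to b_only and units missing a marker drop out", {
  co <- joint_cohort(10, 5, 2, 3)
  fwd <- tabulate_coexpression(co, "TROP2", "PSMA")
  rev <- tabulate_coexpression(co, "PSMA", "TROP2")
  expect_equal(unname(rev$counts),
               unname(fwd$counts[c("both_positive", "b_only", "a_only", "neither")]))

  co_na <- as.data.frame(co)
  co_na$PSMA_hscore[1:4] <- NA
  tab <- tabulate_coexpression(
    cohort_table(co_na, schema = attr(co, "schema")), "TROP2", "PSMA")
  expect_equal(tab$total, 16)
})

test_that("subtype strata filter units and empty strata raise a typed error", {
  lab <- c(rep("AR+/NE-", 12), rep("AR-/NE+", 8))
  co <- joint_cohort(10, 5, 2, 3, subtype_label = lab)
  tab <- tabulate_coexpression(co, "TROP2", "PSMA", stratum = "AR+/NE-")
  expect_equal(tab$total, 12)
  expect_error(
    tabulate_coexpression(co, "TROP2", "PSMA", stratum = "AR+/NE+"),
    class = "tmahet_empty_stratum_error")
})

test_that("block unit reconciles cores by max before cross-tabulation", {
  df <- data.frame(
    patient_id = "P1", site_id = "S1", block_id = "B1", core_id = c("C1", "C2"),
    anatomic_site = "liver",
    TROP2_hscore = c(0, 100), PSMA_hscore = c(0, 0),
    stringsAsFactors = FALSE)
  co <- cohort_table(df, schema = schema_config(markers = c("TROP2", "PSMA")))
  tab <- tabulate_coexpression(co, "TROP2", "PSMA", unit = "block")
  expect_equal(tab$total, 1)
  expect_equal(unname(tab$counts["a_only"]), 1)
})

test_that("patient three-way classification follows the site rule with inclusive boundary", {
  co <- patient_cohort(list(P1 = c(0, 5, 10), P2 = c(0, 150), P3 = c(20, 200),
                            P4 = 8, P5 = 20))
  expect_equal(classify_patient(co, "P1", "DLL3")$class, "non_expressor")
  expect_equal(classify_patient(co, "P2", "DLL3")$class, "heterogeneous")
  expect_equal(classify_patient(co, "P3", "DLL3")$class, "uniform_high")
  # single-unit patients can never be heterogeneous
  expect_equal(classify_patient(co, "P4", "DLL3")$class, "non_expressor")
  expect_equal(classify_patient(co, "P5", "DLL3")$class, "uniform_high")
})

test_that("cores aggregate into sites by max before patient classification", {
  df <- data.frame(
    patient_id = "P1", site_id = c("S1", "S1", "S2"), block_id = "B1",
    core_id = c("C1", "C2", "C1"), anatomic_site = "liver",
    DLL3_hscore = c(0, 90, 40), stringsAsFactors = FALSE)
  co <- cohort_table(df, schema = schema_config(markers = "DLL3"))
  pc <- classify_patient(co, "P1", "DLL3")
  expect_equal(pc$class, "uniform_high")  # site S1 positive via its second core
  expect_equal(pc$n_units, 2L)
})

test_that("cohort-wide classification partitions evaluable patients and logs exclusions", {
  co <- patient_cohort(list(P1 = c(0, 0), P2 = c(0, 100), P3 = c(50, 60),
                            P4 = NA_real_))
  pcs <- classify_patients(co, "DLL3")
  expect_equal(nrow(pcs), 3)
  expect_equal(attr(pcs, "excluded"), "P4")
  s <- attr(pcs, "summary")
  expect_equal(sum(s$n), 3)
  expect_equal(s$total, rep(3, 3))
  expect_error(classify_patient(co, "P4", "DLL3"),
               class = "tmahet_not_evaluable_error")
})

test_that("subtype positivity reports numerator, denominator and half-up percentage", {
  lab <- rep("AR-/NE+", 83)
  co <- joint_cohort(69, 0, 0, 14, marker_a = "DLL3", marker_b = "CEACAM5",
                     subtype_label = lab)
  sp <- subtype_positivity(co, "DLL3", "AR-/NE+")
  expect_equal(sp$n_positive, 69)
  expect_equal(sp$n_total, 83)
  expect_equal(sp$percentage, 83)
  sp0 <- subtype_positivity(joint_cohort(0, 0, 0, 10), "TROP2")
  expect_equal(sp0$percentage, 0)
})

test_that("patient-level any-site positivity counts a patient once", {
  co <- patient_cohort(list(P1 = c(0, 150), P2 = c(0, 0), P3 = c(30, 40)),
                       marker = "TROP2")
  sp <- subtype_positivity(co, "TROP2", unit = "patient")
  expect_equal(sp$n_positive, 2)
  expect_equal(sp$n_total, 3)
  expect_equal(sp$percentage, 67)
})
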